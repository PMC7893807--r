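# Test-result records share one shape so reports can flatten them.
test_result <- function(statistic_name, statistic, p_perm = NULL,
                        p_asymptotic = NULL, n_permutations = NULL,
                        seed = NULL, ...) {
  c(list(statistic_name = statistic_name, statistic = statistic,
         p_perm = p_perm, p_asymptotic = p_asymptotic,
         n_permutations = n_permutations, seed = seed), list(...))
}

# Tie-corrected Kruskal-Wallis H from precomputed ranks. `g` is an integer
# group index vector; `n_per` its group sizes; `tie_factor` the constant
# 1 - sum(t^3 - t)/(N^3 - N) for the rank vector.
kw_h_from_ranks <- function(ranks, g, n_per, tie_factor) {
  N <- length(ranks)
  rank_sums <- rowsum(ranks, g, reorder = TRUE)[, 1]
  h <- 12 / (N * (N + 1)) * sum(rank_sums^2 / n_per) - 3 * (N + 1)
  if (tie_factor > 0) h / tie_factor else 0
}

#' Permutation Kruskal-Wallis test
#'
#' Computes the tie-corrected Kruskal-Wallis H statistic and a permutation
#' p-value from `B` random shuffles of the group labels, using the add-one
#' estimator p = (1 + #\{H_b >= H_obs\}) / (1 + B) so p is never zero. The
#' asymptotic chi-square p-value is reported alongside.
#'
#' @param values Numeric vector.
#' @param group_labels Vector of group labels, same length, >= 2 non-empty
#'   groups.
#' @param B Number of permutations (default 5000).
#' @param seed Integer seed; the permutation p is exactly reproducible from
#'   `(seed, B)`.
#' @return A test-result list: `statistic` (H), `p_perm`, `p_asymptotic`,
#'   `n_permutations`, `seed`, `df`.
#' @export
kruskal_wallis_perm <- function(values, group_labels, B = 5000, seed = 1) {
  stopifnot(length(values) == length(group_labels))
  keep <- !is.na(values) & !is.na(group_labels)
  values <- values[keep]
  g <- factor(group_labels[keep])
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(g) == 0)) stop("empty group", call. = FALSE)
  N <- length(values)
  ranks <- rank(values)
  ties <- table(ranks)
  tie_factor <- 1 - sum(ties^3 - ties) / (N^3 - N)
  gi <- as.integer(g)
  n_per <- tabulate(gi, nlevels(g))
  h_obs <- kw_h_from_ranks(ranks, gi, n_per, tie_factor)
  h_perm <- withr_seed(seed, {
    vapply(seq_len(B), function(b) {
      kw_h_from_ranks(ranks, gi[sample.int(N)], n_per, tie_factor)
    }, numeric(1))
  })
  test_result("kruskal_wallis_H", h_obs,
              p_perm = (1 + sum(h_perm >= h_obs)) / (1 + B),
              p_asymptotic = stats::pchisq(h_obs, df = nlevels(g) - 1,
                                           lower.tail = FALSE),
              n_permutations = B, seed = seed, df = nlevels(g) - 1,
              n = N)
}

#' Permutation Spearman correlation
#'
#' Spearman rho with average-rank ties; two-sided permutation p-value from
#' `B` shuffles of `y`, add-one estimator. A constant input vector yields
#' rho 0 with a `degenerate` flag.
#'
#' @param x,y Paired numeric vectors, n >= 5 after NA removal.
#' @param B Number of permutations (default 5000).
#' @param seed Integer seed.
#' @return A test-result list with `statistic` (rho), `p_perm`,
#'   `p_asymptotic` (t approximation), `degenerate`.
#' @export
spearman_perm <- function(x, y, B = 5000, seed = 1) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("need >= 5 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(test_result("spearman_rho", 0, p_perm = 1, n_permutations = B,
                       seed = seed, degenerate = TRUE, n = n))
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  rho_perm <- withr_seed(seed, {
    vapply(seq_len(B), function(b) stats::cor(rx, ry[sample.int(n)]),
           numeric(1))
  })
  tstat <- rho_obs * sqrt((n - 2) / (1 - rho_obs^2 + 1e-300))
  test_result("spearman_rho", rho_obs,
              p_perm = (1 + sum(abs(rho_perm) >= abs(rho_obs) - 1e-12)) /
                (1 + B),
              p_asymptotic = 2 * stats::pt(abs(tstat), df = n - 2,
                                           lower.tail = FALSE),
              n_permutations = B, seed = seed, degenerate = FALSE, n = n)
}

#' Odds ratio with Fisher exact test
#'
#' Sample odds ratio (a*d)/(b*c) of a 2x2 table. With any zero cell the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied and flagged.
#' The two-sided Fisher exact p sums hypergeometric probabilities no larger
#' than that of the observed table.
#'
#' @param t A [contingency_2x2()] table.
#' @return List: `odds_ratio`, `fisher_p`, `corrected` flag, `table`.
#' @export
odds_ratio <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  m <- unclass(t)
  corrected <- any(m == 0)
  mm <- if (corrected) m + 0.5 else m
  or <- (mm[1, 1] * mm[2, 2]) / (mm[1, 2] * mm[2, 1])
  p <- stats::fisher.test(m)$p.value
  list(odds_ratio = or, fisher_p = p, corrected = corrected, table = m,
       statistic_name = "odds_ratio", statistic = or, p_asymptotic = p)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Closed-form N(ad - bc)^2 / (r1 r2 c1 c2) with df = 1; optional Yates
#' continuity correction (|ad - bc| reduced by N/2, floored at 0).
#'
#' @param t A [contingency_2x2()] table.
#' @param yates Apply the continuity correction (default FALSE).
#' @return A test-result list with `statistic` (chi-square),
#'   `p_asymptotic`, `df`.
#' @export
chi_square <- function(t, yates = FALSE) {
  stopifnot(inherits(t, "contingency_2x2"))
  m <- unclass(t)
  r <- rowSums(m); cs <- colSums(m); N <- sum(m)
  if (any(r == 0) || any(cs == 0))
    stop("empty margin: expected cell count 0", call. = FALSE)
  delta <- abs(m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
  if (yates) delta <- max(0, delta - N / 2)
  stat <- N * delta^2 / (r[1] * r[2] * cs[1] * cs[2])
  test_result("chi_square", unname(stat),
              p_asymptotic = stats::pchisq(stat, df = 1, lower.tail = FALSE),
              df = 1, yates = yates)
}

#' Dominance-flip test for an opposite-pattern genus pair
#'
#' Classifies every sample by whether genus `genus_a` dominates `genus_b`
#' in relative abundance — ratio (a + eps)/(b + eps) > 1 with eps equal to
#' half the smallest nonzero relative abundance in the table — and
#' cross-tabulates dominance against the two subtypes, testing association
#' with [chi_square()].
#'
#' @param table An `abundance_table`.
#' @param genus_a,genus_b Genus ids present in the table.
#' @param assignment A subtype assignment (see [cluster_subtypes()]) or a
#'   named vector of labels.
#' @return List: `contingency` (2x2: subtype x dominance), `test`, `ratio`
#'   (per-sample abundance ratios), `epsilon`.
#' @export
opposite_pattern_test <- function(table, genus_a, genus_b, assignment) {
  stopifnot(inherits(table, "abundance_table"))
  miss <- setdiff(c(genus_a, genus_b), colnames(table))
  if (length(miss) > 0)
    stop("genus missing from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rel <- to_relative(table)
  m <- unclass(rel)
  nz <- m[m > 0]
  if (length(nz) == 0) stop("empty abundance table", call. = FALSE)
  eps <- min(nz) / 2
  labels <- assignment_labels(assignment)
  ids <- intersect(rownames(m), names(labels))
  ratio <- (m[ids, genus_a] + eps) / (m[ids, genus_b] + eps)
  dom <- ratio > 1
  lab <- factor(labels[ids], levels = c("mp1", "mp2"))
  ct <- contingency_2x2(sum(dom & lab == "mp1"), sum(!dom & lab == "mp1"),
                        sum(dom & lab == "mp2"), sum(!dom & lab == "mp2"))
  list(contingency = ct, test = chi_square(ct), ratio = ratio, epsilon = eps)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate correction with monotonicity enforcement;
#' input order is preserved. Inputs must lie in (0, 1].
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Clinical, severity, and brain comparisons between subtypes
#'
#' Runs the full between-subtype statistical profile: permutation
#' Kruskal-Wallis tests of CARS total, ADOS total, items scored >= 3 and
#' the three CARS domain scores; a severity-by-subtype odds ratio with
#' Fisher exact p; and, when brain volumes are supplied, per-region
#' Kruskal-Wallis tests BH-adjusted as one family plus Spearman
#' correlations of each flagged region (BH-adjusted p < `alpha`) with the
#' distorted-sensory-response score within each subtype. Samples missing a
#' value (ADOS, imaging) are dropped from the affected test only; each
#' record carries its effective n.
#'
#' @param metadata Metadata data frame (see [read_metadata()]).
#' @param assignment Subtype assignment from [cluster_subtypes()] or a
#'   named label vector.
#' @param brain Optional samples x regions volume matrix.
#' @param B Permutations per test (default 5000).
#' @param seed Global seed; each constituent test gets a named substream.
#' @param alpha Flagging threshold for the brain family (default 0.05).
#' @return Nested report list with elements `clinical`, `severity`, and
#'   optionally `brain`.
#' @export
group_profile <- function(metadata, assignment, brain = NULL, B = 5000,
                          seed = 1, alpha = 0.05) {
  labels <- assignment_labels(assignment)
  ids <- intersect(metadata$sample_id, names(labels))
  if (length(ids) < length(labels))
    message("dropping ", length(labels) - length(ids),
            " assigned sample(s) absent from metadata")
  md <- metadata[match(ids, metadata$sample_id), ]
  lab <- labels[ids]
  dom <- score_domains(md)
  vars <- list(cars_total = md$cars_total, ados_total = md$ados_total,
               items_ge3 = dom$items_ge3,
               social_impairment = dom$social_impairment,
               negative_emotionality = dom$negative_emotionality,
               distorted_sensory_response = dom$distorted_sensory_response)
  clinical <- lapply(names(vars), function(v) {
    kruskal_wallis_perm(vars[[v]], lab, B = B,
                        seed = substream_seed(seed, paste0("clinical.", v)))
  })
  names(clinical) <- names(vars)

  sev <- md$severity
  ct <- contingency_2x2(sum(lab == "mp1" & sev == "severe"),
                        sum(lab == "mp1" & sev != "severe"),
                        sum(lab == "mp2" & sev == "severe"),
                        sum(lab == "mp2" & sev != "severe"))
  report <- list(clinical = clinical,
                 severity = c(odds_ratio(ct), list(n = length(ids))))

  if (!is.null(brain)) {
    bids <- intersect(ids, rownames(brain))
    bm <- brain[bids, , drop = FALSE]
    blab <- lab[bids]
    regions <- colnames(bm)
    reg_tests <- lapply(regions, function(r) {
      kruskal_wallis_perm(bm[, r], blab, B = B,
                          seed = substream_seed(seed, paste0("brain.", r)))
    })
    names(reg_tests) <- regions
    raw_p <- vapply(reg_tests, function(t) t$p_perm, numeric(1))
    adj_p <- bh_adjust(raw_p)
    for (i in seq_along(reg_tests)) reg_tests[[i]]$p_bh <- adj_p[i]
    flagged <- regions[adj_p < alpha]
    sensory <- stats::setNames(dom$distorted_sensory_response, ids)
    correlations <- list()
    for (r in flagged) {
      for (sub in c("mp1", "mp2")) {
        sel <- bids[blab[bids] == sub]
        if (length(sel) >= 5) {
          correlations[[paste(r, sub, sep = ".")]] <-
            spearman_perm(bm[sel, r], sensory[sel], B = B,
                          seed = substream_seed(seed,
                                                paste0("corr.", r, ".", sub)))
        }
      }
    }
    report$brain <- list(regions = reg_tests, flagged = flagged,
                         sensory_correlations = correlations)
  }
  report
}
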
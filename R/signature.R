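# Behavioral variables entering the Spearman screen: CARS total, ADOS
# total, and the three CARS domain scores.
behavior_matrix <- function(metadata) {
  dom <- score_domains(metadata)
  cbind(cars_total = metadata$cars_total,
        ados_total = metadata$ados_total,
        social_impairment = dom$social_impairment,
        negative_emotionality = dom$negative_emotionality,
        distorted_sensory_response = dom$distorted_sensory_response)
}

# Plain Kruskal-Wallis H (tie corrected), no permutation: the greedy
# objective.
kw_h_stat <- function(values, groups) {
  g <- factor(groups)
  N <- length(values)
  ranks <- rank(values)
  ties <- table(ranks)
  tie_factor <- 1 - sum(ties^3 - ties) / (N^3 - N)
  kw_h_from_ranks(ranks, as.integer(g), tabulate(as.integer(g), nlevels(g)),
                  tie_factor)
}

#' Genus-wise Spearman association with behavioral variables
#'
#' For every genus, Spearman rho (average-rank ties) against each
#' behavioral variable; per variable, p-values are BH-adjusted across
#' genera. Each genus keeps its best absolute rho together with the
#' variable achieving it and that variable's adjusted p. A constant genus
#' column gets rho 0 and a degenerate flag.
#'
#' @param table An `abundance_table` (converted to relative abundances).
#' @param behaviors Numeric matrix of per-sample behavioral variables with
#'   column names, rows aligned to the table's samples; or a metadata data
#'   frame, from which CARS total, ADOS total and the three domain scores
#'   are derived.
#' @return Data frame, one row per genus: `genus`, `rho`, `variable`,
#'   `p_adjusted`, `degenerate`, sorted by decreasing `|rho|`.
#' @export
marginal_association <- function(table, behaviors) {
  stopifnot(inherits(table, "abundance_table"))
  if (nrow(table) < 8) stop("need >= 8 samples", call. = FALSE)
  if (is.data.frame(behaviors) && "cars_total" %in% names(behaviors)) {
    ids <- behaviors$sample_id
    behaviors <- behavior_matrix(behaviors)
    rownames(behaviors) <- ids
    behaviors <- behaviors[rownames(table), , drop = FALSE]
  }
  stopifnot(nrow(behaviors) == nrow(table), !is.null(colnames(behaviors)))
  rel <- to_relative(table)
  m <- unclass(rel)
  genera <- colnames(m)
  vars <- colnames(behaviors)
  rho <- matrix(0, length(genera), length(vars),
                dimnames = list(genera, vars))
  pval <- matrix(1, length(genera), length(vars),
                 dimnames = list(genera, vars))
  degen_genus <- apply(m, 2, stats::sd) == 0
  for (v in vars) {
    y <- behaviors[, v]
    ok <- !is.na(y)
    for (g in genera) {
      x <- m[ok, g]
      if (stats::sd(x) == 0 || stats::sd(y[ok]) == 0) next
      ct <- stats::cor.test(x, y[ok], method = "spearman", exact = FALSE)
      rho[g, v] <- unname(ct$estimate)
      pval[g, v] <- ct$p.value
    }
    pval[, v] <- bh_adjust(pmin(pmax(pval[, v], 1e-300), 1))
  }
  best <- apply(abs(rho), 1, which.max)
  out <- data.frame(genus = genera,
                    rho = rho[cbind(seq_along(genera), best)],
                    variable = vars[best],
                    p_adjusted = pval[cbind(seq_along(genera), best)],
                    degenerate = degen_genus,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-abs(out$rho), out$genus), ]
}

#' Greedy forward search for a behavior-associated genus signature
#'
#' Reconstructs the discovery procedure: genera are first screened by their
#' best absolute Spearman correlation with the behavioral variables (top
#' `pool` kept as candidates), then forward selection grows the signature
#' from the empty set. At each step every remaining candidate is tentatively
#' added, the samples are re-clustered into two subtypes on the tentative
#' signature (Bray-Curtis, average linkage), and the candidate maximizing
#' the Kruskal-Wallis H of `cars_total` across the two clusters is kept.
#' A clustering with a singleton cluster scores 0. Ties are broken by
#' higher marginal absolute rho, then lexicographic genus id.
#'
#' Stopping: with the default `stop = "target_size"` the search always
#' adds the argmax candidate until `target_size` genera are selected,
#' stopping early only when no candidate produces a scoreable (non-zero)
#' clustering. A single strongly shifted genus often yields a
#' presence/absence split whose severity separation no small superset can
#' beat, so requiring strict improvement (`stop = "no_improvement"`)
#' typically truncates the signature at one or two genera; that mode is
#' kept for the monotone-trace guarantee but is not the default.
#'
#' @param table An `abundance_table`.
#' @param metadata Metadata data frame with `sample_id` and `cars_total`
#'   (also supplies the screen's behavioral variables).
#' @param pool Candidate pool size from the marginal screen (default 30).
#' @param target_size Signature size to aim for (default 12).
#' @param min_cluster Smallest admissible cluster (default 2; a singleton
#'   scores 0).
#' @param stop Stopping rule: `"target_size"` (default) or
#'   `"no_improvement"` (strictly increasing objective trace).
#' @return List of class `signature_result`: `selected_genera` (in
#'   selection order), `objective_trace` (H after each addition),
#'   `marginal` (the screen table), `truncated` flag.
#' @export
greedy_search <- function(table, metadata, pool = 30, target_size = 12,
                          min_cluster = 2,
                          stop = c("target_size", "no_improvement")) {
  stop_rule <- match.arg(stop)
  stopifnot(inherits(table, "abundance_table"))
  md <- metadata[match(rownames(table), metadata$sample_id), ]
  if (anyNA(md$sample_id))
    stop("metadata missing sample(s) present in the table", call. = FALSE)
  marginal <- marginal_association(table, md)
  candidates <- utils::head(marginal$genus[!marginal$degenerate], pool)
  rho_of <- stats::setNames(abs(marginal$rho), marginal$genus)
  cars <- md$cars_total
  rel <- to_relative(table)

  # Tentative-signature clustering tolerates samples with zero subset
  # total (common for 1-2 genus candidates): their profiles stay zero and
  # the distance between two empty profiles is 0.
  objective <- function(sig) {
    m <- unclass(rel)[, sig, drop = FALSE]
    rs <- rowSums(m)
    pos <- rs > 0
    m[pos, ] <- m[pos, , drop = FALSE] / rs[pos]
    if (max(m) == 0) return(0)
    d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
    d[!is.finite(d)] <- 0
    if (max(d) == 0) return(0)
    cl <- upgma_cut2(d)$cluster
    if (min(tabulate(cl, 2)) < min_cluster) return(0)
    kw_h_stat(cars, cl)
  }

  selected <- character(0)
  trace <- numeric(0)
  current <- 0
  while (length(selected) < target_size && length(candidates) > 0) {
    scores <- vapply(candidates, function(g) objective(c(selected, g)),
                     numeric(1))
    best_score <- max(scores)
    if (length(selected) > 0 &&
        ((stop_rule == "no_improvement" && best_score <= current) ||
         best_score == 0)) break
    top <- candidates[scores == best_score]
    top <- top[order(-rho_of[top], top)]
    pick <- top[1]
    selected <- c(selected, pick)
    trace <- c(trace, best_score)
    current <- best_score
    candidates <- setdiff(candidates, pick)
  }
  truncated <- length(selected) < target_size
  if (truncated)
    warning(sprintf("signature stopped at %d of %d genera",
                    length(selected), target_size))
  structure(list(selected_genera = selected, objective_trace = trace,
                 marginal = marginal, truncated = truncated,
                 target_size = target_size, pool = pool),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat(sprintf("<signature_result> %d genera, final objective H = %.3f\n",
              length(x$selected_genera),
              if (length(x$objective_trace)) max(x$objective_trace) else 0))
  cat(paste(x$selected_genera, collapse = ", "), "\n")
  invisible(x)
}

#' Write a signature result as TSV
#' @param result A `signature_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signature <- function(result, path) {
  stopifnot(inherits(result, "signature_result"))
  idx <- match(result$selected_genera, result$marginal$genus)
  df <- data.frame(rank = seq_along(result$selected_genera),
                   genus = result$selected_genera,
                   marginal_rho = result$marginal$rho[idx],
                   variable = result$marginal$variable[idx],
                   p_adjusted = result$marginal$p_adjusted[idx],
                   objective = result$objective_trace)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
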
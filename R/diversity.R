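#' Bray-Curtis dissimilarity on a genus subset
#'
#' Computes d(u, v) = sum|u_i - v_i| / sum(u_i + v_i) between all sample
#' pairs over the selected genera. When a `genera` subset is given the
#' table is restricted to it and (for relative tables or
#' `renormalize = TRUE`) each row is renormalized to the subset, matching
#' ordination on a signature rather than the full community.
#'
#' @param table An `abundance_table`.
#' @param genera Optional character vector of genus ids to restrict to.
#' @param renormalize Renormalize rows to the selected subset (default TRUE).
#' @return Square symmetric matrix of dissimilarities with sample ids on
#'   both axes.
#' @export
bray_curtis <- function(table, genera = NULL, renormalize = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  m <- if (is.null(genera)) unclass(table)
       else unclass(subset_table(table, genera = genera))
  rs <- rowSums(m)
  zero <- which(rs == 0)
  if (length(zero) > 0)
    stop("sample(s) with zero total over selected genera: ",
         paste(rownames(m)[zero], collapse = ", "), call. = FALSE)
  if (renormalize) m <- m / rs
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  diag(d) <- 0
  d[d < 0] <- 0
  validate_distance_matrix(d)
}

#' Per-sample alpha diversity
#'
#' Reports observed features (genera with nonzero abundance), Shannon
#' entropy over nonzero proportions, Pielou evenness (Shannon divided by
#' log richness; undefined when fewer than two features are observed) and,
#' when a tree is supplied, Faith's phylogenetic diversity (total branch
#' length of the union of root-to-leaf paths of observed genera, rooted
#' convention).
#'
#' @param table An `abundance_table` (counts or relative).
#' @param tree Optional rooted [ape::phylo] whose leaves cover every genus
#'   observed in any sample.
#' @param base Logarithm base for Shannon entropy (default `exp(1)`;
#'   Pielou evenness is base-invariant).
#' @return Data frame with one row per sample: `sample_id`,
#'   `observed_features`, `shannon`, `pielou` (NA when undefined),
#'   `faith_pd` (absent without a tree).
#' @export
alpha_diversity <- function(table, tree = NULL, base = exp(1)) {
  stopifnot(inherits(table, "abundance_table"))
  m <- unclass(table)
  rs <- rowSums(m)
  if (any(rs == 0))
    stop("all-zero sample row(s): ",
         paste(rownames(m)[rs == 0], collapse = ", "), call. = FALSE)
  p <- m / rs
  observed <- as.integer(rowSums(m > 0))
  shannon <- vapply(seq_len(nrow(p)), function(i) {
    pi <- p[i, p[i, ] > 0]
    -sum(pi * log(pi, base = base))
  }, numeric(1))
  pielou <- ifelse(observed >= 2, shannon / log(observed, base = base),
                   NA_real_)
  out <- data.frame(sample_id = rownames(m), observed_features = observed,
                    shannon = shannon, pielou = pielou,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(tree)) {
    validate_tree(tree)
    out$faith_pd <- vapply(seq_len(nrow(m)), function(i) {
      faith_pd_one(colnames(m)[m[i, ] > 0], tree)
    }, numeric(1))
  }
  out
}

# Faith PD for one sample: total branch length of edges on any
# root-to-observed-leaf path.
faith_pd_one <- function(observed_genera, tree) {
  miss <- setdiff(observed_genera, tree$tip.label)
  if (length(miss) > 0)
    stop("genus observed but absent from tree: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(observed_genera) == 0) return(0)
  n_tip <- length(tree$tip.label)
  parent <- integer(n_tip + tree$Nnode)
  edge_len <- numeric(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_len[tree$edge[, 2]] <- tree$edge.length
  keep <- logical(n_tip + tree$Nnode)
  for (tip in match(observed_genera, tree$tip.label)) {
    node <- tip
    while (node != 0 && !keep[node]) {
      keep[node] <- TRUE
      node <- parent[node]
    }
  }
  sum(edge_len[keep])
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers -D^2/2 and eigendecomposes it. Axes with negative
#' eigenvalues (non-Euclidean dissimilarities such as Bray-Curtis produce
#' them) are recorded but dropped; `proportion_explained` is computed over
#' the positive eigenvalues only.
#'
#' @param dm Square symmetric dissimilarity matrix with ids.
#' @param n_axes Number of axes requested (default 2). If fewer positive
#'   eigenvalues exist the result is truncated with a warning.
#' @return List of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, sorted descending), `proportion_explained`.
#' @export
pcoa <- function(dm, n_axes = 2) {
  dm <- validate_distance_matrix(as.matrix(dm))
  n <- nrow(dm)
  if (n_axes > n - 1) stop("n_axes must be <= n_samples - 1", call. = FALSE)
  B <- -0.5 * dm^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))  # second sweep also restores the grand mean
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(eig$values > 1e-9 * max(abs(eig$values), 1e-300))
  k <- min(n_axes, length(pos))
  if (k < n_axes)
    warning(sprintf("only %d positive eigenvalue(s); returning %d axis/axes",
                    length(pos), k))
  coords <- eig$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(eig$values[pos[seq_len(k)]]), k)
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(
    coordinates = coords,
    eigenvalues = eig$values,
    proportion_explained =
      eig$values[pos[seq_len(k)]] / sum(eig$values[pos])),
    class = "pcoa_result")
}

#' Rarefy a count table to even depth
#'
#' Optional depth normalization: subsamples each sample's counts without
#' replacement to the minimum (or given) depth. Off by default throughout
#' the pipeline; provided because amplicon workflows differ on this.
#'
#' @param table An `abundance_table` in counts mode.
#' @param depth Target depth (default: minimum row sum).
#' @param seed Integer seed for the subsampling.
#' @return A rarefied counts-mode `abundance_table`.
#' @export
rarefy_table <- function(table, depth = NULL, seed = 1) {
  stopifnot(inherits(table, "abundance_table"),
            abundance_mode(table) == "counts")
  m <- unclass(table)
  if (is.null(depth)) depth <- min(rowSums(m))
  if (any(rowSums(m) < depth))
    stop("sample(s) shallower than target depth", call. = FALSE)
  out <- withr_seed(seed, {
    t(apply(m, 1, function(row) {
      picked <- sample(rep.int(seq_along(row), row), depth)
      tabulate(picked, nbins = length(row))
    }))
  })
  dimnames(out) <- dimnames(m)
  abundance_table(out, mode = "counts")
}

# Evaluate expr with a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
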
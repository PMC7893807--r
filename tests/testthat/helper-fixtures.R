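# Shared fixtures and brute-force oracles, built in code at test time.

# Small counts table with named axes.
tiny_table <- function(values, samples = NULL, genera = NULL,
                       mode = "counts") {
  m <- as.matrix(values)
  rownames(m) <- samples %||% sprintf("s%d", seq_len(nrow(m)))
  colnames(m) <- genera %||% sprintf("g%d", seq_len(ncol(m)))
  abundance_table(m, mode = mode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Metadata with prescribed CARS totals: items are constructed on the legal
# grid so that they sum to the requested total (total must be reachable,
# i.e. in [15, 60] and a multiple of 0.5).
made_metadata <- function(cars_totals, ids = NULL) {
  n <- length(cars_totals)
  ids <- ids %||% sprintf("s%d", seq_len(n))
  items <- t(vapply(cars_totals, function(tot) {
    stopifnot(tot >= 15, tot <= 60, abs(tot * 2 - round(tot * 2)) < 1e-9)
    x <- rep(1, 15)
    rem <- tot - 15
    for (j in seq_len(15)) {
      add <- min(3, rem)
      x[j] <- 1 + floor(add * 2) / 2
      rem <- rem - (x[j] - 1)
    }
    x
  }, numeric(15)))
  colnames(items) <- paste0("cars", 1:15)
  df <- data.frame(sample_id = ids, items, cars_total = rowSums(items),
                   ados_total = rep(16, n), age_years = rep(5, n),
                   sex = rep("male", n), stringsAsFactors = FALSE)
  gutsig:::validate_metadata(df)
}

# Brute-force average-linkage (UPGMA) agglomeration on a distance matrix.
# Returns merge heights in order and the two-cluster partition.
brute_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 2) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  # final merge height of the two remaining clusters
  heights <- c(heights, mean(d[clusters[[1]], clusters[[2]]]))
  part <- integer(n)
  part[clusters[[1]]] <- 1L
  part[clusters[[2]]] <- 2L
  list(heights = heights, partition = part)
}

# Brute-force kNN vote: exhaustive nearest-neighbor enumeration with the
# same tie rules (distance ties by training order, vote ties by the single
# nearest neighbor).
brute_knn <- function(query, train, labels, k, distance = "euclidean") {
  d <- apply(train, 1, function(tr) {
    if (distance == "euclidean") sqrt(sum((query - tr)^2))
    else sum(abs(query - tr)) / sum(query + tr)
  })
  ord <- order(d, seq_along(d))
  nn <- labels[ord[seq_len(k)]]
  counts <- table(nn)
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) == 1) winners else labels[ord[1]]
}

# Exhaustive two-sided Fisher exact p for a 2x2 table: enumerate all
# tables with the observed margins and sum hypergeometric probabilities
# no larger than the observed one.
brute_fisher <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, N - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
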
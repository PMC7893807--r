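# Deterministic named substreams from one global seed: a string hash mixed
# with the seed by a 31-multiplier LCG mod 2^31 - 1. Keeps derived seeds in
# 32-bit integer range and independent of evaluation order.
substream_seed <- function(seed, stream) {
  x <- as.numeric(seed) %% 2147483647
  for (c in utf8ToInt(as.character(stream)))
    x <- (x * 31 + c) %% 2147483647
  as.integer(x) + 1L
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples;
#' 1 for identical partitions, about 0 for independent ones. Used to score
#' cluster recovery against generator ground truth.
#'
#' @param labels_a,labels_b Vectors of equal length (any label type).
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (maxi - expected)
}
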
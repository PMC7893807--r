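#' CARS behavioral domain scoring
#'
#' The Childhood Autism Rating Scale has 15 items, each scored 1 to 4 in
#' half-point steps. Three behavioral domains are sums over item subsets:
#' distorted sensory response (items 7-9: visual, auditory and near-receptor
#' responsiveness), negative emotionality (items 3, 6, 10: affect,
#' adaptation to change, anxiety reaction), and social impairment (by
#' default items 1, 2, 4, 5 and 10-15). Item 10 contributes to two domains.
#' The item sets are configurable because the instrument's domain
#' definitions vary between sources.
#'
#' @param cars_items Numeric vector (length 15, items in order 1..15) or a
#'   matrix / data frame with columns `cars1`..`cars15`, values on the
#'   half-point grid.
#' @param social_items,negative_items,sensory_items Integer item indices
#'   defining each domain.
#' @return A data frame with columns `social_impairment`,
#'   `negative_emotionality`, `distorted_sensory_response`, `cars_total`
#'   and `items_ge3` (count of items scored >= 3).
#' @examples
#' score_domains(rep(2, 15))
#' @export
score_domains <- function(cars_items,
                          social_items = c(1, 2, 4, 5, 10:15),
                          negative_items = c(3, 6, 10),
                          sensory_items = 7:9) {
  items <- as_item_matrix(cars_items)
  grid <- seq(1, 4, by = 0.5)
  for (j in seq_len(15)) {
    off <- which(!items[, j] %in% grid)
    if (length(off) > 0)
      stop(sprintf("cars%d value %.2f is off the 1..4 half-point grid",
                   j, items[off[1], j]), call. = FALSE)
  }
  check_idx <- function(idx, what) {
    if (any(idx < 1 | idx > 15)) stop(what, " indices out of 1..15", call. = FALSE)
    idx
  }
  data.frame(
    social_impairment =
      rowSums(items[, check_idx(social_items, "social"), drop = FALSE]),
    negative_emotionality =
      rowSums(items[, check_idx(negative_items, "negative"), drop = FALSE]),
    distorted_sensory_response =
      rowSums(items[, check_idx(sensory_items, "sensory"), drop = FALSE]),
    cars_total = rowSums(items),
    items_ge3 = as.integer(rowSums(items >= 3)))
}

as_item_matrix <- function(cars_items) {
  if (is.data.frame(cars_items)) {
    miss <- setdiff(cars_item_cols(), names(cars_items))
    if (length(miss) > 0)
      stop("missing CARS item column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    return(as.matrix(cars_items[, cars_item_cols()]))
  }
  if (is.matrix(cars_items)) {
    if (ncol(cars_items) != 15) stop("need 15 item columns", call. = FALSE)
    return(cars_items)
  }
  if (length(cars_items) != 15) stop("need 15 item scores", call. = FALSE)
  matrix(cars_items, nrow = 1)
}

#' Severity stratum from the CARS total score
#'
#' Children scoring at or above the threshold (default 36, the cutoff used
#' to color severity in clustering heatmaps) are labelled `"severe"`,
#' otherwise `"mild_moderate"`.
#'
#' @param cars_total Numeric vector of CARS totals in \[15, 60\].
#' @param threshold Severity cutoff (default 36).
#' @return Character vector of labels.
#' @export
severity_label <- function(cars_total, threshold = 36) {
  if (any(cars_total < 15 | cars_total > 60))
    stop("cars_total outside [15, 60]", call. = FALSE)
  ifelse(cars_total >= threshold, "severe", "mild_moderate")
}
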
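#' Two-cluster microbiome subtyping
#'
#' Computes Bray-Curtis dissimilarity on the signature genera (rows
#' renormalized to the signature), agglomerates by average linkage (UPGMA)
#' and cuts the dendrogram at two clusters. The cluster with the lower mean
#' CARS total is labelled `mp1` (the less severe subpopulation, `mp2` being
#' the more severe); on a tied mean the larger cluster is `mp1`.
#'
#' @param table An `abundance_table` covering the samples to subtype.
#' @param signature Character vector of signature genus ids.
#' @param metadata Metadata data frame with `sample_id` and `cars_total`.
#' @return List of class `subtype_assignment`: `labels` (named character
#'   vector, `mp1`/`mp2`), `hclust` (the linkage record), `signature`,
#'   `labelling_rule`.
#' @export
cluster_subtypes <- function(table, signature, metadata) {
  stopifnot(inherits(table, "abundance_table"), length(signature) >= 1)
  if (nrow(table) < 4) stop("need >= 4 samples to subtype", call. = FALSE)
  d <- bray_curtis(table, genera = signature)
  if (max(d) == 0) stop("degenerate abundance data: all distances 0",
                        call. = FALSE)
  part <- upgma_cut2(d)
  labels <- label_by_severity(part, metadata)
  structure(list(labels = labels$labels, hclust = part$hc,
                 signature = signature,
                 labelling_rule = labels$rule),
            class = "subtype_assignment")
}

# Average-linkage clustering of a distance matrix, cut at 2 clusters.
# Returns the integer partition (cluster ids 1/2 keyed by sample) and the
# hclust record.
upgma_cut2 <- function(d) {
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, k = 2)
  list(cluster = cl, hc = hc)
}

label_by_severity <- function(part, metadata) {
  cl <- part$cluster
  cars <- stats::setNames(metadata$cars_total, metadata$sample_id)[names(cl)]
  m1 <- mean(cars[cl == 1], na.rm = TRUE)
  m2 <- mean(cars[cl == 2], na.rm = TRUE)
  if (isTRUE(all.equal(m1, m2))) {
    mp1_cluster <- if (sum(cl == 1) >= sum(cl == 2)) 1 else 2
    rule <- "tied mean cars_total; larger cluster is mp1"
  } else {
    mp1_cluster <- if (m1 < m2) 1 else 2
    rule <- "lower mean cars_total is mp1"
  }
  labels <- ifelse(cl == mp1_cluster, "mp1", "mp2")
  names(labels) <- names(cl)
  list(labels = labels, rule = rule)
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat(sprintf("<subtype_assignment> %d samples: mp1 = %d, mp2 = %d\n",
              length(x$labels), sum(x$labels == "mp1"),
              sum(x$labels == "mp2")))
  invisible(x)
}

# Accept either a subtype_assignment or a named label vector.
assignment_labels <- function(assignment) {
  if (inherits(assignment, "subtype_assignment")) return(assignment$labels)
  if (is.null(names(assignment)))
    stop("assignment must be a subtype_assignment or a named label vector",
         call. = FALSE)
  assignment
}

#' Fit a k-nearest-neighbors subtype classifier
#'
#' Stores signature-renormalized relative abundances of the training
#' samples plus their subtype labels. Prediction takes a majority vote
#' among the `k` nearest training rows; distance ties are broken by
#' training-row order and vote ties by the single nearest neighbor.
#'
#' @param table Training `abundance_table`.
#' @param signature Signature genus ids.
#' @param labels Named subtype labels (or a `subtype_assignment`).
#' @param k Odd positive integer, `k <= n` training samples (default 3).
#' @param distance `"bray_curtis"` (default) or `"euclidean"`.
#' @return A `knn_model`.
#' @export
fit_knn <- function(table, signature, labels, k = 3,
                    distance = c("bray_curtis", "euclidean")) {
  distance <- match.arg(distance)
  labels <- assignment_labels(labels)
  if (k < 1 || k %% 2 == 0) stop("k must be odd and positive", call. = FALSE)
  if (k > length(labels)) stop("k > number of training samples", call. = FALSE)
  rel <- signature_profile(table, signature)
  ids <- intersect(rownames(rel), names(labels))
  structure(list(train = rel[ids, , drop = FALSE],
                 labels = labels[ids], k = as.integer(k),
                 distance = distance, signature = signature),
            class = "knn_model")
}

# Relative abundance over the signature genera, renormalized to the subset.
# Genera absent from the table are imputed as zero with a warning.
signature_profile <- function(table, signature) {
  stopifnot(inherits(table, "abundance_table"))
  m <- unclass(table)
  missing <- setdiff(signature, colnames(m))
  if (length(missing) > 0) {
    warning("signature genera absent from table, imputing zeros: ",
            paste(missing, collapse = ", "))
    zeros <- matrix(0, nrow(m), length(missing),
                    dimnames = list(rownames(m), missing))
    m <- cbind(m, zeros)
  }
  m <- m[, signature, drop = FALSE]
  rs <- rowSums(m)
  if (any(rs == 0))
    stop("sample(s) with zero total over signature genera: ",
         paste(rownames(m)[rs == 0], collapse = ", "), call. = FALSE)
  m / rs
}

row_distances <- function(query, train, distance) {
  if (distance == "euclidean")
    return(sqrt(colSums((t(train) - query)^2)))
  # Bray-Curtis between one query row and every training row
  apply(train, 1, function(tr) sum(abs(query - tr)) / sum(query + tr))
}

#' Predict subtypes with a fitted kNN model
#'
#' @param object A `knn_model` from [fit_knn()].
#' @param table An `abundance_table` of new samples (or a plain matrix of
#'   signature-renormalized profiles).
#' @param ... Unused.
#' @return Named character vector of predicted labels.
#' @export
predict.knn_model <- function(object, table, ...) {
  profiles <- if (inherits(table, "abundance_table"))
    signature_profile(table, object$signature)
  else table
  out <- vapply(seq_len(nrow(profiles)), function(i) {
    knn_vote(profiles[i, ], object$train, object$labels, object$k,
             object$distance)
  }, character(1))
  names(out) <- rownames(profiles)
  out
}

knn_vote <- function(query, train, labels, k, distance) {
  d <- row_distances(query, train, distance)
  ord <- order(d, seq_along(d))  # stable: distance ties by training order
  nn <- ord[seq_len(k)]
  votes <- table(labels[nn])
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1) top else labels[ord[1]]
}

#' Leave-one-out cross-validated accuracy
#'
#' Each sample is predicted by a kNN model trained on the remaining n - 1
#' with the supplied (fixed) subtype labels; accuracy is the fraction
#' predicted correctly. Note the labels come from clustering the full set,
#' mirroring the usual discovery-cohort evaluation, so this measures label
#' reproducibility rather than fully out-of-sample accuracy.
#'
#' @inheritParams fit_knn
#' @return List: `accuracy` in \[0, 1\], `predicted` (named labels), `k`.
#' @export
loocv_accuracy <- function(table, signature, labels, k = 3,
                           distance = c("bray_curtis", "euclidean")) {
  distance <- match.arg(distance)
  labels <- assignment_labels(labels)
  rel <- signature_profile(table, signature)
  ids <- intersect(rownames(rel), names(labels))
  rel <- rel[ids, , drop = FALSE]
  lab <- labels[ids]
  n <- length(ids)
  if (n < k + 1) stop("need n >= k + 1 samples for LOOCV", call. = FALSE)
  pred <- vapply(seq_len(n), function(i) {
    knn_vote(rel[i, ], rel[-i, , drop = FALSE], lab[-i], k, distance)
  }, character(1))
  names(pred) <- ids
  list(accuracy = mean(pred == lab), predicted = pred, k = k,
       distance = distance)
}

#' Serialize / restore a kNN model as structured text
#'
#' The model (training profiles, labels, k, distance, signature) round
#' trips through a versioned JSON file so a discovery run can hand its
#' classifier to a later cohort.
#'
#' @param model A `knn_model`.
#' @param path Output path.
#' @return `write_knn_model` invisibly returns `path`; `read_knn_model`
#'   returns the restored `knn_model`.
#' @export
write_knn_model <- function(model, path) {
  stopifnot(inherits(model, "knn_model"))
  payload <- list(format_version = 1L,
                  signature = model$signature,
                  k = model$k, distance = model$distance,
                  sample_ids = rownames(model$train),
                  labels = unname(model$labels),
                  train = apply(model$train, 1, as.numeric,
                                simplify = FALSE))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_knn_model
#' @export
read_knn_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  train <- do.call(rbind, p$train)
  dimnames(train) <- list(p$sample_ids, p$signature)
  structure(list(train = train,
                 labels = stats::setNames(p$labels, p$sample_ids),
                 k = as.integer(p$k), distance = p$distance,
                 signature = p$signature),
            class = "knn_model")
}
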
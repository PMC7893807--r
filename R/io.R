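#' Read sample metadata with CARS items
#'
#' The metadata TSV must contain `sample_id`, the 15 CARS items
#' (`cars1`..`cars15`), `cars_total`, `ados_total`, `age_years` and `sex`.
#' `ados_total` may be missing (NA) for individual samples; every other
#' field is required. Item scores must lie on the half-point grid
#' 1, 1.5, ..., 4 and `cars_total` must equal the item sum.
#'
#' @param path Path to a tab-delimited file.
#' @return A `data.frame`, one row per sample, with a derived `severity`
#'   column (see [severity_label()]).
#' @export
read_metadata <- function(path) {
  df <- read_tsv_strict(path)
  validate_metadata(df)
}

cars_item_cols <- function() paste0("cars", 1:15)

validate_metadata <- function(df) {
  required <- c("sample_id", cars_item_cols(), "cars_total", "ados_total",
                "age_years", "sex")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop("metadata missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  grid <- seq(1, 4, by = 0.5)
  for (col in cars_item_cols()) {
    v <- df[[col]]
    if (anyNA(v)) stop("missing values in ", col, call. = FALSE)
    off <- which(!v %in% grid)
    if (length(off) > 0)
      stop(sprintf("item %s off the 1..4 half-point grid for sample '%s'",
                   col, df$sample_id[off[1]]), call. = FALSE)
  }
  items <- as.matrix(df[, cars_item_cols()])
  tot <- rowSums(items)
  bad <- which(abs(tot - df$cars_total) > 1e-9)
  if (length(bad) > 0)
    stop(sprintf("cars_total != sum of items for sample '%s'",
                 df$sample_id[bad[1]]), call. = FALSE)
  if (!all(df$sex %in% c("female", "male")))
    stop("sex must be 'female' or 'male'", call. = FALSE)
  if (any(df$age_years <= 0))
    stop("age_years must be positive", call. = FALSE)
  if (any(!is.na(df$ados_total) & df$ados_total < 0))
    stop("ados_total must be >= 0", call. = FALSE)
  df$severity <- severity_label(df$cars_total)
  df
}

#' Write sample metadata to TSV
#' @param metadata Metadata data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny over genera from Newick
#'
#' Thin validating wrapper around [ape::read.tree()]. Leaves must be
#' uniquely labelled and all branch lengths non-negative; these are the
#' preconditions of Faith's phylogenetic diversity.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file ", path, call. = FALSE)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("tree has unlabeled leaves", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels in tree", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch length in tree", call. = FALSE)
  tree
}

#' Read brain-region volumes
#'
#' TSV with `sample_id` first, one column per region, volumes in mm^3.
#' Volumes must be positive; NA marks samples without imaging.
#'
#' @param path Path to a tab-delimited file.
#' @return A numeric matrix, samples x regions.
#' @export
read_brain_volumes <- function(path) {
  df <- read_tsv_strict(path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  validate_brain_volumes(m)
}

validate_brain_volumes <- function(m) {
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("duplicate ids in brain volume table", call. = FALSE)
  if (any(!is.na(m) & m <= 0))
    stop("brain volumes must be positive (mm^3)", call. = FALSE)
  m
}

#' Construct a validated 2x2 contingency table
#'
#' Rows are groups (e.g. the two subpopulations), columns outcomes
#' (e.g. severe / mild-moderate).
#'
#' @param a,b,c,d Non-negative integer counts: `a`,`b` the first row,
#'   `c`,`d` the second.
#' @return A 2x2 integer matrix of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (anyNA(x) || any(x < 0) || any(abs(x - round(x)) > 1e-9))
    stop("contingency counts must be non-negative integers", call. = FALSE)
  m <- matrix(as.integer(round(x)), 2, 2, byrow = TRUE)
  if (all(rowSums(m) == 0) || all(colSums(m) == 0))
    stop("contingency table needs at least one nonzero row and column",
         call. = FALSE)
  structure(m, class = c("contingency_2x2", "matrix", "array"))
}

#' Read/write a square distance matrix as TSV
#'
#' The file has an id header row and an id first column; the matrix must be
#' symmetric with zero diagonal.
#'
#' @param path File path.
#' @return A `dist`-compatible square matrix with ids on both axes.
#' @export
read_distance_matrix <- function(path) {
  df <- read_tsv_strict(path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  validate_distance_matrix(m)
}

validate_distance_matrix <- function(m) {
  if (!identical(rownames(m), colnames(m)))
    stop("distance matrix row and column ids differ", call. = FALSE)
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be 0", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-12)
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(m < 0)) stop("negative distances", call. = FALSE)
  m
}

#' @rdname read_distance_matrix
#' @param dm Square symmetric matrix with matching dimnames.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm), dm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report
#'
#' Emits two artifacts: a machine-readable JSON file (`<path>.json`) with
#' the full nested report, and a flat TSV (`<path>.tsv`) of the test
#' statistics for spreadsheet use.
#'
#' @param report A list as produced by [group_profile()] or
#'   [run_discovery()]; any element named `tests` (a data frame) goes to
#'   the flat TSV.
#' @param path Output stem (extensions are appended).
#' @return Invisibly, the two paths written.
#' @export
write_results <- function(report, path) {
  json_path <- paste0(path, ".json")
  tsv_path <- paste0(path, ".tsv")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  tests <- collect_tests(report)
  utils::write.table(tests, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json = json_path, tsv = tsv_path))
}

# Pull every test_result-shaped record out of a nested report list.
collect_tests <- function(report) {
  rows <- list()
  walk <- function(x, label) {
    if (is.list(x) && !is.null(x$statistic_name)) {
      rows[[length(rows) + 1]] <<- data.frame(
        test = label,
        statistic = x$statistic_name,
        value = x$statistic,
        p_perm = if (is.null(x$p_perm)) NA_real_ else x$p_perm,
        p_asymptotic = if (is.null(x$p_asymptotic)) NA_real_ else x$p_asymptotic,
        n_permutations = if (is.null(x$n_permutations)) NA_integer_
                         else x$n_permutations,
        seed = if (is.null(x$seed)) NA_integer_ else x$seed,
        stringsAsFactors = FALSE)
    } else if (is.list(x)) {
      for (nm in names(x))
        walk(x[[nm]], if (nzchar(label)) paste(label, nm, sep = ".") else nm)
    }
  }
  walk(report, "")
  if (length(rows) == 0)
    return(data.frame(test = character(), statistic = character(),
                      value = numeric(), p_perm = numeric(),
                      p_asymptotic = numeric(), n_permutations = integer(),
                      seed = integer()))
  do.call(rbind, rows)
}

#' Read back a JSON report written by [write_results()]
#' @param path The `.json` path.
#' @return The report list.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
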
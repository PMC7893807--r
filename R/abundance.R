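#' Construct a validated abundance table
#'
#' The central input of the pipeline: a samples x genera matrix of
#' non-negative counts or relative abundances with named, unique axes.
#'
#' @param values Numeric matrix, samples in rows, genera in columns, with
#'   both dimnames set.
#' @param mode Either `"counts"` or `"relative"`. In relative mode every
#'   row must sum to 1 within 1e-6.
#' @return An object of class `abundance_table`: the validated matrix with
#'   a `mode` attribute.
#' @export
abundance_table <- function(values, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance matrix needs sample (row) and genus (column) names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate genus ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyNA(values))
    stop("abundance values must not be missing", call. = FALSE)
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative abundance at sample '%s', genus '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]),
         call. = FALSE)
  if (mode == "relative") {
    rs <- rowSums(values)
    bad <- which(abs(rs - 1) > 1e-6)
    if (length(bad) > 0)
      stop(sprintf("row sum != 1 for relative-mode sample '%s' (sum %.6f)",
                   rownames(values)[bad[1]], rs[bad[1]]), call. = FALSE)
  }
  structure(values, mode = mode, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d genera, mode = %s\n",
              nrow(x), ncol(x), abundance_mode(x)))
  invisible(x)
}

#' Mode of an abundance table ("counts" or "relative")
#' @param table An `abundance_table`.
#' @return Character scalar.
#' @export
abundance_mode <- function(table) attr(table, "mode")

# Subset an abundance table keeping class/mode; validation re-applied by
# callers that renormalize.
subset_table <- function(table, samples = rownames(table),
                         genera = colnames(table)) {
  missing_g <- setdiff(genera, colnames(table))
  if (length(missing_g) > 0)
    stop("genera absent from table: ", paste(missing_g, collapse = ", "),
         call. = FALSE)
  missing_s <- setdiff(samples, rownames(table))
  if (length(missing_s) > 0)
    stop("samples absent from table: ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  m <- unclass(table)[samples, genera, drop = FALSE]
  structure(m, mode = abundance_mode(table),
            class = c("abundance_table", "matrix", "array"))
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its total so rows sum to one.
#'
#' @param table An `abundance_table` in counts mode (a relative-mode table
#'   is returned unchanged).
#' @return An `abundance_table` with `mode = "relative"`.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (abundance_mode(table) == "relative") return(table)
  rs <- rowSums(table)
  zero <- which(rs == 0)
  if (length(zero) > 0)
    stop("all-zero sample row(s): ",
         paste(rownames(table)[zero], collapse = ", "), call. = FALSE)
  abundance_table(unclass(table) / rs, mode = "relative")
}

#' Read an abundance table from TSV
#'
#' Expects a header row; by default the first column holds sample ids and
#' remaining columns genera. With `orientation = "genera_as_rows"` the file
#' is transposed after reading (first column genus ids, columns samples).
#'
#' @param path Path to a tab-delimited UTF-8 file.
#' @param orientation `"samples_as_rows"` (default) or `"genera_as_rows"`.
#' @param mode `"auto"` (counts iff all values are whole numbers),
#'   `"counts"`, or `"relative"`.
#' @return An `abundance_table`.
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples_as_rows",
                                                 "genera_as_rows"),
                                 mode = c("auto", "counts", "relative")) {
  orientation <- match.arg(orientation)
  mode <- match.arg(mode)
  df <- read_tsv_strict(path)
  if (ncol(df) < 2)
    stop("abundance TSV needs an id column plus at least one data column",
         call. = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric abundance values in ", path, call. = FALSE)
  rownames(m) <- ids
  if (orientation == "genera_as_rows") m <- t(m)
  if (mode == "auto")
    mode <- if (all(abs(m - round(m)) < 1e-9)) "counts" else "relative"
  abundance_table(m, mode = mode)
}

#' Write an abundance table to TSV
#' @param table An `abundance_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(sample_id = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Strict TSV reader: refuses ragged rows, reporting the offending line.
read_tsv_strict <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2) stop("TSV '", path, "' has no data rows", call. = FALSE)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nfield != nfield[1])
  if (length(bad) > 0)
    stop(sprintf("ragged TSV '%s': line %d has %d fields, header has %d",
                 path, bad[1], nfield[bad[1]], nfield[1]), call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
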
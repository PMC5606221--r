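#' Construct a features-by-samples data matrix
#'
#' Light wrapper around a numeric matrix that records whether entries are
#' counts, continuous measurements, or binary indicators, and carries feature
#' and sample identifiers. All dissimilarity constructors accept either a
#' `buds_data` object or a plain matrix (rows = features, columns = samples).
#'
#' @param values numeric matrix, p features x n samples, no missing entries.
#' @param kind one of `"counts"`, `"continuous"`, `"binary"`.
#' @param feature_ids,sample_ids optional character labels; taken from
#'   `dimnames(values)` when present, otherwise generated.
#' @return an object of class `buds_data`: the matrix with `kind` attribute
#'   and complete dimnames.
#' @export
#' @examples
#' X <- data_matrix(matrix(rpois(60, 3), nrow = 10), kind = "counts")
data_matrix <- function(values, kind = c("counts", "continuous", "binary"),
                        feature_ids = NULL, sample_ids = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (anyNA(values)) stop("missing entries are not allowed")
  if (ncol(values) < 4L) stop("need at least 4 samples (columns)")
  if (kind == "binary" && !all(values %in% c(0, 1)))
    stop("kind = 'binary' requires all entries in {0, 1}")
  if (is.null(feature_ids)) feature_ids <- rownames(values)
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(values, kind = kind, class = c("buds_data", "matrix", "array"))
}

#' @export
print.buds_data <- function(x, ...) {
  cat(sprintf("buds data matrix: %d features x %d samples (kind: %s)\n",
              nrow(x), ncol(x), attr(x, "kind")))
  invisible(x)
}

as_data_matrix <- function(X, kind = NULL) {
  if (inherits(X, "buds_data")) return(X)
  if (is.null(kind)) {
    kind <- if (all(X %in% c(0, 1))) "binary"
            else if (all(X >= 0 & X == round(X))) "counts"
            else "continuous"
  }
  data_matrix(X, kind = kind)
}

#' Read a data matrix from TSV/CSV
#'
#' Expects rows = features with the feature id in the first column and sample
#' ids in the header (the layout written by [write_data_matrix()]). Use
#' `transpose = TRUE` for samples-as-rows files.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @param kind passed to [data_matrix()]; guessed from the values if `NULL`.
#' @param transpose logical; transpose after reading.
#' @return a `buds_data` object.
#' @export
read_data_matrix <- function(path, kind = NULL, transpose = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- read.delim(path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "double"
  if (transpose) m <- t(m)
  as_data_matrix(if (is.null(kind)) m else m, kind = kind)
}

#' @rdname read_data_matrix
#' @param X matrix or `buds_data` to write.
#' @export
write_data_matrix <- function(X, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(feature_id = rownames(X), as.data.frame(unclass(X)[,]),
                   check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
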
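## Dissimilarity constructors. All return a plain symmetric numeric matrix
## with zero diagonal, sample ids as dimnames, and attributes `metric` and
## `rank_transformed` — the observed data of the model.

new_dissimilarity <- function(values, sample_ids, metric,
                              rank_transformed = FALSE) {
  dimnames(values) <- list(sample_ids, sample_ids)
  attr(values, "metric") <- metric
  attr(values, "rank_transformed") <- rank_transformed
  values
}

#' Validate a dissimilarity matrix
#'
#' Checks symmetry, zero diagonal and non-negativity; used internally by every
#' consumer of a dissimilarity matrix. Accepts `dist` objects and coerces them.
#'
#' @param D square numeric matrix or `dist` object.
#' @param tol symmetry tolerance.
#' @return the validated matrix (invisibly its input, coerced to matrix).
#' @export
check_dissimilarity <- function(D, tol = 1e-8) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || !is.numeric(D)) stop("'D' must be a numeric matrix")
  if (nrow(D) != ncol(D)) stop("'D' must be square")
  if (max(abs(D - t(D))) > tol) stop("'D' must be symmetric")
  if (any(diag(D) != 0)) stop("'D' must have a zero diagonal")
  if (any(D < 0)) stop("'D' must be nonnegative")
  if (is.null(rownames(D))) {
    ids <- paste0("s", seq_len(nrow(D)))
    dimnames(D) <- list(ids, ids)
  }
  (D + t(D)) / 2
}

sample_ids_of <- function(X) colnames(X)

#' Jaccard dissimilarity between samples
#'
#' Presence/absence Jaccard distance between the columns of a features x
#' samples matrix: \eqn{d_{ij} = 1 - |supp_i \cap supp_j| / |supp_i \cup
#' supp_j|}. Counts are thresholded at `> 0` first. A pair of samples that are
#' both entirely absent is assigned distance 0 by convention. Robust to noise
#' on sparse composition data such as 16S OTU tables.
#'
#' @param X `buds_data` or matrix with kind counts or binary.
#' @return symmetric n x n dissimilarity matrix (attribute `metric = "jaccard"`).
#' @export
#' @examples
#' X <- matrix(c(1,0,1, 1,1,0, 0,0,0, 1,0,1), nrow = 3)
#' jaccard_matrix(X)
jaccard_matrix <- function(X) {
  X <- as_data_matrix(X)
  if (attr(X, "kind") == "continuous")
    stop("Jaccard distance expects counts or binary data")
  B <- unclass(X) > 0
  if (!any(B)) stop("all-zero matrix carries no presence/absence information")
  ## empty sites are legal here (handled by the convention below)
  D <- as.matrix(suppressWarnings(
    vegan::vegdist(t(B * 1), method = "jaccard", binary = TRUE)))
  D[!is.finite(D)] <- 0
  empty <- colSums(B) == 0L
  if (any(empty)) {            # both-empty pairs: no information, distance 0
    ee <- outer(empty, empty, "&")
    D[ee] <- 0
  }
  diag(D) <- 0
  new_dissimilarity(D, sample_ids_of(X), "jaccard")
}

#' Pearson correlation dissimilarity between samples
#'
#' \eqn{d_{ij} = (1 - \rho(x_i, x_j)) / 2} with \eqn{\rho} the Pearson
#' correlation between sample columns; lies in `[0, 1]`. Intended for
#' normalized, log-transformed expression data.
#'
#' @param X `buds_data` or numeric matrix (features x samples).
#' @return symmetric n x n dissimilarity matrix (attribute
#'   `metric = "correlation"`).
#' @export
correlation_distance_matrix <- function(X) {
  X <- as_data_matrix(X, kind = "continuous")
  v <- apply(unclass(X), 2, stats::var)
  if (any(v == 0))
    stop("constant sample column(s): ",
         paste(colnames(X)[v == 0], collapse = ", "))
  D <- (1 - stats::cor(unclass(X)[,])) / 2
  D <- pmin(pmax(D, 0), 1)
  diag(D) <- 0
  new_dissimilarity((D + t(D)) / 2, sample_ids_of(X), "correlation")
}

#' Kernel L1 dissimilarity between binary samples
#'
#' Normalized L1 (Hamming fraction) between binary columns:
#' \eqn{d_{ij} = p^{-1} \sum_k |x_{ik} - x_{jk}|}; lies in `[0, 1]`. Suited to
#' vote-type binary data. The name follows common usage for L1-kernel-induced
#' distances; the normalization by the feature count is this package's
#' reading, recorded in the `metric` attribute.
#'
#' @param X binary `buds_data` or matrix (features x samples).
#' @return symmetric n x n dissimilarity matrix (attribute
#'   `metric = "kernel_l1"`).
#' @export
kernel_l1_matrix <- function(X) {
  X <- as_data_matrix(X)
  if (!all(unclass(X) %in% c(0, 1))) stop("kernel L1 requires binary entries")
  D <- as.matrix(stats::dist(t(unclass(X)[,]), method = "manhattan")) / nrow(X)
  diag(D) <- 0
  new_dissimilarity(D, sample_ids_of(X), "kernel_l1")
}

#' Ordinal rank transform of a dissimilarity matrix
#'
#' Replaces each off-diagonal dissimilarity by
#' \eqn{\tilde d_{ij} = 1 - \sqrt{1 - rank(d_{ij})/m}} where ranks (average
#' ranks for ties) are taken over the \eqn{m = n(n-1)/2} upper-triangle values.
#' Spreads dissimilarities concentrated away from zero over `(0, 1]` while
#' preserving their ordering, in the spirit of ordinal multidimensional
#' scaling.
#'
#' @param D symmetric dissimilarity matrix.
#' @return transformed matrix with `rank_transformed = TRUE`.
#' @export
rank_transform <- function(D) {
  D <- check_dissimilarity(D)
  n <- nrow(D)
  up <- upper.tri(D)
  v <- D[up]
  m <- length(v)
  r <- rank(v, ties.method = "average")
  out <- matrix(0, n, n)
  out[up] <- 1 - sqrt(1 - r / m)
  out <- out + t(out)
  new_dissimilarity(out, rownames(D),
                    paste0(attr(D, "metric") %||% "custom", "+rank"),
                    rank_transformed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a square dissimilarity matrix as TSV
#'
#' @param path file path (TSV with header and rowname column of sample ids).
#' @return `read_dissimilarity`: validated matrix; `write_dissimilarity`:
#'   the path, invisibly.
#' @export
read_dissimilarity <- function(path) {
  tab <- read.delim(path, sep = "\t", check.names = FALSE, row.names = 1)
  D <- as.matrix(tab)
  if (!identical(rownames(D), colnames(D)))
    stop("row and column sample ids of the dissimilarity file do not match")
  check_dissimilarity(D)
}

#' @rdname read_dissimilarity
#' @param D matrix to write.
#' @export
write_dissimilarity <- function(D, path) {
  df <- data.frame(sample_id = rownames(D), as.data.frame(D[,]),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
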
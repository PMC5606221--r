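#' Seriate a data matrix by the latent ordering
#'
#' Orders heatmap columns by ascending \eqn{\hat\tau} and rows by the feature
#' score \eqn{z_k = \tilde x_k^T \hat\tau}, the dot product of the k-th row of
#' the column-normalized matrix \eqn{\tilde X} with the latent coordinates —
#' the mean location along the trajectory where feature k "resides". Data with
#' sequential feature turnover produce banded/triangular reordered matrices.
#'
#' @param X features x samples matrix or [data_matrix()].
#' @param tau_hat latent coordinates (e.g. `coef()` of a [buds()] fit).
#' @param normalize `"sum"` (columns scaled to unit sum, the composition
#'   view; default) or `"norm"` (unit Euclidean norm).
#' @return list of class `buds_seriation`: `row_order`, `col_order`, `z`.
#' @export
seriate <- function(X, tau_hat, normalize = c("sum", "norm")) {
  normalize <- match.arg(normalize)
  X <- as_data_matrix(X)
  V <- unclass(X)[,]
  if (ncol(V) != length(tau_hat)) stop("X not conformable with tau_hat")
  cs <- switch(normalize, sum = colSums(V),
               norm = sqrt(colSums(V^2)))
  if (any(cs == 0))
    stop("zero column(s) cannot be normalized: ",
         paste(colnames(V)[cs == 0], collapse = ", "))
  Xt <- sweep(V, 2, cs, "/")
  z <- as.vector(Xt %*% tau_hat)
  names(z) <- rownames(V)
  row_order <- order(z, seq_along(z))
  col_order <- order(tau_hat, seq_along(tau_hat))
  structure(list(row_order = row_order, col_order = col_order, z = z),
            class = "buds_seriation")
}

#' @export
print.buds_seriation <- function(x, ...) {
  cat(sprintf("seriation of %d features x %d samples; z range [%.3f, %.3f]\n",
              length(x$row_order), length(x$col_order), min(x$z), max(x$z)))
  invisible(x)
}

#' Association between the latent ordering and a sample covariate
#'
#' Spearman rank correlation (average ranks for ties) between \eqn{\hat\tau}
#' and a numeric covariate, plus the paired ranks for a rank-rank scatter.
#' High |rho| flags the covariate as a candidate driver of the dominant
#' gradient (e.g. water depth, age at collection).
#'
#' @param tau_hat latent coordinates.
#' @param covariate numeric vector, same length; ties allowed.
#' @return list with `rho` and a data.frame `ranks` (tau_rank, covariate_rank).
#' @export
covariate_association <- function(tau_hat, covariate) {
  if (length(covariate) != length(tau_hat))
    stop("covariate not conformable with tau_hat")
  if (stats::sd(covariate) == 0) stop("constant covariate")
  rho <- stats::cor(tau_hat, covariate, method = "spearman")
  list(rho = rho,
       ranks = data.frame(
         tau_rank = rank(tau_hat, ties.method = "average"),
         covariate_rank = rank(covariate, ties.method = "average")))
}

#' Smoothed trend of a feature along the latent ordering
#'
#' Locally weighted (LOESS, local linear) regression of one feature on
#' \eqn{\hat\tau}, evaluated on the sorted observed coordinates — the
#' feature-dynamics curve showing where along the gradient a gene switches on
#' or a taxon peaks.
#'
#' @param x_k feature values across samples.
#' @param tau_hat latent coordinates.
#' @param span smoother bandwidth in (0, 1], default 0.5.
#' @return list of class `buds_trend`: `grid` (sorted tau), `fitted`, `span`.
#' @export
feature_trend <- function(x_k, tau_hat, span = 0.5) {
  if (length(x_k) != length(tau_hat)) stop("lengths differ")
  if (length(x_k) < 5) stop("need at least 5 samples for a trend")
  if (span <= 0 || span > 1) stop("'span' must be in (0, 1]")
  grid <- sort(unique(tau_hat))   # strictly increasing evaluation grid
  if (stats::sd(x_k) == 0) {
    fitted <- rep(x_k[1], length(grid))
  } else {
    df <- data.frame(y = x_k, t = tau_hat)
    fit <- stats::loess(y ~ t, data = df, span = span, degree = 1,
                        surface = "direct",
                        family = "gaussian")
    fitted <- stats::predict(fit, newdata = data.frame(t = grid))
  }
  structure(list(grid = grid, fitted = as.numeric(fitted), span = span),
            class = "buds_trend")
}
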
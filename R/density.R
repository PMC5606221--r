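#' Density clouds and per-sample confidence contours in the compromise space
#'
#' Kernel density estimate (2D, normal kernel, normal-reference plug-in
#' bandwidth) over the pooled slice projections of a [distatis()] result —
#' the overall data-density cloud — plus, for each selected sample, a KDE over
#' that sample's `t` projected positions with highest-density contours at the
#' stated probability levels. Contour area measures location confidence: the
#' larger the isoline footprint, the less certain the sample's position.
#'
#' @param result a `buds_distatis` object (2-dimensional consensus).
#' @param selected sample ids (or indices) for per-sample contours.
#' @param levels highest-density probability levels, default
#'   `c(0.5, 0.8, 0.95)`.
#' @param gridsize KDE grid resolution per axis.
#' @return list of class `buds_density`: `grid` (list x, y), `density`
#'   (matrix, integrates to ~1), `bandwidth`, and `per_point_contours` — for
#'   each selected sample a list of contour polylines (`level`, `x`, `y`,
#'   `area`) plus a `degenerate` flag for point-mass projections.
#' @export
density_and_contours <- function(result, selected = NULL,
                                 levels = c(0.5, 0.8, 0.95),
                                 gridsize = 101) {
  stopifnot(inherits(result, "buds_distatis"))
  if (ncol(result$consensus) != 2)
    stop("density clouds require a 2D compromise (k = 2)")
  proj <- result$slice_projections
  t <- dim(proj)[1]; n <- dim(proj)[2]
  if (!is.null(selected) && t < 10)
    stop("per-point contours need at least 10 slices")
  ids <- rownames(result$consensus) %||% as.character(seq_len(n))
  pooled <- cbind(as.vector(proj[, , 1]), as.vector(proj[, , 2]))
  lims <- c(range(pooled[, 1]), range(pooled[, 2]))
  pad <- c(-1, 1, -1, 1) * 0.15 *
    c(diff(lims[1:2]), diff(lims[1:2]), diff(lims[3:4]), diff(lims[3:4]))
  lims <- lims + pad
  h <- c(MASS::bandwidth.nrd(pooled[, 1]), MASS::bandwidth.nrd(pooled[, 2]))
  kd <- MASS::kde2d(pooled[, 1], pooled[, 2], h = h, n = gridsize, lims = lims)
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  dens <- kd$z / (sum(kd$z) * cell)   # normalize on the grid
  out_contours <- list()
  if (!is.null(selected)) {
    if (is.numeric(selected)) selected <- ids[selected]
    for (id in selected) {
      j <- match(id, ids)
      if (is.na(j)) stop("unknown sample id: ", id)
      pts <- cbind(proj[, j, 1], proj[, j, 2])
      if (stats::sd(pts[, 1]) < 1e-12 && stats::sd(pts[, 2]) < 1e-12) {
        out_contours[[id]] <- list(degenerate = TRUE,
                                   center = colMeans(pts), polylines = list())
        next
      }
      hj <- c(MASS::bandwidth.nrd(pts[, 1]), MASS::bandwidth.nrd(pts[, 2]))
      hj[hj <= 0] <- max(hj, 1e-3) * 0.1 + 1e-6
      kj <- MASS::kde2d(pts[, 1], pts[, 2], h = hj, n = gridsize,
                        lims = c(range(pts[, 1]) + c(-4, 4) * hj[1],
                                 range(pts[, 2]) + c(-4, 4) * hj[2]))
      cj <- diff(kj$x[1:2]) * diff(kj$y[1:2])
      zj <- kj$z / (sum(kj$z) * cj)
      polylines <- list()
      for (lv in levels) {
        thr <- hdr_threshold(zj, cj, lv)
        cl <- grDevices::contourLines(kj$x, kj$y, zj, levels = thr)
        for (p in cl)
          polylines[[length(polylines) + 1L]] <-
            list(level = lv, x = p$x, y = p$y, area = polygon_area(p$x, p$y))
      }
      out_contours[[id]] <- list(degenerate = FALSE, center = colMeans(pts),
                                 polylines = polylines)
    }
  }
  structure(list(grid = list(x = kd$x, y = kd$y), density = dens,
                 bandwidth = h, levels = levels,
                 per_point_contours = out_contours),
            class = "buds_density")
}

## density threshold whose super-level set contains `mass` probability
hdr_threshold <- function(z, cell, mass) {
  zs <- sort(as.vector(z), decreasing = TRUE)
  cum <- cumsum(zs) * cell
  i <- which(cum >= mass)[1]
  if (is.na(i)) min(zs) else zs[i]
}

## shoelace formula (absolute value)
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Total contour area of a sample at one level
#'
#' Sums the polygon areas of all contour pieces at the given highest-density
#' level for one sample of a [density_and_contours()] result.
#'
#' @param field a `buds_density` object.
#' @param id sample id present in `field$per_point_contours`.
#' @param level one of the levels the field was built with.
#' @return numeric area (0 for degenerate point masses).
#' @export
contour_area <- function(field, id, level = 0.95) {
  pc <- field$per_point_contours[[id]]
  if (is.null(pc)) stop("no contours stored for sample ", id)
  if (isTRUE(pc$degenerate)) return(0)
  sum(vapply(pc$polylines,
             function(p) if (abs(p$level - level) < 1e-9) p$area else 0, 0))
}
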
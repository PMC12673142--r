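#' @include AllClasses.R utils.R
NULL

#' Mean fiducial marker error (MFME)
#'
#' Mean Euclidean distance between matched fiducial marker coordinates in
#' the two modalities after registration; indicates how accurately a
#' preoperatively planned point can be located in the robot frame.
#'
#' @param markersOct,markersIioct matched k x 3 coordinate matrices (mm),
#'   same order.
#' @return MFME in micrometres.
#' @export
mfme <- function(markersOct, markersIioct) {
  a <- asCoordMatrix(markersOct)
  b <- asCoordMatrix(markersIioct)
  if (nrow(a) != nrow(b))
    stop("marker sets must have equal counts (", nrow(a), " vs ", nrow(b), ")")
  if (nrow(a) == 0) stop("need at least one marker pair")
  mean(rowNorms(a - b)) * 1000
}

#' Chamfer distance between two point clouds
#'
#' Symmetric mean nearest-neighbour distance,
#' \eqn{CD = \frac{1}{2|A|}\sum_{a} \min_b \|a-b\| +
#' \frac{1}{2|B|}\sum_{b} \min_a \|b-a\|}, a global alignment measure
#' independent of landmark annotations.
#'
#' @param cloudA,cloudB non-empty clouds (matrix or
#'   \linkS4class{PointCloud3D}).
#' @return Chamfer distance in micrometres.
#' @export
chamferDistance <- function(cloudA, cloudB) {
  a <- asCoordMatrix(cloudA)
  b <- asCoordMatrix(cloudB)
  if (nrow(a) == 0 || nrow(b) == 0) stop("clouds must be non-empty")
  dab <- knnSearch(b, a, 1L)$distance[, 1]
  dba <- knnSearch(a, b, 1L)$distance[, 1]
  (mean(dab) / 2 + mean(dba) / 2) * 1000
}

## distance from a 2D point to the boundary of the convex hull of pts,
## negative when outside; hull given as indices from chull()
hullBoundaryDistance <- function(point, pts) {
  h <- chull(pts)
  poly <- pts[h, , drop = FALSE]
  k <- nrow(poly)
  if (k < 3) stop("cloud's lateral extent is degenerate (collinear)")
  dmin <- Inf
  inside <- TRUE
  for (i in seq_len(k)) {
    a <- poly[i, ]
    b <- poly[i %% k + 1, ]
    dmin <- min(dmin, segmentDistance(point[1], point[2], a, b))
    # chull returns vertices clockwise; the interior is to the right
    crossz <- (b[1] - a[1]) * (point[2] - a[2]) -
      (b[2] - a[2]) * (point[1] - a[1])
    if (crossz > 1e-12) inside <- FALSE
  }
  if (inside) dmin else -dmin
}

#' Crop two clouds to a shared z-aligned cylinder
#'
#' Non-overlapping margins distort the Chamfer distance; both clouds are
#' cropped to the z-axis-aligned cylinder of maximum radius that is fully
#' covered by both, operationalised as the smaller of the two distances
#' from the axis to the boundary of each cloud's lateral convex hull.
#'
#' @param cloudA,cloudB registered clouds in a common frame.
#' @param axisPoint (x, y) or (x, y, z) point the cylinder axis passes
#'   through (typically the target fovea).
#' @return list with \code{a}, \code{b} (cropped clouds) and
#'   \code{cropRadius} (mm).
#' @export
cropCylinder <- function(cloudA, cloudB, axisPoint) {
  a <- asCoordMatrix(cloudA)
  b <- asCoordMatrix(cloudB)
  ax <- axisPoint[1:2]
  da <- hullBoundaryDistance(ax, a[, 1:2, drop = FALSE])
  db <- hullBoundaryDistance(ax, b[, 1:2, drop = FALSE])
  if (da < 0 || db < 0)
    stop("cylinder axis lies outside the lateral hull of ",
         if (da < 0) "cloud A" else "cloud B")
  cropRadius <- min(da, db)
  keep <- function(m) sqrt((m[, 1] - ax[1])^2 + (m[, 2] - ax[2])^2) <=
    cropRadius + 1e-12
  subsetCloud <- function(cl, k) {
    if (is(cl, "PointCloud3D")) {
      lb <- pointLabels(cl)
      pointCloud(coords(cl)[k, , drop = FALSE],
                 labels = if (length(lb)) lb[k] else character(0),
                 frame = frameTag(cl))
    } else cl[k, , drop = FALSE]
  }
  list(a = subsetCloud(cloudA, keep(a)), b = subsetCloud(cloudB, keep(b)),
       cropRadius = cropRadius)
}

#' Paired per-point comparison of registration errors
#'
#' Compares per-point minimum distances before and after a pipeline
#' change (e.g. with and without curvature correction): reports the mean
#' and standard deviation of the paired differences
#' \eqn{d_i = before_i - after_i} (micrometre scale if the inputs are in
#' micrometres) and the two-sided paired t-test p-value. A zero-variance
#' difference cannot support a t statistic; the p-value is then NA with
#' \code{degenerate = TRUE}.
#'
#' @param distBefore,distAfter equal-length per-point distances with the
#'   same point identity per index.
#' @return list with \code{meanDiff}, \code{sd}, \code{pValue},
#'   \code{degenerate}.
#' @export
pairedCcComparison <- function(distBefore, distAfter) {
  if (length(distBefore) != length(distAfter))
    stop("paired distance vectors must have equal length")
  if (length(distBefore) < 2) stop("need at least 2 paired observations")
  d <- distBefore - distAfter
  s <- sd(d)
  if (s == 0)
    return(list(meanDiff = mean(d), sd = 0, pValue = NA_real_,
                degenerate = TRUE))
  tt <- t.test(distBefore, distAfter, paired = TRUE,
               alternative = "two.sided")
  list(meanDiff = mean(d), sd = s, pValue = tt$p.value, degenerate = FALSE)
}

#' Histogram of bidirectional nearest-neighbour distances
#'
#' The distances that constitute the Chamfer distance (both directions
#' pooled), binned at the given width.
#'
#' @param cloudA,cloudB non-empty clouds.
#' @param binWidthUm bin width in micrometres (default 25).
#' @return list with \code{breaks}, \code{mids} (um), \code{counts} and
#'   the raw \code{distances} (um). Counts sum to |A| + |B|.
#' @export
distanceHistogram <- function(cloudA, cloudB, binWidthUm = 25) {
  a <- asCoordMatrix(cloudA)
  b <- asCoordMatrix(cloudB)
  if (nrow(a) == 0 || nrow(b) == 0) stop("clouds must be non-empty")
  d <- c(knnSearch(b, a, 1L)$distance[, 1],
         knnSearch(a, b, 1L)$distance[, 1]) * 1000
  breaks <- seq(0, max(d) + binWidthUm, by = binWidthUm)
  counts <- tabulate(findInterval(d, breaks, rightmost.closed = FALSE,
                                  left.open = FALSE),
                     nbins = length(breaks) - 1)
  list(breaks = breaks, mids = breaks[-length(breaks)] + binWidthUm / 2,
       counts = counts, distances = d)
}
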
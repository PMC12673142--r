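#' @include AllClasses.R
NULL

## small numerical helpers shared across modules

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

rowNorms <- function(m) sqrt(rowSums(m^2))

asCoordMatrix <- function(x) {
  if (is(x, "PointCloud3D")) return(coords(x))
  if (is.null(dim(x))) return(matrix(x, ncol = 3, byrow = TRUE))
  as.matrix(x)
}

#' k-nearest-neighbour search
#'
#' Finds, for each query point, the \code{k} nearest points of
#' \code{target}, using a k-d tree. Distances are Euclidean, mm.
#'
#' @param target n x 3 matrix or \linkS4class{PointCloud3D} searched in.
#' @param query m x 3 matrix or cloud of query points.
#' @param k number of neighbours.
#' @return list with \code{index} (m x k, 1-based into target) and
#'   \code{distance} (m x k, mm), nearest first.
#' @export
knnSearch <- function(target, query, k = 1L) {
  tm <- asCoordMatrix(target)
  qm <- asCoordMatrix(query)
  if (nrow(tm) == 0) stop("target cloud is empty")
  if (nrow(qm) == 0) stop("query cloud is empty")
  .cppKnn(tm, qm, as.integer(k))
}

#' Rotation matrix about an arbitrary axis (Rodrigues)
#'
#' @param axis rotation axis (any non-zero 3-vector).
#' @param angle rotation angle in radians (right-handed).
#' @return 3 x 3 rotation matrix.
#' @export
rotationAboutAxis <- function(axis, angle) {
  u <- unitize(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rotation aligning one direction with another
#'
#' Returns the minimal rotation taking direction \code{a} onto direction
#' \code{b} (Rodrigues construction). Antiparallel inputs are handled by an
#' explicit 180-degree rotation about an arbitrary perpendicular axis.
#'
#' @param a,b non-zero 3-vectors (only directions matter).
#' @return 3 x 3 rotation matrix R with R a / |a| = b / |b|.
#' @export
rotationBetween <- function(a, b) {
  a <- unitize(a); b <- unitize(b)
  ax <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  s <- vnorm(ax)
  cth <- sum(a * b)
  if (s < 1e-15) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- p - sum(p * a) * a
    return(rotationAboutAxis(perp, pi))
  }
  rotationAboutAxis(ax, atan2(s, cth))
}

## Otsu threshold on a 256-bin histogram of the given intensities,
## maximising between-class variance; returns a threshold on the intensity
## scale. Deterministic replacement for manual annotation of "white".
otsuThreshold <- function(x, rng = range(x)) {
  if (diff(rng) == 0) return(rng[1])
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + floor((x - rng[1]) / diff(rng) * nb)), nb)
  p <- h / sum(h)
  w <- cumsum(p)
  mu <- cumsum(p * seq_len(nb))
  muT <- mu[nb]
  bcv <- (muT * w - mu)^2 / (w * (1 - w))
  bcv[!is.finite(bcv)] <- 0
  kk <- which.max(bcv)
  rng[1] + kk / nb * diff(rng)
}

#' Voxel-grid downsampling of a point cloud
#'
#' Partitions space into cubic cells of the given edge length and replaces
#' the points of each occupied cell by their centroid, in first-occurrence
#' order of the cells. Used to thin the source cloud before nonrigid
#' registration.
#'
#' @param cloud a \linkS4class{PointCloud3D} or n x 3 matrix.
#' @param spacing cell edge length in mm.
#' @return matrix of cell centroids (m x 3).
#' @export
voxelDownsample <- function(cloud, spacing) {
  m <- asCoordMatrix(cloud)
  if (spacing <= 0) stop("spacing must be positive")
  key <- paste(floor(m[, 1] / spacing), floor(m[, 2] / spacing),
               floor(m[, 3] / spacing))
  f <- factor(key, levels = unique(key))
  cnt <- as.vector(table(f)[levels(f)])
  rowsum(m, f, reorder = FALSE) / cnt
}
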
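#' @include AllClasses.R utils.R
NULL

#' Geometric least-squares sphere fit
#'
#' Fits centre \eqn{c} and radius \eqn{r} minimising the geometric cost
#' \eqn{\sum_i (\|p_i - c\| - r)^2}. The fit is initialised algebraically
#' (linear least squares on the expansion of \eqn{\|p\|^2}) and refined by
#' Gauss-Newton iterations on the geometric cost; algebraic-only fits are
#' biased under noise, the geometric refinement removes that bias.
#'
#' @param cloud a \linkS4class{PointCloud3D} or n x 3 matrix with at least
#'   4 non-coplanar points.
#' @param maxIterations Gauss-Newton iteration cap.
#' @param tol relative parameter-change tolerance.
#' @return a \linkS4class{SphereFit}.
#' @examples
#' th <- seq(0, pi, length.out = 50)
#' p <- cbind(sin(th) * cos(3 * th), sin(th) * sin(3 * th), cos(th)) * 10
#' fitSphere(p + rep(c(1, 2, 3), each = 50))
#' @export
fitSphere <- function(cloud, maxIterations = 100L, tol = 1e-14) {
  m <- asCoordMatrix(cloud)
  n <- nrow(m)
  if (n < 4) stop("sphere fit needs at least 4 points")
  # algebraic initialisation: |p|^2 = 2 p . c + (r^2 - |c|^2)
  A <- cbind(2 * m, 1)
  b <- rowSums(m^2)
  qrA <- qr(A)
  if (qrA$rank < 4)
    stop("degenerate input: points are coplanar or otherwise rank-deficient ",
         "(design rank ", qrA$rank, " < 4)")
  # guard against numerically coplanar input that still has full rank
  sv <- svd(scale(m, scale = FALSE), nu = 0, nv = 0)$d
  if (sv[3] < 1e-10 * sv[1])
    stop("degenerate input: points are coplanar within numerical precision ",
         "(condition number ", format(sv[1] / max(sv[3], 1e-300), digits = 3),
         ")")
  beta <- qr.coef(qrA, b)
  cen <- beta[1:3]
  rad <- sqrt(max(beta[4] + sum(cen^2), .Machine$double.eps))
  # Gauss-Newton on f_i = |p_i - c| - r
  par <- c(cen, rad)
  for (it in seq_len(maxIterations)) {
    dif <- m - matrix(par[1:3], n, 3, byrow = TRUE)
    dst <- rowNorms(dif)
    f <- dst - par[4]
    J <- cbind(-dif / dst, -1)
    step <- tryCatch(qr.coef(qr(J), -f), error = function(e) rep(0, 4))
    step[is.na(step)] <- 0
    par <- par + step
    if (max(abs(step)) < tol * max(1, abs(par[4]))) break
  }
  dst <- rowNorms(m - matrix(par[1:3], n, 3, byrow = TRUE))
  sphereFit(par[1:3], par[4],
            rmsResidual = sqrt(mean((dst - par[4])^2)), nPoints = n)
}

#' Build the curvature-correction target sphere
#'
#' Constructs the sphere of the (accurate, iiOCT-measured) radius that is
#' tangent to the fitted diagnostic-OCT sphere at the fovea: it passes
#' exactly through \code{foveaOct} and its centre lies on the ray from the
#' fovea towards the OCT sphere centre,
#' \eqn{c' = p_f + r_t (c - p_f)/\|c - p_f\|}. Only the radius of the
#' iiOCT fit is used, since the two modalities live in different frames
#' before alignment.
#'
#' @param octFit \linkS4class{SphereFit} of the distorted OCT cloud.
#' @param foveaOct fovea coordinate in the OCT frame (3-vector, mm).
#' @param rTarget target radius in mm (typically the iiOCT fitted radius).
#' @return a \linkS4class{SphereFit} (residual 0, n = 0).
#' @export
buildTargetSphere <- function(octFit, foveaOct, rTarget) {
  if (rTarget <= 0) stop("target radius must be positive")
  d <- sphereCenter(octFit) - foveaOct
  if (vnorm(d) == 0) stop("fovea coincides with the OCT sphere centre")
  sphereFit(foveaOct + rTarget * d / vnorm(d), rTarget)
}

#' Intersect a line with a sphere
#'
#' Solves the quadratic for the line \code{origin + t * direction}. When a
#' hemisphere axis \code{u} is given, also reports which intersection lies
#' on the retinal hemisphere, operationalised as \eqn{(j - c) \cdot u < 0}
#' with \code{u} the fovea-to-centre direction (the hemisphere containing
#' the fovea).
#'
#' @param origin,direction line origin and direction (direction non-zero).
#' @param sphere a \linkS4class{SphereFit}.
#' @param hemisphereAxis optional unit vector u (fovea-to-centre).
#' @return list with \code{points} (0-2 rows x 3, ordered by increasing t)
#'   and \code{retinal} (logical per row, or NULL when no axis given).
#' @export
lineSphereIntersect <- function(origin, direction, sphere,
                                hemisphereAxis = NULL) {
  if (vnorm(direction) == 0) stop("direction must be non-zero")
  d <- direction / vnorm(direction)
  oc <- origin - sphereCenter(sphere)
  b <- sum(d * oc)
  cc <- sum(oc^2) - sphereRadius(sphere)^2
  disc <- b^2 - cc
  if (disc < 0) return(list(points = matrix(numeric(0), 0, 3), retinal = NULL))
  if (disc == 0) {
    ts <- -b
  } else {
    ts <- c(-b - sqrt(disc), -b + sqrt(disc))
  }
  pts <- matrix(origin, length(ts), 3, byrow = TRUE) + outer(ts, d)
  ret <- NULL
  if (!is.null(hemisphereAxis)) {
    u <- unitize(hemisphereAxis)
    ret <- as.vector((pts - matrix(sphereCenter(sphere), length(ts), 3,
                                   byrow = TRUE)) %*% u) < 0
  }
  list(points = pts, retinal = ret)
}

## vectorised retinal-hemisphere intersection used by correctCurvature:
## for each row of `pts`, intersect the line pts[i] + t * dirs[i] with the
## sphere and keep the root on the hemisphere containing the fovea.
retinalIntersections <- function(pts, dirs, center, radius, u) {
  n <- nrow(pts)
  dn <- dirs / rowNorms(dirs)
  oc <- pts - matrix(center, n, 3, byrow = TRUE)
  b <- rowSums(dn * oc)
  cc <- rowSums(oc^2) - radius^2
  disc <- b^2 - cc
  miss <- disc < 0
  disc[miss] <- 0
  t1 <- -b - sqrt(disc)
  t2 <- -b + sqrt(disc)
  j1 <- pts + dn * t1
  j2 <- pts + dn * t2
  um <- matrix(u, n, 3, byrow = TRUE)
  r1 <- rowSums((j1 - matrix(center, n, 3, byrow = TRUE)) * um) < 0
  r2 <- rowSums((j2 - matrix(center, n, 3, byrow = TRUE)) * um) < 0
  pick1 <- r1
  j <- j2
  j[pick1, ] <- j1[pick1, ]
  bad <- miss | (!r1 & !r2)
  list(points = j, bad = bad)
}

#' Fovea-anchored curvature correction
#'
#' Corrects the curvature-flattened diagnostic OCT cloud so that its
#' spherical base matches the target radius measured by iiOCT. For each
#' point \eqn{p_i} a line is drawn towards the centre of the sphere fitted
#' to the distorted cloud; the deformation vector is the difference
#' \eqn{\epsilon_i = j_i^{target} - j_i^{OCT}} between the line's
#' intersections with the target and OCT spheres on the retinal (fovea-side)
#' hemisphere, and the corrected point is \eqn{p_i + \epsilon_i}. Points are
#' corrected independently; the construction translates each point along its
#' own line, so radial feature offsets relative to the spherical base are
#' preserved exactly rather than projected away.
#'
#' @param cloud distorted OCT \linkS4class{PointCloud3D}.
#' @param octFit sphere fitted to \code{cloud}.
#' @param target target sphere from \code{\link{buildTargetSphere}}.
#' @param fovea optional fovea coordinate (mm). When omitted it is
#'   recovered as the tangency point of the two spheres.
#' @return list with \code{cloud} (corrected \linkS4class{PointCloud3D})
#'   and \code{field} (\linkS4class{DeformationField}).
#' @export
correctCurvature <- function(cloud, octFit, target, fovea = NULL) {
  m <- coords(cloud)
  if (nrow(m) == 0) stop("cannot correct an empty cloud")
  cOct <- sphereCenter(octFit)
  cTgt <- sphereCenter(target)
  if (is.null(fovea)) {
    # tangency point: on the target sphere along +/- the centre-offset axis,
    # whichever also lies on the OCT sphere
    ax <- cOct - cTgt
    if (vnorm(ax) == 0) {
      # concentric spheres: anchor direction undefined; any radial direction
      # would do only if radii are equal, otherwise no tangency exists
      stop("cannot recover the fovea from concentric spheres; pass fovea=")
    }
    ax <- ax / vnorm(ax)
    cand1 <- cTgt - sphereRadius(target) * ax
    cand2 <- cTgt + sphereRadius(target) * ax
    e1 <- abs(vnorm(cand1 - cOct) - sphereRadius(octFit))
    e2 <- abs(vnorm(cand2 - cOct) - sphereRadius(octFit))
    fovea <- if (e1 <= e2) cand1 else cand2
  }
  uOct <- unitize(cOct - fovea)
  uTgt <- unitize(cTgt - fovea)
  dirs <- matrix(cOct, nrow(m), 3, byrow = TRUE) - m
  zero <- rowNorms(dirs) == 0
  if (any(zero))
    stop("point(s) coincide with the OCT sphere centre: ",
         paste(head(which(zero), 5), collapse = ", "))
  jo <- retinalIntersections(m, dirs, cOct, sphereRadius(octFit), uOct)
  jt <- retinalIntersections(m, dirs, cTgt, sphereRadius(target), uTgt)
  bad <- jo$bad | jt$bad
  if (any(bad))
    stop("line towards the OCT centre misses a sphere for point(s): ",
         paste(head(which(bad), 10), collapse = ", "))
  eps <- jt$points - jo$points
  corrected <- pointCloud(m + eps, labels = pointLabels(cloud),
                          frame = frameTag(cloud))
  list(cloud = corrected,
       field = new("DeformationField", vectors = eps, sourceFit = octFit,
                   targetFit = target))
}
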
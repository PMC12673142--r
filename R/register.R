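#' @include AllClasses.R utils.R curvature.R
NULL

#' Point-to-plane ICP settings
#'
#' Defaults follow the pipeline's operating point: at most 100 iterations,
#' termination when the relative RMSE change falls below 1e-6, a 20 um
#' correspondence distance threshold (appropriate for densely sampled,
#' curvature-corrected, landmark-initialised clouds; sparser targets need a
#' threshold of at least the target spacing) and 30-neighbour normal
#' estimation.
#'
#' @param maxIterations iteration cap.
#' @param relRmseTol relative RMSE-change termination tolerance.
#' @param correspondenceThreshold distance threshold in mm.
#' @param normalK neighbourhood size for normal estimation.
#' @return list of class \code{"icpControl"}.
#' @export
icpControl <- function(maxIterations = 100L, relRmseTol = 1e-6,
                       correspondenceThreshold = 0.020, normalK = 30L) {
  stopifnot(maxIterations > 0, relRmseTol > 0, correspondenceThreshold > 0,
            normalK > 0)
  structure(list(maxIterations = as.integer(maxIterations),
                 relRmseTol = relRmseTol,
                 correspondenceThreshold = correspondenceThreshold,
                 normalK = as.integer(normalK)),
            class = "icpControl")
}

#' Nonrigid coherent point drift settings
#'
#' \code{alpha} weighs the motion-coherence regulariser (large alpha gives
#' near-rigid fields, small alpha allows local deformation); \code{beta}
#' is the Gaussian kernel width of the coherence prior in mm. The source
#' cloud is thinned to \code{downsampleSpacing} before optimisation and
#' the resulting field is densified back with
#' \code{knnDensify}-nearest-neighbour inverse-distance weighting. Where
#' no reference dictates otherwise, beta = 2 mm, outlier weight 0.1 and an
#' EM cap of 150 iterations are used.
#'
#' @param alpha coherence weight (> 0).
#' @param beta kernel width, mm.
#' @param w outlier weight in [0, 1).
#' @param downsampleSpacing source thinning spacing, mm.
#' @param knnDensify neighbours used when densifying.
#' @param maxEmIterations EM iteration cap.
#' @param tol relative sigma^2-change termination tolerance.
#' @param sigma2Floor lower bound on the mixture variance, mm^2
#'   (default 0, i.e. disabled). On partially overlapping clouds the
#'   annealing can collapse: the mixture matches assigned points exactly,
#'   the effective coherence weight \code{alpha * sigma2} vanishes and
#'   the field overfits. Setting the floor to about half the sampling
#'   resolution squared (e.g. \code{(downsampleSpacing / 2)^2}) keeps
#'   the posterior soft at the scale below which correspondence is
#'   meaningless and confines the field to the data-supported region.
#' @return list of class \code{"cpdControl"}.
#' @export
cpdControl <- function(alpha = 0.0003, beta = 2, w = 0.1,
                       downsampleSpacing = 0.300, knnDensify = 4L,
                       maxEmIterations = 150L, tol = 1e-8,
                       sigma2Floor = 0) {
  stopifnot(alpha > 0, beta > 0, w >= 0, w < 1, downsampleSpacing > 0,
            knnDensify > 0, maxEmIterations > 0, sigma2Floor >= 0)
  structure(list(alpha = alpha, beta = beta, w = w,
                 downsampleSpacing = downsampleSpacing,
                 knnDensify = as.integer(knnDensify),
                 maxEmIterations = as.integer(maxEmIterations), tol = tol,
                 sigma2Floor = sigma2Floor),
            class = "cpdControl")
}

#' Landmark-based initial alignment
#'
#' Aligns the diagnostic OCT cloud with the iiOCT frame in three exact
#' steps: (1) translate so the fovea landmarks coincide; (2) tilt-correct
#' by rotating the fovea-to-sphere-centre direction
#' \eqn{n = c - p_f} of the OCT fit onto that of the iiOCT fit (Rodrigues
#' rotation about the fovea); (3) rotate about the common visual axis
#' (the shared n direction through the fovea) by the signed angle between
#' the ONH offsets projected onto the plane perpendicular to that axis.
#' With the visual axis along z this reduces to a z-rotation by the
#' signed in-plane ONH angle; the projection avoids re-introducing tilt,
#' since the axial ONH mismatch can remain large even after curvature
#' correction. The fovea residual is exactly zero and the n directions
#' exactly parallel after alignment.
#'
#' @param octCloud OCT \linkS4class{PointCloud3D} (already
#'   curvature-corrected when CC is in use).
#' @param octLandmarks,iioctLandmarks \linkS4class{Landmarks} with fovea
#'   and ONH.
#' @param octFit,iioctFit \linkS4class{SphereFit}s of the two clouds.
#' @return list with \code{cloud} (transformed OCT cloud, iiOCT frame)
#'   and \code{transform} (the composite \linkS4class{RigidTransform}).
#' @export
initialAlign <- function(octCloud, octLandmarks, octFit,
                         iioctLandmarks, iioctFit) {
  pfO <- octLandmarks@fovea
  pfI <- iioctLandmarks@fovea
  nO <- sphereCenter(octFit) - pfO
  nI <- sphereCenter(iioctFit) - pfI
  if (vnorm(nO) == 0 || vnorm(nI) == 0)
    stop("sphere centre coincides with the fovea")
  R1 <- rotationBetween(nO, nI)
  axis <- unitize(nI)
  # ONH offsets relative to the (common) fovea, OCT side tilt-corrected
  oO <- as.numeric(R1 %*% (octLandmarks@onh - pfO))
  oI <- iioctLandmarks@onh - pfI
  projO <- oO - sum(oO * axis) * axis
  projI <- oI - sum(oI * axis) * axis
  if (vnorm(projO) < 1e-12 || vnorm(projI) < 1e-12)
    stop("ONH offset projects to zero length; cannot resolve the rotation ",
         "about the visual axis")
  crossOI <- c(projO[2] * projI[3] - projO[3] * projI[2],
               projO[3] * projI[1] - projO[1] * projI[3],
               projO[1] * projI[2] - projO[2] * projI[1])
  phi <- atan2(sum(crossOI * axis), sum(projO * projI))
  R2 <- rotationAboutAxis(axis, phi)
  R <- R2 %*% R1
  tf <- rigidTransform(R, as.numeric(pfI - R %*% pfO))
  list(cloud = applyTransform(tf, octCloud, frame = "iioct"),
       transform = tf)
}

#' Estimate per-point surface normals
#'
#' Local plane fit (principal component analysis) over the k nearest
#' neighbours of each point. Normals are consistently oriented towards
#' the centre of a sphere fitted to the cloud (upward for retinal
#' clouds); for degenerate cloud-wide sphere fits a far point above the
#' centroid is used as the orientation reference. Points whose
#' neighbourhood is rank-deficient get an NA normal and are excluded from
#' the point-to-plane metric.
#'
#' @param cloud a \linkS4class{PointCloud3D} with more than k points.
#' @param k neighbourhood size.
#' @return n x 3 matrix of unit normals (NA rows where degenerate).
#' @export
estimateNormals <- function(cloud, k = 30L) {
  m <- asCoordMatrix(cloud)
  n <- nrow(m)
  if (n <= k) stop("cloud must have more than k points")
  ref <- tryCatch(sphereCenter(fitSphere(m)), error = function(e)
    colMeans(m) + c(0, 0, 10 * max(rowNorms(sweep(m, 2, colMeans(m))))))
  nn <- knnSearch(m, m, k = k + 1L)  # first neighbour is the point itself
  normals <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    nb <- m[nn$index[i, ], , drop = FALSE]
    nb <- sweep(nb, 2, colMeans(nb))
    ev <- eigen(crossprod(nb), symmetric = TRUE)
    if (ev$values[2] < 1e-12 * max(ev$values[1], 1e-300)) next  # collinear
    v <- ev$vectors[, 3]
    if (sum(v * (ref - m[i, ])) < 0) v <- -v
    normals[i, ] <- v
  }
  normals
}

#' Point-to-plane iterative closest point
#'
#' Alternates nearest-neighbour correspondence (rejecting pairs farther
#' than the correspondence threshold) with a closed-form small-angle
#' minimisation of the point-to-plane error
#' \eqn{E(R, t) = \sum ((b - (Ra + t)) \cdot n_b)^2} over the matched
#' pairs. Iteration stops at the cap or when the relative RMSE change
#' drops below the tolerance. An initial alignment must already have been
#' applied; with no correspondences at the first iteration the threshold
#' is too tight for the current alignment and an error is raised.
#'
#' @param source moving \linkS4class{PointCloud3D} (diagnostic OCT).
#' @param target fixed \linkS4class{PointCloud3D} (iiOCT).
#' @param targetNormals n x 3 unit normals of the target (from
#'   \code{\link{estimateNormals}}).
#' @param control an \code{\link{icpControl}} list.
#' @return list with \code{transform} (\linkS4class{RigidTransform}
#'   mapping the original source into the target), \code{cloud} (the
#'   transformed source) and \code{history} (data.frame: iteration, rmse
#'   in mm, nCorrespondences).
#' @export
icpPointToPlane <- function(source, target, targetNormals,
                            control = icpControl()) {
  src0 <- asCoordMatrix(source)
  tgt <- asCoordMatrix(target)
  okN <- !is.na(targetNormals[, 1])
  tgt <- tgt[okN, , drop = FALSE]
  nrm <- targetNormals[okN, , drop = FALSE]
  if (nrow(tgt) == 0) stop("target has no points with valid normals")
  R <- diag(3)
  tr <- c(0, 0, 0)
  cur <- src0
  hist <- data.frame(iteration = integer(0), rmse = numeric(0),
                     nCorrespondences = integer(0))
  prevRmse <- NA_real_
  for (it in seq_len(control$maxIterations)) {
    nn <- knnSearch(tgt, cur, k = 1L)
    ok <- nn$distance[, 1] <= control$correspondenceThreshold
    if (!any(ok)) {
      if (it == 1L)
        stop("no correspondences within ",
             control$correspondenceThreshold * 1000,
             " um at the first iteration; the clouds are too far apart - ",
             "increase the correspondence threshold or improve the ",
             "initial alignment")
      break
    }
    a <- cur[ok, , drop = FALSE]
    b <- tgt[nn$index[ok, 1], , drop = FALSE]
    nb <- nrm[nn$index[ok, 1], , drop = FALSE]
    resid <- rowSums((b - a) * nb)
    rmse <- sqrt(mean(resid^2))
    hist <- rbind(hist, data.frame(iteration = it, rmse = rmse,
                                   nCorrespondences = sum(ok)))
    # linearised solve: unknowns (omega, t), rows [a x n, n]
    axn <- cbind(a[, 2] * nb[, 3] - a[, 3] * nb[, 2],
                 a[, 3] * nb[, 1] - a[, 1] * nb[, 3],
                 a[, 1] * nb[, 2] - a[, 2] * nb[, 1])
    A <- cbind(axn, nb)
    x <- tryCatch(solve(crossprod(A), crossprod(A, resid)),
                  error = function(e) matrix(0, 6, 1))
    omega <- x[1:3]
    dt <- x[4:6]
    ang <- vnorm(omega)
    dR <- if (ang < 1e-15) diag(3) else rotationAboutAxis(omega, ang)
    R <- dR %*% R
    tr <- as.numeric(dR %*% tr + dt)
    cur <- t(R %*% t(src0)) + matrix(tr, nrow(src0), 3, byrow = TRUE)
    if (!is.na(prevRmse)) {
      if (prevRmse < 1e-15 ||
          abs(prevRmse - rmse) / prevRmse < control$relRmseTol) break
    }
    prevRmse <- rmse
  }
  tf <- rigidTransform(R, tr)
  outCloud <- if (is(source, "PointCloud3D"))
    applyTransform(tf, source) else pointCloud(cur)
  list(transform = tf, cloud = outCloud, history = hist)
}

#' Nonrigid coherent point drift
#'
#' Models the (downsampled) source points as Gaussian mixture centroids
#' drifting coherently towards the target points: expectation-
#' maximisation of the mixture likelihood with a motion-coherence
#' regulariser of weight \code{alpha} on a Gaussian kernel of width
#' \code{beta}. The displacement of source point i is
#' \eqn{(G W)_i} with \eqn{G_{ij} = \exp(-\|y_i - y_j\|^2 / (2\beta^2))}.
#' The algorithm is deterministic for fixed inputs and iteration cap;
#' non-convergence at the cap returns the best-so-far field with a
#' warning flag.
#'
#' @param source moving cloud (already downsampled to
#'   \code{control$downsampleSpacing}; matrix or
#'   \linkS4class{PointCloud3D}).
#' @param target fixed cloud.
#' @param control a \code{\link{cpdControl}} list.
#' @return list with \code{displacements} (n x 3 per-source-point field,
#'   mm), \code{sigma2} (final mixture variance), \code{iterations} and
#'   \code{converged}.
#' @export
cpdNonrigid <- function(source, target, control = cpdControl()) {
  Y <- asCoordMatrix(source)   # GMM centroids (moving), M x 3
  X <- asCoordMatrix(target)   # data points, N x 3
  M <- nrow(Y); N <- nrow(X); D <- 3
  if (M == 0 || N == 0) stop("source and target must be non-empty")
  G <- exp(-as.matrix(dist(Y))^2 / (2 * control$beta^2))
  W <- matrix(0, M, D)
  TY <- Y
  sigma2 <- sum(outer(rowSums(X^2), rep(1, M)) +
                outer(rep(1, N), rowSums(Y^2)) -
                2 * X %*% t(Y)) / (D * M * N)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(control$maxEmIterations)) {
    # E-step: posterior P (M x N)
    d2 <- outer(rowSums(TY^2), rep(1, N)) + outer(rep(1, M), rowSums(X^2)) -
      2 * TY %*% t(X)
    num <- exp(-d2 / (2 * sigma2))
    cden <- colSums(num) +
      (2 * pi * sigma2)^(D / 2) * control$w / (1 - control$w) * M / N
    P <- num / matrix(pmax(cden, 1e-300), M, N, byrow = TRUE)
    P1 <- rowSums(P)
    Np <- sum(P1)
    PX <- P %*% X
    # M-step: (diag(P1) G + alpha sigma2 I) W = PX - diag(P1) Y
    # small diagonal guard keeps the solve well-posed when both the
    # coherence weight and the posterior mass of a row vanish
    A <- G * P1 + diag(control$alpha * sigma2 + 1e-9, M)
    W <- solve(A, PX - Y * P1)
    TY <- Y + G %*% W
    sig2new <- (sum(colSums(P) * rowSums(X^2)) -
                2 * sum(PX * TY) + sum(P1 * rowSums(TY^2))) / (Np * D)
    sig2new <- max(sig2new, control$sigma2Floor, 1e-12)
    if (abs(sigma2 - sig2new) / sigma2 < control$tol) {
      sigma2 <- sig2new
      converged <- TRUE
      break
    }
    sigma2 <- sig2new
  }
  if (!converged)
    warning("CPD reached the EM iteration cap without meeting the ",
            "tolerance; returning the best-so-far field")
  list(displacements = G %*% W, sigma2 = sigma2, iterations = it,
       converged = converged)
}

#' Densify a sparse deformation field
#'
#' Transfers displacements computed on a downsampled cloud back to the
#' dense cloud: for each dense point the k nearest sparse points are
#' found with a k-d tree and their displacement vectors averaged with
#' inverse-distance weights (a dense point coinciding with a sparse point
#' receives that sparse displacement exactly). The result always lies in
#' the convex hull of the contributing sparse vectors.
#'
#' @param denseSource dense cloud (matrix or \linkS4class{PointCloud3D}).
#' @param sparseSource downsampled cloud the field was computed on.
#' @param sparseDisplacements m x 3 displacement field.
#' @param knn number of neighbours (default 4).
#' @return n x 3 dense displacement field.
#' @export
densifyDeformation <- function(denseSource, sparseSource,
                               sparseDisplacements, knn = 4L) {
  dm <- asCoordMatrix(denseSource)
  sm <- asCoordMatrix(sparseSource)
  if (nrow(sm) == 0) stop("sparse source is empty")
  if (knn > nrow(sm)) stop("knn exceeds the sparse cloud size")
  nn <- knnSearch(sm, dm, k = knn)
  wts <- 1 / (nn$distance + 1e-12)
  wts <- wts / rowSums(wts)
  out <- matrix(0, nrow(dm), 3)
  for (j in seq_len(knn))
    out <- out + wts[, j] * sparseDisplacements[nn$index[, j], , drop = FALSE]
  out
}
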
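# shared small phantom pair for the registration tests
regFixture <- function(octSpacing = 0.25) {
  tr <- generateTrueSurface(eyePhantomSpec(vesselSpec = list(),
                                           wireSpec = list(),
                                           wireCrossings =
                                             matrix(numeric(0), 0, 2)),
                            8, octSpacing)
  fit <- fitSphere(coords(tr$cloud))
  list(cloud = tr$cloud, lm = tr$landmarks, fit = fit)
}

test_that("initial alignment is exact at the landmarks", {
  fx <- regFixture()
  # already aligned: identity
  ia <- initialAlign(fx$cloud, fx$lm, fx$fit, fx$lm, fx$fit)
  expect_lt(max(abs(ia$transform@rotation - diag(3))), 1e-9)
  expect_lt(max(abs(ia$transform@translation)), 1e-9)

  # 30 degree rotation about z through the fovea is inverted exactly
  rot <- rigidTransform(rotationAboutAxis(c(0, 0, 1), 30 * pi / 180))
  octCloud <- applyTransform(rot, fx$cloud)
  octLm <- applyTransform(rot, fx$lm)
  octFit <- sphereFit(applyTransform(rot, sphereCenter(fx$fit)),
                      sphereRadius(fx$fit))
  ia <- initialAlign(octCloud, octLm, octFit, fx$lm, fx$fit)
  expect_lt(max(abs(coords(ia$cloud) - coords(fx$cloud))), 1e-9)
  # recovered in-plane angle is -30 degrees
  phi <- atan2(ia$transform@rotation[2, 1], ia$transform@rotation[1, 1])
  expect_equal(phi, -30 * pi / 180, tolerance = 1e-9)
})

test_that("initial alignment post-conditions hold for a general offset", {
  fx <- regFixture()
  off <- rigidTransform(rotationAboutAxis(c(0, 0, 1), 0.31) %*%
                          rotationAboutAxis(c(1, 0.4, 0), 0.05),
                        c(2.5, -1.4, 0.8))
  octCloud <- applyTransform(off, fx$cloud)
  octLm <- applyTransform(off, fx$lm)
  octFit <- sphereFit(applyTransform(off, sphereCenter(fx$fit)),
                      sphereRadius(fx$fit))
  ia <- initialAlign(octCloud, octLm, octFit, fx$lm, fx$fit)
  # fovea residual exactly zero
  fovAligned <- applyTransform(ia$transform, octLm@fovea)
  expect_lt(max(abs(fovAligned - fx$lm@fovea)), 1e-12)
  # fovea-to-centre directions parallel
  nOct <- ia$transform@rotation %*% (sphereCenter(octFit) - octLm@fovea)
  nIi <- sphereCenter(fx$fit) - fx$lm@fovea
  cosang <- sum(nOct * nIi) / sqrt(sum(nOct^2) * sum(nIi^2))
  expect_lt(abs(cosang - 1), 1e-12)
  # ONH x-y angular offset zero (iiOCT visual axis is z here)
  onhAligned <- applyTransform(ia$transform, octLm@onh) - fx$lm@fovea
  onhTarget <- fx$lm@onh - fx$lm@fovea
  ang <- atan2(onhAligned[1] * onhTarget[2] - onhAligned[2] * onhTarget[1],
               sum(onhAligned[1:2] * onhTarget[1:2]))
  expect_lt(abs(ang), 1e-9)
  # ONH directly on the visual axis cannot resolve the in-plane rotation
  exact <- sphereFit(c(0, 0, 10), 10)
  expect_error(initialAlign(fx$cloud, landmarks(c(0, 0, 0), c(0, 0, 5)),
                            exact, fx$lm, exact), "zero length")
})

test_that("normal estimation matches analytic normals and flags degeneracy", {
  g <- as.matrix(expand.grid(x = seq(-1, 1, 0.1), y = seq(-1, 1, 0.1)))
  plane <- pointCloud(cbind(g, 0))
  n <- estimateNormals(plane, k = 8)
  expect_true(all(abs(abs(n[, 3]) - 1) < 1e-9))
  expect_true(all(n[, 3] > 0) || all(n[, 3] < 0))  # consistent signing

  sph <- sphereSample(800, center = c(0, 0, 5), radius = 5, seed = 6,
                      capAngle = 0.8)
  ns <- estimateNormals(pointCloud(sph), k = 12)
  toCenter <- (matrix(c(0, 0, 5), 800, 3, byrow = TRUE) - sph) / 5
  agree <- rowSums(ns * toCenter)
  expect_gt(min(agree, na.rm = TRUE), 0.99)
  expect_error(estimateNormals(plane, k = nPoints(plane)), "more than k")
})

test_that("point-to-plane ICP converges immediately on identical clouds", {
  fx <- regFixture()
  nrm <- estimateNormals(fx$cloud, k = 12)
  res <- icpPointToPlane(fx$cloud, fx$cloud, nrm,
                         icpControl(correspondenceThreshold = 0.1))
  expect_lte(nrow(res$history), 2L)
  expect_lt(res$history$rmse[1], 1e-12)
  expect_lt(max(abs(res$transform@rotation - diag(3))), 1e-9)
})

test_that("point-to-plane ICP recovers a known small rigid perturbation", {
  spec <- eyePhantomSpec(noiseSd = 0)
  tr <- generateTrueSurface(spec, 8, 0.12)
  target <- tr$cloud
  pert <- rigidTransform(rotationAboutAxis(c(1, 0, 0), 0.5 * pi / 180),
                         c(0, 0, 0.020))
  source <- applyTransform(pert, target)
  nrm <- estimateNormals(target, k = 20)
  res <- icpPointToPlane(source, target, nrm,
                         icpControl(correspondenceThreshold = 0.5))
  expect_lt(tail(res$history$rmse, 1) * 1000, 1)  # terminal RMSE < 1 um
  rec <- composeTransform(res$transform, pert)  # should be identity
  expect_lt(max(abs(rec@rotation - diag(3))), 1e-4)
  expect_lt(max(abs(rec@translation)), 5e-4)
})

test_that("ICP reports a zero-correspondence error for distant clouds", {
  a <- pointCloud(sphereSample(100, radius = 1, seed = 2))
  b <- pointCloud(sphereSample(100, center = c(10, 0, 0), radius = 1,
                               seed = 3))
  nrm <- estimateNormals(b, k = 10)
  expect_error(icpPointToPlane(a, b, nrm,
                               icpControl(correspondenceThreshold = 0.020)),
               "no correspondences")
})

test_that("CPD leaves identical clouds untouched for any coherence", {
  g <- as.matrix(expand.grid(x = seq(-2, 2, 0.4), y = seq(-2, 2, 0.4)))
  Y <- cbind(g, 0.05 * (g[, 1]^2 + g[, 2]^2))
  for (al in c(2, 0.0003)) {
    r <- cpdNonrigid(Y, Y, cpdControl(alpha = al, maxEmIterations = 50))
    expect_lt(max(sqrt(rowSums(r$displacements^2))) * 1000, 1)  # < 1 um
  }
})

test_that("large-coherence CPD acts rigidly and cannot modify curvature", {
  # rigidly perturbed pair: the recovered field is essentially rigid
  spec <- bareSpec(noiseSd = 0)
  tr <- generateTrueSurface(spec, 8, 0.25)
  Y <- voxelDownsample(coords(tr$cloud), 0.4)
  tf <- rigidTransform(rotationAboutAxis(c(1, 1, 0), 1 * pi / 180),
                       c(0.15, -0.1, 0.08))
  X <- applyTransform(tf, Y)
  r <- suppressWarnings(cpdNonrigid(Y, X, cpdControl(alpha = 2,
                                                     maxEmIterations = 60)))
  expect_lt(rigidityRatio(Y, r$displacements), 0.05)
  expect_lt(chamferDistance(Y + r$displacements, X), 5)  # aligned, um

  # curvature-mismatched pair: a very stiff field leaves the mismatch
  dist <- distortSurface(tr$cloud, spec)
  Yd <- voxelDownsample(coords(dist), 0.4)
  Xc <- coords(tr$cloud)
  cdInit <- chamferDistance(Yd, Xc)
  stiff <- suppressWarnings(
    cpdNonrigid(Yd, Xc, cpdControl(alpha = 1e6, maxEmIterations = 40)))
  expect_gt(chamferDistance(Yd + stiff$displacements, Xc), 0.9 * cdInit)
  loose <- suppressWarnings(
    cpdNonrigid(Yd, Xc, cpdControl(alpha = 0.0003, maxEmIterations = 40)))
  expect_lt(chamferDistance(Yd + loose$displacements, Xc), 0.6 * cdInit)
})

test_that("weak-coherence CPD leaves points without nearby data uncorrected", {
  g <- as.matrix(expand.grid(x = seq(-2, 2, 0.25), y = seq(-2, 2, 0.25)))
  Y <- cbind(g, 0.05 * (g[, 1]^2 + g[, 2]^2))
  ctr <- sqrt(Y[, 1]^2 + Y[, 2]^2) < 1
  X <- Y[ctr, ]
  X[, 3] <- X[, 3] + 0.2
  beta <- 0.5
  # bounded-coefficient regime: sigma floor at half the sampling spacing
  r <- suppressWarnings(
    cpdNonrigid(Y, X, cpdControl(alpha = 20, beta = beta,
                                 maxEmIterations = 80,
                                 sigma2Floor = 0.15^2)))
  d <- sqrt(rowSums(r$displacements^2))
  dd <- knnSearch(X, Y, 1)$distance[, 1]
  far <- dd > 3 * beta
  expect_gt(sum(far), 20)
  expect_gt(mean(d[dd < 0.3]), 0.15)            # the shift is being fitted
  expect_lt(mean(d[far]), 0.1 * mean(d[dd < 0.3]))
})

test_that("densification is an inverse-distance convex combination", {
  sparse <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  disp <- rbind(c(0, 0, 0.1), c(0.2, 0, 0), c(0, -0.1, 0), c(0.05, 0.05, 0))
  # coincident point: exact passthrough
  out <- densifyDeformation(rbind(c(0, 0, 0)), sparse, disp, knn = 4)
  expect_equal(unname(out[1, ]), c(0, 0, 0.1), tolerance = 1e-9)
  # uniform field maps to the uniform value
  uni <- matrix(rep(c(0.01, -0.02, 0.3), each = 4), 4, 3)
  set.seed(5)
  dense <- matrix(runif(30, 0, 1), 10, 3)
  expect_equal(densifyDeformation(dense, sparse, uni, knn = 4),
               matrix(rep(c(0.01, -0.02, 0.3), each = 10), 10, 3),
               tolerance = 1e-9)
  # symmetric opposing displacements cancel at the midpoint
  sym <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  sd4 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)) * 0.1
  mid <- densifyDeformation(rbind(c(0, 0, 0)), sym, sd4, knn = 4)
  expect_lt(max(abs(mid)), 1e-12)
  # convex combination: every component within the neighbour range
  rdisp <- matrix(rnorm(12), 4, 3)
  outs <- densifyDeformation(dense, sparse, rdisp, knn = 4)
  for (j in 1:3) {
    expect_true(all(outs[, j] <= max(rdisp[, j]) + 1e-12))
    expect_true(all(outs[, j] >= min(rdisp[, j]) - 1e-12))
  }
  expect_error(densifyDeformation(dense, sparse, rdisp, knn = 5),
               "exceeds")
})
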
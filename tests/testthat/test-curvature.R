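test_that("sphere fitting recovers exact data to machine precision", {
  p <- sphereSample(100, center = c(1, 2, 3), radius = 10, seed = 4)
  f <- fitSphere(p)
  expect_lt(max(abs(sphereCenter(f) - c(1, 2, 3))), 1e-9)
  expect_lt(abs(sphereRadius(f) - 10), 1e-9)
  expect_lt(f@rmsResidual, 1e-9)
})

test_that("sphere fitting is consistent under noise", {
  set.seed(1)
  p <- sphereSample(10000, radius = 10, seed = 1, capAngle = pi) +
    matrix(rnorm(30000, 0, 0.01), ncol = 3)
  f <- fitSphere(p)
  expect_lt(abs(sphereRadius(f) - 10), 0.01)
  expect_lt(abs(f@rmsResidual - 0.01), 0.001)
})

test_that("degenerate sphere-fit inputs are rejected", {
  coplanar <- cbind(matrix(rnorm(8), 4, 2), 0)
  expect_error(fitSphere(coplanar), "degenerate|coplanar")
  expect_error(fitSphere(matrix(rnorm(9), 3, 3)), "at least 4")
})

test_that("sphere fit matches a brute-force optimiser on small instances", {
  for (seed in 1:3) {
    p <- sphereSample(15, center = c(0.5, -0.3, 2), radius = 4,
                      seed = seed) +
      matrix(rnorm(45, 0, 0.02), ncol = 3)
    f <- fitSphere(p)
    # independent oracle: general-purpose optimiser from several starts
    best <- NULL
    for (s in 1:5) {
      set.seed(100 + s)
      start <- c(colMeans(p) + rnorm(3, 0, 0.5), 4 + rnorm(1, 0, 0.5))
      o <- optim(start, sphereCost, m = p, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
      if (is.null(best) || o$value < best$value) best <- o
    }
    expect_lt(abs(sphereCost(c(sphereCenter(f), sphereRadius(f)), p) -
                    best$value), 1e-6)
    expect_lt(max(abs(c(sphereCenter(f), sphereRadius(f)) - best$par)),
              1e-4)
  }
})

test_that("the target sphere passes through the fovea on the centre ray", {
  octFit <- sphereFit(c(0, 0, 20.6), 20.6)
  tgt <- buildTargetSphere(octFit, c(0, 0, 0), 9.356)
  expect_equal(sphereCenter(tgt), c(0, 0, 9.356))
  expect_equal(sqrt(sum((sphereCenter(tgt) - c(0, 0, 0))^2)),
               sphereRadius(tgt))
  # identity case: same radius reproduces the source sphere
  same <- buildTargetSphere(octFit, c(0, 0, 0), 20.6)
  expect_equal(sphereCenter(same), sphereCenter(octFit))
  expect_error(buildTargetSphere(octFit, c(0, 0, 20.6), 5), "coincides")
})

test_that("line-sphere intersection enumerates 0, 1 or 2 points", {
  unitS <- sphereFit(c(0, 0, 0), 1)
  hit <- lineSphereIntersect(c(0, 0, -5), c(0, 0, 1), unitS,
                             hemisphereAxis = c(0, 0, 1))
  expect_equal(nrow(hit$points), 2L)
  expect_equal(hit$points[, 3], c(-1, 1))
  expect_equal(hit$retinal, c(TRUE, FALSE))
  tang <- lineSphereIntersect(c(-5, 1, 0), c(1, 0, 0), unitS)
  expect_equal(nrow(tang$points), 1L)
  expect_equal(unname(tang$points[1, ]), c(0, 1, 0))
  miss <- lineSphereIntersect(c(-5, 2, 0), c(1, 0, 0), unitS)
  expect_equal(nrow(miss$points), 0L)
  expect_error(lineSphereIntersect(c(0, 0, 0), c(0, 0, 0), unitS),
               "non-zero")
})

test_that("curvature correction is exact on pure spheres and fovea-anchored", {
  spec <- bareSpec()
  tr <- generateTrueSurface(spec, 10, 0.2)
  dist <- distortSurface(tr$cloud, spec)
  octFit <- fitSphere(coords(dist))
  tgt <- buildTargetSphere(octFit, c(0, 0, 0), 10)
  cc <- correctCurvature(dist, octFit, tgt, fovea = c(0, 0, 0))
  expect_lt(abs(sphereRadius(fitSphere(coords(cc$cloud))) - 10), 1e-6)
  # epsilon vanishes at the fovea ...
  fovCC <- correctCurvature(pointCloud(c(0, 0, 0)), octFit, tgt,
                            fovea = c(0, 0, 0))
  expect_lt(max(abs(deformationVectors(fovCC$field))), 1e-9)
  # ... and grows monotonically with angular distance from the fovea axis
  eps <- sqrt(rowSums(deformationVectors(cc$field)^2))
  rho <- sqrt(coords(dist)[, 1]^2 + coords(dist)[, 2]^2)
  o <- order(rho)
  expect_true(all(diff(eps[o]) > -1e-9))
  # a point on the OCT sphere is carried exactly onto the target sphere
  onSphere <- pointCloud(c(0, 0, 22) - 22 * c(sin(0.2), 0, cos(0.2)))
  out <- correctCurvature(onSphere, octFit, tgt, fovea = c(0, 0, 0))
  expect_lt(abs(sqrt(sum((coords(out$cloud)[1, ] -
                            sphereCenter(tgt))^2)) - 10), 1e-9)
})

test_that("the fovea is recovered from the sphere pair when not supplied", {
  octFit <- sphereFit(c(0.3, -0.2, 22.1), 22)
  fov <- sphereCenter(octFit) - 22 * unlist(c(0.1, 0.05,
                                              sqrt(1 - 0.1^2 - 0.05^2)))
  tgt <- buildTargetSphere(octFit, fov, 10)
  pts <- pointCloud(rbind(fov, fov + c(0.5, 0.2, 0.05)))
  withFov <- correctCurvature(pts, octFit, tgt, fovea = fov)
  without <- correctCurvature(pts, octFit, tgt)
  expect_equal(coords(withFov$cloud), coords(without$cloud),
               tolerance = 1e-9)
})

test_that("radial feature offsets are preserved through correction", {
  spec <- eyePhantomSpec()
  tr <- generateTrueSurface(spec, 10, 0.15)
  dist <- distortSurface(tr$cloud, spec)
  retina <- pointLabels(dist) != "fiducial"
  octFit <- fitSphere(coords(dist)[retina, ])
  tgt <- buildTargetSphere(octFit, c(0, 0, 0), 10)
  cc <- correctCurvature(dist, octFit, tgt, fovea = c(0, 0, 0))
  set.seed(11)
  idx <- sort(sample(seq_len(nPoints(dist)), 80))  # spot check, any subset
  before <- offsetAlongLine(coords(dist)[idx, ], sphereCenter(octFit),
                            octFit, c(0, 0, 0))
  after <- offsetAlongLine(coords(cc$cloud)[idx, ], sphereCenter(octFit),
                           tgt, c(0, 0, 0))
  expect_lt(max(abs(before - after)) * 1000, 1)  # < 1 um
})
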
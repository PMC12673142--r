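test_that("a featureless phantom is an exact sphere with exact landmarks", {
  spec <- bareSpec()
  tr <- generateTrueSurface(spec, 10, 0.25)
  f <- fitSphere(coords(tr$cloud))
  expect_lt(abs(sphereRadius(f) - 10), 1e-6)
  expect_lt(max(abs(sphereCenter(f) - c(0, 0, 10))), 1e-6)
  expect_equal(tr$landmarks@fovea, c(0, 0, 0))
  expect_error(generateTrueSurface(spec, 15, 0.25), "too large")
})

test_that("relief features sit at the advertised heights", {
  spec <- eyePhantomSpec(foveaDepth = 0.2)
  # surface point above the fovea is the pit depth above the pure sphere
  expect_equal(phantomSurfaceHeight(bareSpec(), 0, 0), 0)
  specPitOnly <- eyePhantomSpec(foveaDepth = 0.2, onhDepth = 0,
                                vesselSpec = list(), wireSpec = list(),
                                wireCrossings = matrix(numeric(0), 0, 2))
  expect_equal(phantomSurfaceHeight(specPitOnly, 0, 0), 0.2)
  # default spec: wire-labelled points exist and carry the wire relief
  tr <- generateTrueSurface(spec, 10, 0.05)
  expect_true("fiducial" %in% pointLabels(tr$cloud))
  expect_equal(nrow(tr$landmarks@fiducials), 3L)
})

test_that("phantom generation is deterministic", {
  spec <- eyePhantomSpec(seed = 42L)
  a <- generateTrueSurface(spec, 8, 0.2)
  b <- generateTrueSurface(spec, 8, 0.2)
  expect_identical(coords(a$cloud), coords(b$cloud))
  traj <- projectToSphere(makeGridTrajectory(4, 0.2),
                          sphereFit(c(0, 0, 10), 10))
  s1 <- sampleIioct(spec, traj)
  s2 <- sampleIioct(spec, traj)
  expect_identical(s1$log@samples, s2$log@samples)
})

test_that("distortion swaps the spherical base and is anchored at the fovea", {
  spec <- bareSpec()
  tr <- generateTrueSurface(spec, 10, 0.25)
  dist <- distortSurface(tr$cloud, spec)
  f <- fitSphere(coords(dist))
  expect_lt(abs(sphereRadius(f) - 22), 1e-6)
  # the fovea surface point is a fixed point of the distortion
  fov <- distortSurface(pointCloud(c(0, 0, 0)), spec)
  expect_lt(max(abs(coords(fov))), 1e-12)
  # magnitude grows towards the periphery
  disp <- sqrt(rowSums((coords(dist) - coords(tr$cloud))^2))
  rho <- sqrt(coords(tr$cloud)[, 1]^2 + coords(tr$cloud)[, 2]^2)
  o <- order(rho)
  expect_true(all(diff(disp[o]) > -1e-9))
})

test_that("distort then correct is a near-exact round trip near the fovea", {
  # full featured phantom, corrected with the known distortion spheres
  spec <- eyePhantomSpec()
  tr <- generateTrueSurface(spec, 10, 0.1)
  dist <- distortSurface(tr$cloud, spec)
  octSphere <- sphereFit(c(0, 0, 22), 22)
  target <- buildTargetSphere(octSphere, c(0, 0, 0), 10)
  cc <- correctCurvature(dist, octSphere, target, fovea = c(0, 0, 0))
  res <- sqrt(rowSums((coords(cc$cloud) - coords(tr$cloud))^2))
  rho <- sqrt(coords(tr$cloud)[, 1]^2 + coords(tr$cloud)[, 2]^2)
  expect_lt(max(res[rho <= 3]) * 1000, 5)  # um
})

test_that("iiOCT sampling inverts exactly without noise and obeys the noise model", {
  spec <- bareSpec(noiseSd = 0)
  traj <- projectToSphere(makeGridTrajectory(6, 0.2),
                          sphereFit(c(0, 0, 10), 10), standoffMm = 1)
  samp <- sampleIioct(spec, traj)
  expect_equal(samp$nInvalid, 0L)
  rec <- reconstructIioct(samp$log)
  expect_lt(max(abs(coords(rec) - coords(samp$contact))), 1e-9)
  # contact points lie on the analytic surface
  m <- coords(samp$contact)
  expect_lt(max(abs(m[, 3] - phantomSurfaceHeight(spec, m[, 1], m[, 2]))),
            1e-9)

  # noise: sd of (d_noisy - d_true) within 5% of the requested 12.5 um
  spec2 <- bareSpec(noiseSd = 0.0125, seed = 3L)
  traj2 <- projectToSphere(makeGridTrajectory(8, 0.08),
                           sphereFit(c(0, 0, 10), 10))
  samp2 <- sampleIioct(spec2, traj2)
  dTrue <- sqrt(rowSums((coords(samp2$contact) -
                           tipPositions(samp2$log))^2))
  expect_gt(nPoints(samp2$log), 10000)
  expect_lt(abs(sd(distances(samp2$log) - dTrue) - 0.0125), 0.05 * 0.0125)
})

test_that("rays that miss the surface are flagged invalid", {
  spec <- bareSpec()
  traj <- projectToSphere(makeGridTrajectory(4, 0.5),
                          sphereFit(c(0, 0, 10), 10))
  up <- new("Trajectory", tipPositions = tipPositions(traj),
            orientations = -orientations(traj), pattern = "grid",
            nominalSpacing = 0.5, metadata = list())
  samp <- sampleIioct(spec, up)
  expect_equal(samp$nInvalid, nPoints(traj))
  expect_equal(nPoints(samp$log), 0L)
})

test_that("rasterisation and segmentation are quantisation-exact inverses", {
  spec <- eyePhantomSpec()
  tr <- generateTrueSurface(spec, 4, 0.1)
  dz <- 0.0028
  ras <- rasterizeVolume(tr$cloud, voxelDims = c(0.1, 0.1, dz),
                         depthPx = 512L)
  map <- segmentCscanSurface(ras$volume, threshold = 0.5)
  # indices match the rasterisation ground truth exactly
  m <- coords(tr$cloud)
  izTruth <- as.integer(round((ras$zTop - m[, 3]) / dz))
  expect_identical(as.vector(map@index), izTruth)
  # recovered surface heights within dz/2
  cl <- surfaceToCloud(map)
  zRec <- ras$zTop + coords(cl)[, 3]
  expect_lt(max(abs(zRec - m[, 3])), dz / 2 + 1e-12)
  expect_error(rasterizeVolume(pointCloud(matrix(numeric(0), 0, 3)),
                               c(0.1, 0.1, dz), 512L), "empty")
  expect_error(rasterizeVolume(tr$cloud, c(0.1, 0.1, dz), 16L),
               "axial range")
})
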
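test_that("serpentine rasters follow the closed-form geometry", {
  t1 <- makeGridTrajectory(10, 0.05)
  expect_equal(t1@metadata$nLines, 201L)
  expect_equal(nPoints(t1), 201L * 201L)
  expect_equal(pathLength(t1), 201 * 10 + 200 * 0.05, tolerance = 1e-9)
  # consecutive spacing equals the pitch everywhere (transits included)
  d <- coords(t1)
  gaps <- sqrt(rowSums((d[-1, ] - d[-nrow(d), ])^2))
  expect_lt(max(abs(gaps - 0.05)), 1e-9)

  # boundary case: pitch = field gives the two boundary lines
  t2 <- makeGridTrajectory(10, 10)
  expect_equal(t2@metadata$nLines, 2L)
  expect_equal(pathLength(t2), 2 * 10 + 1 * 10, tolerance = 1e-9)

  # pitch not dividing the field: lines stop at the last multiple inside
  t3 <- makeGridTrajectory(10, 0.3)
  expect_equal(t3@metadata$nLines, 34L)
  expect_equal(pathLength(t3), 34 * 9.9 + 33 * 0.3, tolerance = 1e-9)

  expect_error(makeGridTrajectory(10, 0), "positive")
  expect_error(makeGridTrajectory(10, 11), "exceed")
})

test_that("spirals end at the requested radius with uniform arc spacing", {
  sp <- makeSpiralTrajectory(5, 5, 0.05)
  m <- coords(sp)
  expect_equal(sqrt(sum(m[nrow(m), 1:2]^2)), 5, tolerance = 1e-6)
  # independent arc-length oracle: closed form s(theta) for r = a theta
  a <- 5 / (2 * pi * 5)
  th <- atan2(m[, 2], m[, 1]) + 2 * pi * floor((sqrt(m[, 1]^2 + m[, 2]^2) /
                                                  a - atan2(m[, 2], m[, 1]) +
                                                  pi) / (2 * pi))
  sArc <- a / 2 * (th * sqrt(1 + th^2) + asinh(th))
  interior <- diff(sArc)[-(nPoints(sp) - 1)]  # last gap is the remainder
  expect_lt(max(abs(interior - 0.05) / 0.05), 0.01)
  tiny <- makeSpiralTrajectory(1, 1, 100)
  expect_gte(nPoints(tiny), 2L)
})

test_that("sphere projection places tips at the standoff with inward gaze", {
  sph <- sphereFit(c(0, 0, 10), 10)
  traj <- projectToSphere(makeGridTrajectory(8, 0.5), sph, standoffMm = 1)
  tips <- tipPositions(traj)
  # all tips at radius - standoff from the centre
  rad <- sqrt(rowSums((tips - matrix(c(0, 0, 10), nrow(tips), 3,
                                     byrow = TRUE))^2))
  expect_lt(max(abs(rad - 9)), 1e-9)
  # centre point sits exactly one standoff above the sphere pole
  ic <- which.min(rowSums(tips[, 1:2]^2))
  expect_equal(unname(tips[ic, ]), c(0, 0, 1), tolerance = 1e-9)
  # orientations point radially at the retina (away from the centre)
  toCentre <- matrix(c(0, 0, 10), nrow(tips), 3, byrow = TRUE) - tips
  toCentre <- toCentre / sqrt(rowSums(toCentre^2))
  expect_lt(max(abs(rowSums(orientations(traj) * toCentre) + 1)), 1e-9)
  expect_error(projectToSphere(makeGridTrajectory(30, 1), sph), "equator")
})

test_that("greedy spacing subsampling obeys the arc-length rule", {
  line <- new("Trajectory",
              tipPositions = cbind(seq(0, 10, by = 0.05), 0, 0),
              orientations = matrix(rep(c(0, 0, -1), each = 201), ncol = 3),
              pattern = "grid", nominalSpacing = 0.05, metadata = list())
  expect_identical(subsampleSpacing(line, 0.05), line)
  s3 <- subsampleSpacing(line, 0.30)
  gaps <- diff(tipPositions(s3)[, 1])
  expect_true(all(gaps >= 0.300 - 1e-9 & gaps < 0.350))
  s2 <- subsampleSpacing(line, 0.15)
  expect_equal(nPoints(s2) / nPoints(line), 1 / 3, tolerance = 0.02)
  expect_error(subsampleSpacing(line, 0.01), ">=")
})

test_that("the timing model ties spacing, velocity and frequency", {
  tm <- timingModel(frequency = 40, velocity = 2)
  expect_equal(tm@spacing, 0.05)  # 50 um
  tm2 <- timingModel(frequency = 40, spacing = 0.3)
  expect_equal(tm2@velocity, 12)
  expect_error(timingModel(40), "at least one")
  expect_error(new("TimingModel", frequency = 40, velocity = 2,
                   spacing = 0.3), "velocity / frequency")
})

test_that("acquisition times scale with path length and velocity", {
  t1 <- makeGridTrajectory(10, 0.05)
  expect_equal(acquisitionTime(t1, timingModel(40, velocity = 2)), 1010)
  expect_equal(acquisitionTime(t1, timingModel(40, velocity = 4)), 505)
  # rigid motion leaves the time unchanged
  moved <- applyTransform(rigidTransform(
    rotationAboutAxis(c(1, 2, 3), 0.7), c(5, -2, 1)), t1)
  expect_equal(acquisitionTime(moved, timingModel(40, velocity = 2)), 1010,
               tolerance = 1e-9)
})
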
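test_that("MFME is the mean pairwise marker distance in micrometres", {
  m <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 0, 1))
  expect_equal(mfme(m, m), 0)
  expect_equal(mfme(rbind(c(0, 0, 0)), rbind(c(0.1, 0, 0))), 100)
  a <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  b <- rbind(c(0.001, 0, 0), c(0.002, 0, 0), c(0.003, 0, 0))
  expect_equal(mfme(a, b), 2)
  expect_error(mfme(a, b[1:2, ]), "equal counts")
})

test_that("Chamfer distance matches the exhaustive double loop", {
  a <- pointCloud(rbind(c(0, 0, 0)))
  b <- pointCloud(rbind(c(0, 0, 1)))
  expect_equal(chamferDistance(a, a), 0)
  expect_equal(chamferDistance(a, b), 1000)  # 1 mm, both directions

  set.seed(11)
  A <- matrix(rnorm(150), 50, 3)
  B <- matrix(rnorm(150), 50, 3)
  brute <- function(A, B) {
    dAB <- apply(A, 1, function(p) min(sqrt(colSums((t(B) - p)^2))))
    dBA <- apply(B, 1, function(p) min(sqrt(colSums((t(A) - p)^2))))
    (mean(dAB) + mean(dBA)) / 2 * 1000
  }
  expect_equal(chamferDistance(A, B), brute(A, B), tolerance = 1e-12)
  # symmetry and rigid invariance
  expect_equal(chamferDistance(A, B), chamferDistance(B, A))
  tf <- rigidTransform(rotationAboutAxis(c(1, -1, 2), 1.1), c(3, 2, -1))
  expect_equal(chamferDistance(applyTransform(tf, A), applyTransform(tf, B)),
               chamferDistance(A, B), tolerance = 1e-9)
})

test_that("cylinder cropping uses the smaller hull inradius", {
  th <- seq(0, 2 * pi, length.out = 2001)[-1]
  disc <- function(r) pointCloud(cbind(c(0, as.vector(outer(seq(0.2, 1, 0.2) * r, cos(th)))),
                                       c(0, as.vector(outer(seq(0.2, 1, 0.2) * r, sin(th)))),
                                       0))
  cr <- cropCylinder(disc(5), disc(4), c(0, 0, 0))
  expect_equal(cr$cropRadius, 4, tolerance = 1e-5)
  ra <- sqrt(rowSums(coords(cr$a)[, 1:2]^2))
  expect_lte(max(ra), 4 + 1e-4)

  # identical disc-shaped clouds: only a thin hull-boundary band removed
  g <- as.matrix(expand.grid(x = seq(-3, 3, 0.05), y = seq(-3, 3, 0.05)))
  g <- g[g[, 1]^2 + g[, 2]^2 <= 9, ]
  cl <- pointCloud(cbind(g, 0))
  both <- cropCylinder(cl, cl, c(0, 0, 0))
  expect_gt(both$cropRadius, 0.98 * 3)
  expect_gte(nPoints(both$a), nPoints(cl) * 0.97)

  # square of side 10: inradius 5, corners removed
  g <- as.matrix(expand.grid(x = seq(-5, 5, 0.5), y = seq(-5, 5, 0.5)))
  sq <- pointCloud(cbind(g, 0))
  crSq <- cropCylinder(sq, sq, c(0, 0, 0))
  expect_equal(crSq$cropRadius, 5, tolerance = 1e-9)
  expect_lt(nPoints(crSq$a), nPoints(sq))
  expect_error(cropCylinder(disc(2), disc(3), c(10, 0, 0)), "outside")
})

test_that("paired per-point comparison reports mean, sd and the t-test", {
  x <- c(1, 2, 3, 4, 5)
  same <- pairedCcComparison(x, x)
  expect_equal(same$meanDiff, 0)
  expect_true(same$degenerate)

  shift <- pairedCcComparison(rep(20, 100), rep(10, 100))
  expect_equal(shift$meanDiff, 10)
  expect_equal(shift$sd, 0)
  expect_true(shift$degenerate)
  expect_true(is.na(shift$pValue))

  set.seed(5)
  before <- rnorm(1000, 500, 100)
  after <- rnorm(1000, 100, 50)
  res <- pairedCcComparison(before, after)
  expect_false(res$degenerate)
  expect_lt(res$pValue, 1e-18)
  expect_equal(res$meanDiff, mean(before) - mean(after))
  expect_error(pairedCcComparison(1, 1), "at least 2")
})

test_that("distance histograms conserve counts and reduce to the Chamfer mean", {
  set.seed(21)
  A <- matrix(rnorm(120), 40, 3)
  B <- matrix(rnorm(120), 40, 3)
  h <- distanceHistogram(A, B, binWidthUm = 25)
  expect_equal(sum(h$counts), 80)
  # equal-sized clouds: the mean of the pooled distances is the CD
  expect_equal(mean(h$distances), chamferDistance(A, B), tolerance = 1e-9)

  hSame <- distanceHistogram(A, A)
  expect_equal(sum(hSame$counts > 0), 1L)
  expect_equal(hSame$counts[1], 80L)
})
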
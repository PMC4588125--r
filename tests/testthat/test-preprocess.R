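test_that("canonical HRF has the expected two-gamma shape", {
  h <- canonicalHrf(tr = 0.1)
  expect_equal(h[1], 0)                       # gamma density at 0, shape > 1
  expect_equal(max(h), 1)                     # peak-normalized
  peakT <- (which.max(h) - 1) * 0.1
  expect_gte(peakT, 4); expect_lte(peakT, 6)
  # exactly one sign change: positive lobe then undershoot
  sgn <- sign(h[abs(h) > 1e-12])
  expect_equal(sum(diff(sgn) != 0), 1)
  expect_error(canonicalHrf(peakDelay = -1), "positive")
  expect_error(canonicalHrf(kernelLength = 3), "exceed")
})

test_that("task regressor is the boxcar convolved with the kernel", {
  d <- visualBlockDesign()
  # identity kernel reproduces the boxcar
  reg <- taskRegressor(d, hrf = 1, retainOnly = FALSE)
  t <- (seq_len(nVolumes(d)) - 1) * repetitionTime(d)
  box <- as.numeric(t >= 20 & t < 40 | t >= 60 & t < 80 |
                    t >= 100 & t < 120)
  expect_equal(reg, box)
  # causality: zero before the first onset
  hrf <- canonicalHrf(tr = repetitionTime(d))
  regFull <- taskRegressor(d, hrf, retainOnly = FALSE)
  expect_true(all(regFull[t < 20] == 0))
  # brute-force convolution oracle
  oracle <- rep(0, nVolumes(d))
  for (i in seq_len(nVolumes(d)))
    for (k in seq_along(hrf))
      if (i - k + 1 >= 1)
        oracle[i] <- oracle[i] + hrf[k] * box[i - k + 1]
  expect_equal(regFull, oracle, tolerance = 1e-12)
  # 20 s into a block the response has plateaued near the kernel sum
  idx20 <- which.min(abs(t - 39.5))
  expect_gt(regFull[idx20], 0.9 * max(regFull))
  # retained-grid version is the truncation of the full one
  expect_equal(taskRegressor(d, hrf),
               regFull[(nDiscard(d) + 1):nVolumes(d)])
})

test_that("DCT high-pass basis has floor(2 n tr f) orthogonal columns", {
  b <- dctHighpassBasis(226, 0.645, 1 / 128)
  expect_equal(ncol(b), 2)                   # floor(2.277)
  g <- crossprod(b)
  expect_lt(max(abs(g - diag(diag(g)))), 1e-12)
  # cutoff below the fundamental: no drift modeled
  expect_equal(ncol(dctHighpassBasis(226, 0.645, 1e-5)), 0)
  expect_error(dctHighpassBasis(226, 0.645, 0), "positive")
})

test_that("Butterworth low-pass is zero-phase with unit DC gain", {
  tr <- 0.1
  expect_equal(butterworthLowpass(rep(3.7, 500), tr = tr, cutoff = 1),
               rep(3.7, 500), tolerance = 1e-6)
  # sinusoid at the cutoff: two passes of the half-power point -> 0.5
  f <- 1
  t <- (0:4999) * tr
  y <- butterworthLowpass(sin(2 * pi * f * t), tr = tr, cutoff = f)
  mid <- 1000:4000
  expect_lt(abs(max(abs(y[mid])) - 0.5), 0.025)
  # linearity
  x1 <- rnorm(300); x2 <- rnorm(300)
  expect_equal(butterworthLowpass(x1 + 2 * x2, tr = tr, cutoff = 1),
               butterworthLowpass(x1, tr = tr, cutoff = 1) +
                 2 * butterworthLowpass(x2, tr = tr, cutoff = 1),
               tolerance = 1e-8)
  # 0.75 Hz is realizable at tr 0.645 (Nyquist 0.775) but not at tr 0.7
  expect_silent(butterworthLowpass(rnorm(100), tr = 0.645))
  x <- rnorm(100)
  expect_warning(out <- butterworthLowpass(x, tr = 0.7), "Nyquist")
  expect_identical(out, x)
  expect_error(butterworthLowpass(x, order = 0, tr = 0.645), "order")
})

test_that("motion derivatives are backward differences with zero first row", {
  m <- matrix(rnorm(60), 10, 6)
  d <- motionDerivatives(m)
  expect_equal(d[1, ], rep(0, 6))
  expect_equal(d[-1, ], diff(m))
  ramp <- matrix(rep(0.3 * (0:9), 6), 10, 6)
  expect_equal(motionDerivatives(ramp)[-1, ], matrix(0.3, 9, 6))
  expect_equal(motionDerivatives(matrix(1, 5, 6)), matrix(0, 5, 6))
})

test_that("framewise displacement follows the mean-absolute-difference form", {
  expect_equal(framewiseDisplacement(matrix(0, 10, 6))$meanTranslational, 0)
  # single +0.3 mm step on one translation axis at N = 2
  m <- matrix(0, 2, 6); m[2, 1] <- 0.3
  fd <- framewiseDisplacement(m)
  expect_equal(fd$translational, c(0, 0.1))
  expect_equal(fd$meanTranslational, 0.1)
  # radians input matches the same table pre-converted to degrees
  m2 <- matrix(rnorm(60, sd = 0.01), 10, 6)
  m2deg <- m2; m2deg[, 4:6] <- m2deg[, 4:6] * 180 / pi
  expect_equal(framewiseDisplacement(m2, rotationUnit = "rad"),
               framewiseDisplacement(m2deg, rotationUnit = "deg"))
  expect_error(framewiseDisplacement(matrix(0, 5, 5)), "6 columns")
})

test_that("residualization is an orthogonal, idempotent projection", {
  set.seed(8)
  n <- 100
  nuis <- cbind(a = rnorm(n), b = rnorm(n))
  x <- 3 * nuis[, 1] + rnorm(n)
  r <- residualize(x, nuis)
  expect_lt(abs(cor(r, nuis[, 1])), 1e-10)
  expect_lt(max(abs(crossprod(nuis, r))), 1e-9)
  expect_equal(residualize(r, nuis), r, tolerance = 1e-12)
  # normal-equations oracle
  X <- cbind(1, nuis)
  beta <- solve(t(X) %*% X, t(X) %*% x)
  expect_equal(r, as.numeric(x - X %*% beta), tolerance = 1e-10)
  # rank deficiency names the collinear column
  bad <- cbind(nuis, dup = nuis[, 1])
  expect_error(residualize(x, bad), "rank-deficient")
})

test_that("the joint nuisance set is labelled and full rank", {
  d <- visualBlockDesign()
  cfg <- syntheticConfig(nSubjects = 1L, seed = 4L)
  ds <- simulateCohort(cfg)
  nuis <- buildNuisance(d, motion = cohortMotion(ds)[[1]])
  expect_equal(nrow(nuis), nRetained(d))
  labs <- attr(nuis, "labels")
  expect_equal(ncol(nuis), length(labs))
  expect_setequal(unique(labs),
                  c("task", "motion", "motion-derivative", "dct"))
  expect_equal(qr(cbind(1, nuis))$rank, ncol(nuis) + 1)
  # residuals after preprocessing are orthogonal to the task regressor
  pp <- preprocessSeries(cohortSubjects(ds)[[1]], d,
                         motion = cohortMotion(ds)[[1]],
                         lowpassCutoff = NULL)
  reg <- taskRegressor(d)
  for (j in seq_len(ncol(pp@values)))
    expect_lt(abs(cor(pp@values[, j], reg)), 1e-10)
})
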
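test_that("kernel weights follow the printed Gaussian form literally", {
  w <- kernelWeights(kernelSpec(h = 24))
  expect_equal(unname(w["0"]), 1)
  expect_equal(unname(w["12"]), exp(-144 / 24), tolerance = 1e-15)
  expect_equal(length(w), 25)                  # symmetric support +-12
  expect_equal(unname(w), unname(rev(w)))      # even function
  wr <- kernelWeights(kernelSpec(h = 24, shape = "rectangular"))
  expect_equal(unname(wr), rep(1, 25))
  expect_error(kernelSpec(h = 2), ">= 3")
})

test_that("weighted correlation matches the longhand oracle and is bounded", {
  set.seed(3)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- rnorm(n); w <- runif(n, 0.1, 2)
    expect_equal(weightedCorrelation(x, y, w), weightedCorOracle(x, y, w),
                 tolerance = 1e-13)
  }
  # affine dependence
  x <- rnorm(10); w <- runif(10, 0.5, 1)
  expect_equal(weightedCorrelation(x, 2 * x + 5, w), 1)
  expect_equal(weightedCorrelation(x, -x, w), -1)
  # degenerate cases signal NA, not an error
  expect_true(is.na(weightedCorrelation(rep(1, 10), rnorm(10), w)))
  expect_true(is.na(weightedCorrelation(x, x, c(1, 1, rep(0, 8)))))
})

test_that("TVCC is exact on degenerate inputs and at the uniform limit", {
  set.seed(5)
  x <- rnorm(60)
  tv <- tvcc(x, x, kernelSpec(h = 10))
  expect_lt(max(abs(tvccR(tv)[tvccValid(tv)] - 1)), 1e-12)
  # rectangular window spanning the whole series = global Pearson r
  y <- 0.5 * x + rnorm(60)
  n <- 61; x2 <- rnorm(n); y2 <- 0.3 * x2 + rnorm(n)
  tvr <- tvcc(x2, y2, kernelSpec(h = 60, shape = "rectangular"))
  center <- 31                                  # window covers 1..61
  expect_equal(tvccR(tvr)[center], cor(x2, y2), tolerance = 1e-12)
  expect_error(tvcc(x, x, kernelSpec(h = 60)), "too short")
})

test_that("TVCC is invariant to affine rescaling up to sign", {
  set.seed(11)
  x <- rnorm(120); y <- rnorm(120)
  spec <- kernelSpec(h = 24)
  base <- tvccR(tvcc(x, y, spec))
  expect_equal(tvccR(tvcc(3 * x + 7, 0.5 * y - 2, spec)), base,
               tolerance = 1e-12)
  expect_equal(tvccR(tvcc(-2 * x, y, spec)), -base, tolerance = 1e-12)
})

test_that("Gaussian TVCC approaches rectangular TVCC as h grows", {
  set.seed(13)
  x <- rnorm(100); y <- rnorm(100)
  # fixed support (+-12 points), flatter and flatter weights
  rect <- tvccR(tvcc(x, y, kernelSpec(h = 24, shape = "rectangular")))
  dev <- vapply(c(24, 1000, 1e6), function(hh) {
    w <- exp(-(-12:12)^2 / hh)
    g <- vapply(13:88, function(t)
      weightedCorrelation(x[(t - 12):(t + 12)], y[(t - 12):(t + 12)], w),
      numeric(1))
    max(abs(g - rect[13:88]))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 0.01)
})

test_that("Fisher transform is the clipped atanh with exact round trip", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), atanh(0.5))
  expect_equal(round(fisherZ(0.5), 4), 0.5493)
  r <- seq(-0.999, 0.999, by = 0.003)
  expect_equal(fisherZInv(fisherZ(r)), r, tolerance = 1e-10)
  expect_true(is.finite(fisherZ(1)))
  expect_true(all(diff(fisherZ(seq(-0.99, 0.99, 0.01))) > 0))
})

test_that("epoch sample grids follow the half-open interval arithmetic", {
  expect_equal(epochOffsets(c(-10, 0), 0.645), -15:-1)   # 15 samples
  expect_equal(epochOffsets(c(-10, 30), 0.645), -15:46)
  expect_equal(epochOffsets(c(0, 10), 0.645), 0:15)      # 16 samples
  expect_equal(epochOffsets(c(10, 20), 0.645), 16:31)
})

test_that("epoch averaging is the element-wise cycle mean", {
  d <- visualBlockDesign()
  n <- nRetained(d)
  oi <- onsetIndices(d)
  k <- epochOffsets(c(-10, 30), repetitionTime(d))
  # identical segments in every cycle: average equals any one segment
  v <- rep(0, n)
  seg <- sin(seq_along(k))
  for (o in oi) v[o + k] <- seg
  expect_equal(epochAverage(v, d)$mean, seg)
  # random series: matches the longhand mean of the three segments
  set.seed(17)
  v <- rnorm(n)
  a <- v[oi[1] + k]; b <- v[oi[2] + k]; c_ <- v[oi[3] + k]
  expect_equal(epochAverage(v, d)$mean, (a + b + c_) / 3)
  # a window that leaves the series errors with the cycle named
  expect_error(epochAverage(v, d, window = c(-10, 60)), "cycle 3")
})

test_that("point-wise slopes recover linear trends exactly", {
  tt <- seq(-10, 30, by = 0.645)
  expect_equal(pointwiseSlope(3.2 * tt - 1, tt), rep(3.2, length(tt)))
  expect_equal(pointwiseSlope(rep(2, length(tt)), tt),
               rep(0, length(tt)))
  # closed-form oracle at every sample, including truncated edges
  set.seed(19)
  v <- rnorm(length(tt))
  sl <- pointwiseSlope(v, tt, fitWindow = 16)
  half <- floor(8 / 0.645)
  for (i in c(1, 5, 30, length(tt))) {
    idx <- max(1, i - half):min(length(tt), i + half)
    tc <- tt[idx] - mean(tt[idx])
    expect_equal(sl[i], sum(tc * (v[idx] - mean(v[idx]))) / sum(tc^2),
                 tolerance = 1e-12)
  }
})

test_that("sub-period FC is the cycle-mean Fisher z of plain correlations", {
  d <- visualBlockDesign()
  n <- nRetained(d)
  set.seed(23)
  x <- rnorm(n)
  # x with itself: every cell is the clipped atanh(1)
  sp <- subPeriodFcSubject(x, x, d)
  expect_equal(unname(sp), rep(atanh(1 - 1e-7), 4))
  # longhand oracle on a random pair
  y <- rnorm(n)
  oi <- onsetIndices(d)
  breaks <- c(-10, 0, 10, 20, 30)
  oracle <- numeric(4)
  for (q in 1:4) {
    zs <- numeric(3)
    for (c_ in 1:3) {
      k <- epochOffsets(breaks[q:(q + 1)], repetitionTime(d))
      zs[c_] <- atanh(cor(x[oi[c_] + k], y[oi[c_] + k]))
    }
    oracle[q] <- mean(zs)
  }
  expect_equal(unname(subPeriodFcSubject(x, y, d)), oracle,
               tolerance = 1e-9)
})

test_that("cohort sub-period FC recovers a constant correlation level", {
  cfg <- noiseOnlyConfig(nSubjects = 200L, seed = 29L, rho = 0.5)
  ds <- simulateCohort(cfg)
  xs <- lapply(cohortSubjects(ds), function(s) s@values[, "LMOG"])
  ys <- lapply(cohortSubjects(ds), function(s) s@values[, "LFuG"])
  sp <- subPeriodFc(xs, ys, cfg@design, pair = c("LMOG", "LFuG"))
  means <- colMeans(subPeriodValues(sp))
  expect_true(all(abs(means - atanh(0.5)) < 0.05))
})
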
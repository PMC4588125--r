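test_that("BH step-up matches the hand-worked example and edge cases", {
  # p(4) = 0.04 <= 4 * 0.05 / 4, so every smaller p is admitted too
  r <- bhFdr(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(r$reject))
  expect_equal(r$threshold, 0.04)
  expect_false(any(bhFdr(rep(1, 5))$reject))
  # m = 1 reduces to p <= alpha
  expect_true(bhFdr(0.049)$reject)
  expect_false(bhFdr(0.051)$reject)
  # stable under input reordering
  p <- c(0.3, 0.001, 0.04, 0.9, 0.012)
  expect_equal(bhFdr(p)$reject[order(p)],
               bhFdr(sort(p))$reject)
})

test_that("BH adjusted p-values agree with the reference implementation", {
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))^2
    r <- bhFdr(p, alpha = 0.05)
    expect_equal(r$adjusted, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_equal(r$reject, p.adjust(p, "BH") <= 0.05)
  }
})

test_that("BH rejections are monotone in alpha", {
  set.seed(9)
  p <- runif(40)^1.5
  r1 <- bhFdr(p, alpha = 0.02)
  r2 <- bhFdr(p, alpha = 0.10)
  expect_true(all(r2$reject[r1$reject]))
})

test_that("per-subject baselines are means over the pre-stimulus samples", {
  relT <- seq(-10, 29.9, by = 0.645)
  relT <- relT[relT < 30]
  mat <- matrix(rnorm(5 * length(relT)), 5)
  ep <- new("EpochedSeries", quantity = "fc_z", relTimes = relT,
            perSubject = mat, tr = 0.645)
  b <- baselinePerSubject(ep)
  sel <- relT >= -10 & relT < 0
  expect_equal(b, rowMeans(mat[, sel]))
  expect_equal(baselinePerSubject(
    new("EpochedSeries", quantity = "fc_z", relTimes = relT,
        perSubject = matrix(7, 2, length(relT)), tr = 0.645)),
    c(7, 7))
  expect_error(baselinePerSubject(ep, c(50, 60)), "no epoch samples")
})

test_that("point-wise baseline tests match the textbook t formula", {
  set.seed(11)
  relT <- (-15:46) * 0.645
  n <- 12
  mat <- matrix(rnorm(n * length(relT)), n)
  ep <- new("EpochedSeries", quantity = "fc_z", relTimes = relT,
            perSubject = mat, tr = 0.645)
  res <- pointwiseBaselineTest(ep)
  b <- baselinePerSubject(ep)
  sel <- which(relT >= 0)
  for (j in c(1, 10, length(sel))) {
    d <- mat[, sel[j]] - b
    tOracle <- mean(d) / (sd(d) / sqrt(n))
    expect_equal(res$t[j], tOracle, tolerance = 1e-12)
    expect_equal(res$p[j], 2 * pt(-abs(tOracle), n - 1),
                 tolerance = 1e-12)
  }
  # epochs identical to baselines: nothing rejected
  flat <- matrix(rep(rnorm(n), length(relT)), n)
  epFlat <- new("EpochedSeries", quantity = "fc_z", relTimes = relT,
                perSubject = flat, tr = 0.645)
  resFlat <- pointwiseBaselineTest(epFlat)
  expect_true(all(resFlat$t == 0))
  expect_false(any(resFlat$reject))
  expect_true(all(resFlat$degenerate))
  # a consistent shift at one sample is detected
  shift <- flat
  shift[, which(relT >= 0)[5]] <- shift[, which(relT >= 0)[5]] + 1 +
    rnorm(n, sd = 1e-3)
  epS <- new("EpochedSeries", quantity = "fc_z", relTimes = relT,
             perSubject = shift, tr = 0.645)
  resS <- pointwiseBaselineTest(epS)
  expect_true(resS$reject[5])
  expect_equal(resS$direction[5], 1)
  # permuting subjects leaves the statistics unchanged
  resPerm <- pointwiseBaselineTest(
    new("EpochedSeries", quantity = "fc_z", relTimes = relT,
        perSubject = mat[sample(n), ], tr = 0.645))
  expect_equal(resPerm$t, res$t)
})

test_that("trend tests flag consistent slopes and respect exchangeability", {
  relT <- (-15:46) * 0.645
  n <- 10
  zero <- new("EpochedSeries", quantity = "slope", relTimes = relT,
              perSubject = matrix(0, n, length(relT)), tr = 0.645)
  expect_false(any(pointwiseTrendTest(zero)$reject))
  set.seed(13)
  mat <- matrix(rnorm(n * length(relT)), n)
  mat[, 20] <- -0.5 + rnorm(n, sd = 0.05)
  ep <- new("EpochedSeries", quantity = "slope", relTimes = relT,
            perSubject = mat, tr = 0.645)
  res <- pointwiseTrendTest(ep)
  expect_true(res$reject[20])
  expect_equal(res$direction[20], -1)
})

test_that("repeated-measures ANOVA partitions the within-subject SS", {
  # identical rows across conditions: no condition effect
  flat <- matrix(rep(rnorm(6), 4), 6, 4)
  r <- rmAnovaOneway(flat)
  expect_equal(r$f, 0)
  expect_equal(r$p, 1)
  # k = 2: F equals the squared paired t
  set.seed(17)
  a <- rnorm(9); b <- rnorm(9)
  r2 <- rmAnovaOneway(cbind(a, b))
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(r2$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
  # longhand sums-of-squares oracle on a 4 x 4 integer table
  m <- matrix(c(3, 5, 4, 6,
                2, 4, 5, 7,
                6, 7, 7, 9,
                1, 2, 4, 4), 4, 4, byrow = TRUE)
  grand <- mean(m)
  ssS <- 0; ssC <- 0; ssT <- 0
  for (i in 1:4) ssS <- ssS + 4 * (mean(m[i, ]) - grand)^2
  for (j in 1:4) ssC <- ssC + 4 * (mean(m[, j]) - grand)^2
  for (i in 1:4) for (j in 1:4) ssT <- ssT + (m[i, j] - grand)^2
  ssE <- ssT - ssS - ssC
  fOracle <- (ssC / 3) / (ssE / 9)
  r4 <- rmAnovaOneway(m)
  expect_equal(r4$f, fOracle, tolerance = 1e-12)
  expect_equal(r4$dfCondition, 3)
  expect_equal(r4$dfError, 9)
  expect_error(rmAnovaOneway(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("repeated-measures ANOVA agrees with aov with an Error stratum", {
  set.seed(19)
  n <- 8; k <- 4
  m <- matrix(rnorm(n * k), n, k) + rnorm(n)   # subject effects included
  df <- data.frame(y = as.numeric(m),
                   subj = factor(rep(seq_len(n), times = k)),
                   cond = factor(rep(seq_len(k), each = n)))
  fit <- summary(aov(y ~ cond + Error(subj), data = df))
  tab <- fit[["Error: Within"]][[1]]
  r <- rmAnovaOneway(m)
  expect_equal(r$f, tab[1, "F value"], tolerance = 1e-10)
  expect_equal(r$p, tab[1, "Pr(>F)"], tolerance = 1e-10)
  # Greenhouse-Geisser epsilon is bounded and deflates both df
  rg <- rmAnovaOneway(m, greenhouseGeisser = TRUE)
  expect_gte(rg$epsilon, 1 / (k - 1))
  expect_lte(rg$epsilon, 1 + 1e-9)
  expect_equal(rg$pGG,
               pf(rg$f, rg$epsilon * rg$dfCondition,
                  rg$epsilon * rg$dfError, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("post-hoc tests are gated on the ANOVA and FDR-corrected", {
  set.seed(23)
  m <- matrix(rnorm(40), 10, 4)
  expect_false(posthocAdjacent(m, gateP = 0.2)$gated)
  # equal EARLY and LATE columns give a zero middle statistic
  m2 <- m; m2[, 3] <- m2[, 2]
  r <- posthocAdjacent(m2, gateP = 0.01)
  expect_true(r$gated)
  expect_equal(r$tests$t[2], 0)
  expect_equal(r$tests$p[2], 1)
  # each paired t matches the reference implementation
  m3 <- matrix(rnorm(60), 15, 4)
  r3 <- posthocAdjacent(m3, gateP = 0.001)
  for (j in 1:3) {
    tt <- t.test(m3[, j], m3[, j + 1], paired = TRUE)
    expect_equal(r3$tests$t[j], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(r3$tests$p[j], tt$p.value, tolerance = 1e-10)
  }
  expect_equal(r3$tests$reject,
               as.logical(bhFdr(r3$tests$p)$reject))
})
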
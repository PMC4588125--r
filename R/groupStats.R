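#' Benjamini-Hochberg FDR step-up procedure
#'
#' Classical step-up: sort the p-values, find the largest rank i with
#' p(i) <= i * alpha / m, and reject all hypotheses of rank <= i. Stable
#' with respect to input order; NA p-values are never rejected and do not
#' count toward m.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @param alpha numeric(1), target FDR level (default 0.05).
#' @return list with \code{reject} (logical, input order),
#'   \code{threshold} (largest admitted p-value, 0 if none) and
#'   \code{adjusted} (BH-adjusted p-values).
#' @export
bhFdr <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  ok <- !is.na(p)
  m <- sum(ok)
  reject <- rep(FALSE, length(p))
  adjusted <- rep(NA_real_, length(p))
  threshold <- 0
  if (m > 0L) {
    ord <- order(p[ok])
    ps <- p[ok][ord]
    crit <- seq_len(m) * alpha / m
    pass <- which(ps <= crit)
    adj <- rev(cummin(rev(ps * m / seq_len(m))))
    adj <- pmin(adj, 1)
    if (length(pass)) {
      iMax <- max(pass)
      threshold <- ps[iMax]
      rej <- logical(m)
      rej[ord[seq_len(iMax)]] <- TRUE
      reject[ok] <- rej
    }
    tmp <- numeric(m)
    tmp[ord] <- adj
    adjusted[ok] <- tmp
  }
  list(reject = reject, threshold = threshold, adjusted = adjusted)
}

# one-sample two-tailed t-test per column of a subjects x samples matrix
# of differences; zero across-subject variance yields t = 0, p = 1 with a
# degenerate flag so pathological inputs complete.
.columnTTests <- function(diffs) {
  n <- nrow(diffs)
  mns <- colMeans(diffs)
  sds <- apply(diffs, 2L, stats::sd)
  degenerate <- sds == 0
  tStat <- ifelse(degenerate, 0, mns / (sds / sqrt(n)))
  pVal <- ifelse(degenerate, 1,
                 2 * stats::pt(-abs(tStat), df = n - 1L))
  list(estimate = mns, t = tStat, p = pVal, degenerate = degenerate)
}

#' Per-subject baseline of an epoched quantity
#'
#' The mean over the samples whose relative time falls in the baseline
#' interval (half-open; default the pre-stimulus [-10, 0) s).
#'
#' @param epoched An [EpochedSeries-class].
#' @param baselineInterval numeric(2), seconds (default c(-10, 0)).
#' @return numeric, one baseline per subject.
#' @export
baselinePerSubject <- function(epoched, baselineInterval = c(-10, 0)) {
  sel <- epoched@relTimes >= baselineInterval[1L] - 1e-9 &
         epoched@relTimes < baselineInterval[2L] - 1e-9
  if (!any(sel)) stop("baseline interval contains no epoch samples")
  rowMeans(epoched@perSubject[, sel, drop = FALSE])
}

#' Point-wise baseline-referenced group test
#'
#' For every post-onset sample (relative time >= 0), a two-tailed
#' one-sample t-test across subjects of (value - subject baseline),
#' followed by Benjamini-Hochberg FDR correction jointly over the tested
#' samples of this signal.
#'
#' @param epoched An [EpochedSeries-class] (cycle-averaged BOLD or FC z).
#' @param baselines numeric, per-subject baselines
#'   (default [baselinePerSubject()] on the pre-stimulus interval).
#' @param alpha numeric(1), FDR level (default 0.05).
#' @return data.frame with one row per tested sample: \code{relTime},
#'   \code{estimate} (group mean difference), \code{t}, \code{p},
#'   \code{reject}, \code{direction} (sign of the mean difference) and
#'   \code{degenerate}; the BH threshold is attached as attribute
#'   \code{"threshold"}.
#' @export
pointwiseBaselineTest <- function(epoched,
                                  baselines = baselinePerSubject(epoched),
                                  alpha = 0.05) {
  if (nrow(epoched@perSubject) < 2L) stop("need at least 2 subjects")
  sel <- epoched@relTimes >= -1e-9
  diffs <- sweep(epoched@perSubject[, sel, drop = FALSE], 1L, baselines)
  tt <- .columnTTests(diffs)
  fdr <- bhFdr(tt$p, alpha)
  out <- data.frame(relTime = epoched@relTimes[sel],
                    estimate = tt$estimate, t = tt$t, p = tt$p,
                    reject = fdr$reject, direction = sign(tt$estimate),
                    degenerate = tt$degenerate, row.names = NULL)
  attr(out, "threshold") <- fdr$threshold
  attr(out, "alpha") <- alpha
  out
}

#' Point-wise trend (slope) group test
#'
#' Two-tailed one-sample t-test of the per-subject slope against zero at
#' every epoch sample with a defined slope, with BH-FDR correction over
#' the tested samples.
#'
#' @param slopes An [EpochedSeries-class] of quantity \code{"slope"}
#'   (see [pointwiseSlope()]).
#' @param alpha numeric(1), FDR level.
#' @return data.frame as in [pointwiseBaselineTest()].
#' @export
pointwiseTrendTest <- function(slopes, alpha = 0.05) {
  if (nrow(slopes@perSubject) < 2L) stop("need at least 2 subjects")
  ok <- colSums(is.na(slopes@perSubject)) == 0L
  vals <- slopes@perSubject[, ok, drop = FALSE]
  tt <- .columnTTests(vals)
  fdr <- bhFdr(tt$p, alpha)
  out <- data.frame(relTime = slopes@relTimes[ok],
                    estimate = tt$estimate, t = tt$t, p = tt$p,
                    reject = fdr$reject, direction = sign(tt$estimate),
                    degenerate = tt$degenerate, row.names = NULL)
  attr(out, "threshold") <- fdr$threshold
  attr(out, "alpha") <- alpha
  out
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject sums-of-squares partition for a subjects x conditions
#' matrix: SS_total = SS_subjects + SS_conditions + SS_error, with
#' F = MS_conditions / MS_error on (k - 1, (n - 1)(k - 1)) degrees of
#' freedom. No sphericity correction is applied by default; a
#' Greenhouse-Geisser-corrected p-value is available via
#' \code{greenhouseGeisser = TRUE}.
#'
#' @param data numeric matrix, subjects x conditions (no missing cells).
#' @param greenhouseGeisser logical, also report the epsilon-corrected
#'   p-value.
#' @return list with \code{f}, \code{dfCondition}, \code{dfError},
#'   \code{p}, the sums of squares, and (optionally) \code{epsilon} and
#'   \code{pGG}.
#' @export
rmAnovaOneway <- function(data, greenhouseGeisser = FALSE) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("missing cells are not allowed")
  n <- nrow(data)
  k <- ncol(data)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 conditions")
  grand <- mean(data)
  ssSubject <- k * sum((rowMeans(data) - grand)^2)
  ssCondition <- n * sum((colMeans(data) - grand)^2)
  ssTotal <- sum((data - grand)^2)
  ssError <- ssTotal - ssSubject - ssCondition
  dfC <- k - 1L
  dfE <- (n - 1L) * (k - 1L)
  msC <- ssCondition / dfC
  msE <- ssError / dfE
  f <- if (msE > 0) msC / msE else if (msC == 0) 0 else Inf
  p <- if (msE > 0) stats::pf(f, dfC, dfE, lower.tail = FALSE)
       else if (msC == 0) 1 else 0
  if (msC == 0) {  # no condition effect at all
    f <- 0
    p <- 1
  }
  out <- list(f = f, dfCondition = dfC, dfError = dfE, p = p,
              ssSubject = ssSubject, ssCondition = ssCondition,
              ssError = ssError)
  if (greenhouseGeisser) {
    S <- stats::cov(data)
    dS <- mean(diag(S))
    mS <- mean(S)
    rowM <- rowMeans(S)
    eps <- (k * (dS - mS))^2 /
      ((k - 1) * (sum(S^2) - 2 * k * sum(rowM^2) + k^2 * mS^2))
    out$epsilon <- eps
    out$pGG <- stats::pf(f, dfC * eps, dfE * eps, lower.tail = FALSE)
  }
  out
}

# paired two-tailed t-test from the textbook difference formula; zero
# variance of the differences is handled explicitly.
.pairedT <- function(a, b) {
  d <- a - b
  n <- length(d)
  sd_ <- stats::sd(d)
  m <- mean(d)
  if (sd_ == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t <- m / (sd_ / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1L)
  }
  c(estimate = m, t = t, p = p)
}

#' Post-hoc adjacent-pair comparisons, gated on the ANOVA
#'
#' Run only when the repeated-measures ANOVA p-value is below the gate
#' (0.05): paired two-tailed t-tests between adjacent sub-periods
#' (PRE vs EARLY, EARLY vs LATE, LATE vs POST), with BH-FDR correction
#' over the three tests.
#'
#' @param data numeric matrix, subjects x 4 (PRE/EARLY/LATE/POST).
#' @param gateP numeric(1), the ANOVA p-value.
#' @param alpha numeric(1), FDR level for the post-hoc family.
#' @param gate numeric(1), the ANOVA significance gate (default 0.05).
#' @return list with \code{gated} (logical: were the tests run?) and, when
#'   gated in, a data.frame \code{tests} with columns \code{comparison},
#'   \code{estimate}, \code{t}, \code{p}, \code{reject}.
#' @export
posthocAdjacent <- function(data, gateP, alpha = 0.05, gate = 0.05) {
  data <- as.matrix(data)
  stopifnot(ncol(data) == 4L)
  if (is.na(gateP) || gateP >= gate)
    return(list(gated = FALSE, tests = NULL))
  cmp <- list(c(1L, 2L), c(2L, 3L), c(3L, 4L))
  labs <- c("PRE-EARLY", "EARLY-LATE", "LATE-POST")
  res <- t(vapply(cmp, function(ij)
    .pairedT(data[, ij[1L]], data[, ij[2L]]), numeric(3L)))
  fdr <- bhFdr(res[, "p"], alpha)
  list(gated = TRUE,
       tests = data.frame(comparison = labs,
                          estimate = res[, "estimate"],
                          t = res[, "t"], p = res[, "p"],
                          reject = fdr$reject, row.names = NULL))
}

#' Sub-period ANOVA with post-hoc tests for one ROI pair
#'
#' Convenience wrapper: repeated-measures ANOVA over the four sub-period
#' Fisher-z FC values followed by the gated adjacent-pair post-hoc tests.
#'
#' @param subPeriod A [SubPeriodFc-class].
#' @param alpha numeric(1), FDR level for the post-hoc family.
#' @param greenhouseGeisser logical, see [rmAnovaOneway()].
#' @return list with \code{anova} (see [rmAnovaOneway()]) and
#'   \code{posthoc} (see [posthocAdjacent()]).
#' @export
subPeriodInference <- function(subPeriod, alpha = 0.05,
                               greenhouseGeisser = FALSE) {
  an <- rmAnovaOneway(subPeriod@perSubject,
                      greenhouseGeisser = greenhouseGeisser)
  ph <- posthocAdjacent(subPeriod@perSubject, an$p, alpha)
  list(anova = an, posthoc = ph)
}
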
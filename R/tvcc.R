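#' Sliding-window kernel weights
#'
#' For the Gaussian kernel the weight at integer offset u is
#' exp(-u^2 / h) on the symmetric support |u| <= floor(h / 2) — taken
#' literally with u in samples and h the window size in samples, so with
#' h = 24 the edge weight is exp(-144/24) = exp(-6). The rectangular
#' kernel puts weight 1 on the same support. Weights are not
#' pre-normalized; normalization happens inside the weighted moments.
#'
#' @param spec A [KernelSpec-class].
#' @return named numeric vector of weights at offsets
#'   -floor(h/2) .. +floor(h/2).
#' @export
kernelWeights <- function(spec) {
  stopifnot(is(spec, "KernelSpec"))
  m <- floor(spec@h / 2)
  u <- seq.int(-m, m)
  w <- switch(spec@shape,
              gaussian = exp(-u^2 / spec@h),
              rectangular = rep(1, length(u)))
  names(w) <- u
  w
}

#' Weighted Pearson correlation
#'
#' r = sum w (x - xbar_w)(y - ybar_w) /
#'     sqrt(sum w (x - xbar_w)^2 * sum w (y - ybar_w)^2),
#' with weight-normalized means. Returns NA (the undefined-correlation
#' signal) rather than raising when fewer than 3 samples carry positive
#' weight or either weighted variance is zero.
#'
#' @param x,y numeric vectors of equal length.
#' @param w numeric weights, same length, all >= 0.
#' @return numeric(1) in [-1, 1], or NA if undefined.
#' @export
weightedCorrelation <- function(x, y, w) {
  stopifnot(length(x) == length(y), length(x) == length(w), all(w >= 0))
  if (sum(w > 0) < 3L) return(NA_real_)
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  dx <- x - mx
  dy <- y - my
  vx <- sum(w * dx^2)
  vy <- sum(w * dy^2)
  scale <- max(vx, vy)
  if (scale <= 0 || vx <= 1e-14 * scale || vy <= 1e-14 * scale)
    return(NA_real_)
  r <- sum(w * dx * dy) / sqrt(vx * vy)
  min(1, max(-1, r))
}

#' Fisher z-transform and its inverse
#'
#' z = atanh(r) after clipping |r| to 1 - 1e-7, so perfectly correlated
#' windows map to a large finite value instead of infinity.
#'
#' @param r numeric, correlation(s) with |r| <= 1.
#' @return numeric, transformed values.
#' @export
fisherZ <- function(r) {
  lim <- 1 - 1e-7
  atanh(pmin(pmax(r, -lim), lim))
}

#' @rdname fisherZ
#' @param z numeric, Fisher z value(s).
#' @export
fisherZInv <- function(z) tanh(z)

#' Time-varying correlation coefficient (TVCC)
#'
#' Windowed correlation of two equal-length series, estimated at every
#' sample by [weightedCorrelation()] over the kernel window centered
#' there. At the series edges the window is truncated to the available
#' samples and the remaining weights are renormalized — the series is
#' never padded or reflected. Samples whose truncated window holds fewer
#' than 3 points, or where either windowed variance vanishes, are marked
#' invalid (NA).
#'
#' @param x,y numeric vectors, length > h.
#' @param spec A [KernelSpec-class] (default Gaussian, h = 24).
#' @param tr numeric(1), sampling interval in seconds (metadata).
#' @param t0 numeric(1), time of the first sample (metadata).
#' @param pair character(2), ROI names (metadata).
#' @return A [TvccSeries-class].
#' @examples
#' set.seed(1)
#' x <- rnorm(200); y <- 0.7 * x + rnorm(200, sd = sqrt(1 - 0.49))
#' tv <- tvcc(x, y)
#' mean(tvccR(tv), na.rm = TRUE)
#' @export
tvcc <- function(x, y, spec = kernelSpec(), tr = 1, t0 = 0,
                 pair = c("x", "y")) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n <= spec@h) stop("input too short: length must exceed h")
  w <- kernelWeights(spec)
  m <- floor(spec@h / 2)
  offsets <- seq.int(-m, m)
  # center for numerical stability (correlation is offset-invariant)
  xc <- x - mean(x)
  yc <- y - mean(y)
  Sw <- Sx <- Sy <- Sxx <- Syy <- Sxy <- Cnt <- numeric(n)
  for (j in seq_along(offsets)) {
    u <- offsets[j]
    wt <- w[j]
    tIdx <- max(1L, 1L - u):min(n, n - u)   # centers with sample t+u in range
    sIdx <- tIdx + u
    Sw[tIdx] <- Sw[tIdx] + wt
    Cnt[tIdx] <- Cnt[tIdx] + 1
    Sx[tIdx] <- Sx[tIdx] + wt * xc[sIdx]
    Sy[tIdx] <- Sy[tIdx] + wt * yc[sIdx]
    Sxx[tIdx] <- Sxx[tIdx] + wt * xc[sIdx]^2
    Syy[tIdx] <- Syy[tIdx] + wt * yc[sIdx]^2
    Sxy[tIdx] <- Sxy[tIdx] + wt * xc[sIdx] * yc[sIdx]
  }
  mx <- Sx / Sw
  my <- Sy / Sw
  vx <- Sxx / Sw - mx^2
  vy <- Syy / Sw - my^2
  cv <- Sxy / Sw - mx * my
  scale <- pmax(vx, vy)
  valid <- Cnt >= 3 & scale > 0 & vx > 1e-14 * scale & vy > 1e-14 * scale
  r <- rep(NA_real_, n)
  r[valid] <- pmin(1, pmax(-1, cv[valid] / sqrt(vx[valid] * vy[valid])))
  z <- rep(NA_real_, n)
  z[valid] <- fisherZ(r[valid])
  new("TvccSeries", pair = as.character(pair), r = r, z = z,
      kernel = spec, validMask = valid, tr = as.numeric(tr),
      t0 = as.numeric(t0))
}

#' @rdname tvcc
#' @param object A TvccSeries.
#' @export
tvccR <- function(object) object@r

#' @rdname tvcc
#' @export
tvccZ <- function(object) object@z

#' @rdname tvcc
#' @export
tvccValid <- function(object) object@validMask

#' Relative-time sample offsets for an epoch window
#'
#' Integer offsets k with lo <= k * tr < hi (half-open interval).
#'
#' @param window numeric(2), c(lo, hi) in seconds relative to onset.
#' @param tr numeric(1), sampling interval in seconds.
#' @return integer vector of offsets.
#' @export
epochOffsets <- function(window, tr) {
  kLo <- ceiling(window[1L] / tr - 1e-9)
  kHi <- ceiling(window[2L] / tr - 1e-9) - 1L
  seq.int(kLo, kHi)
}

#' Cycle-averaged epoch of a per-sample quantity
#'
#' Extracts, for each block onset, the samples at relative offsets k with
#' lo <= k * tr < hi (onset mapped to the nearest retained sample,
#' relative time 0 = onset sample) and averages the cycles element-wise.
#'
#' @param values numeric vector on the retained sampling grid of
#'   \code{design} (e.g. one ROI's BOLD or one pair's TVCC z).
#' @param design A TaskDesign.
#' @param window numeric(2), epoch window in seconds (default c(-10, 30)).
#' @return list with \code{relTimes} (seconds) and \code{mean} (numeric,
#'   cycle-averaged values).
#' @export
epochAverage <- function(values, design, window = c(-10, 30)) {
  tr <- repetitionTime(design)
  k <- epochOffsets(window, tr)
  oi <- onsetIndices(design)
  n <- length(values)
  seg <- matrix(NA_real_, length(oi), length(k))
  for (c_ in seq_along(oi)) {
    idx <- oi[c_] + k
    if (idx[1L] < 1L || idx[length(idx)] > n)
      stop(sprintf("epoch window for cycle %d exceeds the series bounds", c_))
    seg[c_, ] <- values[idx]
  }
  list(relTimes = k * tr, mean = colMeans(seg))
}

#' Assemble per-subject epoch rows into an EpochedSeries
#'
#' @param rows list of numeric vectors (one per subject), all on the same
#'   relative-time grid.
#' @param relTimes numeric, relative times in seconds.
#' @param quantity \code{"bold"}, \code{"fc_z"} or \code{"slope"}.
#' @param tr numeric(1), sampling interval.
#' @return An [EpochedSeries-class].
#' @export
epochedSeries <- function(rows, relTimes, quantity, tr) {
  mat <- do.call(rbind, rows)
  colnames(mat) <- sprintf("%.3f", relTimes)
  new("EpochedSeries", quantity = quantity, relTimes = relTimes,
      perSubject = mat, tr = as.numeric(tr))
}

#' @rdname epochedSeries
#' @param object An EpochedSeries.
#' @export
epochValues <- function(object) object@perSubject

#' @rdname epochedSeries
#' @export
epochTimes <- function(object) object@relTimes

#' Point-wise least-squares slope over a rectangular window
#'
#' At every sample of an epoch, the ordinary least-squares slope of value
#' against time (seconds) over the centered rectangular window of
#' \code{fitWindow} seconds (offsets |m| <= floor(fitWindow / 2 / tr)),
#' truncated at the epoch edges. Windows left with fewer than 3 samples
#' yield NA.
#'
#' @param values numeric vector (one epoch row) or an
#'   [EpochedSeries-class].
#' @param relTimes numeric, times in seconds (ignored when \code{values}
#'   is an EpochedSeries).
#' @param fitWindow numeric(1), window length in seconds (default 16).
#' @return numeric vector of slopes in units per second, or an
#'   EpochedSeries of quantity \code{"slope"}.
#' @export
pointwiseSlope <- function(values, relTimes = NULL, fitWindow = 16) {
  if (is(values, "EpochedSeries")) {
    rows <- lapply(seq_len(nrow(values@perSubject)), function(i)
      pointwiseSlope(values@perSubject[i, ], values@relTimes, fitWindow))
    return(epochedSeries(rows, values@relTimes, "slope", values@tr))
  }
  n <- length(values)
  stopifnot(length(relTimes) == n)
  tr <- if (n > 1L) relTimes[2L] - relTimes[1L] else 1
  half <- floor((fitWindow / 2) / tr)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- max(1L, i - half):min(n, i + half)
    if (length(idx) < 3L) next
    tt <- relTimes[idx]
    vv <- values[idx]
    tc <- tt - mean(tt)
    out[i] <- sum(tc * (vv - mean(vv))) / sum(tc^2)
  }
  out
}

#' Sub-period functional connectivity for one subject
#'
#' Plain (unweighted) Pearson correlation of two preprocessed series
#' within each of the four half-open sub-periods around every block onset
#' (default PRE [-10, 0), EARLY [0, 10), LATE [10, 20), POST [20, 30)
#' seconds), Fisher z-transformed per (cycle, sub-period) cell and
#' averaged over the cycles.
#'
#' @param x,y numeric vectors on the retained grid of \code{design}.
#' @param design A TaskDesign.
#' @param breaks numeric(5), sub-period boundaries in seconds relative to
#'   onset (default c(-10, 0, 10, 20, 30)).
#' @return named numeric(4) of cycle-averaged Fisher-z FC
#'   (PRE/EARLY/LATE/POST); a cell with zero variance in every cycle is
#'   NA.
#' @export
subPeriodFcSubject <- function(x, y, design,
                               breaks = c(-10, 0, 10, 20, 30)) {
  stopifnot(length(breaks) == 5L)
  tr <- repetitionTime(design)
  oi <- onsetIndices(design)
  n <- length(x)
  zmat <- matrix(NA_real_, length(oi), 4L)
  for (c_ in seq_along(oi)) {
    for (q in seq_len(4L)) {
      k <- epochOffsets(breaks[q:(q + 1L)], tr)
      idx <- oi[c_] + k
      if (idx[1L] < 1L || idx[length(idx)] > n)
        stop(sprintf("sub-period window for cycle %d exceeds the series bounds", c_))
      xs <- x[idx]
      ys <- y[idx]
      if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next  # undefined cell
      zmat[c_, q] <- fisherZ(stats::cor(xs, ys))
    }
  }
  stats::setNames(colMeans(zmat, na.rm = TRUE),
                  c("PRE", "EARLY", "LATE", "POST"))
}

#' Sub-period FC across a cohort
#'
#' @param xs,ys lists of numeric vectors (one per subject).
#' @param design A TaskDesign.
#' @param breaks numeric(5), see [subPeriodFcSubject()].
#' @param pair character(2), ROI names.
#' @return A [SubPeriodFc-class].
#' @export
subPeriodFc <- function(xs, ys, design, breaks = c(-10, 0, 10, 20, 30),
                        pair = c("x", "y")) {
  rows <- mapply(function(x, y) subPeriodFcSubject(x, y, design, breaks),
                 xs, ys, SIMPLIFY = FALSE)
  mat <- do.call(rbind, rows)
  new("SubPeriodFc", pair = as.character(pair), perSubject = mat,
      breaks = as.numeric(breaks))
}

#' @rdname subPeriodFc
#' @param object A SubPeriodFc.
#' @export
subPeriodValues <- function(object) object@perSubject
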
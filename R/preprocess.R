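#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak minus a scaled
#' undershoot), sampled at the repetition time and peak-normalized to a
#' maximum of 1. Defaults are the standard canonical parameters: peak
#' delay 6 s, undershoot delay 16 s, both dispersions 1 s, undershoot
#' ratio 6, kernel length 32 s.
#'
#' @param peakDelay,undershootDelay numeric(1), seconds.
#' @param peakDispersion,undershootDispersion numeric(1), seconds.
#' @param undershootRatio numeric(1), peak-to-undershoot amplitude ratio.
#' @param kernelLength numeric(1), seconds of kernel support.
#' @param tr numeric(1), sampling interval in seconds.
#' @return numeric kernel sampled at 0, tr, 2 tr, ... up to kernelLength,
#'   with maximum value 1.
#' @examples
#' h <- canonicalHrf(tr = 0.645)
#' plot(seq_along(h) - 1, h, type = "l")
#' @export
canonicalHrf <- function(peakDelay = 6, undershootDelay = 16,
                         peakDispersion = 1, undershootDispersion = 1,
                         undershootRatio = 6, kernelLength = 32,
                         tr = 0.645) {
  if (any(c(peakDelay, undershootDelay, peakDispersion,
            undershootDispersion, undershootRatio) <= 0))
    stop("HRF parameters must be positive")
  if (kernelLength <= peakDelay)
    stop("kernelLength must exceed peakDelay")
  if (tr <= 0) stop("tr must be positive")
  t <- seq(0, kernelLength, by = tr)
  h <- stats::dgamma(t, shape = peakDelay / peakDispersion,
                     scale = peakDispersion) -
       stats::dgamma(t, shape = undershootDelay / undershootDispersion,
                     scale = undershootDispersion) / undershootRatio
  h / max(h)
}

#' Task regressor: boxcar convolved with the HRF
#'
#' Builds the unit boxcar (1 during task blocks, 0 otherwise) on the full
#' volume grid, convolves it with the sampled HRF kernel, and (by default)
#' truncates to the retained post-discard samples so that the initial
#' transient is handled exactly.
#'
#' @param design A TaskDesign.
#' @param hrf numeric, sampled kernel (same tr as the design); the default
#'   is the canonical HRF. Pass \code{1} for an identity kernel.
#' @param retainOnly logical, drop the discarded initial samples
#'   (default TRUE).
#' @return numeric regressor.
#' @export
taskRegressor <- function(design, hrf = canonicalHrf(tr = repetitionTime(design)),
                          retainOnly = TRUE) {
  nVol <- nVolumes(design)
  tr <- repetitionTime(design)
  t <- (seq_len(nVol) - 1L) * tr
  box <- rep(0, nVol)
  for (on in onsets(design))
    box[t >= on - 1e-9 & t < on + blockDuration(design) - 1e-9] <- 1
  # causal discrete convolution, truncated to the scan length
  full <- rep(0, nVol)
  for (k in seq_along(hrf)) {
    idx <- k:nVol
    full[idx] <- full[idx] + hrf[k] * box[idx - k + 1L]
  }
  if (retainOnly) full[(nDiscard(design) + 1L):nVol] else full
}

#' Discrete-cosine high-pass basis
#'
#' Cosine columns with frequency strictly below the cutoff, excluding the
#' constant term (an intercept is supplied separately during
#' residualization). The number of columns is floor(2 n tr cutoff),
#' matching the usual GLM drift basis for a 1/128 Hz high-pass.
#'
#' @param nSamples integer(1), number of time points.
#' @param tr numeric(1), sampling interval in seconds.
#' @param cutoff numeric(1), high-pass cutoff frequency in Hz
#'   (default 1/128).
#' @return numeric matrix with nSamples rows and floor(2 n tr cutoff)
#'   columns (possibly 0), mutually orthogonal.
#' @export
dctHighpassBasis <- function(nSamples, tr, cutoff = 1 / 128) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (nSamples <= 2L) stop("need more than 2 samples")
  k <- floor(2 * nSamples * tr * cutoff)
  if (k < 1L)
    return(matrix(numeric(0), nSamples, 0L))
  t <- seq_len(nSamples) - 1L
  basis <- vapply(seq_len(k), function(j)
    sqrt(2 / nSamples) * cos(pi * (2 * t + 1) * j / (2 * nSamples)),
    numeric(nSamples))
  colnames(basis) <- paste0("dct", seq_len(k))
  basis
}

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order (by default) Butterworth low-pass applied forward and
#' backward (zero phase, DC gain 1). When the requested cutoff is at or
#' above the Nyquist frequency the filter is unrealizable; the function
#' then warns and returns the input unchanged.
#'
#' @param x numeric vector or time-by-channel matrix.
#' @param order integer(1), filter order (>= 1).
#' @param cutoff numeric(1), cutoff frequency in Hz (default 0.75).
#' @param tr numeric(1), sampling interval in seconds.
#' @return Filtered data, same shape as \code{x}.
#' @export
butterworthLowpass <- function(x, order = 2L, cutoff = 0.75, tr) {
  if (order < 1L) stop("order must be >= 1")
  nyquist <- 1 / (2 * tr)
  if (cutoff >= nyquist) {
    warning(sprintf(
      "cutoff %.3g Hz is not below the Nyquist frequency %.3g Hz; returning input unchanged",
      cutoff, nyquist))
    return(x)
  }
  bf <- signal::butter(order, cutoff / nyquist, type = "low")
  # odd-reflection padding at both ends so the forward/backward passes
  # settle before the data start (suppresses edge transients)
  apply1 <- function(v) {
    n <- length(v)
    p <- min(n - 1L, max(50L, 3L * (2L * order + 1L)))
    pre <- 2 * v[1L] - v[(p + 1L):2L]
    post <- 2 * v[n] - v[(n - 1L):(n - p)]
    out <- as.numeric(signal::filtfilt(bf, c(pre, v, post)))
    out[(p + 1L):(p + n)]
  }
  if (is.matrix(x)) {
    out <- apply(x, 2L, apply1)
    dimnames(out) <- dimnames(x)
    out
  } else {
    apply1(x)
  }
}

#' First-order temporal derivatives of motion parameters
#'
#' Backward differences; the first row is 0.
#'
#' @param motion numeric matrix, frames x 6.
#' @return numeric matrix of the same shape.
#' @export
motionDerivatives <- function(motion) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L) stop("need at least 2 frames")
  rbind(matrix(0, 1L, ncol(motion)), diff(motion))
}

#' Framewise displacement summary
#'
#' Translational FD per frame is the mean of the three absolute
#' frame-to-frame translation differences (mm); rotational FD is the
#' analogous mean over the three rotation parameters in degrees. The
#' first frame's FD is 0 by definition; summary means are taken over the
#' differenced frames (frames 2..N), with no frame excluded.
#'
#' @param motion numeric matrix, frames x 6 (3 translations then 3
#'   rotations).
#' @param rotationUnit \code{"deg"} or \code{"rad"}, unit of the rotation
#'   columns in the input.
#' @return list with per-frame vectors \code{translational} and
#'   \code{rotational} (first element 0) and scalar summaries
#'   \code{meanTranslational} (mm) and \code{meanRotational} (degrees).
#' @export
framewiseDisplacement <- function(motion, rotationUnit = c("deg", "rad")) {
  rotationUnit <- match.arg(rotationUnit)
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion table must have exactly 6 columns")
  rot <- motion[, 4:6, drop = FALSE]
  if (rotationUnit == "rad") rot <- rot * 180 / pi
  td <- c(0, rowMeans(abs(diff(motion[, 1:3, drop = FALSE]))))
  rd <- c(0, rowMeans(abs(diff(rot))))
  list(translational = td, rotational = rd,
       meanTranslational = if (length(td) > 1L) mean(td[-1L]) else 0,
       meanRotational = if (length(rd) > 1L) mean(rd[-1L]) else 0)
}

#' Assemble a nuisance regressor matrix
#'
#' Builds the joint nuisance set on the retained sampling grid: the task
#' regressor (boxcar convolved with the canonical HRF), the six motion
#' parameters and their first-order derivatives, optional white-matter /
#' CSF summary columns, and the discrete-cosine high-pass basis. The
#' intercept is not included here; [residualize()] adds it.
#'
#' @param design A TaskDesign.
#' @param motion optional numeric matrix of motion parameters; either
#'   nVolumes rows (full grid; the discarded frames are dropped) or
#'   nRetained rows.
#' @param wmCsf optional numeric matrix of extra nuisance columns on the
#'   retained grid (e.g. white-matter/CSF eigenvariates).
#' @param includeTask logical, include the task regressor (default TRUE;
#'   removing evoked activity is required before windowed correlation, but
#'   the flag exists so the consequence of skipping it can be
#'   demonstrated).
#' @param includeHighpass logical, include the DCT drift basis.
#' @param highpassCutoff numeric(1), Hz (default 1/128).
#' @param hrf numeric, sampled HRF kernel for the task regressor.
#' @return numeric matrix, nRetained x p, with labelled columns and a
#'   \code{"labels"} attribute tagging each column's role.
#' @export
buildNuisance <- function(design, motion = NULL, wmCsf = NULL,
                          includeTask = TRUE, includeHighpass = TRUE,
                          highpassCutoff = 1 / 128,
                          hrf = canonicalHrf(tr = repetitionTime(design))) {
  n <- nRetained(design)
  cols <- list()
  labels <- character(0)
  if (includeTask) {
    cols$task <- matrix(taskRegressor(design, hrf), ncol = 1L,
                        dimnames = list(NULL, "task"))
    labels <- c(labels, "task")
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) == nVolumes(design))
      motion <- motion[(nDiscard(design) + 1L):nVolumes(design), ,
                       drop = FALSE]
    if (nrow(motion) != n)
      stop("motion table must have nVolumes or nRetained rows")
    deriv <- motionDerivatives(motion)
    colnames(motion) <- paste0("motion", seq_len(ncol(motion)))
    colnames(deriv) <- paste0("motion_deriv", seq_len(ncol(deriv)))
    cols$motion <- motion
    cols$deriv <- deriv
    labels <- c(labels, rep("motion", ncol(motion)),
                rep("motion-derivative", ncol(deriv)))
  }
  if (!is.null(wmCsf)) {
    wmCsf <- as.matrix(wmCsf)
    if (nrow(wmCsf) != n)
      stop("wmCsf columns must be on the retained grid")
    if (is.null(colnames(wmCsf)))
      colnames(wmCsf) <- paste0("wmcsf", seq_len(ncol(wmCsf)))
    cols$wmcsf <- wmCsf
    labels <- c(labels, rep("wm-csf", ncol(wmCsf)))
  }
  if (includeHighpass) {
    dct <- dctHighpassBasis(n, repetitionTime(design), highpassCutoff)
    if (ncol(dct) > 0L) {
      cols$dct <- dct
      labels <- c(labels, rep("dct", ncol(dct)))
    }
  }
  out <- if (length(cols)) do.call(cbind, unname(cols))
         else matrix(numeric(0), n, 0L)
  attr(out, "labels") <- labels
  out
}

#' Regress nuisance columns out of a series
#'
#' Ordinary least-squares residualization against the nuisance matrix plus
#' an intercept. Residuals are orthogonal to every nuisance column to
#' machine precision, and the operation is idempotent.
#'
#' @param x A [RoiTimeSeries-class], numeric matrix (time x channel) or
#'   numeric vector.
#' @param nuisance numeric matrix (time x p) or NULL (mean removal only).
#' @return Residuals, same type and shape as \code{x}.
#' @export
residualize <- function(x, nuisance = NULL) {
  if (is(x, "RoiTimeSeries")) {
    out <- x
    out@values <- residualize(x@values, nuisance)
    return(out)
  }
  vec <- !is.matrix(x)
  xm <- if (vec) matrix(x, ncol = 1L) else x
  n <- nrow(xm)
  design <- cbind(intercept = rep(1, n), nuisance)
  qrD <- qr(design)
  if (qrD$rank < ncol(design)) {
    bad <- colnames(design)[qrD$pivot[(qrD$rank + 1L):ncol(design)]]
    stop("rank-deficient nuisance matrix; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  res <- xm - qr.fitted(qrD, xm)
  dimnames(res) <- dimnames(xm)
  if (vec) as.numeric(res) else res
}

#' Preprocess a subject's ROI series for connectivity analysis
#'
#' Applies the standard order of operations: joint residualization against
#' the full nuisance set (task regressor unless \code{removeTask = FALSE},
#' motion + derivatives, optional extra columns, DCT high-pass), then the
#' zero-phase Butterworth low-pass. A single joint regression is used so
#' the result does not depend on the order of individual nuisance
#' removals.
#'
#' @param series A [RoiTimeSeries-class] on the retained grid.
#' @param design A TaskDesign.
#' @param motion optional motion-parameter matrix (see [buildNuisance()]).
#' @param wmCsf optional extra nuisance columns.
#' @param removeTask logical, regress out the task-evoked response
#'   (default TRUE; required for valid windowed correlation of the
#'   stochastic component).
#' @param highpass logical, include the 1/128 Hz DCT drift basis.
#' @param lowpassCutoff numeric(1), Hz (default 0.75); NULL disables.
#' @return A [RoiTimeSeries-class] of preprocessed residuals.
#' @export
preprocessSeries <- function(series, design, motion = NULL, wmCsf = NULL,
                             removeTask = TRUE, highpass = TRUE,
                             lowpassCutoff = 0.75) {
  stopifnot(is(series, "RoiTimeSeries"))
  nuis <- buildNuisance(design, motion = motion, wmCsf = wmCsf,
                        includeTask = removeTask,
                        includeHighpass = highpass)
  out <- residualize(series, if (ncol(nuis)) nuis else NULL)
  if (!is.null(lowpassCutoff))
    out@values <- butterworthLowpass(out@values, cutoff = lowpassCutoff,
                                     tr = series@tr)
  out
}
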
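#' @import methods
NULL

#' TaskDesign: temporal skeleton of a block-designed experiment
#'
#' Holds block onsets and durations together with the sampling grid
#' (repetition time, number of acquired volumes, number of initial volumes
#' discarded before analysis). All downstream epoching and sub-period
#' analyses are driven by this object.
#'
#' @slot onsets numeric, block onset times in seconds from scan start,
#'   strictly increasing.
#' @slot blockDuration numeric(1), block length in seconds.
#' @slot tr numeric(1), repetition time in seconds.
#' @slot nVolumes integer(1), number of acquired volumes.
#' @slot nDiscard integer(1), number of initial volumes removed before
#'   analysis (dummy scans / T1 equilibration).
#'
#' @seealso [taskDesign()], [visualBlockDesign()]
#' @export
setClass("TaskDesign",
  representation(
    onsets = "numeric",
    blockDuration = "numeric",
    tr = "numeric",
    nVolumes = "integer",
    nDiscard = "integer"
  )
)

setValidity("TaskDesign", function(object) {
  msg <- character()
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "tr must be a single positive number")
  if (length(object@onsets) < 1L || is.unsorted(object@onsets, strictly = TRUE))
    msg <- c(msg, "onsets must be non-empty and strictly increasing")
  if (length(object@blockDuration) != 1L || object@blockDuration <= 0)
    msg <- c(msg, "blockDuration must be a single positive number")
  if (object@nDiscard < 0L || object@nDiscard >= object@nVolumes)
    msg <- c(msg, "nDiscard must be in [0, nVolumes)")
  scanLen <- object@nVolumes * object@tr
  if (any(object@onsets + object@blockDuration > scanLen + 1e-9))
    msg <- c(msg, "every block must end within the scan")
  if (object@nDiscard * object@tr >= object@onsets[1L])
    msg <- c(msg, "discarded volumes must not reach the first onset (baseline must survive)")
  if (length(msg)) msg else TRUE
})

#' KernelSpec: sliding-window kernel for time-varying correlation
#'
#' @slot h numeric(1), window size in samples. For a Gaussian kernel the
#'   weight at integer offset u is exp(-u^2 / h) on the symmetric support
#'   |u| <= floor(h / 2); for a rectangular kernel the weight is 1 on the
#'   same support.
#' @slot shape character(1), \code{"gaussian"} or \code{"rectangular"}.
#'
#' @seealso [kernelSpec()], [kernelWeights()], [tvcc()]
#' @export
setClass("KernelSpec",
  representation(h = "numeric", shape = "character")
)

setValidity("KernelSpec", function(object) {
  msg <- character()
  if (length(object@h) != 1L || object@h < 3)
    msg <- c(msg, "h must be a single number >= 3")
  if (!object@shape %in% c("gaussian", "rectangular"))
    msg <- c(msg, "shape must be 'gaussian' or 'rectangular'")
  if (length(msg)) msg else TRUE
})

#' RoiTimeSeries: per-subject ROI-by-time BOLD matrix
#'
#' A uniform-grid multivariate time series: one column per ROI, one row per
#' retained volume. \code{t0} anchors the first retained sample in seconds
#' from scan start so that epoching relative to block onsets is exact.
#'
#' @slot subjectId character(1).
#' @slot tr numeric(1), sampling interval in seconds.
#' @slot t0 numeric(1), time of the first retained sample in seconds from
#'   scan start.
#' @slot values numeric matrix, time x ROI, with ROI names as column names.
#'
#' @seealso [roiTimeSeries()], [readRoiTimeSeries()]
#' @export
setClass("RoiTimeSeries",
  representation(
    subjectId = "character",
    tr = "numeric",
    t0 = "numeric",
    values = "matrix"
  )
)

setValidity("RoiTimeSeries", function(object) {
  msg <- character()
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "tr must be a single positive number")
  if (nrow(object@values) < 2L)
    msg <- c(msg, "need at least 2 time points")
  if (is.null(colnames(object@values)) ||
      anyDuplicated(colnames(object@values)))
    msg <- c(msg, "values must have unique ROI column names")
  if (anyNA(object@values))
    msg <- c(msg, "values must not contain missing values")
  if (length(msg)) msg else TRUE
})

#' TvccSeries: time-varying correlation between one ROI pair
#'
#' Per-sample windowed correlation r(t) and its Fisher z-transform on the
#' same grid as the input series. \code{validMask} flags samples where the
#' (possibly edge-truncated) window held at least 3 points with positive
#' weighted variance.
#'
#' @slot pair character(2), ROI names.
#' @slot r numeric, per-sample correlation.
#' @slot z numeric, per-sample Fisher z (atanh of clipped r).
#' @slot kernel KernelSpec used for estimation.
#' @slot validMask logical, per-sample estimability flag.
#' @slot tr numeric(1) sampling interval; @slot t0 time of first sample (s).
#'
#' @seealso [tvcc()]
#' @export
setClass("TvccSeries",
  representation(
    pair = "character",
    r = "numeric",
    z = "numeric",
    kernel = "KernelSpec",
    validMask = "logical",
    tr = "numeric",
    t0 = "numeric"
  )
)

setValidity("TvccSeries", function(object) {
  msg <- character()
  if (length(object@pair) != 2L)
    msg <- c(msg, "pair must name exactly two ROIs")
  n <- length(object@r)
  if (length(object@z) != n || length(object@validMask) != n)
    msg <- c(msg, "r, z and validMask must have equal length")
  if (any(abs(object@r[object@validMask]) > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "|r| must not exceed 1 at valid samples")
  if (length(msg)) msg else TRUE
})

#' EpochedSeries: cycle-averaged quantity on a relative-time grid
#'
#' One row per subject; each row is the element-wise mean over the task
#' cycles of a quantity (BOLD, FC z, or slope) on a uniform grid of sample
#' offsets relative to block onset.
#'
#' @slot quantity character(1), one of \code{"bold"}, \code{"fc_z"},
#'   \code{"slope"}.
#' @slot relTimes numeric, relative times in seconds (uniform, step = tr).
#' @slot perSubject numeric matrix, subject x relative-time.
#' @slot tr numeric(1).
#'
#' @seealso [epochAverage()], [pointwiseSlope()]
#' @export
setClass("EpochedSeries",
  representation(
    quantity = "character",
    relTimes = "numeric",
    perSubject = "matrix",
    tr = "numeric"
  )
)

setValidity("EpochedSeries", function(object) {
  msg <- character()
  if (!object@quantity %in% c("bold", "fc_z", "slope"))
    msg <- c(msg, "quantity must be 'bold', 'fc_z' or 'slope'")
  if (ncol(object@perSubject) != length(object@relTimes))
    msg <- c(msg, "perSubject columns must match relTimes")
  d <- diff(object@relTimes)
  if (length(d) && max(abs(d - object@tr)) > 1e-9)
    msg <- c(msg, "relTimes must be uniform with step tr")
  if (length(msg)) msg else TRUE
})

#' SubPeriodFc: per-subject sub-period functional connectivity
#'
#' Cycle-averaged Fisher-z correlation of one ROI pair in the four
#' half-open sub-periods around block onset (PRE, EARLY, LATE, POST).
#'
#' @slot pair character(2).
#' @slot perSubject numeric matrix, subject x 4, columns PRE/EARLY/LATE/POST.
#' @slot breaks numeric(5), the sub-period boundaries in seconds relative to
#'   onset (default -10, 0, 10, 20, 30); intervals are half-open [lo, hi).
#'
#' @seealso [subPeriodFc()], [rmAnovaOneway()]
#' @export
setClass("SubPeriodFc",
  representation(
    pair = "character",
    perSubject = "matrix",
    breaks = "numeric"
  )
)

setValidity("SubPeriodFc", function(object) {
  msg <- character()
  if (ncol(object@perSubject) != 4L)
    msg <- c(msg, "perSubject must have 4 columns")
  if (length(object@breaks) != 5L || is.unsorted(object@breaks, strictly = TRUE))
    msg <- c(msg, "breaks must be 5 strictly increasing boundaries")
  if (any(!is.finite(object@perSubject)))
    msg <- c(msg, "perSubject must be finite")
  if (length(msg)) msg else TRUE
})

#' CorrelationTrajectory: prescribed instantaneous correlation over time
#'
#' Piecewise-linear target correlation rho(t) between one ROI pair, used by
#' the synthetic generator as ground truth. Interpolation between knots is
#' linear; |rho| must stay strictly below 1.
#'
#' @slot pair character(2), ROI names.
#' @slot times numeric, knot times in seconds from scan start.
#' @slot rho numeric, target correlation at each knot, each in (-1, 1).
#'
#' @seealso [correlationTrajectory()], [trajectoryRho()]
#' @export
setClass("CorrelationTrajectory",
  representation(pair = "character", times = "numeric", rho = "numeric")
)

setValidity("CorrelationTrajectory", function(object) {
  msg <- character()
  if (length(object@pair) != 2L || object@pair[1L] == object@pair[2L])
    msg <- c(msg, "pair must name two distinct ROIs")
  if (length(object@times) != length(object@rho) || length(object@times) < 1L)
    msg <- c(msg, "times and rho must be non-empty and equal length")
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "knot times must be strictly increasing")
  if (any(abs(object@rho) >= 1))
    msg <- c(msg, "|rho| must be < 1 at every knot")
  if (length(msg)) msg else TRUE
})

#' SyntheticConfig: full specification of a simulated cohort
#'
#' @slot nSubjects integer(1).
#' @slot seed integer(1), master seed; per-subject streams are derived
#'   deterministically from (seed, subject index).
#' @slot design TaskDesign.
#' @slot roiNames character, ROI labels.
#' @slot activatedRois character, subset of roiNames receiving the
#'   boxcar-convolved-HRF activation.
#' @slot activationAmplitude numeric(2), mean and between-subject s.d. of
#'   the activation amplitude (signal units; noise is unit variance).
#' @slot trajectories list of CorrelationTrajectory.
#' @slot trajectorySd numeric(1), between-subject s.d. of each trajectory's
#'   level (added to rho, then clipped to a valid range).
#' @slot arCoefficient numeric(1) in [0, 1), AR(1) coefficient of the noise.
#' @slot noiseSd numeric(1), marginal s.d. of the ROI noise.
#' @slot driftAmplitude numeric(1), scale of the random quadratic drift.
#' @slot motionSd numeric(2), per-frame random-walk step s.d. for the three
#'   translations (mm) and the three rotations (degrees).
#'
#' @seealso [syntheticConfig()], [simulateCohort()]
#' @export
setClass("SyntheticConfig",
  representation(
    nSubjects = "integer",
    seed = "integer",
    design = "TaskDesign",
    roiNames = "character",
    activatedRois = "character",
    activationAmplitude = "numeric",
    trajectories = "list",
    trajectorySd = "numeric",
    arCoefficient = "numeric",
    noiseSd = "numeric",
    driftAmplitude = "numeric",
    motionSd = "numeric"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1L)
    msg <- c(msg, "nSubjects must be >= 1")
  if (anyDuplicated(object@roiNames))
    msg <- c(msg, "roiNames must be unique")
  if (!all(object@activatedRois %in% object@roiNames))
    msg <- c(msg, "activatedRois must be a subset of roiNames")
  if (length(object@activationAmplitude) != 2L ||
      object@activationAmplitude[2L] < 0)
    msg <- c(msg, "activationAmplitude must be c(mean, sd) with sd >= 0")
  if (object@arCoefficient < 0 || object@arCoefficient >= 1)
    msg <- c(msg, "arCoefficient must be in [0, 1)")
  if (object@noiseSd < 0 || object@driftAmplitude < 0 ||
      object@trajectorySd < 0 || any(object@motionSd < 0))
    msg <- c(msg, "all standard deviations must be >= 0")
  if (length(object@motionSd) != 2L)
    msg <- c(msg, "motionSd must be c(translation mm, rotation deg)")
  for (tr in object@trajectories) {
    if (!is(tr, "CorrelationTrajectory")) {
      msg <- c(msg, "trajectories must be CorrelationTrajectory objects")
    } else if (!all(tr@pair %in% object@roiNames)) {
      msg <- c(msg, sprintf("trajectory pair (%s, %s) not in roiNames",
                            tr@pair[1L], tr@pair[2L]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticDataset: a simulated multi-subject cohort with ground truth
#'
#' @slot subjects list of RoiTimeSeries (one per subject).
#' @slot truth list (one per subject) with realized trajectories
#'   (rho on the retained grid, per pair) and activation amplitudes.
#' @slot motion list of 6-column motion-parameter matrices (full volume
#'   grid; 3 translations mm, 3 rotations deg).
#' @slot config SyntheticConfig that generated the data.
#'
#' @seealso [simulateCohort()]
#' @export
setClass("SyntheticDataset",
  representation(
    subjects = "list",
    truth = "list",
    motion = "list",
    config = "SyntheticConfig"
  )
)

setValidity("SyntheticDataset", function(object) {
  msg <- character()
  n <- length(object@subjects)
  if (length(object@truth) != n || length(object@motion) != n)
    msg <- c(msg, "one truth and one motion record per subject required")
  if (length(msg)) msg else TRUE
})
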
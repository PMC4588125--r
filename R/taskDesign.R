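#' Construct a TaskDesign
#'
#' @param onsets numeric, block onsets in seconds from scan start.
#' @param blockDuration numeric(1), block length in seconds.
#' @param tr numeric(1), repetition time in seconds.
#' @param nVolumes integer(1), number of acquired volumes.
#' @param nDiscard integer(1), initial volumes discarded before analysis.
#' @return A [TaskDesign-class] object.
#' @examples
#' d <- taskDesign(c(20, 60, 100), 20, 0.645, 240, 14)
#' nRetained(d)
#' @export
taskDesign <- function(onsets, blockDuration, tr, nVolumes, nDiscard = 0L) {
  new("TaskDesign",
      onsets = as.numeric(onsets),
      blockDuration = as.numeric(blockDuration),
      tr = as.numeric(tr),
      nVolumes = as.integer(nVolumes),
      nDiscard = as.integer(nDiscard))
}

#' The block-designed visual checkerboard design
#'
#' The multiband acquisition this package's defaults emulate: TR = 0.645 s,
#' 240 volumes (~155 s), the first 14 volumes discarded, and a 20 s rest /
#' 20 s flickering-checkerboard alternation repeated three times, followed
#' by a terminal 35 s rest. Block onsets fall at 20, 60 and 100 s.
#'
#' @return A [TaskDesign-class] object.
#' @examples
#' visualBlockDesign()
#' @export
visualBlockDesign <- function() {
  taskDesign(onsets = c(20, 60, 100), blockDuration = 20,
             tr = 0.645, nVolumes = 240L, nDiscard = 14L)
}

#' @rdname taskDesign
#' @param object,design A TaskDesign.
#' @export
onsets <- function(design) design@onsets

#' @rdname taskDesign
#' @export
blockDuration <- function(design) design@blockDuration

#' @rdname taskDesign
#' @export
repetitionTime <- function(design) design@tr

#' @rdname taskDesign
#' @export
nVolumes <- function(design) design@nVolumes

#' @rdname taskDesign
#' @export
nDiscard <- function(design) design@nDiscard

#' Number of retained (post-discard) volumes
#' @param design A TaskDesign.
#' @return integer(1)
#' @export
nRetained <- function(design) design@nVolumes - design@nDiscard

#' Times of the retained samples
#'
#' Volume j (1-based, full grid) is timestamped (j - 1) * tr, so the first
#' retained sample sits at nDiscard * tr seconds from scan start.
#'
#' @param design A TaskDesign.
#' @return numeric vector of length `nRetained(design)`, seconds from scan
#'   start.
#' @export
retainedTimes <- function(design) {
  (design@nDiscard + seq_len(nRetained(design)) - 1L) * design@tr
}

#' Onset sample indices on the retained grid
#'
#' Maps each block onset to the nearest retained sample (1-based index into
#' the retained series).
#'
#' @param design A TaskDesign.
#' @return integer vector, one index per block.
#' @export
onsetIndices <- function(design) {
  tt <- retainedTimes(design)
  idx <- vapply(design@onsets, function(o) which.min(abs(tt - o)), integer(1L))
  as.integer(idx)
}

setMethod("show", "TaskDesign", function(object) {
  cat("TaskDesign:", length(object@onsets), "blocks of",
      object@blockDuration, "s\n")
  cat("  onsets (s):", paste(object@onsets, collapse = ", "), "\n")
  cat(sprintf("  tr = %g s, %d volumes (%d discarded, %d retained)\n",
              object@tr, object@nVolumes, object@nDiscard,
              nRetained(object)))
})

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries '%s': %d samples x %d ROIs (tr = %g s, t0 = %g s)\n",
              object@subjectId, nrow(object@values), ncol(object@values),
              object@tr, object@t0))
  cat("  ROIs:", paste(colnames(object@values), collapse = ", "), "\n")
})

setMethod("show", "KernelSpec", function(object) {
  cat(sprintf("KernelSpec: %s, h = %g samples (support |u| <= %d)\n",
              object@shape, object@h, floor(object@h / 2)))
})

setMethod("show", "TvccSeries", function(object) {
  cat(sprintf("TvccSeries %s-%s: %d samples, %d valid (%s kernel, h = %g)\n",
              object@pair[1L], object@pair[2L], length(object@r),
              sum(object@validMask), object@kernel@shape, object@kernel@h))
})

setMethod("show", "EpochedSeries", function(object) {
  cat(sprintf("EpochedSeries [%s]: %d subjects x %d samples, rel time %.2f..%.2f s\n",
              object@quantity, nrow(object@perSubject),
              ncol(object@perSubject), min(object@relTimes),
              max(object@relTimes)))
})

setMethod("show", "SubPeriodFc", function(object) {
  cat(sprintf("SubPeriodFc %s-%s: %d subjects, sub-periods [%s) s\n",
              object@pair[1L], object@pair[2L], nrow(object@perSubject),
              paste(object@breaks, collapse = ", ")))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf("SyntheticConfig: %d subjects, %d ROIs (%d activated), seed %d\n",
              object@nSubjects, length(object@roiNames),
              length(object@activatedRois), object@seed))
  cat(sprintf("  AR(1) = %g, noise sd = %g, %d correlation trajectories\n",
              object@arCoefficient, object@noiseSd,
              length(object@trajectories)))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d subjects x %d ROIs, %d retained samples\n",
              length(object@subjects), length(object@config@roiNames),
              nRetained(object@config@design)))
})

#' Construct a RoiTimeSeries
#'
#' @param values numeric matrix, time x ROI, ROI names as column names.
#' @param tr numeric(1), sampling interval in seconds.
#' @param t0 numeric(1), time of the first sample in seconds from scan start.
#' @param subjectId character(1).
#' @return A [RoiTimeSeries-class].
#' @export
roiTimeSeries <- function(values, tr, t0 = 0, subjectId = "subject") {
  new("RoiTimeSeries", subjectId = subjectId, tr = as.numeric(tr),
      t0 = as.numeric(t0), values = as.matrix(values))
}

#' @rdname roiTimeSeries
#' @param x A RoiTimeSeries.
#' @export
roiNames <- function(x) colnames(x@values)

#' @rdname roiTimeSeries
#' @export
roiValues <- function(x) x@values

#' Construct a KernelSpec
#'
#' The default reproduces the Gaussian window used throughout this package:
#' h = 24 samples, i.e. about 16 s at tr = 0.645 s.
#'
#' @param h numeric(1), window size in samples (>= 3).
#' @param shape \code{"gaussian"} or \code{"rectangular"}.
#' @return A [KernelSpec-class].
#' @export
kernelSpec <- function(h = 24, shape = c("gaussian", "rectangular")) {
  shape <- match.arg(shape)
  new("KernelSpec", h = as.numeric(h), shape = shape)
}

#' Window size in samples for a window length given in seconds
#'
#' The number of whole samples spanned by the window:
#' h = floor(seconds / tr). At tr = 0.645 s this reproduces the canonical
#' pairing of a 16 s window with h = 24 samples, and gives h = 21 and 27
#' for the 14 s and 18 s sensitivity windows.
#'
#' @param seconds numeric, window length(s) in seconds.
#' @param tr numeric(1), sampling interval in seconds.
#' @return numeric, window sizes in samples.
#' @export
windowSamples <- function(seconds, tr) floor(seconds / tr)
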
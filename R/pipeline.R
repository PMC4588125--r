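#' Full connectivity-dynamics analysis of a cohort
#'
#' Runs the complete estimation chain on a set of subjects: joint
#' nuisance residualization (with and without the task regressor),
#' zero-phase low-pass filtering, windowed time-varying correlation for
#' every requested ROI pair and window size, Fisher transformation, cycle
#' averaging, point-wise baseline and trend tests with FDR control, and
#' the four-sub-period repeated-measures validation.
#'
#' BOLD-level analyses use the series preprocessed \emph{without} task
#' removal (the evoked response is the signal of interest there); all
#' connectivity analyses use the series with the task-evoked component
#' regressed out, which is required for a valid windowed correlation of
#' the stochastic component.
#'
#' @param subjects list of [RoiTimeSeries-class] on a common design grid.
#' @param design A TaskDesign.
#' @param motion optional list of motion matrices (one per subject).
#' @param pairs list of character(2) ROI pairs; default all pairs.
#' @param windowSeconds numeric, TVCC window length(s) in seconds
#'   (default 16; pass c(14, 16, 18) for the sensitivity sweep).
#' @param kernelShape \code{"gaussian"} (default) or \code{"rectangular"}.
#' @param alpha numeric(1), FDR level (default 0.05).
#' @param epochWindow numeric(2), epoch window in seconds
#'   (default c(-10, 30)).
#' @param subPeriodBreaks numeric(5), sub-period boundaries (default
#'   c(-10, 0, 10, 20, 30)).
#' @param lowpassCutoff numeric(1) or NULL, Hz.
#' @param highpass logical, include the 1/128 Hz DCT drift basis.
#' @param analyses character, subset of c("bold", "fc", "subperiod") to
#'   run (default all).
#' @return list with elements \code{bold} (per ROI: \code{epoch},
#'   \code{baselineTest}, \code{slopes}, \code{trendTest}), \code{fc}
#'   (per window, per pair: the same four plus the TVCC z matrices),
#'   \code{subPeriod} (per pair: \code{fc} ([SubPeriodFc-class]),
#'   \code{anova}, \code{posthoc}), and the analysis parameters.
#' @export
analyzeCohort <- function(subjects, design, motion = NULL, pairs = NULL,
                          windowSeconds = 16,
                          kernelShape = c("gaussian", "rectangular"),
                          alpha = 0.05, epochWindow = c(-10, 30),
                          subPeriodBreaks = c(-10, 0, 10, 20, 30),
                          lowpassCutoff = 0.75, highpass = TRUE,
                          analyses = c("bold", "fc", "subperiod")) {
  kernelShape <- match.arg(kernelShape)
  analyses <- match.arg(analyses, several.ok = TRUE)
  rois <- roiNames(subjects[[1L]])
  if (is.null(pairs)) {
    cmb <- utils::combn(rois, 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  }
  tr <- repetitionTime(design)
  nSub <- length(subjects)

  # one shared preprocessing pass per subject
  fcSeries <- vector("list", nSub)
  boldSeries <- vector("list", nSub)
  needFc <- any(c("fc", "subperiod") %in% analyses)
  for (s in seq_len(nSub)) {
    mot <- if (is.null(motion)) NULL else motion[[s]]
    if (needFc)
      fcSeries[[s]] <- preprocessSeries(subjects[[s]], design,
                                        motion = mot, removeTask = TRUE,
                                        highpass = highpass,
                                        lowpassCutoff = lowpassCutoff)
    if ("bold" %in% analyses)
      boldSeries[[s]] <- preprocessSeries(subjects[[s]], design,
                                          motion = mot, removeTask = FALSE,
                                          highpass = highpass,
                                          lowpassCutoff = lowpassCutoff)
  }

  # BOLD: epoch, baseline test, slopes, trend test per ROI
  bold <- list()
  for (roi in if ("bold" %in% analyses) rois else character(0)) {
    rows <- lapply(boldSeries, function(ss)
      epochAverage(ss@values[, roi], design, epochWindow)$mean)
    relTimes <- epochAverage(boldSeries[[1L]]@values[, roi], design,
                             epochWindow)$relTimes
    ep <- epochedSeries(rows, relTimes, "bold", tr)
    sl <- pointwiseSlope(ep)
    bold[[roi]] <- list(epoch = ep,
                        baselineTest = pointwiseBaselineTest(ep, alpha = alpha),
                        slopes = sl,
                        trendTest = pointwiseTrendTest(sl, alpha = alpha))
  }

  # FC: TVCC per window and pair
  fc <- list()
  for (ws in if ("fc" %in% analyses) windowSeconds else numeric(0)) {
    spec <- kernelSpec(h = windowSamples(ws, tr), shape = kernelShape)
    wKey <- sprintf("%gs", ws)
    fc[[wKey]] <- list(kernel = spec, pairs = list())
    for (pr in pairs) {
      pKey <- paste(pr, collapse = "-")
      zRows <- lapply(fcSeries, function(ss)
        tvccZ(tvcc(ss@values[, pr[1L]], ss@values[, pr[2L]], spec,
                   tr = tr, t0 = ss@t0, pair = pr)))
      epRows <- lapply(zRows, function(z)
        epochAverage(z, design, epochWindow)$mean)
      relTimes <- epochAverage(zRows[[1L]], design, epochWindow)$relTimes
      ep <- epochedSeries(epRows, relTimes, "fc_z", tr)
      sl <- pointwiseSlope(ep)
      fc[[wKey]]$pairs[[pKey]] <- list(
        pair = pr, epoch = ep,
        baselineTest = pointwiseBaselineTest(ep, alpha = alpha),
        slopes = sl,
        trendTest = pointwiseTrendTest(sl, alpha = alpha))
    }
  }

  # sub-period validation (window-free, from the residual series)
  subPeriod <- list()
  for (pr in if ("subperiod" %in% analyses) pairs else list()) {
    pKey <- paste(pr, collapse = "-")
    xs <- lapply(fcSeries, function(ss) ss@values[, pr[1L]])
    ys <- lapply(fcSeries, function(ss) ss@values[, pr[2L]])
    sp <- subPeriodFc(xs, ys, design, subPeriodBreaks, pair = pr)
    inf <- subPeriodInference(sp, alpha = alpha)
    subPeriod[[pKey]] <- list(pair = pr, fc = sp, anova = inf$anova,
                              posthoc = inf$posthoc)
  }

  list(design = design, pairs = pairs, windowSeconds = windowSeconds,
       alpha = alpha, epochWindow = epochWindow,
       subPeriodBreaks = subPeriodBreaks,
       bold = bold, fc = fc, subPeriod = subPeriod)
}

#' Demonstrate why the task-evoked response must be removed before TVCC
#'
#' On a cohort with constant noise correlation and nonzero activation, the
#' deterministic task-evoked component inflates windowed correlation
#' estimates in a time-locked way. This utility runs the connectivity
#' analysis for one activated ROI pair twice — with and without
#' task-regressor removal — and compares the range of the cycle-averaged
#' group-mean TVCC.
#'
#' @param config A SyntheticConfig with constant trajectories and nonzero
#'   activation amplitude (the default uses the 20-subject cohort size of
#'   the emulated experiment, constant rho = 0.4 between the
#'   within-hemisphere visual pairs).
#' @param pair character(2), the activated ROI pair to analyze.
#' @param windowSeconds numeric(1), TVCC window length in seconds.
#' @return list with \code{rangeWithRemoval}, \code{rangeWithoutRemoval}
#'   (range of the cycle-averaged group-mean TVCC z) and their
#'   \code{ratio} (without / with).
#' @export
taskRemovalDemo <- function(config = syntheticConfig(
                              nSubjects = 20L,
                              trajectories = constantTrajectories(
                                visualBlockDesign(), rho = 0.4)),
                            pair = c("LMOG", "LFuG"),
                            windowSeconds = 16) {
  design <- config@design
  tr <- repetitionTime(design)
  spec <- kernelSpec(h = windowSamples(windowSeconds, tr))
  ds <- simulateCohort(config)
  groupMeanEpoch <- function(removeTask) {
    rows <- lapply(seq_along(ds@subjects), function(s) {
      ss <- preprocessSeries(ds@subjects[[s]], design,
                             motion = ds@motion[[s]],
                             removeTask = removeTask)
      z <- tvccZ(tvcc(ss@values[, pair[1L]], ss@values[, pair[2L]],
                      spec, tr = tr, t0 = ss@t0, pair = pair))
      epochAverage(z, design)$mean
    })
    colMeans(do.call(rbind, rows))
  }
  withRemoval <- groupMeanEpoch(TRUE)
  withoutRemoval <- groupMeanEpoch(FALSE)
  list(rangeWithRemoval = diff(range(withRemoval)),
       rangeWithoutRemoval = diff(range(withoutRemoval)),
       ratio = diff(range(withoutRemoval)) / diff(range(withRemoval)))
}

# tidy writers ---------------------------------------------------------

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

.epochTidy <- function(ep, subjects) {
  mat <- epochValues(ep)
  data.frame(
    subject = rep(subjects, times = ncol(mat)),
    relTime = rep(epochTimes(ep), each = nrow(mat)),
    value = as.numeric(mat))
}

#' Run the end-to-end pipeline and write a run directory
#'
#' Simulates (or loads) a cohort, runs [analyzeCohort()], and writes all
#' stage outputs as tab-delimited text together with a machine-readable
#' manifest (package version, config hash, seed, per-stage row counts).
#' Identical configurations produce byte-identical numeric outputs.
#'
#' @param config A [SyntheticConfig-class], or a path to a YAML run
#'   configuration (see [readSyntheticConfig()]).
#' @param outDir output directory (created; must be empty or absent).
#' @param windowSeconds numeric, TVCC window length(s) in seconds.
#' @param pairs list of character(2) pairs; default all.
#' @param alpha numeric(1), FDR level.
#' @param seed optional integer overriding the config seed.
#' @return invisibly, the [analyzeCohort()] result list, with the run
#'   directory attached as attribute \code{"outDir"}.
#' @export
runPipeline <- function(config = syntheticConfig(), outDir,
                        windowSeconds = 16, pairs = NULL, alpha = 0.05,
                        seed = NULL) {
  if (is.character(config)) config <- readSyntheticConfig(config)
  if (!is.null(seed)) config@seed <- as.integer(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  resDir <- file.path(outDir, "results")
  dir.create(resDir, showWarnings = FALSE)

  configPath <- file.path(outDir, "config.yaml")
  writeSyntheticConfig(config, configPath)
  design <- config@design

  ds <- simulateCohort(config)
  serDir <- file.path(outDir, "series")
  motDir <- file.path(outDir, "motion")
  dir.create(serDir, showWarnings = FALSE)
  dir.create(motDir, showWarnings = FALSE)
  fdRows <- list()
  for (s in seq_along(ds@subjects)) {
    id <- ds@subjects[[s]]@subjectId
    writeRoiTimeSeries(ds@subjects[[s]], file.path(serDir, paste0(id, ".tsv")))
    .writeTsv(as.data.frame(ds@motion[[s]]),
              file.path(motDir, paste0(id, ".tsv")))
    fd <- framewiseDisplacement(ds@motion[[s]])
    fdRows[[s]] <- data.frame(subject = id,
                              meanTranslationalFd = fd$meanTranslational,
                              meanRotationalFd = fd$meanRotational)
  }
  .writeTsv(do.call(rbind, fdRows), file.path(outDir, "fd.tsv"))
  writeTruth(ds, file.path(outDir, "truth.yaml"))

  res <- analyzeCohort(ds@subjects, design, motion = ds@motion,
                       pairs = pairs, windowSeconds = windowSeconds,
                       alpha = alpha)

  subjectIds <- vapply(ds@subjects, function(x) x@subjectId, character(1L))
  # BOLD outputs
  boldEpoch <- do.call(rbind, lapply(names(res$bold), function(roi)
    cbind(roi = roi, .epochTidy(res$bold[[roi]]$epoch, subjectIds))))
  .writeTsv(boldEpoch, file.path(resDir, "epochs_bold.tsv"))
  .writeTsv(do.call(rbind, lapply(names(res$bold), function(roi)
    cbind(roi = roi, res$bold[[roi]]$baselineTest))),
    file.path(resDir, "stats_bold_baseline.tsv"))
  .writeTsv(do.call(rbind, lapply(names(res$bold), function(roi)
    cbind(roi = roi, res$bold[[roi]]$trendTest))),
    file.path(resDir, "stats_bold_trend.tsv"))

  # FC outputs per window
  fcEpoch <- list(); fcBase <- list(); fcTrend <- list()
  for (wKey in names(res$fc)) {
    for (pKey in names(res$fc[[wKey]]$pairs)) {
      pres <- res$fc[[wKey]]$pairs[[pKey]]
      fcEpoch[[paste(wKey, pKey)]] <-
        cbind(window = wKey, pair = pKey,
              .epochTidy(pres$epoch, subjectIds))
      fcBase[[paste(wKey, pKey)]] <-
        cbind(window = wKey, pair = pKey, pres$baselineTest)
      fcTrend[[paste(wKey, pKey)]] <-
        cbind(window = wKey, pair = pKey, pres$trendTest)
    }
  }
  .writeTsv(do.call(rbind, fcEpoch), file.path(resDir, "epochs_fc.tsv"))
  .writeTsv(do.call(rbind, fcBase),
            file.path(resDir, "stats_fc_baseline.tsv"))
  .writeTsv(do.call(rbind, fcTrend),
            file.path(resDir, "stats_fc_trend.tsv"))

  # sub-period outputs
  spRows <- list(); anRows <- list(); phRows <- list()
  for (pKey in names(res$subPeriod)) {
    sp <- res$subPeriod[[pKey]]
    vals <- subPeriodValues(sp$fc)
    spRows[[pKey]] <- data.frame(
      pair = pKey, subject = rep(subjectIds, times = 4L),
      period = rep(colnames(vals), each = nrow(vals)),
      z = as.numeric(vals))
    anRows[[pKey]] <- data.frame(
      pair = pKey, f = sp$anova$f, dfCondition = sp$anova$dfCondition,
      dfError = sp$anova$dfError, p = sp$anova$p)
    phRows[[pKey]] <- if (sp$posthoc$gated)
      cbind(pair = pKey, gated = TRUE, sp$posthoc$tests)
    else data.frame(pair = pKey, gated = FALSE, comparison = NA,
                    estimate = NA, t = NA, p = NA, reject = NA)
  }
  .writeTsv(do.call(rbind, spRows), file.path(resDir, "subperiods.tsv"))
  .writeTsv(do.call(rbind, anRows),
            file.path(resDir, "subperiod_anova.tsv"))
  .writeTsv(do.call(rbind, phRows),
            file.path(resDir, "subperiod_posthoc.tsv"))

  manifest <- list(
    package = "tvconn",
    version = as.character(utils::packageVersion("tvconn")),
    configHash = unname(tools::md5sum(configPath)),
    seed = config@seed,
    nSubjects = config@nSubjects,
    nRetained = nRetained(design),
    windowSeconds = windowSeconds,
    alpha = alpha,
    nPairs = length(res$pairs),
    rows = list(
      epochs_bold = nrow(boldEpoch),
      epochs_fc = sum(vapply(fcEpoch, nrow, integer(1L))),
      subperiods = sum(vapply(spRows, nrow, integer(1L)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(res, "outDir") <- outDir
  invisible(res)
}

#' Summarize a completed run directory
#'
#' Reads the tidy outputs of [runPipeline()] and assembles group-level
#' summary tables: per-signal epoch curves (group mean, SEM and FDR
#' rejection flags) and the sub-period table with ANOVA p-values and
#' post-hoc flags.
#'
#' @param runDir a directory written by [runPipeline()].
#' @return list with data.frames \code{boldCurves}, \code{fcCurves},
#'   \code{subPeriodSummary} and the parsed \code{manifest}.
#' @export
reportRun <- function(runDir) {
  need <- c("results/epochs_bold.tsv", "results/epochs_fc.tsv",
            "results/stats_bold_baseline.tsv",
            "results/stats_fc_baseline.tsv",
            "results/subperiod_anova.tsv",
            "results/subperiod_posthoc.tsv", "manifest.json")
  missing <- need[!file.exists(file.path(runDir, need))]
  if (length(missing))
    stop("incomplete run; missing: ", paste(missing, collapse = ", "))
  rd <- function(f) utils::read.delim(file.path(runDir, f))
  curves <- function(df, keys) {
    agg <- stats::aggregate(df$value, by = df[keys], FUN = function(v)
      c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v))))
    out <- cbind(agg[keys], as.data.frame(agg$x))
    out[do.call(order, out[keys]), , drop = FALSE]
  }
  boldEp <- rd("results/epochs_bold.tsv")
  fcEp <- rd("results/epochs_fc.tsv")
  boldCurves <- merge(curves(boldEp, c("roi", "relTime")),
                      rd("results/stats_bold_baseline.tsv")[
                        c("roi", "relTime", "reject", "direction")],
                      by = c("roi", "relTime"), all.x = TRUE)
  fcCurves <- merge(curves(fcEp, c("window", "pair", "relTime")),
                    rd("results/stats_fc_baseline.tsv")[
                      c("window", "pair", "relTime", "reject", "direction")],
                    by = c("window", "pair", "relTime"), all.x = TRUE)
  an <- rd("results/subperiod_anova.tsv")
  ph <- rd("results/subperiod_posthoc.tsv")
  list(boldCurves = boldCurves, fcCurves = fcCurves,
       subPeriodSummary = merge(an, ph, by = "pair",
                                suffixes = c("_anova", "_posthoc")),
       manifest = jsonlite::read_json(file.path(runDir, "manifest.json")))
}
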
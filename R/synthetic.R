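#' Construct a CorrelationTrajectory
#'
#' @param pair character(2), ROI names.
#' @param times numeric, knot times in seconds from scan start (strictly
#'   increasing).
#' @param rho numeric, target instantaneous correlation at each knot, each
#'   strictly inside (-1, 1). Values between knots are linearly
#'   interpolated; outside the knot range the nearest knot value is held.
#' @return A [CorrelationTrajectory-class].
#' @export
correlationTrajectory <- function(pair, times, rho) {
  new("CorrelationTrajectory", pair = as.character(pair),
      times = as.numeric(times), rho = as.numeric(rho))
}

#' Evaluate a trajectory on a time grid
#'
#' @param trajectory A CorrelationTrajectory.
#' @param times numeric, evaluation times in seconds.
#' @return numeric, rho at each time (linear interpolation, flat
#'   extrapolation).
#' @export
trajectoryRho <- function(trajectory, times) {
  if (length(trajectory@times) == 1L)
    return(rep(trajectory@rho, length(times)))
  stats::approx(trajectory@times, trajectory@rho, xout = times,
                rule = 2)$y
}

#' Mixing weight for a target instantaneous correlation
#'
#' In the shared/unique two-process construction
#' x_i = sqrt(lambda) c + sqrt(1 - lambda) e_i (c, e_i independent with
#' unit variance and identical autocovariance), the instantaneous
#' correlation of the pair equals lambda. The weight is therefore |rho|;
#' negative targets are realized by negating the shared component's
#' contribution for one member of the pair.
#'
#' @param rho numeric, target correlation(s) with |rho| < 1.
#' @return numeric, mixing weight(s) lambda = |rho|.
#' @export
mixingWeightFromRho <- function(rho) {
  if (any(abs(rho) >= 1))
    stop("invalid trajectory: |rho| must be < 1")
  abs(rho)
}

#' Construct a SyntheticConfig
#'
#' Defaults emulate the block-designed visual experiment: six ROIs (two
#' lower visual, two higher visual, two default-mode), sustained
#' boxcar-convolved-HRF activation in the four visual ROIs, unit-variance
#' AR(1) noise, quadratic drift, and random-walk motion tables. The
#' default trajectories prescribe the task-related connectivity dynamic:
#' the MOG-FuG correlation within each hemisphere falls from 0.6 to 0.2
#' during the late stimulation period and recovers after block offset
#' (see [recoveryTrajectories()]).
#'
#' @param nSubjects integer, cohort size (default 20).
#' @param seed integer, master seed.
#' @param design A TaskDesign (default [visualBlockDesign()]).
#' @param roiNames character, ROI labels.
#' @param activatedRois character, ROIs receiving the task activation.
#' @param activationAmplitude numeric(2), mean and between-subject s.d. of
#'   the activation amplitude in units of the noise s.d.
#' @param trajectories list of [CorrelationTrajectory-class]; default
#'   `recoveryTrajectories(design)`.
#' @param trajectorySd numeric(1), between-subject s.d. of trajectory level.
#' @param arCoefficient numeric(1), AR(1) coefficient of the noise.
#' @param noiseSd numeric(1), marginal noise s.d.
#' @param driftAmplitude numeric(1), scale of the quadratic drift.
#' @param motionSd numeric(2), random-walk step s.d. (translations mm,
#'   rotations deg).
#' @return A [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nSubjects = 20L,
                            seed = 1L,
                            design = visualBlockDesign(),
                            roiNames = c("LMOG", "RMOG", "LFuG", "RFuG",
                                         "mPFC", "PCC"),
                            activatedRois = c("LMOG", "RMOG", "LFuG",
                                              "RFuG"),
                            activationAmplitude = c(1, 0.2),
                            trajectories = recoveryTrajectories(design),
                            trajectorySd = 0.05,
                            arCoefficient = 0.3,
                            noiseSd = 1,
                            driftAmplitude = 0.5,
                            motionSd = c(0.02, 0.02)) {
  new("SyntheticConfig",
      nSubjects = as.integer(nSubjects), seed = as.integer(seed),
      design = design, roiNames = roiNames, activatedRois = activatedRois,
      activationAmplitude = as.numeric(activationAmplitude),
      trajectories = trajectories, trajectorySd = as.numeric(trajectorySd),
      arCoefficient = as.numeric(arCoefficient),
      noiseSd = as.numeric(noiseSd),
      driftAmplitude = as.numeric(driftAmplitude),
      motionSd = as.numeric(motionSd))
}

#' Default time-varying correlation scenario: transient within-block drop
#'
#' Prescribes, for each listed pair, a correlation that sits at
#' \code{rhoBase} at rest, ramps down to \code{rhoDip} during the late part
#' of each stimulation block, and recovers after block offset. Knots per
#' cycle (relative to onset): +5 s still at base, +12 s at the dip, +20 s
#' (block offset) at the dip, +27 s back at base. No published effect
#' size exists for this kind of within-block drop, so 0.6 -> 0.2 is this
#' package's default choice of a moderate, realistic magnitude.
#'
#' The default pairs are the two within-hemisphere lower-to-higher visual
#' pairs. They are deliberately disjoint: the shared-process construction
#' spends |rho| of each member ROI's unit variance on the pair's shared
#' component, so the summed |rho| over all trajectories touching one ROI
#' must stay below 1.
#'
#' @param design A TaskDesign.
#' @param rhoBase numeric(1), resting correlation level.
#' @param rhoDip numeric(1), late-block correlation level.
#' @param pairs list of character(2) ROI pairs.
#' @return list of [CorrelationTrajectory-class].
#' @export
recoveryTrajectories <- function(design, rhoBase = 0.6, rhoDip = 0.2,
                                 pairs = list(c("LMOG", "LFuG"),
                                              c("RMOG", "RFuG"))) {
  scanEnd <- nVolumes(design) * repetitionTime(design)
  times <- 0
  rho <- rhoBase
  for (on in onsets(design)) {
    times <- c(times, on + c(5, 12, 20, 27))
    rho <- c(rho, rhoBase, rhoDip, rhoDip, rhoBase)
  }
  times <- c(times, scanEnd)
  rho <- c(rho, rhoBase)
  lapply(pairs, correlationTrajectory, times = times, rho = rho)
}

#' Constant-correlation trajectories (null scenario)
#'
#' @param design A TaskDesign.
#' @param rho numeric(1), constant correlation.
#' @param pairs list of character(2) ROI pairs.
#' @return list of [CorrelationTrajectory-class].
#' @export
constantTrajectories <- function(design, rho = 0.4,
                                 pairs = list(c("LMOG", "LFuG"),
                                              c("RMOG", "RFuG"))) {
  scanEnd <- nVolumes(design) * repetitionTime(design)
  lapply(pairs, correlationTrajectory, times = c(0, scanEnd),
         rho = c(rho, rho))
}

# Deterministic per-subject seed from (master seed, subject index).
# Pure arithmetic below 2^31 so cohorts are reproducible under parallel
# or out-of-order subject generation.
subjectSeed <- function(seed, subjectIndex) {
  as.integer((as.double(seed) %% 2147483629 * 48271 +
              as.double(subjectIndex) * 104729) %% 2147483629)
}

# Unit-variance stationary AR(1) series of length n.
arNoise <- function(n, phi) {
  if (phi == 0) return(stats::rnorm(n))
  innov <- stats::rnorm(n, sd = sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = stats::rnorm(1)))
}

#' Simulate one subject's ROI time series
#'
#' Each ROI series on the full volume grid is the sum of (i) the task
#' activation — a unit boxcar convolved with the canonical HRF, scaled by
#' the subject's activation amplitude — for activated ROIs, (ii)
#' unit-variance AR(1) noise scaled by \code{noiseSd}, with the prescribed
#' instantaneous pairwise correlation imposed by time-varying mixing of
#' shared and unique AR processes, and (iii) a random quadratic drift.
#' The returned series keeps only the post-discard samples; the truth
#' record carries the realized (subject-jittered) rho(t) on that retained
#' grid together with the activation amplitudes.
#'
#' @param config A SyntheticConfig.
#' @param subjectIndex integer, 1-based subject index.
#' @return list with elements \code{series} ([RoiTimeSeries-class]),
#'   \code{truth} (list: \code{rho} matrix retained-samples x pairs,
#'   \code{pairs}, \code{amplitude} named numeric) and \code{motion}
#'   (nVolumes x 6 matrix).
#' @export
simulateSubject <- function(config, subjectIndex) {
  design <- config@design
  nVol <- nVolumes(design)
  tr <- repetitionTime(design)
  rois <- config@roiNames
  nRoi <- length(rois)
  fullTimes <- (seq_len(nVol) - 1L) * tr

  # use a private seeded stream; restore the caller's RNG state on exit
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                  envir = globalenv())
  })
  set.seed(subjectSeed(config@seed, subjectIndex))

  # 1. activation amplitudes (one draw per activated ROI)
  amp <- stats::setNames(numeric(nRoi), rois)
  nAct <- length(config@activatedRois)
  if (nAct > 0L)
    amp[config@activatedRois] <- stats::rnorm(
      nAct, config@activationAmplitude[1L], config@activationAmplitude[2L])

  # 2. subject-level trajectory jitter (level shift, clipped)
  nTraj <- length(config@trajectories)
  jitter <- if (nTraj > 0L) stats::rnorm(nTraj, 0, config@trajectorySd)
            else numeric(0)
  rhoGrid <- matrix(0, nVol, nTraj)
  pairNames <- character(nTraj)
  for (p in seq_len(nTraj)) {
    tj <- config@trajectories[[p]]
    pairNames[p] <- paste(tj@pair, collapse = "-")
    rhoGrid[, p] <- pmin(pmax(trajectoryRho(tj, fullTimes) + jitter[p],
                              -0.95), 0.95)
  }
  # per-ROI shared-variance budget must stay below 1
  for (roi in rois) {
    inPair <- vapply(config@trajectories,
                     function(tj) roi %in% tj@pair, logical(1L))
    if (any(inPair)) {
      budget <- rowSums(abs(rhoGrid[, inPair, drop = FALSE]))
      if (any(budget >= 1))
        stop(sprintf(
          "infeasible trajectories: summed |rho| for ROI '%s' reaches %.3f (must stay < 1)",
          roi, max(budget)))
    }
  }

  # 3. noise: shared AR process per trajectory + unique AR per ROI,
  #    time-varying mixing so the instantaneous correlation tracks rho(t)
  phi <- config@arCoefficient
  shared <- if (nTraj > 0L)
    vapply(seq_len(nTraj), function(p) arNoise(nVol, phi),
           numeric(nVol)) else matrix(0, nVol, 0)
  unique_ <- vapply(seq_len(nRoi), function(i) arNoise(nVol, phi),
                    numeric(nVol))
  noise <- matrix(0, nVol, nRoi, dimnames = list(NULL, rois))
  for (i in seq_len(nRoi)) {
    sharedVar <- rep(0, nVol)
    contrib <- rep(0, nVol)
    for (p in seq_len(nTraj)) {
      tj <- config@trajectories[[p]]
      if (!rois[i] %in% tj@pair) next
      lam <- mixingWeightFromRho(rhoGrid[, p])
      # sign of rho is carried by the second member of the pair
      sgn <- if (rois[i] == tj@pair[2L]) sign(rhoGrid[, p]) else 1
      sgn[sgn == 0] <- 1
      contrib <- contrib + sgn * sqrt(lam) * shared[, p]
      sharedVar <- sharedVar + lam
    }
    noise[, i] <- contrib + sqrt(1 - sharedVar) * unique_[, i]
  }

  # 4. drift: quadratic with random coefficients on normalized time
  s <- seq(-1, 1, length.out = nVol)
  driftCoef <- stats::rnorm(3)
  drift <- config@driftAmplitude *
    (driftCoef[1L] + driftCoef[2L] * s + driftCoef[3L] * s^2)

  # 5. motion: Gaussian random walks (nuisance theater, regressed out
  #    downstream; not an artifact model)
  steps <- cbind(
    matrix(stats::rnorm(3L * nVol, 0, config@motionSd[1L]), nVol, 3L),
    matrix(stats::rnorm(3L * nVol, 0, config@motionSd[2L]), nVol, 3L))
  motion <- apply(steps, 2L, cumsum)
  motion <- sweep(motion, 2L, motion[1L, ])  # start at zero
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")

  # assemble on the full grid, then discard the initial volumes
  activ <- taskRegressor(design, canonicalHrf(tr = tr), retainOnly = FALSE)
  series <- matrix(0, nVol, nRoi, dimnames = list(NULL, rois))
  for (i in seq_len(nRoi))
    series[, i] <- amp[rois[i]] * activ + config@noiseSd * noise[, i] + drift

  keep <- (nDiscard(design) + 1L):nVol
  truth <- list(
    pairs = pairNames,
    rho = rhoGrid[keep, , drop = FALSE],
    amplitude = amp)
  list(
    series = roiTimeSeries(series[keep, , drop = FALSE], tr = tr,
                           t0 = nDiscard(design) * tr,
                           subjectId = sprintf("sub-%03d", subjectIndex)),
    truth = truth,
    motion = motion)
}

#' Simulate a multi-subject cohort
#'
#' @param config A SyntheticConfig.
#' @return A [SyntheticDataset-class] with one [RoiTimeSeries-class], one
#'   truth record and one motion table per subject. Identical configs give
#'   bit-identical datasets; per-subject RNG streams are derived from
#'   (seed, subject index) so subjects are independent of generation order.
#' @examples
#' cfg <- syntheticConfig(nSubjects = 2, seed = 7)
#' ds <- simulateCohort(cfg)
#' ds
#' @export
simulateCohort <- function(config) {
  subs <- lapply(seq_len(config@nSubjects),
                 function(i) simulateSubject(config, i))
  new("SyntheticDataset",
      subjects = lapply(subs, `[[`, "series"),
      truth = lapply(subs, `[[`, "truth"),
      motion = lapply(subs, `[[`, "motion"),
      config = config)
}

#' @rdname simulateCohort
#' @param dataset A SyntheticDataset.
#' @export
cohortSubjects <- function(dataset) dataset@subjects

#' @rdname simulateCohort
#' @export
cohortTruth <- function(dataset) dataset@truth

#' @rdname simulateCohort
#' @export
cohortMotion <- function(dataset) dataset@motion
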
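# shared fixtures: small designs and configs used across test files

fixtureDesign <- function() visualBlockDesign()

# a short single-block design for cheap tests
shortDesign <- function() taskDesign(20, 20, 0.645, 100, 10)

# cohort with constant correlation and no activation/drift: pure
# correlated AR noise (calibration and null checks)
noiseOnlyConfig <- function(nSubjects, seed, rho = 0.6) {
  syntheticConfig(
    nSubjects = nSubjects, seed = seed,
    activationAmplitude = c(0, 0),
    trajectories = constantTrajectories(visualBlockDesign(), rho = rho),
    trajectorySd = 0, driftAmplitude = 0, motionSd = c(0, 0))
}

# the null study conditions: constant rho, activation present
nullStudyConfig <- function(seed, nSubjects = 20L) {
  syntheticConfig(
    nSubjects = nSubjects, seed = seed,
    trajectories = constantTrajectories(visualBlockDesign(), rho = 0.4))
}

# the recovery study conditions: rho 0.6 -> 0.2 (late block) -> 0.6
recoveryStudyConfig <- function(seed, nSubjects = 20L) {
  syntheticConfig(nSubjects = nSubjects, seed = seed)
}

analysisPairs <- function() list(c("LMOG", "LFuG"), c("RMOG", "RFuG"))

# independent longhand weighted-correlation oracle: every sum expanded
# explicitly, no vectorized shortcuts shared with the implementation
weightedCorOracle <- function(x, y, w) {
  sw <- 0; sx <- 0; sy <- 0
  for (i in seq_along(x)) { sw <- sw + w[i]; sx <- sx + w[i] * x[i]
                            sy <- sy + w[i] * y[i] }
  mx <- sx / sw; my <- sy / sw
  sxx <- 0; syy <- 0; sxy <- 0
  for (i in seq_along(x)) {
    sxx <- sxx + w[i] * (x[i] - mx)^2
    syy <- syy + w[i] * (y[i] - my)^2
    sxy <- sxy + w[i] * (x[i] - mx) * (y[i] - my)
  }
  sxy / sqrt(sxx * syy)
}
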
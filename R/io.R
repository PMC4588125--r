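#' Write / read ROI time series as tab-delimited text
#'
#' The layout is a header row, a \code{time} column (seconds from scan
#' start) and one column per ROI.
#'
#' @param x A [RoiTimeSeries-class].
#' @param path file path.
#' @return \code{writeRoiTimeSeries}: the path, invisibly.
#' @export
writeRoiTimeSeries <- function(x, path) {
  tt <- x@t0 + (seq_len(nrow(x@values)) - 1L) * x@tr
  df <- data.frame(time = tt, x@values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeRoiTimeSeries
#' @param subjectId character(1), subject label for the returned object.
#' @return \code{readRoiTimeSeries}: a [RoiTimeSeries-class].
#' @export
readRoiTimeSeries <- function(path, subjectId = basename(path)) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("file must contain a 'time' column")
  tt <- df$time
  if (length(tt) < 2L) stop("need at least 2 samples")
  tr <- stats::median(diff(tt))
  vals <- as.matrix(df[, setdiff(names(df), "time"), drop = FALSE])
  roiTimeSeries(vals, tr = tr, t0 = tt[1L], subjectId = subjectId)
}

#' Read an ROI coordinate table
#'
#' Accepts tab- or comma-delimited text with a header and columns
#' \code{name}, \code{x}, \code{y}, \code{z} (world mm) and
#' \code{radius} (mm).
#'
#' @param path file path.
#' @return data.frame with those five columns.
#' @export
readRoiTable <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z", "radius")
  if (!all(need %in% names(df)))
    stop("ROI table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$name)) stop("ROI names must be unique")
  if (any(df$radius <= 0)) stop("ROI radii must be positive")
  df[, need]
}

#' Read a 6-column motion-parameter table
#'
#' Whitespace-delimited text, three translations (mm) then three
#' rotations; the rotation unit is declared by the caller and converted
#' downstream where needed.
#'
#' @param path file path.
#' @return numeric matrix, frames x 6.
#' @export
readMotion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L)
    stop("motion table must have exactly 6 columns, found ", ncol(m))
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

#' Write a cohort's ground truth as structured text
#'
#' Per subject: the activation amplitudes (key/value) and the realized
#' rho(t) knot table on the retained grid, serialized as YAML.
#'
#' @param dataset A [SyntheticDataset-class].
#' @param path file path (.yaml).
#' @return the path, invisibly.
#' @export
writeTruth <- function(dataset, path) {
  design <- dataset@config@design
  tt <- retainedTimes(design)
  recs <- lapply(seq_along(dataset@truth), function(s) {
    tr_ <- dataset@truth[[s]]
    list(subject = dataset@subjects[[s]]@subjectId,
         amplitude = as.list(tr_$amplitude),
         pairs = as.list(tr_$pairs),
         time = as.numeric(tt),
         rho = lapply(seq_along(tr_$pairs),
                      function(p) as.numeric(tr_$rho[, p])))
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' Write / read a SyntheticConfig as a declarative YAML file
#'
#' @param config A [SyntheticConfig-class].
#' @param path file path (.yaml).
#' @return \code{writeSyntheticConfig}: the path invisibly;
#'   \code{readSyntheticConfig}: a [SyntheticConfig-class].
#' @export
writeSyntheticConfig <- function(config, path) {
  d <- config@design
  lst <- list(
    nSubjects = config@nSubjects,
    seed = config@seed,
    design = list(onsets = as.numeric(onsets(d)),
                  blockDuration = blockDuration(d),
                  tr = repetitionTime(d),
                  nVolumes = nVolumes(d),
                  nDiscard = nDiscard(d)),
    roiNames = as.list(config@roiNames),
    activatedRois = as.list(config@activatedRois),
    activationAmplitude = as.numeric(config@activationAmplitude),
    trajectorySd = config@trajectorySd,
    arCoefficient = config@arCoefficient,
    noiseSd = config@noiseSd,
    driftAmplitude = config@driftAmplitude,
    motionSd = as.numeric(config@motionSd),
    trajectories = lapply(config@trajectories, function(tj)
      list(pair = as.list(tj@pair), times = as.numeric(tj@times),
           rho = as.numeric(tj@rho))))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeSyntheticConfig
#' @export
readSyntheticConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  known <- c("nSubjects", "seed", "design", "roiNames", "activatedRois",
             "activationAmplitude", "trajectorySd", "arCoefficient",
             "noiseSd", "driftAmplitude", "motionSd", "trajectories")
  extra <- setdiff(names(lst), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  d <- lst$design
  design <- taskDesign(d$onsets, d$blockDuration, d$tr, d$nVolumes,
                       d$nDiscard)
  trajs <- lapply(lst$trajectories, function(tj)
    correlationTrajectory(unlist(tj$pair), tj$times, tj$rho))
  syntheticConfig(
    nSubjects = lst$nSubjects, seed = lst$seed, design = design,
    roiNames = unlist(lst$roiNames),
    activatedRois = as.character(unlist(lst$activatedRois)),
    activationAmplitude = lst$activationAmplitude,
    trajectories = trajs, trajectorySd = lst$trajectorySd,
    arCoefficient = lst$arCoefficient, noiseSd = lst$noiseSd,
    driftAmplitude = lst$driftAmplitude, motionSd = lst$motionSd)
}
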
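#' Spherical ROI voxel mask
#'
#' Voxels whose world-space centers lie within Euclidean distance
#' \code{radius} (inclusive) of the sphere center. Voxel indices are
#' 0-based in the affine convention (the NIfTI xform maps 0-based voxel
#' indices to world mm); the returned matrix uses 1-based R indices.
#'
#' @param spec list or one-row data.frame with fields \code{name},
#'   \code{x}, \code{y}, \code{z} (world mm) and \code{radius} (mm).
#' @param dim integer(3), image grid dimensions.
#' @param affine numeric 4x4 matrix mapping 0-based voxel indices to
#'   world mm.
#' @return integer matrix (nVoxels x 3) of 1-based voxel indices, with
#'   attribute \code{"linear"} giving the linear index into the 3D grid.
#' @examples
#' aff <- diag(c(3, 3, 3, 1))
#' m <- makeSphereMask(list(name = "v", x = 21, y = 21, z = 21, radius = 8),
#'                     dim = c(15, 15, 15), affine = aff)
#' nrow(m)  # 81 voxels for an 8 mm sphere on a 3 mm grid
#' @export
makeSphereMask <- function(spec, dim, affine) {
  stopifnot(length(dim) == 3L, all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  center <- c(spec$x, spec$y, spec$z)
  # bounding box in voxel space to avoid scanning the full grid
  inv <- solve(affine)
  vc <- (inv %*% c(center, 1))[1:3]
  # conservative per-axis half-width from the affine column norms
  colNorm <- sqrt(colSums(affine[1:3, 1:3]^2))
  halo <- ceiling(spec$radius / min(colNorm)) + 1L
  rng <- lapply(1:3, function(a)
    max(0L, floor(vc[a]) - halo):min(dim[a] - 1L, ceiling(vc[a]) + halo))
  grid <- as.matrix(expand.grid(i = rng[[1L]], j = rng[[2L]], k = rng[[3L]]))
  world <- t(affine %*% rbind(t(grid), 1))[, 1:3, drop = FALSE]
  d2 <- rowSums(sweep(world, 2L, center)^2)
  inside <- d2 <= spec$radius^2 + 1e-9
  if (!any(inside))
    stop(sprintf("empty mask: ROI '%s' lies outside the field of view",
                 spec$name))
  vox <- grid[inside, , drop = FALSE] + 1L   # to 1-based R indices
  linear <- vox[, 1L] + dim[1L] * (vox[, 2L] - 1L) +
    dim[1L] * dim[2L] * (vox[, 3L] - 1L)
  structure(vox, linear = as.integer(linear))
}

# time x voxel matrix for a mask from a 4D array
.maskMatrix <- function(series4d, mask) {
  d <- dim(series4d)
  stopifnot(length(d) == 4L)
  lin <- attr(mask, "linear")
  nVoxSpace <- prod(d[1:3])
  flat <- matrix(series4d, nrow = nVoxSpace, ncol = d[4L])
  t(flat[lin, , drop = FALSE])   # time x voxel
}

#' Mean ROI time series
#'
#' Per-time arithmetic mean over the mask voxels.
#'
#' @param series4d numeric 4D array (x, y, z, time).
#' @param mask voxel mask from [makeSphereMask()].
#' @return numeric vector of length \code{dim(series4d)[4]}.
#' @export
extractMean <- function(series4d, mask) {
  rowMeans(.maskMatrix(series4d, mask))
}

#' First-eigenvariate ROI time series
#'
#' The nuisance matrix (plus an intercept) is regressed from every voxel
#' series; the first left singular vector of the residual time-by-voxel
#' matrix is scaled to the root-mean-square amplitude of the ROI
#' (u1 * s1 / sqrt(nVoxels)) and sign-aligned so that its correlation
#' with the ROI-mean residual series is non-negative. If that mean series
#' is degenerate (zero variance), the tie-break aligns against the first
#' voxel's residual series instead.
#'
#' @param series4d numeric 4D array (x, y, z, time).
#' @param mask voxel mask from [makeSphereMask()].
#' @param adjust optional nuisance matrix (time x p) regressed out before
#'   the decomposition.
#' @return numeric vector of length \code{dim(series4d)[4]}.
#' @export
extractFirstEigenvariate <- function(series4d, mask, adjust = NULL) {
  V <- .maskMatrix(series4d, mask)            # time x voxel
  V <- residualize(V, adjust)
  sv <- svd(V, nu = 1L, nv = 0L)
  eig <- sv$u[, 1L] * sv$d[1L] / sqrt(ncol(V))
  ref <- rowMeans(V)
  cr <- sum((ref - mean(ref)) * (eig - mean(eig)))
  if (abs(cr) < 1e-12) {          # degenerate mean: tie-break on voxel 1
    ref <- V[, 1L]
    cr <- sum((ref - mean(ref)) * (eig - mean(eig)))
  }
  if (cr < 0) eig <- -eig
  eig
}

#' Extract all ROI series from a 4D image
#'
#' @param series4d numeric 4D array or an RNifti image.
#' @param roiTable data.frame with columns name, x, y, z, radius
#'   (world mm).
#' @param affine numeric 4x4 voxel-to-world matrix; defaults to the
#'   image's xform when \code{series4d} is a NIfTI image.
#' @param method \code{"eigenvariate"} (default, the connectivity-analysis
#'   variant) or \code{"mean"}.
#' @param adjust optional nuisance matrix for the eigenvariate method.
#' @param tr numeric(1), sampling interval (metadata; defaults to the
#'   NIfTI time pixdim when available).
#' @param t0 numeric(1), time of the first stored volume.
#' @param subjectId character(1).
#' @return A [RoiTimeSeries-class].
#' @export
extractRoiSeries <- function(series4d, roiTable, affine = NULL,
                             method = c("eigenvariate", "mean"),
                             adjust = NULL, tr = NULL, t0 = 0,
                             subjectId = "subject") {
  method <- match.arg(method)
  if (inherits(series4d, "niftiImage")) {
    if (is.null(affine)) affine <- unclass(RNifti::xform(series4d))
    if (is.null(tr)) tr <- RNifti::pixdim(series4d)[4L]
    series4d <- as.array(series4d)
  }
  if (is.null(affine) || is.null(tr))
    stop("affine and tr are required for plain arrays")
  d <- dim(series4d)
  cols <- lapply(seq_len(nrow(roiTable)), function(i) {
    mask <- makeSphereMask(as.list(roiTable[i, ]), d[1:3], affine)
    if (method == "mean") extractMean(series4d, mask)
    else extractFirstEigenvariate(series4d, mask, adjust)
  })
  values <- do.call(cbind, cols)
  colnames(values) <- as.character(roiTable$name)
  roiTimeSeries(values, tr = tr, t0 = t0, subjectId = subjectId)
}

#' Embed a synthetic cohort into 4D NIfTI volumes
#'
#' Every voxel inside an ROI sphere carries that ROI's simulated series
#' plus i.i.d. voxel noise; background voxels carry pure noise. One
#' gzipped NIfTI per subject is written with the supplied affine and the
#' design TR in the header, together with a tab-delimited ROI coordinate
#' table (name, x, y, z in mm, radius). Spheres must fit inside the grid
#' and must not overlap.
#'
#' @param dataset A [SyntheticDataset-class].
#' @param roiTable data.frame with columns name, x, y, z, radius; names
#'   must match the dataset's ROI names.
#' @param dim integer(3), grid dimensions.
#' @param affine numeric 4x4 voxel-to-world matrix (default 3 mm
#'   isotropic, origin at the corner).
#' @param voxelNoiseSd numeric(1), i.i.d. voxel noise s.d.
#' @param dir output directory (created if needed).
#' @param seed integer(1), seed for the voxel noise.
#' @return invisibly, a list with \code{imagePaths}, \code{roiTablePath}
#'   and the affine used.
#' @export
embedInVolumes <- function(dataset, roiTable, dim = c(24L, 24L, 12L),
                           affine = diag(c(3, 3, 3, 1)),
                           voxelNoiseSd = 0.1, dir = tempfile("volumes"),
                           seed = 1L) {
  design <- dataset@config@design
  masks <- lapply(seq_len(nrow(roiTable)), function(i)
    makeSphereMask(as.list(roiTable[i, ]), dim, affine))
  lins <- lapply(masks, attr, "linear")
  if (anyDuplicated(unlist(lins)))
    stop("geometry error: ROI spheres overlap")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  paths <- character(length(dataset@subjects))
  for (s in seq_along(dataset@subjects)) {
    series <- dataset@subjects[[s]]
    nT <- nrow(series@values)
    vol <- array(stats::rnorm(prod(dim) * nT, sd = max(voxelNoiseSd, 1e-12)),
                 c(dim, nT))
    if (voxelNoiseSd == 0) vol[] <- 0
    flat <- matrix(vol, prod(dim), nT)
    for (i in seq_along(masks)) {
      roi <- as.character(roiTable$name[i])
      base <- series@values[, roi]
      nv <- length(lins[[i]])
      add <- matrix(rep(base, each = nv), nv, nT)
      flat[lins[[i]], ] <- flat[lins[[i]], ] + add
    }
    vol <- array(flat, c(dim, nT))
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- c(sqrt(colSums(affine[1:3, 1:3]^2)),
                             repetitionTime(design))
    RNifti::qform(img) <- structure(affine, code = 2L)
    paths[s] <- file.path(dir, sprintf("%s.nii.gz", series@subjectId))
    RNifti::writeNifti(img, paths[s])
  }
  roiPath <- file.path(dir, "rois.tsv")
  utils::write.table(roiTable, roiPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(imagePaths = paths, roiTablePath = roiPath,
                 affine = affine))
}
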
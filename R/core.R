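## Shared utilities: standardization, volume I/O, searchlight engine.
## All standardization uses the population (1/T) variance so that
## Pearson-correlation identities (r = <z1, z2>/T) hold exactly.

#' Population-variance z-score of a matrix along time (rows)
#'
#' @param m T x V numeric matrix.
#' @param warnZeroVar emit a warning naming zero-variance columns.
#' @return matrix of the same shape; zero-variance columns become all 0.
#' @export
zscoreMatrixTime <- function(m, warnZeroVar = TRUE) {
  if (!all(is.finite(m))) stop("non-finite values in input")
  T <- nrow(m)
  mu <- colMeans(m)
  ctr <- sweep(m, 2L, mu)
  s <- sqrt(colSums(ctr^2) / T)
  zero <- s <= 0
  if (any(zero) && warnZeroVar)
    warning(sprintf("%d zero-variance unit(s) set to all-zeros", sum(zero)))
  s[zero] <- 1
  out <- sweep(ctr, 2L, s, "/")
  out[, zero] <- 0
  out
}

#' Z-score each unit's time series
#'
#' Standardizes every column of the data matrix to mean 0 and population
#' standard deviation 1. Zero-variance units are returned as all-zeros
#' with a warning. Idempotent.
#'
#' @param ts a [SubjectTimeSeries-class].
#' @return a [SubjectTimeSeries-class] with standardized data.
#' @examples
#' ts <- SubjectTimeSeries(cbind(1:3, c(5, 5, 5)))
#' tsData(suppressWarnings(zscoreTime(ts)))
#' @export
zscoreTime <- function(ts) {
  stopifnot(is(ts, "SubjectTimeSeries"))
  initialize(ts, data = zscoreMatrixTime(ts@data))
}

#' Z-score every subject of a dataset along time
#' @param dataset a [MultiSubjectDataset-class]
#' @param warnZeroVar warn on zero-variance units
#' @return a [MultiSubjectDataset-class]
#' @export
zscoreDataset <- function(dataset, warnZeroVar = TRUE) {
  subs <- lapply(dataset@subjects, function(s)
    initialize(s, data = zscoreMatrixTime(s@data, warnZeroVar)))
  initialize(dataset, subjects = subs)
}

## ---- NIfTI I/O ------------------------------------------------------------

#' Read a 4-D NIfTI volume into a SubjectTimeSeries
#'
#' Columns of the returned matrix are the in-mask voxels in the package's
#' fixed serialization order: ascending linear index, x fastest
#' (column-major). Round-trips bit-exactly with [writeVolume()] for
#' finite data.
#'
#' @param path 4-D NIfTI image file.
#' @param maskPath 3-D NIfTI mask on the same grid (non-zero = in mask).
#' @param trSeconds sampling interval in seconds.
#' @param subjectId subject identifier.
#' @return list with elements `ts` ([SubjectTimeSeries-class]) and
#'   `geometry` ([VolumeGeometry-class]).
#' @export
readVolume <- function(path, maskPath, trSeconds = 1, subjectId = "s1") {
  img <- RNifti::readNifti(path)
  msk <- RNifti::readNifti(maskPath)
  if (length(dim(img)) != 4L) stop("image is not 4-D")
  if (!identical(dim(img)[1:3], dim(msk)[1:3]))
    stop("grid mismatch between image and mask")
  mask <- array(as.vector(msk) != 0, dim = dim(msk)[1:3])
  if (!any(mask)) stop("empty mask")
  vox <- tryCatch(RNifti::pixdim(msk)[1:3], error = function(e) c(1, 1, 1))
  if (any(!is.finite(vox)) || any(vox <= 0)) vox <- c(1, 1, 1)
  geometry <- VolumeGeometry(mask, voxelSizeMm = vox)
  T <- dim(img)[4]
  flat <- matrix(as.vector(img), ncol = T)   # voxels x T, x fastest
  data <- t(flat[as.vector(mask), , drop = FALSE])
  ts <- SubjectTimeSeries(data, trSeconds = trSeconds,
                          subjectId = subjectId)
  list(ts = ts, geometry = geometry)
}

#' Write a SubjectTimeSeries as a 4-D NIfTI volume
#'
#' Inverse of [readVolume()]: scatters columns back to their in-mask
#' voxel positions (x-fastest order); out-of-mask voxels are written as 0.
#'
#' @param ts a [SubjectTimeSeries-class] with V = number of in-mask voxels.
#' @param geometry the [VolumeGeometry-class] describing the grid.
#' @param path output `.nii` / `.nii.gz` path.
#' @param maskPath optional path to also write the mask volume.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(ts, geometry, path, maskPath = NULL) {
  V <- sum(geometry@mask)
  if (ncol(ts@data) != V)
    stop(sprintf("ts has %d units but mask has %d voxels",
                 ncol(ts@data), V))
  T <- nrow(ts@data)
  vol <- array(0, dim = c(geometry@dims, T))
  flat <- matrix(0, prod(geometry@dims), T)
  flat[as.vector(geometry@mask), ] <- t(ts@data)
  vol <- array(flat, dim = c(geometry@dims, T))
  img <- RNifti::asNifti(vol, reference = list(
    pixdim = c(-1, geometry@voxelSizeMm, ts@trSeconds, 0, 0, 0)),
    datatype = "double")
  RNifti::writeNifti(img, path)
  if (!is.null(maskPath)) {
    m <- RNifti::asNifti(array(as.integer(geometry@mask),
                               dim = geometry@dims),
                         reference = list(
                           pixdim = c(-1, geometry@voxelSizeMm, 0, 0,
                                      0, 0)))
    RNifti::writeNifti(m, maskPath)
  }
  invisible(path)
}

#' Read / write a plain-text time-series matrix (TSV, T rows x V columns)
#'
#' @param path TSV file path.
#' @param header whether the file has a header row.
#' @param trSeconds,subjectId metadata for the returned object.
#' @return a [SubjectTimeSeries-class].
#' @export
readTimeSeriesTsv <- function(path, header = FALSE, trSeconds = 1,
                              subjectId = basename(path)) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  m <- as.matrix(read.table(path, header = header, sep = "\t"))
  dimnames(m) <- NULL
  SubjectTimeSeries(m, trSeconds = trSeconds, subjectId = subjectId)
}

#' @rdname readTimeSeriesTsv
#' @param ts a [SubjectTimeSeries-class] to write.
#' @export
writeTimeSeriesTsv <- function(ts, path) {
  write.table(ts@data, path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a JSON provenance sidecar next to an output file
#'
#' Every pipeline output gets a `<file>.json` sidecar recording the
#' resolved parameters, seed and package version, so runs are
#' reproducible from their outputs alone.
#'
#' @param path the output file the sidecar describes.
#' @param config named list of resolved parameters.
#' @return sidecar path, invisibly.
#' @export
writeSidecar <- function(path, config) {
  config$package <- "fmrikit"
  config$version <- as.character(packageVersion("fmrikit"))
  config$voxel_order <- "x-fastest ascending (column-major)"
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(config, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(sidecar)
}

#' Number of voxel pairs in a full correlation analysis
#'
#' The full voxel-by-voxel correlation matrix over `nVoxels` voxels has
#' `choose(nVoxels, 2)` distinct pairs -- the quantity that makes
#' whole-brain connectivity analyses expensive (a typical ~30,000-voxel
#' dataset has ~4.5e8 pairs).
#'
#' @param nVoxels number of voxels.
#' @return number of unordered voxel pairs.
#' @examples
#' voxelPairCount(30000)
#' @export
voxelPairCount <- function(nVoxels) choose(nVoxels, 2)

## ---- searchlight ----------------------------------------------------------

#' Offsets of a searchlight neighborhood
#' @keywords internal
.slOffsets <- function(radius, shape) {
  r <- as.integer(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  if (shape == "ball")
    g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

#' In-mask unit indices of the neighborhood around one voxel
#'
#' Neighborhoods at volume edges are truncated, never wrapped.
#'
#' @param center length-3 voxel coordinate (1-based).
#' @param geometry a [VolumeGeometry-class].
#' @param spec a [SearchlightSpec-class].
#' @return integer vector of column indices into the data matrix
#'   (positions in the in-mask serialization).
#' @export
searchlightNeighborhood <- function(center, geometry, spec) {
  off <- .slOffsets(spec@radiusVoxels, spec@shape)
  pts <- sweep(off, 2L, as.integer(center), "+")
  d <- geometry@dims
  keep <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
          pts[, 2] >= 1 & pts[, 2] <= d[2] &
          pts[, 3] >= 1 & pts[, 3] <= d[3]
  pts <- pts[keep, , drop = FALSE]
  lin <- pts[, 1] + (pts[, 2] - 1L) * d[1] + (pts[, 3] - 1L) * d[1] * d[2]
  maskLin <- which(geometry@mask)          # ascending, x fastest
  idx <- match(lin, maskLin)
  sort(idx[!is.na(idx)])
}

#' Generic volumetric searchlight
#'
#' Repeats an arbitrary multisubject analysis in a moving local window
#' over the brain: for every in-mask voxel whose (edge-truncated)
#' neighborhood contains at least `minUnits` in-mask units, applies `fn`
#' to the dataset restricted to the neighborhood's units. Voxels whose
#' neighborhoods are too small, and out-of-mask voxels, carry the `NaN`
#' sentinel, which is never silently dropped.
#'
#' @param dataset a units-aligned [MultiSubjectDataset-class] whose V
#'   equals the mask's in-mask voxel count.
#' @param geometry a [VolumeGeometry-class].
#' @param spec a [SearchlightSpec-class].
#' @param fn function taking a [MultiSubjectDataset-class] (restricted to
#'   a neighborhood) and returning a single number.
#' @return 3-D array of shape `geometry@dims`: `fn` values at evaluated
#'   centers, `NaN` elsewhere.
#' @export
searchlight <- function(dataset, geometry, spec, fn) {
  if (dataset@alignmentMode != "units_aligned")
    stop("searchlight requires a units_aligned dataset")
  V <- ncol(dataset@subjects[[1]]@data)
  if (V != sum(geometry@mask))
    stop("dataset units inconsistent with mask voxel count")
  mats <- lapply(dataset@subjects, function(s) s@data)
  out <- array(NaN, dim = geometry@dims)
  coords <- maskCoordinates(geometry)
  maskLin <- which(geometry@mask)
  for (i in seq_len(nrow(coords))) {
    idx <- searchlightNeighborhood(coords[i, ], geometry, spec)
    if (length(idx) < spec@minUnits) next
    sub <- MultiSubjectDataset(
      lapply(seq_along(mats), function(s)
        SubjectTimeSeries(mats[[s]][, idx, drop = FALSE],
                          trSeconds = dataset@subjects[[s]]@trSeconds,
                          subjectId = dataset@subjects[[s]]@subjectId)),
      alignmentMode = "units_aligned")
    val <- tryCatch(fn(sub), error = function(e)
      stop(sprintf("searchlight fn failed at voxel (%d, %d, %d): %s",
                   coords[i, 1], coords[i, 2], coords[i, 3],
                   conditionMessage(e)), call. = FALSE))
    out[maskLin[i]] <- val
  }
  out
}
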
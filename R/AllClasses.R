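#' @import methods
#' @importFrom stats cor fft mvfft sd rnorm runif quantile median p.adjust
#'   filter aggregate lm coef predict dgamma acf optimize
#' @importFrom utils combn read.table write.table packageVersion head tail
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' One subject's time-by-unit response matrix
#'
#' The universal currency of all methods in the package: a numeric matrix
#' with one row per timepoint (TR) and one column per unit (voxel, parcel
#' or feature), together with the sampling interval.
#'
#' @slot data numeric matrix, T timepoints x V units, all finite.
#' @slot trSeconds positive sampling interval in seconds.
#' @slot subjectId subject identifier.
#' @slot unitLabels optional character vector of length V.
#' @export
setClass("SubjectTimeSeries",
  representation(
    data = "matrix",
    trSeconds = "numeric",
    subjectId = "character",
    unitLabels = "characterOrNULL"
  )
)

setValidity("SubjectTimeSeries", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("data must be a numeric matrix")
  if (nrow(d) < 2L) return("need T >= 2 timepoints")
  if (ncol(d) < 1L) return("need V >= 1 units")
  if (!all(is.finite(d))) return("data contains non-finite values")
  if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
      object@trSeconds <= 0) return("trSeconds must be a positive scalar")
  if (!is.null(object@unitLabels) &&
      length(object@unitLabels) != ncol(d))
    return("unitLabels length must equal number of units")
  TRUE
})

#' Construct a SubjectTimeSeries
#'
#' @param data T x V numeric matrix (rows are timepoints).
#' @param trSeconds sampling interval in seconds.
#' @param subjectId subject identifier string.
#' @param unitLabels optional unit (voxel/parcel) labels.
#' @return A [SubjectTimeSeries-class] object.
#' @examples
#' ts <- SubjectTimeSeries(matrix(rnorm(40), 10, 4), trSeconds = 2)
#' nTimepoints(ts); nUnits(ts)
#' @export
SubjectTimeSeries <- function(data, trSeconds = 1, subjectId = "s1",
                              unitLabels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  new("SubjectTimeSeries", data = data, trSeconds = as.numeric(trSeconds),
      subjectId = as.character(subjectId), unitLabels = unitLabels)
}

#' Aligned collection of subjects
#'
#' Houses the group inputs of ISC/ISFC (which require unit-aligned data)
#' and the shared response model (which only requires time alignment and
#' permits differing voxel counts per subject).
#'
#' @slot subjects list of [SubjectTimeSeries-class], all sharing T.
#' @slot alignmentMode `"units_aligned"` or `"time_aligned_only"`.
#' @export
setClass("MultiSubjectDataset",
  representation(subjects = "list", alignmentMode = "character")
)

setValidity("MultiSubjectDataset", function(object) {
  subs <- object@subjects
  if (length(subs) < 2L) return("need at least 2 subjects")
  if (!all(vapply(subs, is, logical(1), "SubjectTimeSeries")))
    return("subjects must all be SubjectTimeSeries")
  if (!object@alignmentMode %in% c("units_aligned", "time_aligned_only"))
    return("alignmentMode must be 'units_aligned' or 'time_aligned_only'")
  Ts <- vapply(subs, function(s) nrow(s@data), integer(1))
  if (length(unique(Ts)) != 1L)
    return("all subjects must share the same number of timepoints")
  if (object@alignmentMode == "units_aligned") {
    Vs <- vapply(subs, function(s) ncol(s@data), integer(1))
    if (length(unique(Vs)) != 1L)
      return("units_aligned requires identical unit counts")
  }
  TRUE
})

#' Construct a MultiSubjectDataset
#'
#' @param subjects list of [SubjectTimeSeries-class] objects or plain
#'   T x V matrices (converted with `trSeconds`).
#' @param alignmentMode `"units_aligned"` (required by ISC/ISFC) or
#'   `"time_aligned_only"` (sufficient for SRM).
#' @param trSeconds sampling interval used when `subjects` are matrices.
#' @return A [MultiSubjectDataset-class].
#' @export
MultiSubjectDataset <- function(subjects,
                                alignmentMode = c("units_aligned",
                                                  "time_aligned_only"),
                                trSeconds = 1) {
  alignmentMode <- match.arg(alignmentMode)
  subjects <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    if (is(s, "SubjectTimeSeries")) s
    else SubjectTimeSeries(s, trSeconds = trSeconds,
                           subjectId = paste0("s", i))
  })
  new("MultiSubjectDataset", subjects = subjects,
      alignmentMode = alignmentMode)
}

#' Volume geometry linking matrix columns to voxel coordinates
#'
#' Records the grid, voxel size and boolean mask of a volume. In-mask
#' voxels are serialized x-fastest in ascending linear order (Fortran
#' convention), a fixed convention shared by all I/O and searchlight code.
#'
#' @slot dims integer grid dimensions (x, y, z).
#' @slot voxelSizeMm positive voxel edge lengths in mm.
#' @slot mask logical 3-D array of shape `dims`.
#' @export
setClass("VolumeGeometry",
  representation(dims = "integer", voxelSizeMm = "numeric", mask = "array")
)

setValidity("VolumeGeometry", function(object) {
  if (length(object@dims) != 3L) return("dims must have length 3")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!identical(dim(object@mask), object@dims))
    return("mask shape must equal dims")
  if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
    return("voxelSizeMm must be 3 positive values")
  if (sum(object@mask) < 1L) return("empty mask")
  TRUE
})

#' Construct a VolumeGeometry
#'
#' @param mask logical 3-D array; `TRUE` marks in-mask voxels.
#' @param voxelSizeMm voxel edge lengths in mm (length 1 or 3).
#' @return A [VolumeGeometry-class].
#' @export
VolumeGeometry <- function(mask, voxelSizeMm = c(3, 3, 3)) {
  mask <- as.array(mask)
  storage.mode(mask) <- "logical"
  if (length(voxelSizeMm) == 1L) voxelSizeMm <- rep(voxelSizeMm, 3)
  new("VolumeGeometry", dims = as.integer(dim(mask)),
      voxelSizeMm = as.numeric(voxelSizeMm), mask = mask)
}

#' Searchlight window specification
#'
#' @slot radiusVoxels non-negative integer radius.
#' @slot shape `"cube"` or `"ball"`; the ball is the subset of the cube
#'   within Euclidean voxel distance `radiusVoxels` of the center.
#' @slot minUnits minimum number of in-mask units a neighborhood must
#'   contain to be evaluated; smaller neighborhoods yield `NaN`.
#' @export
setClass("SearchlightSpec",
  representation(radiusVoxels = "integer", shape = "character",
                 minUnits = "integer")
)

setValidity("SearchlightSpec", function(object) {
  if (object@radiusVoxels < 0L) return("radiusVoxels must be >= 0")
  if (!object@shape %in% c("cube", "ball"))
    return("shape must be 'cube' or 'ball'")
  if (object@minUnits < 1L) return("minUnits must be >= 1")
  TRUE
})

#' Construct a SearchlightSpec
#' @param radiusVoxels neighborhood radius in voxels.
#' @param shape `"cube"` (default) or `"ball"`.
#' @param minUnits minimum in-mask units required to evaluate a center.
#' @return A [SearchlightSpec-class].
#' @export
SearchlightSpec <- function(radiusVoxels = 1, shape = c("cube", "ball"),
                            minUnits = 1) {
  shape <- match.arg(shape)
  new("SearchlightSpec", radiusVoxels = as.integer(radiusVoxels),
      shape = shape, minUnits = as.integer(minUnits))
}

## ---- result containers ----------------------------------------------------

#' Intersubject correlation result
#'
#' @slot values correlation matrix: N x V for leave-one-out, or
#'   choose(N, 2) x V for pairwise (lexicographic pair order).
#' @slot method `"loo"` or `"pairwise"`.
#' @slot pairIndex for pairwise results, 2-column matrix of (i, j), i < j.
#' @slot summaryValues optional V-length across-subject summary.
#' @slot summaryMethod how `summaryValues` were formed.
#' @export
setClass("ISCResult",
  representation(values = "matrix", method = "character",
                 pairIndex = "matrix", summaryValues = "numeric",
                 summaryMethod = "character")
)

#' Intersubject functional correlation result
#'
#' @slot matrices list of V x V matrices, one per subject (loo) or pair.
#' @slot symmetrized whether each matrix was replaced by (M + t(M))/2.
#' @slot method `"loo"` or `"pairwise"`.
#' @export
setClass("ISFCResult",
  representation(matrices = "list", symmetrized = "logical",
                 method = "character")
)

#' Nonparametric null-distribution test result
#'
#' p-values follow the add-one permutation rule, so the smallest
#' attainable p is 1/(B + 1); q-values are Benjamini-Hochberg adjusted.
#'
#' @slot observed observed statistic(s).
#' @slot nullSamples B x V matrix of null statistics.
#' @slot pValues per-unit p-values in (0, 1].
#' @slot qValues BH-adjusted p-values.
#' @slot method null-construction method.
#' @slot seed RNG seed used.
#' @slot nNull number of null samples B.
#' @slot tail `"greater"` or `"two_sided"`.
#' @export
setClass("NullTestResult",
  representation(observed = "numeric", nullSamples = "matrix",
                 pValues = "numeric", qValues = "numeric",
                 method = "character", seed = "integer",
                 nNull = "integer", tail = "character")
)

setValidity("NullTestResult", function(object) {
  if (any(object@pValues < 1 / (object@nNull + 1) - 1e-12, na.rm = TRUE))
    return("p-values below the attainable minimum 1/(B+1)")
  if (any(object@qValues < object@pValues - 1e-12, na.rm = TRUE))
    return("q-values must be >= p-values")
  TRUE
})

#' Shared response model
#'
#' Per-subject orthonormal transforms `W_i` (V_i x k) and the shared
#' response `S` (k x T) minimizing `sum_i ||X_i - W_i S||_F^2`.
#'
#' @slot k number of shared features.
#' @slot transforms list of V_i x k matrices with orthonormal columns.
#' @slot sharedResponse k x T shared response matrix.
#' @slot objectiveTrace training objective per iteration (non-increasing).
#' @slot nIter number of alternating iterations run.
#' @slot seed RNG seed for the initialization.
#' @export
setClass("SRMModel",
  representation(k = "integer", transforms = "list",
                 sharedResponse = "matrix", objectiveTrace = "numeric",
                 nIter = "integer", seed = "integer")
)

setValidity("SRMModel", function(object) {
  for (W in object@transforms) {
    dev <- max(abs(crossprod(W) - diag(object@k)))
    if (dev > 1e-8) return("transform columns not orthonormal")
  }
  TRUE
})

#' Between-subject time-segment classification report
#'
#' @slot segmentLenTr segment length in TRs.
#' @slot accuracy overall fraction of correctly matched segments.
#' @slot chanceLevel 1 / number of segments.
#' @slot nSegments number of non-overlapping segments.
#' @slot perSubjectAccuracy accuracy per held-out subject.
#' @export
setClass("TimeSegmentReport",
  representation(segmentLenTr = "integer", accuracy = "numeric",
                 chanceLevel = "numeric", nSegments = "integer",
                 perSubjectAccuracy = "numeric")
)

#' Left-to-right HMM event segmentation model
#'
#' Events are traversed in order (stay or advance each TR), starting in
#' event 1 and ending in event K; each event has a characteristic spatial
#' pattern and an isotropic Gaussian emission with shared variance.
#'
#' @slot K number of events.
#' @slot eventPatterns K x V matrix of event patterns (z-scored across units).
#' @slot segments T x K posterior probability of each event at each TR.
#' @slot sigma2 shared emission variance.
#' @slot loglikTrace log-likelihood per fitting iteration.
#' @slot advanceProb per-TR probability of advancing to the next event.
#' @export
setClass("EventSegModel",
  representation(K = "integer", eventPatterns = "matrix",
                 segments = "matrix", sigma2 = "numeric",
                 loglikTrace = "numeric", advanceProb = "numeric")
)

setValidity("EventSegModel", function(object) {
  rs <- rowSums(object@segments)
  if (max(abs(rs - 1)) > 1e-9) return("posterior rows must sum to 1")
  TRUE
})

#' Set of event boundaries
#'
#' 0-based TR indices at which the maximum-a-posteriori event index
#' increments: a boundary at `t` means the event changes between TR
#' `t - 1` and TR `t`, with TRs counted from 0.
#'
#' @slot boundaries strictly increasing 0-based TR indices in `[1, T-1]`.
#' @slot K number of events of the originating model.
#' @slot nTimepoints T of the originating series.
#' @export
setClass("BoundarySet",
  representation(boundaries = "integer", K = "integer",
                 nTimepoints = "integer")
)

#' Simulator noise profile
#'
#' Parameter record of the noise generator and the quantities the noise
#' measurement reports: temporal signal-to-fluctuation ratio (SFNR),
#' spatial SNR, lag-1 autoregressive coefficient, low-frequency drift
#' amplitude, physiological frequencies, spatial smoothness and baseline.
#'
#' @slot sfnr voxel mean / temporal sd of the detrended series (in-mask
#'   average); positive.
#' @slot snr in-mask mean / spatial sd of out-of-mask noise at the middle
#'   timepoint; positive.
#' @slot arRho lag-1 autoregressive coefficient in (-1, 1).
#' @slot driftSdPct low-frequency drift sd as percent of the mean.
#' @slot physioFreqsHz physiological frequencies in Hz (aliased by the TR).
#' @slot spatialFwhmMm FWHM of the spatially smoothed noise component.
#' @slot baseline mean in-mask intensity.
#' @export
setClass("NoiseProfile",
  representation(sfnr = "numeric", snr = "numeric", arRho = "numeric",
                 driftSdPct = "numeric", physioFreqsHz = "numeric",
                 spatialFwhmMm = "numeric", baseline = "numeric")
)

setValidity("NoiseProfile", function(object) {
  if (object@sfnr <= 0) return("sfnr must be positive")
  if (object@snr <= 0) return("snr must be positive")
  if (abs(object@arRho) >= 1) return("arRho must be in (-1, 1)")
  if (object@driftSdPct < 0 || object@spatialFwhmMm < 0)
    return("drift and smoothness must be non-negative")
  if (object@baseline <= 0) return("baseline must be positive")
  TRUE
})

#' Construct a NoiseProfile
#'
#' Defaults describe a plausible 3T acquisition: SFNR 70, spatial SNR 30,
#' mild positive autocorrelation, ~0.5% drift, respiratory (~0.2 Hz) and
#' cardiac (~1.17 Hz) cycles, 4 mm smoothness.
#'
#' @param sfnr temporal signal-to-fluctuation-noise ratio.
#' @param snr spatial signal-to-noise ratio.
#' @param arRho lag-1 autoregressive coefficient.
#' @param driftSdPct drift amplitude, percent of mean.
#' @param physioFreqsHz physiological frequencies (Hz).
#' @param spatialFwhmMm spatial smoothness FWHM (mm).
#' @param baseline mean in-mask intensity.
#' @return A [NoiseProfile-class].
#' @export
NoiseProfile <- function(sfnr = 70, snr = 30, arRho = 0.4,
                         driftSdPct = 0.5, physioFreqsHz = c(0.2, 1.17),
                         spatialFwhmMm = 4, baseline = 100) {
  new("NoiseProfile", sfnr = as.numeric(sfnr), snr = as.numeric(snr),
      arRho = as.numeric(arRho), driftSdPct = as.numeric(driftSdPct),
      physioFreqsHz = as.numeric(physioFreqsHz),
      spatialFwhmMm = as.numeric(spatialFwhmMm),
      baseline = as.numeric(baseline))
}

#' Channel basis tiling a circular stimulus space
#'
#' Rectified-cosine channels raised to an integer power, evaluated on
#' the circular feature distance, with evenly spaced centers over the
#' feature domain. For even exponents with
#' `nChannels > exponent / 2` the channel responses tile: their sum is
#' constant over the whole domain.
#'
#' @slot nChannels number of channels (>= 2).
#' @slot centers channel centers in degrees.
#' @slot domainPeriod period of the feature domain (180 for orientation,
#'   360 for direction).
#' @slot exponent integer power applied to the rectified cosine.
#' @slot dimensionality `"1D_circular"` (the 2-D spatial variant uses
#'   Gaussian bumps; see [makeSpatialBasis()]).
#' @export
setClass("ChannelBasis",
  representation(nChannels = "integer", centers = "numeric",
                 domainPeriod = "numeric", exponent = "integer",
                 dimensionality = "character")
)

setValidity("ChannelBasis", function(object) {
  if (object@nChannels < 2L) return("need at least 2 channels")
  if (object@exponent < 1L) return("exponent must be >= 1")
  gaps <- diff(object@centers)
  if (length(gaps) && max(abs(gaps - gaps[1])) > 1e-9)
    return("centers must be evenly spaced")
  TRUE
})

#' Inverted encoding model
#'
#' @slot weights V units x nChannels encoding weight matrix W solving
#'   the least-squares problem B = WC.
#' @slot basis the [ChannelBasis-class] used for the design.
#' @slot trainConditionNumber condition number of the training design.
#' @export
setClass("IEMModel",
  representation(weights = "matrix", basis = "ChannelBasis",
                 trainConditionNumber = "numeric")
)

#' Stimulus reconstruction from an inverted encoding model
#'
#' @slot channelResponses trials x nChannels reconstructed channel
#'   responses C2.
#' @slot pointEstimates per-trial feature estimates in `[0, domainPeriod)`.
#' @slot circularError signed circular error when truth was supplied
#'   (length 0 otherwise).
#' @export
setClass("Reconstruction",
  representation(channelResponses = "matrix", pointEstimates = "numeric",
                 circularError = "numeric")
)

#' Upsampled stimulus boxcar timecourse
#'
#' @slot values non-negative amplitudes at the upsampled grid.
#' @slot upsampleFactor samples per TR.
#' @slot trSeconds TR in seconds.
#' @export
setClass("StimTimecourse",
  representation(values = "numeric", upsampleFactor = "integer",
                 trSeconds = "numeric")
)
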
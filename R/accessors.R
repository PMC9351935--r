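#' @rdname SubjectTimeSeries
#' @param object,x a package object
#' @export
setGeneric("tsData", function(x) standardGeneric("tsData"))

#' @rdname SubjectTimeSeries
#' @export
setMethod("tsData", "SubjectTimeSeries", function(x) x@data)

#' @rdname SubjectTimeSeries
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))

#' @rdname SubjectTimeSeries
#' @export
setMethod("trSeconds", "SubjectTimeSeries", function(x) x@trSeconds)

#' @rdname SubjectTimeSeries
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname SubjectTimeSeries
#' @export
setMethod("nTimepoints", "SubjectTimeSeries", function(x) nrow(x@data))

#' @rdname SubjectTimeSeries
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' @rdname SubjectTimeSeries
#' @export
setMethod("nUnits", "SubjectTimeSeries", function(x) ncol(x@data))

#' @rdname MultiSubjectDataset
#' @param x a MultiSubjectDataset
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname MultiSubjectDataset
#' @export
setMethod("subjects", "MultiSubjectDataset", function(x) x@subjects)

#' @rdname MultiSubjectDataset
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname MultiSubjectDataset
#' @export
setMethod("nSubjects", "MultiSubjectDataset", function(x) length(x@subjects))

#' @rdname MultiSubjectDataset
#' @export
setMethod("nTimepoints", "MultiSubjectDataset",
          function(x) nrow(x@subjects[[1]]@data))

#' @rdname MultiSubjectDataset
#' @export
setMethod("nUnits", "MultiSubjectDataset",
          function(x) ncol(x@subjects[[1]]@data))

#' List of per-subject data matrices
#' @param x a MultiSubjectDataset
#' @return list of T x V matrices
#' @export
subjectMatrices <- function(x) lapply(x@subjects, function(s) s@data)

#' @rdname ISCResult
#' @param x an ISCResult
#' @export
iscValues <- function(x) x@values

#' @rdname ISCResult
#' @export
iscSummary <- function(x) x@summaryValues

#' @rdname ISFCResult
#' @param x an ISFCResult
#' @export
isfcMatrices <- function(x) x@matrices

#' @rdname NullTestResult
#' @param x a NullTestResult
#' @export
pValues <- function(x) x@pValues

#' @rdname NullTestResult
#' @export
qValues <- function(x) x@qValues

#' @rdname SRMModel
#' @param x an SRMModel
#' @export
srmTransforms <- function(x) x@transforms

#' @rdname SRMModel
#' @export
sharedResponse <- function(x) x@sharedResponse

#' @rdname SRMModel
#' @export
objectiveTrace <- function(x) x@objectiveTrace

#' @rdname EventSegModel
#' @param x an EventSegModel
#' @export
eventPatterns <- function(x) x@eventPatterns

#' @rdname EventSegModel
#' @export
eventSegments <- function(x) x@segments

#' @rdname EventSegModel
#' @export
loglikTrace <- function(x) x@loglikTrace

#' @rdname BoundarySet
#' @param x a BoundarySet
#' @export
boundaryTrs <- function(x) x@boundaries

#' In-mask voxel indices in the package's fixed serialization order
#'
#' In-mask voxels are ordered by ascending linear index with the x
#' coordinate fastest (Fortran/column-major order), so column `j` of a
#' data matrix corresponds to the j-th `TRUE` entry of the mask in this
#' order.
#'
#' @param geometry a [VolumeGeometry-class]
#' @return integer matrix with columns x, y, z (1-based voxel coordinates)
#' @export
maskCoordinates <- function(geometry) {
  which(geometry@mask, arr.ind = TRUE)[order(which(geometry@mask)), ,
                                       drop = FALSE]
}

## ---- show methods ---------------------------------------------------------

setMethod("show", "SubjectTimeSeries", function(object) {
  cat(sprintf("SubjectTimeSeries '%s': %d TRs x %d units, TR = %gs\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              object@trSeconds))
})

setMethod("show", "MultiSubjectDataset", function(object) {
  Vs <- vapply(object@subjects, function(s) ncol(s@data), integer(1))
  cat(sprintf("MultiSubjectDataset: %d subjects, %d TRs, units [%s], %s\n",
              length(object@subjects), nrow(object@subjects[[1]]@data),
              paste(range(Vs), collapse = "-"), object@alignmentMode))
})

setMethod("show", "VolumeGeometry", function(object) {
  cat(sprintf("VolumeGeometry: %s grid, %s mm voxels, %d in-mask\n",
              paste(object@dims, collapse = "x"),
              paste(object@voxelSizeMm, collapse = "x"),
              sum(object@mask)))
})

setMethod("show", "ISCResult", function(object) {
  cat(sprintf("ISCResult (%s): %d x %d, mean r = %.3f\n", object@method,
              nrow(object@values), ncol(object@values),
              mean(object@values, na.rm = TRUE)))
})

setMethod("show", "ISFCResult", function(object) {
  cat(sprintf("ISFCResult (%s%s): %d matrices of %d x %d\n",
              object@method,
              if (object@symmetrized) ", symmetrized" else "",
              length(object@matrices), nrow(object@matrices[[1]]),
              ncol(object@matrices[[1]])))
})

setMethod("show", "NullTestResult", function(object) {
  cat(sprintf(
    "NullTestResult (%s, B = %d, tail = %s): %d unit(s), min p = %.4g\n",
    object@method, object@nNull, object@tail, length(object@pValues),
    min(object@pValues, na.rm = TRUE)))
})

setMethod("show", "SRMModel", function(object) {
  cat(sprintf(
    "SRMModel: k = %d, %d subjects, T = %d, final objective = %.4g\n",
    object@k, length(object@transforms), ncol(object@sharedResponse),
    tail(object@objectiveTrace, 1)))
})

setMethod("show", "EventSegModel", function(object) {
  cat(sprintf(
    "EventSegModel: K = %d events, T = %d, sigma2 = %.4g, loglik = %.4g\n",
    object@K, nrow(object@segments), object@sigma2,
    tail(object@loglikTrace, 1)))
})

setMethod("show", "BoundarySet", function(object) {
  cat(sprintf("BoundarySet: K = %d, boundaries at TRs [%s]\n", object@K,
              paste(object@boundaries, collapse = ", ")))
})

setMethod("show", "NoiseProfile", function(object) {
  cat(sprintf(
    paste0("NoiseProfile: sfnr = %.3g, snr = %.3g, arRho = %.3g, ",
           "drift = %.3g%%, fwhm = %.3g mm, baseline = %.3g\n"),
    object@sfnr, object@snr, object@arRho, object@driftSdPct,
    object@spatialFwhmMm, object@baseline))
})

setMethod("show", "ChannelBasis", function(object) {
  cat(sprintf(
    "ChannelBasis: %d channels over %g deg, exponent %d (%s)\n",
    object@nChannels, object@domainPeriod, object@exponent,
    object@dimensionality))
})

setMethod("show", "IEMModel", function(object) {
  cat(sprintf("IEMModel: %d units x %d channels, cond = %.3g\n",
              nrow(object@weights), ncol(object@weights),
              object@trainConditionNumber))
})

setMethod("show", "TimeSegmentReport", function(object) {
  cat(sprintf(
    "TimeSegmentReport: %d segments of %d TRs, accuracy = %.3f (chance %.3f)\n",
    object@nSegments, object@segmentLenTr, object@accuracy,
    object@chanceLevel))
})
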
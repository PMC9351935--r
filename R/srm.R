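## Shared response model: deterministic alternating minimization of
## sum_i ||X_i - W_i S||_F^2 subject to W_i' W_i = I_k.
##
## Data are stored time x voxel throughout the package; internally the
## model works with the voxel x time orientation X_i = t(data_i) so that
## W_i is V_i x k and S is k x T.

## polar factor (nearest matrix with orthonormal columns); unique for
## full-rank input, and polar(Q A) = Q polar(A) for orthogonal Q
.polar <- function(A, k) {
  sv <- svd(A, nu = k, nv = k)
  sv$u %*% t(sv$v)
}

.srmObjective <- function(X, W, S) {
  sum(vapply(seq_along(X), function(i)
    sum((X[[i]] - W[[i]] %*% S)^2), numeric(1)))
}

#' Fit a shared response model
#'
#' Decomposes z-scored multisubject data into subject-specific
#' orthonormal topographic transforms `W_i` (V_i x k) and a shared
#' low-dimensional response `S` (k x T) by alternating minimization:
#' each `W_i` is updated by orthogonal Procrustes (SVD of `X_i S'`,
#' `W_i = U V'`) and `S` as the average back-projection
#' `(1/N) sum_i W_i' X_i`. Subjects may have different unit counts; only
#' time alignment is required. Data are z-scored per unit before fitting.
#'
#' @param dataset a [MultiSubjectDataset-class] (either alignment mode).
#' @param k number of shared features, `k <= min(V_i)` and `k <= T`.
#' @param nIter number of alternating iterations (run exactly).
#' @param seed RNG seed for the initialization: a random time-domain
#'   probe `P` is drawn once and each transform starts at the polar
#'   factor of `X_i P`, which makes the fit equivariant to orthogonal
#'   rotations of any subject's unit space.
#' @param zscore standardize each unit before fitting (default TRUE).
#'   Set FALSE for data already expressed in the model's geometry, e.g.
#'   exact `W S` constructions, where per-unit rescaling would distort
#'   the orthonormal structure.
#' @return an [SRMModel-class]; `objectiveTrace(model)` records the
#'   training reconstruction error after every iteration and is
#'   non-increasing.
#' @export
srmFit <- function(dataset, k, nIter = 10, seed = 0, zscore = TRUE) {
  mats <- subjectMatrices(dataset)
  N <- length(mats)
  T <- nrow(mats[[1]])
  Vs <- vapply(mats, ncol, integer(1))
  k <- as.integer(k)
  if (k > min(Vs) || k > T)
    stop(sprintf("k = %d exceeds min units (%d) or timepoints (%d)",
                 k, min(Vs), T))
  X <- lapply(mats, function(m) {
    z <- if (zscore) zscoreMatrixTime(m, warnZeroVar = FALSE) else m
    if (all(z == 0)) stop("degenerate all-zero subject")
    t(z)                                   # V_i x T
  })
  set.seed(as.integer(seed))
  ## seeded random time-domain probe, shared across subjects: the polar
  ## initialization W_i = polar(X_i P) is equivariant to orthogonal
  ## rotations of any subject's unit space, so the objective trace is a
  ## function of the data geometry only
  P <- matrix(rnorm(T * k), T, k)
  W <- lapply(X, function(Xi) .polar(Xi %*% P, k))
  S <- Reduce(`+`, lapply(seq_len(N), function(i)
    crossprod(W[[i]], X[[i]]))) / N
  trace <- numeric(nIter)
  for (it in seq_len(nIter)) {
    W <- lapply(seq_len(N), function(i) .polar(X[[i]] %*% t(S), k))
    S <- Reduce(`+`, lapply(seq_len(N), function(i)
      crossprod(W[[i]], X[[i]]))) / N
    trace[it] <- .srmObjective(X, W, S)
  }
  new("SRMModel", k = k, transforms = W, sharedResponse = S,
      objectiveTrace = trace, nIter = as.integer(nIter),
      seed = as.integer(seed))
}

#' Project data into the shared space
#'
#' Applies a subject's learned topographic transform to (typically
#' unseen) data: returns `W_i' X_new`, a k x T' matrix in the shared
#' space. Input data are z-scored per unit first, matching the fit.
#'
#' @param model an [SRMModel-class].
#' @param newData a [SubjectTimeSeries-class] or T' x V_i matrix.
#' @param subjectIndex which subject's transform to use.
#' @param zscore z-score the input per unit before projecting (default
#'   TRUE, matching the training convention).
#' @return k x T' matrix of shared-space responses.
#' @export
srmTransform <- function(model, newData, subjectIndex, zscore = TRUE) {
  m <- if (is(newData, "SubjectTimeSeries")) newData@data else
    as.matrix(newData)
  W <- model@transforms[[subjectIndex]]
  if (ncol(m) != nrow(W))
    stop(sprintf("data has %d units but transform expects %d",
                 ncol(m), nrow(W)))
  if (zscore) m <- zscoreMatrixTime(m, warnZeroVar = FALSE)
  crossprod(W, t(m))
}

#' Reconstruct subject-space data from a shared response
#'
#' Projects a shared-space response back into one subject's voxel space:
#' returns `W_i %*% shared` as a [SubjectTimeSeries-class]. Composing
#' [srmTransform()] then `srmReconstruct()` yields the rank-k orthogonal
#' projection of the input onto the span of `W_i`.
#'
#' @param model an [SRMModel-class].
#' @param shared k x T' matrix.
#' @param subjectIndex which subject's transform to use.
#' @param trSeconds sampling interval recorded on the output.
#' @return a [SubjectTimeSeries-class] with T' rows and V_i columns.
#' @export
srmReconstruct <- function(model, shared, subjectIndex, trSeconds = 1) {
  shared <- as.matrix(shared)
  if (nrow(shared) != model@k)
    stop(sprintf("shared response has %d rows but k = %d",
                 nrow(shared), model@k))
  W <- model@transforms[[subjectIndex]]
  SubjectTimeSeries(t(W %*% shared), trSeconds = trSeconds,
                    subjectId = sprintf("recon_s%d", subjectIndex))
}

#' Between-subject time-segment classification
#'
#' Standard evaluation of functional alignment: the time axis is cut
#' into non-overlapping segments of `segmentLenTr` TRs; each held-out
#' subject's segment (the feature x time block, flattened) is correlated
#' with the other-subject average of every candidate segment, and the
#' argmax is the prediction. Candidates overlapping the true segment's
#' immediate neighbors cannot win by tie: ties are broken toward the
#' earliest segment index, and a tie between the true segment's
#' neighbors and the truth resolves to the smaller index.
#'
#' @param spaces list of k x T matrices (one per subject), e.g. each
#'   subject's shared-space projection, or unit-space data transposed.
#' @param segmentLenTr segment length in TRs (>= 2).
#' @return a [TimeSegmentReport-class].
#' @export
timeSegmentClassify <- function(spaces, segmentLenTr) {
  segmentLenTr <- as.integer(segmentLenTr)
  if (segmentLenTr < 2L) stop("segmentLenTr must be >= 2")
  N <- length(spaces)
  if (N < 2L) stop("need at least 2 subjects")
  T <- ncol(spaces[[1]])
  if (T < 2L * segmentLenTr) stop("need T >= 2 * segmentLenTr")
  nSeg <- T %/% segmentLenTr
  segCols <- lapply(seq_len(nSeg), function(g)
    ((g - 1L) * segmentLenTr + 1L):(g * segmentLenTr))
  total <- Reduce(`+`, spaces)
  perSubj <- vapply(seq_len(N), function(s) {
    other <- (total - spaces[[s]]) / (N - 1)
    correct <- 0L
    for (g in seq_len(nSeg)) {
      x <- as.vector(spaces[[s]][, segCols[[g]]])
      rs <- vapply(seq_len(nSeg), function(h)
        suppressWarnings(cor(x, as.vector(other[, segCols[[h]]]))),
        numeric(1))
      rs[is.na(rs)] <- -Inf
      best <- max(rs)
      cand <- which(rs >= best - 1e-12)
      ## adjacent segments may not win on a tie with the true segment
      if (g %in% cand) {
        cand <- setdiff(cand, setdiff(intersect(cand, c(g - 1L, g + 1L)),
                                      g))
      }
      pred <- min(cand)
      if (pred == g) correct <- correct + 1L
    }
    correct / nSeg
  }, numeric(1))
  new("TimeSegmentReport", segmentLenTr = segmentLenTr,
      accuracy = mean(perSubj), chanceLevel = 1 / nSeg,
      nSegments = as.integer(nSeg), perSubjectAccuracy = perSubj)
}
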
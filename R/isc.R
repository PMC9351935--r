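## Intersubject correlation (ISC), intersubject functional correlation
## (ISFC), spatial and sliding-window variants, and nonparametric tests.
##
## All correlations are Pearson, computed through population z-scores so
## that r = <z_a, z_b> / T exactly. Zero-variance series yield NaN
## entries (never silent zeros) and are excluded from summaries.

## column-wise correlation of two T x V matrices; NaN for zero variance
.colCor <- function(a, b) {
  T <- nrow(a)
  za <- scale(a, scale = FALSE); zb <- scale(b, scale = FALSE)
  sa <- sqrt(colSums(za^2) / T); sb <- sqrt(colSums(zb^2) / T)
  r <- colSums(za * zb) / (T * sa * sb)
  r[sa <= 0 | sb <= 0] <- NaN
  unname(r)
}

.fisherMean <- function(r) {
  z <- atanh(pmin(pmax(r, -1), 1))
  z <- z[!is.nan(z)]
  if (!length(z)) return(NaN)
  tanh(mean(z))
}

.pairIndex <- function(n) t(combn(n, 2))

#' Intersubject correlation
#'
#' Isolates the stimulus-driven component of the response by correlating
#' homologous units across subjects receiving the same stimulus. In the
#' leave-one-out form, each subject's unit time series is correlated with
#' the average of the remaining subjects; in the pairwise form every
#' subject pair is correlated directly.
#'
#' @param dataset a units-aligned [MultiSubjectDataset-class].
#' @param method `"loo"` (leave-one-out) or `"pairwise"`.
#' @param summary across-subject summary per unit: `"none"`,
#'   `"mean_fisher_z"` (mean of atanh-transformed correlations, inverse
#'   transformed) or `"median"`. NaN entries from zero-variance series
#'   are excluded from summaries with a message reporting the count.
#' @return an [ISCResult-class]; `iscSummary()` holds the summary vector
#'   when requested.
#' @examples
#' set.seed(1)
#' s <- matrix(rnorm(200), 100, 2)
#' ds <- MultiSubjectDataset(lapply(1:3, function(i) s + rnorm(200)))
#' isc(ds, summary = "mean_fisher_z")
#' @export
isc <- function(dataset, method = c("loo", "pairwise"),
                summary = c("none", "mean_fisher_z", "median")) {
  method <- match.arg(method)
  summary <- match.arg(summary)
  if (dataset@alignmentMode != "units_aligned")
    stop("ISC requires a units_aligned dataset")
  mats <- subjectMatrices(dataset)
  N <- length(mats); T <- nrow(mats[[1]]); V <- ncol(mats[[1]])
  if (T < 3L) stop("need T >= 3 timepoints for correlation")
  ## z-score each subject per unit so every subject enters the
  ## leave-one-out average with equal weight; this makes all results
  ## exactly invariant to positive per-unit affine rescaling
  mats <- lapply(mats, zscoreMatrixTime, warnZeroVar = FALSE)
  if (method == "loo") {
    total <- Reduce(`+`, mats)
    vals <- t(vapply(seq_len(N), function(s)
      .colCor(mats[[s]], (total - mats[[s]]) / (N - 1)), numeric(V)))
    pairIdx <- matrix(integer(0), 0, 2)
  } else {
    pairIdx <- .pairIndex(N)
    vals <- t(vapply(seq_len(nrow(pairIdx)), function(p)
      .colCor(mats[[pairIdx[p, 1]]], mats[[pairIdx[p, 2]]]), numeric(V)))
  }
  nNaN <- sum(is.nan(vals))
  if (nNaN > 0)
    warning(sprintf("%d NaN ISC entr%s from zero-variance series",
                    nNaN, if (nNaN == 1) "y" else "ies"))
  summ <- numeric(0)
  if (summary != "none") {
    summ <- apply(vals, 2L, function(col) {
      col <- col[!is.nan(col)]
      if (!length(col)) return(NaN)
      if (summary == "mean_fisher_z") .fisherMean(col) else median(col)
    })
  }
  new("ISCResult", values = vals, method = method,
      pairIndex = pairIdx, summaryValues = summ, summaryMethod = summary)
}

#' Intersubject functional correlation
#'
#' Correlates every unit of one subject with every unit of the average of
#' the other subjects (leave-one-out) or of another subject (pairwise),
#' estimating stimulus-driven functional connectivity. The diagonal of
#' the symmetrized leave-one-out ISFC matrix equals the leave-one-out
#' ISC.
#'
#' @param dataset a units-aligned [MultiSubjectDataset-class].
#' @param method `"loo"` or `"pairwise"`.
#' @param symmetrize replace each matrix M by (M + t(M))/2.
#' @return an [ISFCResult-class].
#' @export
isfc <- function(dataset, method = c("loo", "pairwise"),
                 symmetrize = TRUE) {
  method <- match.arg(method)
  if (dataset@alignmentMode != "units_aligned")
    stop("ISFC requires a units_aligned dataset")
  mats <- subjectMatrices(dataset)
  N <- length(mats); T <- nrow(mats[[1]])
  if (T < 3L) stop("need T >= 3 timepoints for correlation")
  mats <- lapply(mats, zscoreMatrixTime, warnZeroVar = FALSE)
  crossCor <- function(a, b) {
    za <- scale(a, scale = FALSE); zb <- scale(b, scale = FALSE)
    sa <- sqrt(colSums(za^2) / T); sb <- sqrt(colSums(zb^2) / T)
    m <- crossprod(za, zb) / (T * outer(sa, sb))
    m[sa <= 0, ] <- NaN; m[, sb <= 0] <- NaN
    m
  }
  if (method == "loo") {
    total <- Reduce(`+`, mats)
    out <- lapply(seq_len(N), function(s)
      crossCor(mats[[s]], (total - mats[[s]]) / (N - 1)))
  } else {
    pairIdx <- .pairIndex(N)
    out <- lapply(seq_len(nrow(pairIdx)), function(p)
      crossCor(mats[[pairIdx[p, 1]]], mats[[pairIdx[p, 2]]]))
  }
  if (symmetrize) out <- lapply(out, function(m) (m + t(m)) / 2)
  new("ISFCResult", matrices = out, symmetrized = symmetrize,
      method = method)
}

#' Spatial (pattern) intersubject correlation
#'
#' Correlates, across units, each subject's spatial response pattern at
#' one timepoint with the average pattern of the remaining subjects,
#' then averages over subjects through the Fisher z transform. With
#' `pairAllTimepoints = TRUE` every pair of timepoints is compared,
#' yielding the T x T spatial analogue of ISFC that reveals recurring
#' patterns.
#'
#' @param dataset a units-aligned [MultiSubjectDataset-class] with V >= 3.
#' @param pairAllTimepoints return the full T x T matrix.
#' @return numeric vector of length T, or a T x T matrix.
#' @export
spatialISC <- function(dataset, pairAllTimepoints = FALSE) {
  if (dataset@alignmentMode != "units_aligned")
    stop("spatial ISC requires a units_aligned dataset")
  mats <- subjectMatrices(dataset)
  N <- length(mats); T <- nrow(mats[[1]]); V <- ncol(mats[[1]])
  if (V < 3L) stop("need V >= 3 units for spatial correlation")
  mats <- lapply(mats, zscoreMatrixTime, warnZeroVar = FALSE)
  ## z-score patterns (rows) across units
  zrow <- function(m) {
    ctr <- m - rowMeans(m)
    s <- sqrt(rowSums(ctr^2) / V)
    s[s <= 0] <- NaN
    ctr / s
  }
  zmats <- lapply(mats, zrow)
  total <- Reduce(`+`, mats)
  if (!pairAllTimepoints) {
    rs <- vapply(seq_len(N), function(s) {
      other <- zrow((total - mats[[s]]) / (N - 1))
      rowSums(zmats[[s]] * other) / V
    }, numeric(T))
    apply(rs, 1L, .fisherMean)
  } else {
    acc <- matrix(0, T, T); cnt <- 0
    for (s in seq_len(N)) {
      other <- zrow((total - mats[[s]]) / (N - 1))
      r <- tcrossprod(zmats[[s]], other) / V   # [t1, t2]
      acc <- acc + atanh(pmin(pmax(r, -1), 1))
      cnt <- cnt + 1
    }
    tanh(acc / cnt)
  }
}

#' Sliding-window intersubject correlation
#'
#' Measures coarse fluctuations of the shared signal over time by
#' running an independent ISC analysis in each window. Window `w`
#' (0-based) covers TRs `[w*stepTr, w*stepTr + windowTr)` (0-based,
#' half-open).
#'
#' @param dataset a units-aligned [MultiSubjectDataset-class].
#' @param windowTr window length in TRs (3 <= windowTr <= T).
#' @param stepTr step between window starts in TRs.
#' @param method passed to [isc()].
#' @return windows x V matrix of per-window across-subject
#'   Fisher-z-mean ISC values.
#' @export
slidingISC <- function(dataset, windowTr, stepTr = 1,
                       method = c("loo", "pairwise")) {
  method <- match.arg(method)
  T <- nTimepoints(dataset)
  if (windowTr < 3L) stop("windowTr must be >= 3")
  if (windowTr > T) stop("window exceeds the number of timepoints")
  starts <- seq(0L, T - windowTr, by = stepTr)
  out <- t(vapply(starts, function(s0) {
    sub <- MultiSubjectDataset(
      lapply(dataset@subjects, function(s)
        initialize(s, data = s@data[(s0 + 1):(s0 + windowTr), ,
                                    drop = FALSE])),
      alignmentMode = "units_aligned")
    iscSummary(isc(sub, method = method, summary = "mean_fisher_z"))
  }, numeric(nUnits(dataset))))
  rownames(out) <- paste0("w", seq_along(starts) - 1L)
  out
}

## ---- nonparametric tests --------------------------------------------------

#' Phase-scramble the columns of a time-series matrix
#'
#' Multiplies each Fourier coefficient by a random unit phasor with
#' conjugate-symmetric phases (DC and Nyquist kept at zero phase), so the
#' surrogate is real-valued and preserves the amplitude spectrum of every
#' column exactly. All columns share the same phase draw, preserving the
#' subject's spatial covariance.
#'
#' @param m T x V matrix.
#' @return surrogate matrix of the same shape.
#' @export
phaseScramble <- function(m) {
  T <- nrow(m)
  nHalf <- floor((T - 1) / 2)
  phase <- numeric(T)
  if (nHalf > 0) {
    ph <- runif(nHalf, 0, 2 * pi)
    phase[2:(nHalf + 1)] <- ph
    phase[T:(T - nHalf + 1)] <- -ph
  }
  rot <- exp(1i * phase)
  Re(mvfft(mvfft(m) * rot, inverse = TRUE)) / T
}

.circularShift <- function(m, offset) {
  T <- nrow(m)
  offset <- offset %% T
  if (offset == 0) return(m)
  m[c((T - offset + 1):T, 1:(T - offset)), , drop = FALSE]
}

.addOneP <- function(obs, nullV, tail) {
  B <- length(nullV)
  pg <- (1 + sum(nullV >= obs)) / (1 + B)
  if (tail == "greater") return(pg)
  pl <- (1 + sum(nullV <= obs)) / (1 + B)
  min(1, 2 * min(pg, pl))
}

#' Nonparametric statistical tests for ISC
#'
#' Builds a null distribution for the per-unit across-subject ISC
#' summary (mean Fisher z) by one of four schemes:
#' `phase_randomization` re-creates surrogate subjects with identical
#' amplitude spectra but random Fourier phases; `circular_shift` rotates
#' each subject's time axis by an independent uniform offset;
#' `subject_bootstrap` resamples subjects with replacement on the
#' Fisher-z leave-one-out values (null centered at the observed mean);
#' `sign_permutation` randomly flips the signs of the per-subject
#' Fisher-z values. p-values follow the add-one rule,
#' p = (1 + #\{null >= observed\}) / (1 + B); q-values are
#' Benjamini-Hochberg adjusted across units.
#'
#' @param result the observed [ISCResult-class].
#' @param dataset the [MultiSubjectDataset-class] the result came from
#'   (needed by the surrogate-data methods).
#' @param method one of `"phase_randomization"`, `"circular_shift"`,
#'   `"subject_bootstrap"`, `"sign_permutation"`.
#' @param nNull number of null samples B.
#' @param seed RNG seed (required; every draw derives from it).
#' @param tail `"greater"` (default) or `"two_sided"` (doubles the
#'   smaller tail, capped at 1).
#' @return a [NullTestResult-class].
#' @export
iscTest <- function(result, dataset,
                    method = c("phase_randomization", "circular_shift",
                               "subject_bootstrap", "sign_permutation"),
                    nNull = 1000, seed,
                    tail = c("greater", "two_sided")) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  if (missing(seed)) stop("an explicit seed is required")
  if (nNull < 1) stop("nNull must be >= 1")
  if (method %in% c("subject_bootstrap", "sign_permutation") &&
      result@method != "loo")
    stop(sprintf("%s requires a leave-one-out ISCResult", method))
  set.seed(as.integer(seed))
  z <- atanh(pmin(pmax(result@values, -1 + 1e-15), 1 - 1e-15))
  observed <- apply(z, 2L, function(col) mean(col[!is.nan(col)]))
  V <- length(observed)
  mats <- subjectMatrices(dataset)
  N <- length(mats); T <- nrow(mats[[1]])
  summStat <- function(ds) {
    r <- isc(ds, method = result@method, summary = "none")@values
    zz <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
    apply(zz, 2L, function(col) mean(col[!is.nan(col)]))
  }
  nullSamples <- matrix(NA_real_, nNull, V)
  for (b in seq_len(nNull)) {
    nullSamples[b, ] <- switch(method,
      phase_randomization = {
        surr <- lapply(mats, phaseScramble)
        summStat(MultiSubjectDataset(surr))
      },
      circular_shift = {
        surr <- lapply(mats, function(m)
          .circularShift(m, sample.int(T - 1L, 1)))
        summStat(MultiSubjectDataset(surr))
      },
      subject_bootstrap = {
        idx <- sample.int(N, N, replace = TRUE)
        colMeans(z[idx, , drop = FALSE], na.rm = TRUE) - observed
      },
      sign_permutation = {
        signs <- sample(c(-1, 1), N, replace = TRUE)
        colMeans(signs * z, na.rm = TRUE)
      })
  }
  p <- vapply(seq_len(V), function(v)
    .addOneP(observed[v], nullSamples[, v], tail), numeric(1))
  q <- p.adjust(p, method = "BH")
  new("NullTestResult", observed = observed, nullSamples = nullSamples,
      pValues = p, qValues = q, method = method,
      seed = as.integer(seed), nNull = as.integer(nNull), tail = tail)
}
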
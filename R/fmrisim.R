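## Realistic fMRI simulation: task signal from onset tables via a
## double-gamma HRF, and noise as a linear combination of baseline,
## low-frequency drift, AR(1) temporal noise, physiological sinusoids,
## spatially smoothed system noise and white machine noise, with an
## iterative multiplicative fit of component amplitudes to a target
## SFNR and lag-1 autocorrelation. This module generates every synthetic
## dataset used elsewhere in the package.

## deterministic per-component sub-seed so adding one component never
## perturbs another's stream
.subSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Read a BIDS-style events table
#'
#' Expects tab-separated columns `onset`, `duration`, `trial_type` and
#' optionally `amplitude` (default 1).
#'
#' @param path events TSV path.
#' @return data.frame with columns onset, duration, condition, amplitude.
#' @export
readDesignTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (!all(c("onset", "duration") %in% names(d)))
    stop("events table needs 'onset' and 'duration' columns")
  cond <- if ("trial_type" %in% names(d)) d$trial_type else
    if ("condition" %in% names(d)) d$condition else "task"
  amp <- if ("amplitude" %in% names(d)) d$amplitude else 1
  designTable(d$onset, d$duration, cond, amp)
}

#' Construct an event design table
#'
#' @param onset event onsets in seconds (non-negative).
#' @param duration event durations in seconds (positive).
#' @param condition condition labels.
#' @param amplitude event amplitudes.
#' @return data.frame of class `"designTable"`.
#' @export
designTable <- function(onset, duration, condition = "task",
                        amplitude = 1) {
  d <- data.frame(onset = as.numeric(onset),
                  duration = as.numeric(duration),
                  condition = as.character(condition),
                  amplitude = as.numeric(amplitude))
  if (nrow(d)) {
    if (any(d$onset < 0)) stop("onsets must be non-negative")
    if (any(d$duration <= 0)) stop("durations must be positive")
  }
  class(d) <- c("designTable", "data.frame")
  d
}

#' Upsampled boxcar stimulus timecourses per condition
#'
#' Each condition's timecourse takes the event amplitude within
#' `[onset, onset + duration)` (half-open, 0-based time) and 0
#' elsewhere, at a resolution of `upsampleFactor` samples per TR.
#' Overlapping events within a condition sum, with a warning.
#'
#' @param design a [designTable()] data.frame.
#' @param totalTimeS scan duration in seconds.
#' @param trSeconds TR in seconds.
#' @param upsampleFactor samples per TR (>= 1).
#' @return named list of [StimTimecourse-class], one per condition.
#' @export
generateStimfunction <- function(design, totalTimeS, trSeconds,
                                 upsampleFactor = 10) {
  upsampleFactor <- as.integer(upsampleFactor)
  n <- ceiling(totalTimeS / trSeconds) * upsampleFactor
  dt <- trSeconds / upsampleFactor
  tGrid <- (seq_len(n) - 1L) * dt
  if (nrow(design) && any(design$onset >= totalTimeS))
    stop("event onset beyond scan end")
  conds <- if (nrow(design)) unique(design$condition) else "task"
  out <- lapply(conds, function(cc) {
    rows <- design[design$condition == cc, , drop = FALSE]
    v <- numeric(n)
    overlapped <- FALSE
    for (i in seq_len(nrow(rows))) {
      inEvent <- tGrid >= rows$onset[i] &
        tGrid < rows$onset[i] + rows$duration[i]
      if (any(v[inEvent] != 0)) overlapped <- TRUE
      v[inEvent] <- v[inEvent] + rows$amplitude[i]
    }
    if (overlapped)
      warning(sprintf(
        "overlapping events in condition '%s'; amplitudes summed", cc))
    new("StimTimecourse", values = v, upsampleFactor = upsampleFactor,
        trSeconds = as.numeric(trSeconds))
  })
  names(out) <- conds
  out
}

#' Double-gamma haemodynamic response function
#'
#' `h(t) = g(t; a1, b1) - c * g(t; a2, b2)` with gamma densities `g`,
#' normalized to peak 1. Defaults: response shape `a1 = 6`, dispersion
#' `b1 = 0.9` s (mode at `(a1 - 1) * b1 = 4.5` s), undershoot shape
#' `a2 = 12`, dispersion `b2 = 0.9` s, undershoot ratio `c = 0.35`.
#'
#' @param t time grid in seconds.
#' @param a1,b1 shape and scale (s) of the response gamma.
#' @param a2,b2 shape and scale (s) of the undershoot gamma.
#' @param c undershoot ratio.
#' @return HRF samples, peak-normalized to 1.
#' @export
doubleGammaHrf <- function(t, a1 = 6, b1 = 0.9, a2 = 12, b2 = 0.9,
                           c = 0.35) {
  h <- dgamma(t, shape = a1, scale = b1) -
    c * dgamma(t, shape = a2, scale = b2)
  h / max(h)
}

#' Convolve a stimulus timecourse with the HRF and downsample to TRs
#'
#' Discrete convolution at the upsampled resolution with a 30 s
#' double-gamma HRF, then downsampling by taking the sample at each TR
#' onset.
#'
#' @param stim a [StimTimecourse-class].
#' @param hrfDurationS HRF support in seconds.
#' @param ... HRF parameters passed to [doubleGammaHrf()].
#' @return numeric vector of length T (TR resolution).
#' @export
convolveHrf <- function(stim, hrfDurationS = 30, ...) {
  dt <- stim@trSeconds / stim@upsampleFactor
  tGrid <- seq(0, hrfDurationS, by = dt)
  h <- doubleGammaHrf(tGrid, ...)
  n <- length(stim@values)
  conv <- convolve(stim@values, rev(h), type = "open")[seq_len(n)]
  conv[seq(1, n, by = stim@upsampleFactor)]
}

## separable 3-D Gaussian smoothing with edge renormalization
.smooth3d <- function(vol, sigmaVox) {
  if (all(sigmaVox <= 0)) return(vol)
  out <- vol
  ones <- array(1, dim = dim(vol))
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    kern <- exp(-((-half:half)^2) / (2 * s^2))
    kern <- kern / sum(kern)
    out <- .convAxis(out, kern, ax)
    ones <- .convAxis(ones, kern, ax)
  }
  out / ones
}

.convAxis <- function(vol, kern, ax) {
  d <- dim(vol)
  half <- (length(kern) - 1L) / 2L
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  v <- aperm(vol, perm)
  dv <- dim(v)
  m <- matrix(v, nrow = dv[1])
  n <- nrow(m)
  res <- matrix(0, n, ncol(m))
  for (j in seq_along(kern)) {
    off <- j - half - 1L
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    res[ok, ] <- res[ok, ] + kern[j] * m[src[ok], ]
  }
  out <- array(res, dim = dv)
  aperm(out, order(perm))
}

## internal: build raw (unscaled) noise component arrays
.noiseComponents <- function(geometry, T, trSeconds, profile, seed) {
  dims <- geometry@dims
  mask <- geometry@mask
  V <- sum(mask)
  nVox <- prod(dims)
  comps <- list()

  ## drift: shared cosine set below 1/128 Hz, unit temporal sd
  set.seed(.subSeed(seed, "drift"))
  scanLen <- T * trSeconds
  jMax <- floor(scanLen / 64)           # j/(2*scanLen) < 1/128
  tIdx <- seq_len(T) - 0.5
  if (jMax >= 1) {
    basis <- vapply(seq_len(jMax), function(j)
      cos(pi * j * tIdx / T), numeric(T))
    w <- rnorm(jMax)
    dr <- as.vector(basis %*% w)
  } else {
    dr <- cos(pi * tIdx / T)
  }
  comps$drift <- dr / sd(dr)

  ## innovations for the AR(1) temporal noise per in-mask voxel; the
  ## generating coefficient is applied at assembly time so the fit can
  ## adjust it without redrawing
  set.seed(.subSeed(seed, "ar"))
  comps$innov <- matrix(rnorm(T * V), T, V)

  ## white machine noise per in-mask voxel
  set.seed(.subSeed(seed, "white"))
  comps$white <- matrix(rnorm(T * V), T, V)

  ## physiological sinusoids: shared frequencies, voxel-specific phase
  ## (cardiac/respiratory cycles reach voxels with different delays);
  ## unit temporal sd per voxel
  set.seed(.subSeed(seed, "physio"))
  if (length(profile@physioFreqsHz)) {
    tSec <- (seq_len(T) - 1) * trSeconds
    py <- matrix(0, T, V)
    for (fq in profile@physioFreqsHz) {
      phase <- runif(V, 0, 2 * pi)
      py <- py + sin(outer(2 * pi * fq * tSec, phase, "+"))
    }
    s <- apply(py, 2L, sd)
    s[s <= 0] <- 1
    comps$physio <- sweep(py, 2L, s, "/")
  } else comps$physio <- NULL

  ## spatially smoothed system noise per timepoint, unit temporal sd
  set.seed(.subSeed(seed, "spatial"))
  if (profile@spatialFwhmMm > 0) {
    sigmaVox <- profile@spatialFwhmMm / 2.355 / geometry@voxelSizeMm
    sp <- matrix(0, T, V)
    for (t in seq_len(T)) {
      f <- .smooth3d(array(rnorm(nVox), dim = dims), sigmaVox)
      sp[t, ] <- f[mask]
    }
    sp <- scale(sp, center = FALSE,
                scale = apply(sp, 2L, sd))
    comps$spatial <- sp
  } else comps$spatial <- NULL

  ## out-of-mask spatial noise at every timepoint
  set.seed(.subSeed(seed, "outside"))
  comps$outside <- matrix(rnorm(T * (nVox - V)), T)
  comps
}

.assembleVolume <- function(comps, geometry, T, profile, amps,
                            rhoGen = profile@arRho) {
  dims <- geometry@dims
  mask <- geometry@mask
  V <- sum(mask)
  nVox <- prod(dims)
  baseline <- profile@baseline
  inMask <- matrix(baseline, T, V)
  driftSd <- profile@driftSdPct / 100 * baseline
  inMask <- inMask + driftSd * comps$drift
  arMat <- if (rhoGen != 0)
    apply(comps$innov, 2L, function(e)
      as.vector(filter(e, rhoGen, method = "recursive"))) *
      sqrt(1 - rhoGen^2)
  else comps$innov
  inMask <- inMask + amps["ar"] * arMat + amps["white"] * comps$white
  if (!is.null(comps$physio))
    inMask <- inMask + amps["physio"] * comps$physio
  if (!is.null(comps$spatial))
    inMask <- inMask + amps["spatial"] * comps$spatial
  flat <- matrix(0, nVox, T)
  flat[as.vector(mask), ] <- t(inMask)
  if (nVox > V)
    flat[!as.vector(mask), ] <-
      t(comps$outside * (baseline / profile@snr))
  array(flat, dim = c(dims, T))
}

#' Generate a 4-D noise volume matching a target profile
#'
#' Noise is a linear combination of a baseline, a low-frequency cosine
#' drift (frequencies below 1/128 Hz, scaled to `driftSdPct`), AR(1)
#' temporal noise, white machine noise, physiological sinusoids at
#' `physioFreqsHz` (evaluated at TR sample times, hence implicitly
#' aliased), spatially smoothed Gaussian system noise, and out-of-mask
#' scanner background noise scaled by `snr`. Component amplitudes are
#' refined multiplicatively for up to `fitIterations` steps until the
#' measured SFNR and lag-1 autocorrelation are within 5% of the target
#' profile; if the budget is exhausted, the achieved values are reported
#' in a warning. Each component draws from its own seeded stream derived
#' from `seed`, so runs are bit-reproducible.
#'
#' @param geometry a [VolumeGeometry-class].
#' @param T number of timepoints (>= 10).
#' @param trSeconds TR in seconds.
#' @param profile the target [NoiseProfile-class].
#' @param fitIterations maximum refinement steps (default 20).
#' @param seed RNG seed.
#' @return 4-D array of shape `c(geometry@dims, T)`, with attribute
#'   `"achieved"` holding the measured profile.
#' @export
generateNoise <- function(geometry, T, trSeconds = 1, profile,
                          fitIterations = 20, seed = 0) {
  if (T < 10) stop("need T >= 10 timepoints")
  comps <- .noiseComponents(geometry, T, trSeconds, profile, seed)
  sigmaT <- profile@baseline / profile@sfnr
  hasSp <- !is.null(comps$spatial)
  hasPh <- !is.null(comps$physio)
  pSp <- if (hasSp) 0.2 else 0
  pPh <- if (hasPh) 0.05 else 0
  f <- 0.5                              # AR share of the AR+white block
  rhoGen <- profile@arRho               # generating AR coefficient
  tol <- 0.05
  amps <- NULL
  achieved <- NULL
  for (it in seq_len(max(1, fitIterations))) {
    pAw <- 1 - pSp - pPh
    amps <- c(ar = sigmaT * sqrt(pAw * f),
              white = sigmaT * sqrt(pAw * (1 - f)),
              physio = sigmaT * sqrt(pPh),
              spatial = sigmaT * sqrt(pSp))
    vol <- .assembleVolume(comps, geometry, T, profile, amps, rhoGen)
    achieved <- suppressWarnings(
      measureNoise(vol, geometry, trSeconds))
    sfnrErr <- achieved@sfnr / profile@sfnr - 1
    rhoTol <- max(tol * abs(profile@arRho), 0.01)
    rhoErr <- achieved@arRho - profile@arRho
    if (abs(sfnrErr) <= tol && abs(rhoErr) <= rhoTol) break
    sigmaT <- sigmaT * achieved@sfnr / profile@sfnr
    if (profile@arRho != 0) {
      ## damped updates: first grow the AR share f; once it saturates,
      ## push the generating coefficient past the target (detrending
      ## and spatial dilution bias the measurement down) and shrink the
      ## competing temporally-white components
      clampRho <- function(x) max(-0.9, min(0.9, x))
      ratio <- achieved@arRho / profile@arRho
      if (ratio < 1) {                 # too little autocorrelation
        if (f < 1) {
          f <- min(1, if (ratio < 0.05) f * 2 else f * ratio^(-0.5))
        } else {
          rhoGen <- clampRho(rhoGen - 0.5 * rhoErr)
          pSp <- pSp * 0.8
          pPh <- pPh * 0.8
        }
      } else {                         # overshoot
        if (abs(rhoGen) > abs(profile@arRho)) {
          rhoGen <- clampRho(rhoGen - 0.5 * rhoErr)
          if (abs(rhoGen) < abs(profile@arRho)) rhoGen <- profile@arRho
        } else {
          f <- max(0.02, f * ratio^(-0.5))
        }
      }
    }
  }
  sfnrErr <- achieved@sfnr / profile@sfnr - 1
  rhoErr <- achieved@arRho - profile@arRho
  if (abs(sfnrErr) > tol ||
      abs(rhoErr) > max(tol * abs(profile@arRho), 0.01))
    warning(sprintf(
      "noise fit not fully converged: achieved sfnr = %.3g (target %.3g), arRho = %.3g (target %.3g)",
      achieved@sfnr, profile@sfnr, achieved@arRho, profile@arRho))
  vol <- .assembleVolume(comps, geometry, T, profile, amps, rhoGen)
  attr(vol, "achieved") <- achieved
  vol
}

## quadratic detrend of columns of a T x V matrix; returns residuals
.quadDetrend <- function(m) {
  T <- nrow(m)
  t1 <- seq_len(T)
  X <- cbind(1, t1, t1^2)
  m - X %*% qr.coef(qr(X), m)
}

#' Measure the noise properties of a 4-D volume
#'
#' Estimates SFNR (voxel mean over temporal sd of the
#' quadratic-detrended series, averaged in-mask), spatial SNR (in-mask
#' mean over the spatial sd of out-of-mask voxels at the middle
#' timepoint; when the mask covers the whole grid a high-frequency
#' temporal proxy is used and flagged with a warning), the lag-1
#' autocorrelation of the detrended in-mask average, and the drift
#' amplitude (sd of the low-frequency cosine projection of the in-mask
#' average, as percent of the mean).
#'
#' @param volume 4-D array (x, y, z, t).
#' @param geometry a [VolumeGeometry-class].
#' @param trSeconds TR in seconds.
#' @return a [NoiseProfile-class] of measured values.
#' @export
measureNoise <- function(volume, geometry, trSeconds = 1) {
  dims <- dim(volume)
  if (length(dims) != 4L) stop("volume must be 4-D")
  T <- dims[4]
  if (T < 10) stop("need T >= 10 timepoints")
  mask <- geometry@mask
  if (!any(mask)) stop("empty mask")
  flat <- matrix(as.vector(volume), ncol = T)
  inMask <- t(flat[as.vector(mask), , drop = FALSE])   # T x V
  mu <- colMeans(inMask)
  resid <- .quadDetrend(inMask)
  sdv <- apply(resid, 2L, sd)
  sdv[sdv <= max(abs(mu), 1) * 1e-10] <- 0   # numerically constant
  if (any(sdv <= 0)) {
    warning("time-constant voxel(s): SFNR reported as Inf")
    sfnr <- Inf
  } else {
    sfnr <- mean(mu / sdv)
  }
  baseline <- mean(mu)
  nOut <- prod(dims[1:3]) - sum(mask)
  if (nOut > 0) {
    mid <- floor(T / 2) + 1L
    outVals <- flat[!as.vector(mask), mid]
    sOut <- sd(outVals)
    snr <- if (sOut > 0) baseline / sOut else Inf
  } else {
    warning("no out-of-mask voxels; SNR uses a high-frequency temporal proxy")
    g <- rowMeans(inMask)
    hf <- sd(diff(g)) / sqrt(2)
    snr <- if (hf > 0) baseline / hf else Inf
  }
  g <- rowMeans(inMask)
  scanLen <- T * trSeconds
  jMax <- floor(scanLen / 64)
  tIdx <- seq_len(T) - 0.5
  driftPct <- 0
  driftBasis <- NULL
  if (jMax >= 1) {
    driftBasis <- vapply(seq_len(jMax), function(j)
      cos(pi * j * tIdx / T), numeric(T))
    if (baseline != 0) {
      proj <- driftBasis %*% qr.coef(qr(driftBasis), g - mean(g))
      driftPct <- sd(as.vector(proj)) / baseline * 100
    }
  }
  ## AR of the average after removing both the quadratic trend and the
  ## low-frequency drift model, so slow drift does not masquerade as
  ## autocorrelation
  t1 <- seq_len(T)
  X <- cbind(1, t1, t1^2, driftBasis)
  gd <- as.vector(g - X %*% qr.coef(qr(X), g))
  ar <- if (sd(gd) > 0)
    sum(gd[-1] * gd[-T]) / sum(gd^2) else 0
  new("NoiseProfile", sfnr = sfnr, snr = snr,
      arRho = max(-0.999, min(0.999, ar)),
      driftSdPct = driftPct, physioFreqsHz = numeric(0),
      spatialFwhmMm = 0, baseline = baseline)
}

#' Insert multivariate task signal into a volume
#'
#' For each ROI voxel `v` and TR `t`, adds
#' `scale/100 * baseline_v * sum_cond pattern_cond[v] * timecourse_cond[t]`,
#' where `baseline_v` is the voxel's temporal mean; non-ROI voxels are
#' untouched. This expresses the signal in percent signal change.
#'
#' @param noiseVolume 4-D array (e.g. from [generateNoise()]).
#' @param roi logical 3-D array of signal voxels; must lie within the
#'   geometry's mask.
#' @param geometry a [VolumeGeometry-class].
#' @param conditionPatterns named list: condition -> numeric vector over
#'   ROI voxels (x-fastest order).
#' @param convolvedTimecourses named list: condition -> length-T vector.
#' @param scalePctSignalChange signal amplitude in percent of baseline.
#' @return 4-D array of the same shape with signal added.
#' @export
applySignal <- function(noiseVolume, roi, geometry, conditionPatterns,
                        convolvedTimecourses, scalePctSignalChange = 1) {
  dims <- dim(noiseVolume)
  T <- dims[4]
  roi <- array(as.logical(roi), dim = dims[1:3])
  if (any(roi & !geometry@mask))
    stop("ROI extends outside the mask")
  conds <- names(conditionPatterns)
  if (!setequal(conds, names(convolvedTimecourses)))
    stop("patterns and timecourses must cover the same conditions")
  flat <- matrix(as.vector(noiseVolume), ncol = T)
  roiIdx <- which(as.vector(roi))
  baselineV <- rowMeans(flat[roiIdx, , drop = FALSE])
  add <- matrix(0, length(roiIdx), T)
  for (cc in conds) {
    pat <- conditionPatterns[[cc]]
    tc <- convolvedTimecourses[[cc]]
    if (length(pat) != length(roiIdx))
      stop(sprintf("pattern for '%s' has %d values but ROI has %d voxels",
                   cc, length(pat), length(roiIdx)))
    if (length(tc) != T)
      stop(sprintf("timecourse for '%s' has length %d but T = %d",
                   cc, length(tc), T))
    add <- add + outer(pat, tc)
  }
  flat[roiIdx, ] <- flat[roiIdx, ] +
    scalePctSignalChange / 100 * baselineV * add
  array(flat, dim = dims)
}
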
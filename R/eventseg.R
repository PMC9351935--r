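## Left-to-right HMM event segmentation.
##
## Model: at every TR a region either stays in its current event or
## advances to the next one; it starts in event 1 and ends in event K;
## each event k has a spatial pattern m_k, and the observed pattern at a
## TR within the event is m_k plus isotropic Gaussian noise with shared
## variance sigma2. Inference is exact constrained forward-backward in
## log space; fitting alternates posterior estimation with
## posterior-weighted pattern updates.

.logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

## z-score each TR's pattern across units (population sd)
.zscoreRows <- function(m) {
  V <- ncol(m)
  ctr <- m - rowMeans(m)
  s <- sqrt(rowSums(ctr^2) / V)
  s[s <= 0] <- 1
  ctr / s
}

## emission log-densities: T x K matrix of log N(x_t; m_k, sigma2 I)
.emissionLoglik <- function(data, patterns, sigma2) {
  V <- ncol(data)
  d2 <- outer(rowSums(data^2), rowSums(patterns^2), "+") -
    2 * tcrossprod(data, patterns)
  -0.5 * V * log(2 * pi * sigma2) - d2 / (2 * sigma2)
}

## constrained forward-backward for the left-to-right chain.
## Returns T x K posterior (start in 1, end in K) and the log-likelihood.
.forwardBackward <- function(ll, advanceProb) {
  T <- nrow(ll); K <- ncol(ll)
  if (K == 1L)
    return(list(gamma = matrix(1, T, 1), loglik = sum(ll)))
  lStay <- log(1 - advanceProb)
  lAdv <- log(advanceProb)
  la <- matrix(-Inf, T, K)
  la[1, 1] <- ll[1, 1]
  for (t in 2:T) {
    stay <- la[t - 1, ] + c(rep(lStay, K - 1), 0)   # event K absorbs
    adv <- c(-Inf, la[t - 1, -K] + lAdv)
    la[t, ] <- ll[t, ] + .logsumexp2(stay, adv)
  }
  lb <- matrix(-Inf, T, K)
  lb[T, K] <- 0
  for (t in (T - 1):1) {
    stayNext <- c(rep(lStay, K - 1), 0) + ll[t + 1, ] + lb[t + 1, ]
    advNext <- c(lAdv + ll[t + 1, -1] + lb[t + 1, -1], -Inf)
    lb[t, ] <- .logsumexp2(stayNext, advNext)
  }
  loglik <- la[T, K]
  lg <- la + lb - loglik
  gamma <- exp(lg)
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, loglik = loglik)
}

## block-average initial patterns, with the block grid phase-shifted by
## `shift` TRs (wrapping); shift 0 is the plain K-equal-blocks start
.blockInitPatterns <- function(data, K, shift = 0L) {
  T <- nrow(data); V <- ncol(data)
  idx <- 1L + floor(((seq_len(T) - 1L + shift) %% T) / (T / K))
  idx <- pmin(K, pmax(1L, idx))
  .zscoreRows(t(vapply(seq_len(K), function(k) {
    ix <- which(idx == k)
    if (!length(ix)) ix <- max(1L, min(T, round(T * (k - 0.5) / K)))
    colMeans(data[ix, , drop = FALSE])
  }, numeric(V))))
}

## one EM run on z-scored data. While `annealVar0 > 0` the E-step uses an
## inflated effective variance max(sigma2, annealVar0 * annealDecay^(it-1))
## (deterministic annealing: posteriors stay soft until patterns settle);
## the returned trace is evaluated at the estimated sigma2.
.eventsegEM <- function(data, K, patterns, advanceProb, nIter, tol,
                        annealVar0 = 0, annealDecay = 0.9) {
  T <- nrow(data); V <- ncol(data)
  sigma2 <- 1
  trace <- numeric(0)
  g <- NULL
  for (it in seq_len(nIter)) {
    veff <- max(sigma2, annealVar0 * annealDecay^(it - 1))
    fb <- .forwardBackward(.emissionLoglik(data, patterns, veff),
                           advanceProb)
    g <- fb$gamma
    trace <- c(trace, fb$loglik)
    if (it > 1 && abs(trace[it] - trace[it - 1]) < tol &&
        veff <= sigma2 * (1 + 1e-9)) break
    if (it == nIter) break
    patterns <- .zscoreRows(crossprod(g, data) / colSums(g))
    d2 <- outer(rowSums(data^2), rowSums(patterns^2), "+") -
      2 * tcrossprod(data, patterns)
    sigma2 <- sum(g * d2) / (T * V)
  }
  final <- .forwardBackward(.emissionLoglik(data, patterns, sigma2),
                            advanceProb)
  list(patterns = patterns, sigma2 = sigma2, gamma = final$gamma,
       loglik = final$loglik, trace = trace)
}

#' Fit a left-to-right HMM event segmentation
#'
#' Alternates between (E) a constrained forward-backward pass over the
#' left-to-right event chain -- per-TR stay probability `1 - K/T`,
#' advance probability `K/T`, conditioned on starting in event 1 and
#' ending in event K -- and (M) posterior-weighted re-estimation of the
#' event patterns (re-z-scored across units) and of the shared emission
#' variance. Data are z-scored per TR across units before fitting.
#'
#' Because the alternation can lock into a poor segmentation when the
#' initial block grid straddles true events, the fit is deterministic
#' but multi-start: `nStarts` phase-shifted block initializations are
#' explored under a slowly decaying inflated emission variance
#' (deterministic annealing), and the solution with the highest final
#' log-likelihood is then refined by plain alternation, whose
#' (non-decreasing) log-likelihood trace is reported.
#'
#' @param ts a [SubjectTimeSeries-class] or T x V matrix.
#' @param K number of events, `1 <= K <= T`.
#' @param nIter maximum alternating iterations per phase.
#' @param tol log-likelihood convergence tolerance.
#' @param nStarts number of phase-shifted initializations.
#' @param annealVar0 initial inflated variance of the annealing phase.
#' @param annealDecay per-iteration decay of the inflated variance.
#' @return an [EventSegModel-class].
#' @export
eventSegFit <- function(ts, K, nIter = 150, tol = 1e-7, nStarts = 5,
                        annealVar0 = 4, annealDecay = 0.9) {
  data <- if (is(ts, "SubjectTimeSeries")) ts@data else as.matrix(ts)
  T <- nrow(data); V <- ncol(data)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K > T) stop("K must not exceed the number of timepoints")
  data <- .zscoreRows(data)
  advanceProb <- if (K == 1L) 0 else K / T
  if (K == 1L) {
    pat <- .zscoreRows(matrix(colMeans(data), 1))
    sigma2 <- mean(sweep(data, 2L, pat[1, ])^2)
    return(new("EventSegModel", K = K, eventPatterns = pat,
               segments = matrix(1, T, 1), sigma2 = sigma2,
               loglikTrace = sum(.emissionLoglik(data, pat, sigma2)),
               advanceProb = 0))
  }
  shifts <- round(T / K * c(0, 1 / 2, -1 / 2, 1 / 4, -1 / 4))
  shifts <- unique(shifts)[seq_len(min(nStarts, 5L))]
  runs <- lapply(shifts, function(sh)
    .eventsegEM(data, K, .blockInitPatterns(data, K, sh), advanceProb,
                nIter, tol, annealVar0, annealDecay))
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
  ## refinement: plain alternation from the winning start; its trace is
  ## the reported (ascending) one
  ref <- .eventsegEM(data, K, best$patterns, advanceProb, nIter, tol,
                     annealVar0 = 0)
  new("EventSegModel", K = K, eventPatterns = ref$patterns,
      segments = ref$gamma, sigma2 = ref$sigma2,
      loglikTrace = ref$trace, advanceProb = advanceProb)
}

#' Infer event posteriors for new data with fixed patterns
#'
#' Runs a single constrained forward-backward pass with prespecified
#' event patterns (e.g. estimated from an independent dataset), without
#' re-estimating anything.
#'
#' @param patterns K x V matrix of event patterns.
#' @param ts a [SubjectTimeSeries-class] or T x V matrix.
#' @param advanceProb per-TR advance probability; default `K/T`.
#' @param sigma2 emission variance used for the pass.
#' @return list with `segments` (T x K posterior) and `loglik`.
#' @export
eventSegApply <- function(patterns, ts, advanceProb = NULL, sigma2 = 1) {
  data <- if (is(ts, "SubjectTimeSeries")) ts@data else as.matrix(ts)
  patterns <- as.matrix(patterns)
  if (ncol(patterns) != ncol(data))
    stop(sprintf("patterns have %d units but data has %d",
                 ncol(patterns), ncol(data)))
  K <- nrow(patterns); T <- nrow(data)
  data <- .zscoreRows(data)
  if (is.null(advanceProb)) advanceProb <- if (K == 1L) 0 else K / T
  fb <- .forwardBackward(.emissionLoglik(data, patterns, sigma2),
                         advanceProb)
  list(segments = fb$gamma, loglik = fb$loglik)
}

#' Fit shared event patterns across several datasets
#'
#' For datasets with aligned units but different durations that realize
#' the same event sequence (e.g. perception and recall of one
#' narrative), runs the E-step per dataset with its own duration-scaled
#' advance probability `K/T_d` and pools the posterior-weighted pattern
#' estimates across datasets in the M-step.
#'
#' @param datasets list of [SubjectTimeSeries-class] or matrices with
#'   equal unit counts.
#' @param K number of events.
#' @param nIter maximum iterations.
#' @param tol total log-likelihood convergence tolerance.
#' @return list with `patterns` (K x V), `segments` (list of T_d x K
#'   posteriors), `sigma2`, and `loglikTrace` (summed over datasets).
#' @export
eventSegFitShared <- function(datasets, K, nIter = 100, tol = 1e-6) {
  mats <- lapply(datasets, function(d)
    if (is(d, "SubjectTimeSeries")) d@data else as.matrix(d))
  if (length(mats) < 2L) stop("need at least 2 datasets")
  Vs <- vapply(mats, ncol, integer(1))
  if (length(unique(Vs)) != 1L)
    stop("all datasets must share the same number of units")
  V <- Vs[1]
  K <- as.integer(K)
  mats <- lapply(mats, .zscoreRows)
  Ts <- vapply(mats, nrow, integer(1))
  if (K > min(Ts)) stop("K must not exceed the shortest dataset")
  advance <- if (K == 1L) rep(0, length(mats)) else K / Ts
  ## initialize from the mean of per-dataset block averages so both
  ## dwell-time structures contribute
  patterns <- .zscoreRows(Reduce(`+`, lapply(mats, .blockInitPatterns,
                                             K = K)) / length(mats))
  sigma2 <- 1
  trace <- numeric(0)
  gammas <- NULL
  annealVar0 <- 4; annealDecay <- 0.9
  for (phase in c("anneal", "refine")) {
    v0 <- if (phase == "anneal") annealVar0 else 0
    trace <- numeric(0)
    for (it in seq_len(nIter)) {
      veff <- max(sigma2, v0 * annealDecay^(it - 1))
      fbs <- lapply(seq_along(mats), function(d)
        .forwardBackward(.emissionLoglik(mats[[d]], patterns, veff),
                         advance[d]))
      gammas <- lapply(fbs, `[[`, "gamma")
      trace <- c(trace, sum(vapply(fbs, `[[`, numeric(1), "loglik")))
      if (it > 1 && abs(trace[it] - trace[it - 1]) < tol &&
          veff <= sigma2 * (1 + 1e-9)) break
      if (it == nIter) break
      num <- Reduce(`+`, lapply(seq_along(mats), function(d)
        crossprod(gammas[[d]], mats[[d]])))
      den <- Reduce(`+`, lapply(gammas, colSums))
      patterns <- .zscoreRows(num / den)
      sigma2 <- sum(vapply(seq_along(mats), function(d) {
        d2 <- outer(rowSums(mats[[d]]^2), rowSums(patterns^2), "+") -
          2 * tcrossprod(mats[[d]], patterns)
        sum(gammas[[d]] * d2)
      }, numeric(1))) / (sum(Ts) * V)
    }
  }
  list(patterns = patterns, segments = gammas, sigma2 = sigma2,
       loglikTrace = trace)
}

#' Extract event boundaries from a fitted model
#'
#' A boundary sits at TR `t` (0-based) when the maximum-a-posteriori
#' event index at `t` exceeds that at `t - 1`; posterior ties resolve to
#' the lower event index.
#'
#' @param model an [EventSegModel-class], or a T x K posterior matrix.
#' @return a [BoundarySet-class].
#' @export
eventBoundaries <- function(model) {
  seg <- if (is(model, "EventSegModel")) model@segments else
    as.matrix(model)
  K <- ncol(seg); T <- nrow(seg)
  map <- apply(seg, 1L, which.max)   # which.max ties -> lower index
  b <- which(diff(map) > 0)          # 0-based boundary = 1-based diff pos
  new("BoundarySet", boundaries = as.integer(b), K = as.integer(K),
      nTimepoints = as.integer(T))
}

#' Permutation test of boundary agreement with annotations
#'
#' The statistic counts annotated boundaries that have a model boundary
#' within `windowTr` TRs. The null preserves the number of model
#' boundaries, placing them uniformly at random without replacement
#' among the valid TRs `1..T-1` (0-based); the p-value follows the
#' add-one rule.
#'
#' @param modelBounds a [BoundarySet-class].
#' @param annotations sorted vector of annotated boundary TRs (0-based,
#'   within `[1, T-1]`).
#' @param windowTr matching half-width in TRs (>= 0).
#' @param nNull number of null placements B.
#' @param seed RNG seed.
#' @return a [NullTestResult-class] with a scalar statistic.
#' @export
boundaryMatchTest <- function(modelBounds, annotations, windowTr = 3,
                              nNull = 1000, seed = 0) {
  if (windowTr < 0) stop("windowTr must be >= 0")
  T <- modelBounds@nTimepoints
  annotations <- as.integer(annotations)
  if (any(annotations < 1L | annotations > T - 1L))
    stop("annotations must lie within [1, T-1]")
  b <- modelBounds@boundaries
  countMatches <- function(bounds) {
    if (!length(bounds)) return(0L)
    sum(vapply(annotations, function(a)
      any(abs(bounds - a) <= windowTr), logical(1)))
  }
  observed <- countMatches(b)
  set.seed(as.integer(seed))
  nullV <- vapply(seq_len(nNull), function(i)
    countMatches(sample(seq_len(T - 1L), length(b))), integer(1))
  p <- (1 + sum(nullV >= observed)) / (1 + nNull)
  new("NullTestResult", observed = as.numeric(observed),
      nullSamples = matrix(as.numeric(nullV), ncol = 1),
      pValues = p, qValues = p, method = "boundary_permutation",
      seed = as.integer(seed), nNull = as.integer(nNull),
      tail = "greater")
}
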
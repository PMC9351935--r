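## Fixture generators shared across the suite. Everything is generated
## in code under fixed seeds; nothing is stored on disk.

## shared-signal dataset: x_i = s + noiseSd * n_i per unit
makeSharedSignalDataset <- function(N = 5, T = 200, V = 10, noiseSd = 1,
                                    seed = 1) {
  set.seed(seed)
  s <- matrix(rnorm(T * V), T, V)
  MultiSubjectDataset(lapply(seq_len(N), function(i)
    s + noiseSd * matrix(rnorm(T * V), T, V)))
}

## exact SRM data: X_i = t(W_i S) with centered S and orthonormal W_i,
## plus optional noise
makeSRMData <- function(N = 4, T = 100, V = 30, k = 5, noiseSd = 0,
                        seed = 3) {
  set.seed(seed)
  S <- matrix(rnorm(k * T), k, T)
  S <- S - rowMeans(S)
  Ws <- lapply(seq_len(N), function(i)
    qr.Q(qr(matrix(rnorm(V * k), V, k))))
  mats <- lapply(seq_len(N), function(i)
    t(Ws[[i]] %*% S) + noiseSd * matrix(rnorm(T * V), T, V))
  list(ds = MultiSubjectDataset(mats, "time_aligned_only"),
       S = S, Ws = Ws, mats = mats)
}

## planted left-to-right event sequence with iid N(0,1) patterns
makePlantedEvents <- function(K = 10, V = 30, minLen = 8, Ttotal = 200,
                              noiseSd = 0.1, seed = 1) {
  set.seed(seed)
  lens <- as.vector(stats::rmultinom(1, Ttotal - K * minLen,
                                     rep(1, K))) + minLen
  T <- sum(lens)
  pats <- matrix(rnorm(K * V), K, V)
  x <- do.call(rbind, lapply(seq_len(K), function(k)
    matrix(rep(pats[k, ], lens[k]), ncol = V, byrow = TRUE))) +
    matrix(rnorm(T * V, 0, noiseSd), T, V)
  list(x = x, lens = lens, patterns = pats,
       boundaries = cumsum(lens)[seq_len(K - 1)])
}

## exact posterior of the left-to-right chain by explicit enumeration of
## all monotone, no-skip paths from event 1 at t=1 to event K at t=T
bruteForceEventPosterior <- function(ll, advanceProb) {
  T <- nrow(ll); K <- ncol(ll)
  paths <- list()
  gen <- function(path) {
    t <- length(path)
    if (t == T) {
      if (path[T] == K) paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    k <- path[t]
    gen(c(path, k))
    if (k < K) gen(c(path, k + 1L))
  }
  gen(1L)
  post <- matrix(0, T, K)
  tot <- 0
  for (p in paths) {
    lw <- sum(ll[cbind(seq_len(T), p)])
    if (T > 1) for (t in 2:T) {
      lw <- lw + if (p[t] == p[t - 1]) {
        if (p[t - 1] < K) log(1 - advanceProb) else 0
      } else log(advanceProb)
    }
    w <- exp(lw)
    tot <- tot + w
    post[cbind(seq_len(T), p)] <- post[cbind(seq_len(T), p)] + w
  }
  post / tot
}

## z-scored rows and emission log-densities matching the fitted model's
## internal conventions (reimplemented here so the oracle path stays
## independent of the package internals)
oracleZscoreRows <- function(m) {
  V <- ncol(m)
  ctr <- m - rowMeans(m)
  s <- sqrt(rowSums(ctr^2) / V)
  s[s <= 0] <- 1
  ctr / s
}

oracleEmission <- function(data, patterns, sigma2) {
  V <- ncol(data)
  t(apply(data, 1L, function(x)
    -0.5 * V * log(2 * pi * sigma2) -
      colSums((t(patterns) - x)^2) / (2 * sigma2)))
}

## largest principal angle (radians) between the row spaces of A and B
principalAngle <- function(A, B) {
  qa <- qr.Q(qr(t(A)))
  qb <- qr.Q(qr(t(B)))
  sv <- svd(crossprod(qa, qb))$d
  acos(min(pmin(pmax(sv, -1), 1)))
}

## small all-true or hollow mask geometries
makeBoxGeometry <- function(dims = c(4, 4, 4), full = TRUE) {
  mask <- array(full, dim = dims)
  if (!full) {
    mask[] <- FALSE
    inner <- lapply(dims, function(d) 2:(d - 1))
    mask[inner[[1]], inner[[2]], inner[[3]]] <- TRUE
  }
  VolumeGeometry(mask, voxelSizeMm = c(3, 3, 3))
}

## brute-force box/ball filter over a 3-D scalar field on a mask: mean
## of per-voxel statistics in the truncated neighborhood (independent
## triple loop, no shared code with searchlight())
bruteForceNeighborhoodMean <- function(values3d, mask, radius,
                                       shape = "cube") {
  d <- dim(values3d)
  out <- array(NaN, dim = d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (!mask[x, y, z]) next
    acc <- c()
    for (dx in -radius:radius) for (dy in -radius:radius)
      for (dz in -radius:radius) {
        if (shape == "ball" && dx^2 + dy^2 + dz^2 > radius^2) next
        xx <- x + dx; yy <- y + dy; zz <- z + dz
        if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] ||
            zz < 1 || zz > d[3]) next
        if (!mask[xx, yy, zz]) next
        acc <- c(acc, values3d[xx, yy, zz])
      }
    out[x, y, z] <- mean(acc)
  }
  out
}
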
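test_that("constrained forward-backward matches brute-force path enumeration", {
  set.seed(31)
  for (cfg in list(c(T = 6, K = 2), c(T = 10, K = 3), c(T = 12, K = 4))) {
    T <- cfg["T"]; K <- cfg["K"]; V <- 5
    x <- matrix(rnorm(T * V), T, V)
    pat <- matrix(rnorm(K * V), K, V)
    sigma2 <- runif(1, 0.5, 2)
    r <- eventSegApply(pat, x, sigma2 = sigma2)
    zs <- oracleZscoreRows(x)
    ll <- oracleEmission(zs, pat, sigma2)
    oracle <- bruteForceEventPosterior(ll, K / T)
    expect_lt(max(abs(r$segments - oracle)), 1e-10)
    expect_lt(max(abs(rowSums(r$segments) - 1)), 1e-9)
  }
})

test_that("K = 1 degenerates to a single always-on event", {
  set.seed(32)
  m <- eventSegFit(matrix(rnorm(200), 20, 10), K = 1)
  expect_equal(eventSegments(m), matrix(1, 20, 1))
  expect_length(boundaryTrs(eventBoundaries(m)), 0)
  expect_error(eventSegFit(matrix(rnorm(200), 20, 10), K = 0), ">= 1")
  expect_error(eventSegFit(matrix(rnorm(200), 20, 10), K = 21),
               "exceed")
})

test_that("planted 10-event boundaries are recovered within one TR", {
  sim <- makePlantedEvents(K = 10, V = 30, Ttotal = 200, noiseSd = 0.1,
                           seed = 1)
  m <- eventSegFit(sim$x, K = 10)
  b <- boundaryTrs(eventBoundaries(m))
  expect_length(b, 9)
  expect_lte(max(abs(b - sim$boundaries)), 1)
  ## refinement trace ascends
  expect_true(all(diff(loglikTrace(m)) > -1e-6))
  ## expected event index non-decreasing (left-to-right structure)
  eidx <- as.vector(eventSegments(m) %*% seq_len(10))
  expect_true(all(diff(eidx) > -1e-9))
  ## endpoint constraints
  expect_equal(which.max(eventSegments(m)[1, ]), 1L)
  expect_equal(which.max(eventSegments(m)[nrow(sim$x), ]), 10L)
})

test_that("boundary recovery holds across several planted configurations", {
  for (seed in 2:6) {
    sim <- makePlantedEvents(K = 8, V = 25, Ttotal = 160,
                             noiseSd = 0.1, seed = seed)
    m <- eventSegFit(sim$x, K = 8)
    b <- boundaryTrs(eventBoundaries(m))
    expect_length(b, 7)
    expect_lte(max(abs(b - sim$boundaries)), 1)
  }
})

test_that("fixed-pattern inference reproduces noise-free blocks and penalizes reversal", {
  set.seed(33)
  K <- 3; V <- 12
  pats <- matrix(rnorm(K * V), K, V)
  blocks <- c(8, 6, 10)
  x <- do.call(rbind, lapply(1:K, function(k)
    matrix(rep(pats[k, ], blocks[k]), ncol = V, byrow = TRUE)))
  r <- eventSegApply(pats, x)
  map <- apply(r$segments, 1L, which.max)
  expect_equal(map, rep(1:3, blocks))
  expect_lt(max(abs(rowSums(r$segments) - 1)), 1e-9)
  ## reversed event order: strictly lower likelihood
  xrev <- do.call(rbind, lapply(3:1, function(k)
    matrix(rep(pats[k, ], blocks[k]), ncol = V, byrow = TRUE)))
  expect_lt(eventSegApply(pats, xrev)$loglik, r$loglik)
  expect_error(eventSegApply(pats, x[, 1:5]), "units")
})

test_that("shared-event fitting pools datasets with different dwell times", {
  set.seed(34)
  K <- 4; V <- 20
  pats <- matrix(rnorm(K * V), K, V)
  mk <- function(lens) do.call(rbind, lapply(seq_len(K), function(k)
    matrix(rep(pats[k, ], lens[k]), ncol = V, byrow = TRUE)))
  d1 <- mk(c(12, 10, 14, 12))
  d2 <- mk(c(6, 5, 7, 6))     # recall-like: dwell compressed by half
  r <- eventSegFitShared(list(d1, d2), K = 4)
  cc <- diag(cor(t(r$patterns), t(oracleZscoreRows(pats))))
  expect_true(all(cc > 0.999))
  map1 <- apply(r$segments[[1]], 1L, which.max)
  map2 <- apply(r$segments[[2]], 1L, which.max)
  expect_equal(map1, rep(1:4, c(12, 10, 14, 12)))
  expect_equal(map2, rep(1:4, c(6, 5, 7, 6)))
  ## boundary fractions agree across datasets
  b1 <- which(diff(map1) > 0) / nrow(d1)
  b2 <- which(diff(map2) > 0) / nrow(d2)
  expect_lt(max(abs(b1 - b2)), 0.05)
  expect_error(eventSegFitShared(list(d1, d2[, 1:10]), 4), "units")
  ## duplicating a dataset does not change the solution
  rd <- eventSegFitShared(list(d1, d1), K = 4)
  r1 <- eventSegFitShared(list(d1, d1, d1), K = 4)
  expect_lt(max(abs(rd$patterns - r1$patterns)), 1e-8)
})

test_that("boundary extraction follows MAP increments with deterministic ties", {
  seg <- matrix(0, 30, 3)
  seg[1:10, 1] <- 1; seg[11:20, 2] <- 1; seg[21:30, 3] <- 1
  b <- eventBoundaries(seg)
  expect_equal(boundaryTrs(b), c(10L, 20L))
  ## tie at a TR resolves to the lower event index (no boundary)
  seg2 <- seg
  seg2[11, ] <- c(0.5, 0.5, 0)
  expect_equal(boundaryTrs(eventBoundaries(seg2)), c(11L, 20L))
})

test_that("duplicating every unit leaves the MAP segmentation unchanged", {
  sim <- makePlantedEvents(K = 5, V = 15, Ttotal = 100, noiseSd = 0.3,
                           seed = 7)
  m1 <- eventSegFit(sim$x, K = 5)
  m2 <- eventSegFit(cbind(sim$x, sim$x), K = 5)
  expect_equal(apply(eventSegments(m1), 1L, which.max),
               apply(eventSegments(m2), 1L, which.max))
})

test_that("cross-validated log-likelihood selects the planted number of events", {
  ## fit patterns on one run, evaluate on an independent run realizing
  ## the same event sequence; argmax over K should concentrate on truth
  Ktrue <- 4; V <- 20
  picks <- vapply(1:5, function(seed) {
    set.seed(100 + seed)
    pats <- matrix(rnorm(Ktrue * V), Ktrue, V)
    mk <- function() {
      lens <- as.vector(stats::rmultinom(1, 80 - Ktrue * 10,
                                         rep(1, Ktrue))) + 10
      do.call(rbind, lapply(seq_len(Ktrue), function(k)
        matrix(rep(pats[k, ], lens[k]), ncol = V, byrow = TRUE))) +
        matrix(rnorm(sum(lens) * V, 0, 0.5), ncol = V)
    }
    train <- mk(); test <- mk()
    Ks <- 2:6
    cvll <- vapply(Ks, function(K) {
      m <- eventSegFit(train, K = K)
      eventSegApply(eventPatterns(m), test, sigma2 = m@sigma2)$loglik
    }, numeric(1))
    Ks[which.max(cvll)]
  }, numeric(1))
  modeK <- as.numeric(names(sort(table(picks), decreasing = TRUE))[1])
  expect_equal(modeK, Ktrue)
})

test_that("boundary-annotation matching counts hits and obeys the add-one rule", {
  b <- new("BoundarySet", boundaries = c(10L, 20L, 30L), K = 4L,
           nTimepoints = 50L)
  ## identical annotations, window 0 -> all matched, p = 1/(B+1)
  r <- boundaryMatchTest(b, c(10, 20, 30), windowTr = 0, nNull = 999,
                         seed = 1)
  expect_equal(r@observed, 3)
  expect_equal(pValues(r), 1 / 1000)
  expect_error(boundaryMatchTest(b, c(10, 60), windowTr = 0), "T-1")
  expect_error(boundaryMatchTest(b, c(10), windowTr = -1), ">= 0")
  ## unrelated annotations on a short scan: non-significant typically
  r2 <- boundaryMatchTest(b, c(5, 25, 45), windowTr = 1, nNull = 199,
                          seed = 2)
  expect_gte(pValues(r2), 1 / 200)
})

test_that("boundary-annotation test has calibrated type-I error", {
  ## annotations independent of the model boundaries
  set.seed(35)
  T <- 300
  rejections <- vapply(1:200, function(i) {
    bounds <- sort(sample(seq_len(T - 1L), 9))
    annot <- sort(sample(seq_len(T - 1L), 9))
    b <- new("BoundarySet", boundaries = as.integer(bounds), K = 10L,
             nTimepoints = as.integer(T))
    pValues(boundaryMatchTest(b, annot, windowTr = 3, nNull = 99,
                              seed = i)) <= 0.05
  }, logical(1))
  rate <- mean(rejections)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})
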
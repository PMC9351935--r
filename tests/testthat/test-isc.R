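test_that("identical signals give ISC 1 and zero-variance units give NaN", {
  T <- 50
  s <- cbind(sin(seq_len(T) / 3), cos(seq_len(T) / 5))
  ds <- MultiSubjectDataset(lapply(1:3, function(i) s))
  for (m in c("loo", "pairwise"))
    expect_equal(max(abs(iscValues(isc(ds, m)) - 1)), 0,
                 tolerance = 1e-12)
  ## one subject constant in unit 2
  s2 <- s; s2[, 2] <- 7
  ds2 <- MultiSubjectDataset(list(s, s, s2))
  expect_warning(r <- isc(ds2, "pairwise"), "zero-variance")
  ## pairs (1,3) and (2,3) involve the constant unit
  expect_true(all(is.nan(iscValues(r)[2:3, 2])))
  expect_false(anyNA(iscValues(r)[, 1]))
})

test_that("shared-signal ISC matches the closed forms for both methods", {
  ## x_i = s + n_i, everything iid standard normal:
  ## pairwise r -> 1/(1 + sigma^2); loo r -> 1/sqrt((1+s2)(1+s2/(N-1)))
  ds <- makeSharedSignalDataset(N = 5, T = 2000, V = 20, noiseSd = 1,
                                seed = 42)
  pw <- mean(iscValues(isc(ds, "pairwise")))
  loo <- mean(iscValues(isc(ds, "loo")))
  expect_equal(pw, 0.5, tolerance = 0.025)
  expect_equal(loo, 1 / sqrt(2 * 1.25), tolerance = 0.025)
})

test_that("pairwise and leave-one-out ISC rank units consistently", {
  set.seed(8)
  N <- 10; T <- 1000; V <- 12
  ## per-unit signal strength gradient
  gains <- seq(0.2, 2, length.out = V)
  s <- matrix(rnorm(T * V), T, V)
  ds <- MultiSubjectDataset(lapply(seq_len(N), function(i)
    sweep(s, 2L, gains, "*") + matrix(rnorm(T * V), T, V)))
  rp <- colMeans(iscValues(isc(ds, "pairwise")))
  rl <- colMeans(iscValues(isc(ds, "loo")))
  expect_gt(cor(rp, rl, method = "spearman"), 0.9)
  expect_true(all(sign(rp) == sign(rl)))
})

test_that("ISC is invariant to positive per-unit affine rescaling", {
  ds <- makeSharedSignalDataset(N = 4, T = 100, V = 6, seed = 9)
  mats <- subjectMatrices(ds)
  mats2 <- mats
  mats2[[2]] <- sweep(sweep(mats2[[2]], 2L, runif(6, 0.5, 3), "*"),
                      2L, rnorm(6), "+")
  r1 <- iscValues(isc(ds))
  r2 <- iscValues(isc(MultiSubjectDataset(mats2)))
  expect_lt(max(abs(r1 - r2)), 1e-10)
})

test_that("Fisher-z summary of identical correlations returns them exactly", {
  r <- 0.37
  vals <- matrix(r, 4, 3)
  ds <- makeSharedSignalDataset(N = 4, T = 50, V = 3, seed = 1)
  ## check through the exported summary path on constructed values
  expect_equal(tanh(mean(atanh(rep(r, 5)))), r, tolerance = 1e-15)
  res <- isc(ds, summary = "mean_fisher_z")
  zexp <- tanh(colMeans(atanh(iscValues(res))))
  expect_equal(iscSummary(res), zexp, tolerance = 1e-12)
})

test_that("ISFC diagonal equals ISC and shared signal fills the matrix", {
  ## diag(symmetrized loo ISFC) == loo ISC on random datasets
  for (seed in 1:20) {
    ds <- makeSharedSignalDataset(N = 3 + seed %% 3, T = 40, V = 5,
                                  noiseSd = runif(1, 0.3, 2),
                                  seed = seed)
    f <- isfc(ds, "loo", symmetrize = TRUE)
    r <- iscValues(isc(ds, "loo"))
    diags <- t(vapply(isfcMatrices(f), diag, numeric(5)))
    expect_lt(max(abs(diags - r)), 1e-10)
    for (m in isfcMatrices(f))
      expect_lt(max(abs(m - t(m))), 1e-12)
  }
  ## same shared signal in both units -> all-ones ISFC
  T <- 60
  sig <- sin(seq_len(T) / 4)
  ds1 <- MultiSubjectDataset(lapply(1:3, function(i) cbind(sig, sig)))
  f1 <- isfc(ds1, "loo")
  expect_equal(max(abs(isfcMatrices(f1)[[1]] - 1)), 0,
               tolerance = 1e-10)
})

test_that("independent noise keeps off-diagonal ISFC near zero and a single unit reduces to ISC", {
  set.seed(10)
  T <- 800
  ds <- MultiSubjectDataset(lapply(1:4, function(i)
    matrix(rnorm(T * 4), T, 4)))
  f <- isfc(ds, "loo")
  offd <- unlist(lapply(isfcMatrices(f), function(m)
    m[upper.tri(m)]))
  expect_lt(abs(mean(offd)), 3 / sqrt(T))
  ## single unit: 1x1 ISFC equals ISC
  ds1 <- MultiSubjectDataset(lapply(subjectMatrices(ds), function(m)
    m[, 1, drop = FALSE]))
  f1 <- isfc(ds1, "loo")
  r1 <- iscValues(isc(ds1, "loo"))
  expect_equal(vapply(isfcMatrices(f1), as.numeric, numeric(1)),
               as.vector(r1), tolerance = 1e-12)
})

test_that("spatial ISC is 1 for identical z-scored subjects and detects planted repeats", {
  set.seed(11)
  T <- 60; V <- 25
  pat <- matrix(rnorm(T * V), T, V)
  pat <- t(scale(t(pat)))   # z-score patterns
  ds <- MultiSubjectDataset(lapply(1:3, function(i) pat))
  s <- spatialISC(ds)
  expect_equal(max(abs(s - 1)), 0, tolerance = 1e-9)

  ## planted repeat: same pattern at t = 10 and t = 50 (plus noise)
  set.seed(12)
  base <- matrix(rnorm(T * V), T, V)
  base[50, ] <- base[10, ]
  dsr <- MultiSubjectDataset(lapply(1:4, function(i)
    base + 0.4 * matrix(rnorm(T * V), T, V)))
  m <- spatialISC(dsr, pairAllTimepoints = TRUE)
  offd <- m[upper.tri(m)]
  expect_gt(mean(m[10, 50] > offd), 0.99)   # top percentile
})

test_that("sliding-window ISC reduces to full ISC and localizes shared signal", {
  ds <- makeSharedSignalDataset(N = 4, T = 100, V = 5, seed = 13)
  full <- iscSummary(isc(ds, summary = "mean_fisher_z"))
  sw <- slidingISC(ds, windowTr = 100, stepTr = 7)
  expect_equal(nrow(sw), 1L)
  expect_equal(as.vector(sw[1, ]), as.vector(full), tolerance = 1e-12)
  ## window count arithmetic
  sw2 <- slidingISC(ds, windowTr = 30, stepTr = 10)
  expect_equal(nrow(sw2), floor((100 - 30) / 10) + 1)
  expect_error(slidingISC(ds, windowTr = 101), "exceeds")
  ## shared signal only in the first half
  set.seed(14)
  T <- 100; V <- 6
  s <- matrix(rnorm(T * V), T, V)
  s[51:100, ] <- 0
  dsl <- MultiSubjectDataset(lapply(1:4, function(i)
    s + matrix(rnorm(T * V), T, V)))
  swl <- slidingISC(dsl, windowTr = 25, stepTr = 25)
  expect_gt(mean(swl[1:2, ]), mean(swl[3:4, ]) + 0.2)
})

test_that("phase scrambling preserves the amplitude spectrum exactly", {
  set.seed(15)
  for (T in c(64, 65)) {   # even and odd lengths
    m <- matrix(rnorm(T * 3), T, 3)
    surr <- phaseScramble(m)
    expect_lt(max(abs(Mod(mvfft(surr)) - Mod(mvfft(m)))), 1e-10)
    expect_lt(max(abs(Im(mvfft(surr)[1, ]))), 1e-10)
    expect_false(isTRUE(all.equal(surr, m)))
  }
})

test_that("null tests follow the add-one rule and reject invalid pairings", {
  ds <- makeSharedSignalDataset(N = 4, T = 60, V = 3, noiseSd = 0.2,
                                seed = 16)
  r <- isc(ds, "loo")
  nt <- iscTest(r, ds, "phase_randomization", nNull = 99, seed = 1)
  expect_true(all(pValues(nt) >= 1 / 100))
  ## strong shared signal: observed beats every null
  expect_equal(min(pValues(nt)), 1 / 100)
  expect_true(all(qValues(nt) >= pValues(nt) - 1e-12))
  ## bootstrap/sign tests need loo results
  rp <- isc(ds, "pairwise")
  expect_error(iscTest(rp, ds, "subject_bootstrap", nNull = 9, seed = 1),
               "leave-one-out")
  expect_error(iscTest(r, ds, "circular_shift", nNull = 9),
               "seed")
  ## determinism
  nt2 <- iscTest(r, ds, "phase_randomization", nNull = 99, seed = 1)
  expect_identical(pValues(nt), pValues(nt2))
})

test_that("circular shift, bootstrap and sign permutation produce sane nulls", {
  ds <- makeSharedSignalDataset(N = 5, T = 80, V = 3, noiseSd = 0.5,
                                seed = 17)
  r <- isc(ds, "loo")
  for (m in c("circular_shift", "subject_bootstrap")) {
    nt <- iscTest(r, ds, m, nNull = 49, seed = 2)
    expect_equal(nt@nNull, 49L)
    expect_true(all(pValues(nt) <= 1))
    ## strong signal beats every null
    expect_equal(min(pValues(nt)), 1 / 50)
  }
  ## sign permutation: the all-positive draw reproduces the observed
  ## statistic, so attainable p is bounded by the 2^-N sign granularity
  nts <- iscTest(r, ds, "sign_permutation", nNull = 49, seed = 2)
  expect_lt(min(pValues(nts)), 0.15)
})
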
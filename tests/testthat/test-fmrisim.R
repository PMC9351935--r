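test_that("stimulus boxcars have the right support, additivity and warnings", {
  d <- designTable(onset = 10, duration = 5, condition = "a")
  tc <- generateStimfunction(d, totalTimeS = 60, trSeconds = 1,
                             upsampleFactor = 10)
  expect_named(tc, "a")
  expect_equal(sum(tc$a@values != 0), 50)      # 5 s x 10 samples/s
  expect_equal(length(tc$a@values), 600)
  ## empty design -> all zeros
  tc0 <- generateStimfunction(designTable(numeric(0), numeric(0),
                                          character(0), numeric(0)),
                              60, 1, 10)
  expect_true(all(tc0$task@values == 0))
  ## overlapping events sum with a warning
  d2 <- designTable(c(10, 12), c(5, 5), "a")
  expect_warning(tc2 <- generateStimfunction(d2, 60, 1, 10),
                 "overlapping")
  expect_equal(max(tc2$a@values), 2)
  expect_error(generateStimfunction(designTable(70, 5, "a"), 60, 1, 10),
               "beyond scan end")
  expect_error(designTable(-1, 5), "non-negative")
  expect_error(designTable(1, 0), "positive")
})

test_that("double-gamma HRF peaks where the gamma mode formula says", {
  t <- seq(0, 30, by = 0.1)
  ## response component alone: mode at (a1 - 1) * b1 = 4.5 s
  g1 <- dgamma(t, shape = 6, scale = 0.9)
  expect_equal(t[which.max(g1)], 4.5)
  ## combined HRF: undershoot shifts the peak slightly earlier
  h <- doubleGammaHrf(t)
  expect_equal(max(h), 1)
  expect_lt(abs(t[which.max(h)] - 4.5), 0.15)
})

test_that("HRF convolution is linear and reduces to the HRF for an impulse", {
  stim <- new("StimTimecourse",
              values = c(1, rep(0, 599)), upsampleFactor = 10L,
              trSeconds = 1)
  out <- convolveHrf(stim)
  t <- seq(0, 30, by = 0.1)
  h <- doubleGammaHrf(t)
  hTr <- h[seq(1, length(h), by = 10)]
  expect_equal(out[seq_along(hTr)], hTr, tolerance = 1e-9)
  ## doubling the stimulus doubles the output exactly
  stim2 <- new("StimTimecourse", values = 2 * stim@values,
               upsampleFactor = 10L, trSeconds = 1)
  expect_equal(convolveHrf(stim2), 2 * out, tolerance = 1e-12)
})

test_that("generated noise reproduces the target profile when measured back", {
  mask <- array(FALSE, c(6, 6, 6)); mask[2:5, 2:5, 2:5] <- TRUE
  geom <- VolumeGeometry(mask)
  prof <- NoiseProfile()
  vol <- suppressWarnings(
    generateNoise(geom, T = 200, trSeconds = 1, profile = prof,
                  seed = 5))
  meas <- suppressWarnings(measureNoise(vol, geom, 1))
  expect_lt(abs(meas@sfnr / prof@sfnr - 1), 0.10)
  expect_lt(abs(meas@arRho - prof@arRho), 0.1)
  expect_lt(abs(meas@baseline / prof@baseline - 1), 0.05)
  ## seeding contract
  vol2 <- suppressWarnings(
    generateNoise(geom, T = 200, trSeconds = 1, profile = prof,
                  seed = 5))
  expect_identical(as.vector(vol), as.vector(vol2))
  vol3 <- suppressWarnings(
    generateNoise(geom, T = 200, trSeconds = 1, profile = prof,
                  seed = 6))
  expect_false(identical(as.vector(vol), as.vector(vol3)))
  expect_error(generateNoise(geom, T = 5, profile = prof), "T >= 10")
})

test_that("pure white-noise profile yields a flat in-mask power spectrum", {
  mask <- array(FALSE, c(5, 5, 5)); mask[2:4, 2:4, 2:4] <- TRUE
  geom <- VolumeGeometry(mask)
  prof <- NoiseProfile(arRho = 1e-9, driftSdPct = 0,
                       physioFreqsHz = numeric(0), spatialFwhmMm = 0)
  vol <- suppressWarnings(
    generateNoise(geom, T = 256, trSeconds = 1, profile = prof,
                  seed = 2))
  flat <- matrix(as.vector(vol), ncol = 256)[as.vector(mask), ]
  pows <- apply(flat, 1L, function(x) {
    x <- x - mean(x)
    Mod(fft(x))[2:128]^2
  })
  avg <- rowMeans(pows)
  expect_lt(max(avg), 3 * median(avg))
})

test_that("physiological frequencies appear as spectral peaks", {
  mask <- array(FALSE, c(6, 6, 6)); mask[2:5, 2:5, 2:5] <- TRUE
  geom <- VolumeGeometry(mask)
  prof <- NoiseProfile(physioFreqsHz = 0.2)
  vol <- suppressWarnings(
    generateNoise(geom, T = 500, trSeconds = 1, profile = prof,
                  seed = 3))
  flat <- matrix(as.vector(vol), ncol = 500)[as.vector(mask), ]
  pows <- apply(flat, 1L, function(x) {
    x <- x - mean(x); Mod(fft(x))[2:250]^2
  })
  avg <- rowMeans(pows)
  freqs <- (1:249) / 500
  band <- freqs > 0.05                 # above the drift/AR bulk
  expect_equal(freqs[band][which.max(avg[band])], 0.2, tolerance = 0.01)
})

test_that("noise measurement matches known constructions", {
  mask <- array(TRUE, c(4, 4, 4))
  geom <- VolumeGeometry(mask)
  T <- 500
  set.seed(6)
  ## constant 100 plus unit white noise -> SFNR ~ 100
  vol <- array(100 + rnorm(64 * T), dim = c(4, 4, 4, T))
  m <- suppressWarnings(measureNoise(vol, geom, 1))
  expect_lt(abs(m@sfnr / 100 - 1), 0.10)
  ## injected AR(1) with rho = 0.5 shared across voxels
  ar <- as.vector(stats::filter(rnorm(T), 0.5, method = "recursive"))
  vol2 <- array(rep(100 + ar, each = 64) +
                  0.01 * rnorm(64 * T), dim = c(4, 4, 4, T))
  m2 <- suppressWarnings(measureNoise(vol2, geom, 1))
  expect_gt(m2@arRho, 0.4)
  expect_lt(m2@arRho, 0.6)
  ## time-constant volume -> Inf SFNR with a warning
  vol3 <- array(7, dim = c(4, 4, 4, 20))
  w <- capture_warnings(m3 <- measureNoise(vol3, geom, 1))
  expect_match(w, "Inf", all = FALSE)
  expect_equal(m3@sfnr, Inf)
  expect_error(measureNoise(array(1, c(4, 4, 4)), geom, 1), "4-D")
})

test_that("signal insertion is additive, scaled in percent, and respects the mask", {
  mask <- array(FALSE, c(5, 5, 5)); mask[2:4, 2:4, 2:4] <- TRUE
  geom <- VolumeGeometry(mask)
  roi <- array(FALSE, c(5, 5, 5)); roi[2:3, 2:3, 2] <- TRUE
  T <- 60
  prof <- NoiseProfile(sfnr = 1e5, driftSdPct = 0,
                       physioFreqsHz = numeric(0), spatialFwhmMm = 0)
  vol <- suppressWarnings(
    generateNoise(geom, T = T, trSeconds = 1, profile = prof, seed = 4))
  tc <- rep(c(1, 0), each = 10, length.out = T)    # boxcar
  nRoi <- sum(roi)
  ## scale 0 -> identical output
  out0 <- applySignal(vol, roi, geom, list(a = rep(1, nRoi)),
                      list(a = tc), scalePctSignalChange = 0)
  expect_identical(out0, array(as.vector(vol), dim = dim(vol)))
  ## scale 1, all-ones pattern: events exceed rest by ~1% of baseline
  out1 <- applySignal(vol, roi, geom, list(a = rep(1, nRoi)),
                      list(a = tc), scalePctSignalChange = 1)
  flat <- matrix(as.vector(out1), ncol = T)
  roiRows <- flat[as.vector(roi), , drop = FALSE]
  lift <- mean(roiRows[, tc == 1]) - mean(roiRows[, tc == 0])
  expect_equal(lift / 100, 0.01, tolerance = 0.01)
  ## non-ROI voxels untouched
  outside <- !as.vector(roi)
  expect_identical(matrix(as.vector(out1), ncol = T)[outside, ],
                   matrix(as.vector(vol), ncol = T)[outside, ])
  ## linearity: the added component equals the closed-form construction
  delta <- matrix(as.vector(out1), ncol = T) -
    matrix(as.vector(vol), ncol = T)
  baseV <- rowMeans(matrix(as.vector(vol), ncol = T))[as.vector(roi)]
  expect_lt(max(abs(delta[as.vector(roi), ] -
                      0.01 * outer(baseV, tc))), 1e-9)
  ## roi outside the mask errors
  badRoi <- array(FALSE, c(5, 5, 5)); badRoi[1, 1, 1] <- TRUE
  expect_error(applySignal(vol, badRoi, geom, list(a = 1),
                           list(a = tc), 1), "outside the mask")
  ## condition mismatch errors
  expect_error(applySignal(vol, roi, geom, list(a = rep(1, nRoi)),
                           list(b = tc), 1), "same conditions")
})

test_that("two-condition simulated data support multivariate classification", {
  mask <- array(FALSE, c(5, 5, 5)); mask[2:4, 2:4, 2:4] <- TRUE
  geom <- VolumeGeometry(mask)
  roi <- array(FALSE, c(5, 5, 5)); roi[2:4, 2:4, 2:3] <- TRUE
  nRoi <- sum(roi)
  T <- 200
  ## alternating 10 s events of two conditions
  onsetsA <- seq(0, 180, by = 40)
  onsetsB <- seq(20, 180, by = 40)
  d <- designTable(c(onsetsA, onsetsB), 10,
                   rep(c("a", "b"), c(length(onsetsA), length(onsetsB))))
  tcs <- generateStimfunction(d, T, 1, 10)
  conv <- lapply(tcs, convolveHrf)
  set.seed(11)
  patA <- sample(c(1, -1), nRoi, replace = TRUE)
  patB <- -patA                                   # orthogonal +-1 pair
  vol <- suppressWarnings(
    generateNoise(geom, T = T, trSeconds = 1,
                  profile = NoiseProfile(sfnr = 500, driftSdPct = 0.1),
                  seed = 12))
  sig <- applySignal(vol, roi, geom, list(a = patA, b = patB),
                     conv, scalePctSignalChange = 2)
  ## event-averaged ROI patterns
  flat <- matrix(as.vector(sig), ncol = T)[as.vector(roi), ]
  grab <- function(onsets) t(vapply(onsets, function(o)
    rowMeans(flat[, (o + 4):(o + 12)]), numeric(nRoi)))
  Xa <- grab(onsetsA); Xb <- grab(onsetsB)
  X <- rbind(Xa, Xb)
  y <- factor(rep(c("a", "b"), c(nrow(Xa), nrow(Xb))))
  ## leave-one-event-out nearest-centroid on demeaned patterns
  X <- sweep(X, 2L, colMeans(X))
  preds <- vapply(seq_len(nrow(X)), function(i) {
    ca <- colMeans(X[setdiff(which(y == "a"), i), , drop = FALSE])
    cb <- colMeans(X[setdiff(which(y == "b"), i), , drop = FALSE])
    if (sum((X[i, ] - ca)^2) < sum((X[i, ] - cb)^2)) "a" else "b"
  }, character(1))
  expect_gt(mean(preds == y), 0.9)
})
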
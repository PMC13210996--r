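# Multitask objective: L1, multi-resolution STFT, class weights,
# cross-entropy + Dice segmentation loss, and their composition.

test_that("L1 loss identities", {
  y <- rnorm(100)
  expect_equal(l1_loss(y, y), 0)
  expect_equal(l1_loss(rep(0, 4), c(1, -1, 1, -1)), 1)
  expect_equal(l1_loss(y + 0.3, y), 0.3)
  expect_error(l1_loss(y, y[-1]), "mismatch")
})

test_that("multi-resolution STFT loss is magnitude-only and matches a direct oracle", {
  set.seed(5)
  y <- rnorm(700)
  cfg <- stft_loss_config()
  expect_equal(multires_stft_loss(y, y, cfg), 0)
  # sign-blind: flipping either argument changes nothing
  expect_equal(multires_stft_loss(-y, y, cfg), 0, tolerance = 1e-12)
  expect_equal(multires_stft_loss(2 * y, -2 * y, cfg), 0, tolerance = 1e-12)
  # yhat = 2y: loss equals mean |Y| over frames/bins/resolutions, computed
  # by a direct spectrogram evaluation
  oracle <- mean(mapply(function(nfft, hop) {
    w <- 0.5 * (1 - cos(2 * pi * (0:(nfft - 1)) / nfft))
    starts <- seq(1, length(y) - nfft + 1, by = hop)
    mags <- sapply(starts, function(s) {
      Mod(fft(y[s:(s + nfft - 1)] * w))[1:(nfft / 2 + 1)]
    })
    mean(mags)
  }, cfg$fft_sizes, cfg$hop_sizes))
  expect_equal(multires_stft_loss(2 * y, y, cfg), oracle, tolerance = 1e-10)
  expect_error(multires_stft_loss(y[1:100], y[1:100], cfg), "FFT")
})

test_that("waveform loss composes its two halves", {
  set.seed(6)
  y <- rnorm(600)
  expect_equal(waveform_loss(y, y), 0)
  # yhat = -y: spectra match, so only the L1 term remains
  expect_equal(waveform_loss(-y, y), 0.5 * mean(abs(2 * y)), tolerance = 1e-10)
  expect_gte(waveform_loss(rnorm(600), y), 0)
})

test_that("class weights follow the square-root inverse-frequency rule", {
  expect_equal(as.numeric(class_weights(c(100, 100, 100, 100))), rep(1, 4))
  # state shares in per-mille from a typical PCG phase distribution
  counts <- c(1566, 2429, 1168, 4837)
  w <- class_weights(counts)
  oracle <- sqrt(mean(counts) / counts)
  oracle <- oracle / mean(oracle)
  expect_equal(as.numeric(w), oracle, tolerance = 1e-12)
  expect_equal(names(which.max(w)), "S2")   # rarest state, largest weight
  expect_equal(mean(w), 1, tolerance = 1e-9)
  expect_equal(as.numeric(class_weights(10 * counts)), as.numeric(w))
  expect_error(class_weights(c(0, 1, 1, 1)), "present")
})

test_that("segmentation loss: uniform-logit cross-entropy equals ln 4", {
  n <- 40
  logits <- matrix(0, 4, n)
  labels <- sample(0:3, n, replace = TRUE)
  parts <- radarpcg:::.segmentation_loss_grad(logits, labels, rep(1, 4),
                                              want_grad = FALSE)
  expect_equal(parts$ce, log(4), tolerance = 1e-12)
  # the CE contribution to the combined loss carries its 0.7 weight
  expect_equal(segmentation_loss(logits, labels),
               0.7 * log(4) + 0.3 * parts$dice, tolerance = 1e-12)
})

test_that("segmentation loss vanishes for confident correct predictions", {
  n <- 60
  labels <- rep(0:3, 15)
  logits <- matrix(-20, 4, n)
  logits[cbind(labels + 1, 1:n)] <- 20
  w <- as.numeric(class_weights(table(factor(labels, levels = 0:3))))
  expect_lt(segmentation_loss(logits, labels, w), 1e-6)
})

test_that("disjoint hard predictions saturate the Dice term", {
  # every class present in reference and prediction, but zero overlap:
  # prediction is the reference cyclically shifted by one state
  n <- 80
  labels <- rep(0:3, each = 20)
  pred <- (labels + 1L) %% 4L
  logits <- matrix(-20, 4, n); logits[cbind(pred + 1L, 1:n)] <- 20
  parts <- radarpcg:::.segmentation_loss_grad(logits, labels, rep(1, 4),
                                              want_grad = FALSE)
  expect_equal(parts$dice, 1, tolerance = 1e-4)
  # with no reference or predicted samples, smoothing scores a class perfect;
  # an all-S1 reference against an all-diastole prediction zeroes two classes
  logits2 <- matrix(-20, 4, 50); logits2[4, ] <- 20
  parts2 <- radarpcg:::.segmentation_loss_grad(logits2, rep(0L, 50), rep(1, 4),
                                               want_grad = FALSE)
  expect_equal(parts2$dice, 0.5, tolerance = 1e-4)
  expect_error(segmentation_loss(logits2, rep(7L, 50)), "0..3")
})

test_that("envelope loss is a symmetric MAE", {
  e <- abs(rnorm(100))
  expect_equal(envelope_loss(e, e), 0)
  expect_equal(envelope_loss(e + 0.1, e), 0.1)
  eh <- abs(rnorm(100))
  expect_equal(envelope_loss(eh, e), envelope_loss(e, eh))
})

test_that("the total loss is the weighted sum of its terms", {
  set.seed(8)
  T <- 600
  out <- list(waveform = rnorm(T), envelope = abs(rnorm(T)),
              logits = matrix(rnorm(4 * T), 4, T))
  tgt <- list(waveform = rnorm(T), envelope = abs(rnorm(T)),
              labels = sample(0:3, T, replace = TRUE))
  w <- loss_weights(0.7, 0.2, 0.1)
  tl <- total_loss(out, tgt, w)
  expect_equal(tl$total,
               0.7 * tl$waveform + 0.2 * tl$segmentation + 0.1 * tl$envelope)
  expect_gte(tl$total, 0)
  # alpha = 1, beta = gamma = 0 reduces to the waveform loss
  tl2 <- total_loss(out, tgt, loss_weights(1, 0, 0))
  expect_equal(tl2$total, waveform_loss(out$waveform, tgt$waveform))
  # perfect outputs: all terms vanish (CE in the hard-margin limit)
  perfect <- list(waveform = tgt$waveform, envelope = tgt$envelope,
                  logits = {z <- matrix(-20, 4, T)
                            z[cbind(tgt$labels + 1, 1:T)] <- 20; z})
  expect_lt(total_loss(perfect, tgt, w)$total, 1e-6)
})

test_that("loss weight and STFT configuration validation", {
  expect_error(loss_weights(-1, 0.5, 0.5), ">= 0")
  expect_error(loss_weights(0, 0, 0), "zero")
  expect_error(stft_loss_config(c(32, 64), c(8)), "equal length")
  expect_error(stft_loss_config(c(32), c(64)), "smaller")
})
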
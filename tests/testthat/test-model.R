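# Multitask self-attention 1D U-Net: construction, shapes, determinism.

test_that("the encoder halves time four times and doubles channels", {
  m <- build_model(model_config(), seed = 1)
  x <- array(rnorm(2000), c(1, 2000, 1))
  enc <- encode(m, x)
  expect_equal(dim(enc$bottleneck), c(192, 125, 1))
  ch <- vapply(enc$skips, function(s) dim(s)[1], 0)
  expect_equal(ch, c(24, 48, 96, 192))
  lens <- vapply(enc$skips, function(s) dim(s)[2], 0)
  expect_equal(lens, c(2000, 1000, 500, 250))
  # minimal input: T = 16 compresses to a single bottleneck step
  enc2 <- encode(m, array(rnorm(16), c(1, 16, 1)))
  expect_equal(dim(enc2$bottleneck), c(192, 1, 1))
  expect_error(encode(m, array(rnorm(30), c(1, 30, 1))), "divisible")
})

test_that("outputs share the input length for any T divisible by 16", {
  m <- build_model(model_config(), seed = 1)
  for (T in c(2000, 2016, 64)) {
    out <- pcg_forward(m, array(rnorm(T), c(1, T, 1)))
    expect_equal(dim(out$waveform), c(1, T, 1))
    expect_equal(dim(out$envelope), c(1, T, 1))
    expect_equal(dim(out$logits), c(4, T, 1))
  }
})

test_that("waveform output is tanh-bounded and finite on extreme inputs", {
  m <- build_model(model_config(), seed = 2)
  for (x in list(array(0, c(1, 64, 1)), array(1e3, c(1, 64, 1)),
                 array(rnorm(64, sd = 50), c(1, 64, 1)))) {
    out <- pcg_forward(m, x)
    expect_true(all(is.finite(out$waveform)))
    expect_true(all(abs(out$waveform) <= 1))
    expect_true(all(is.finite(out$logits)))
  }
})

test_that("evaluation-mode forward is deterministic and batch-consistent", {
  m <- build_model(model_config(), seed = 3)
  x1 <- array(rnorm(64), c(1, 64, 1))
  o1 <- pcg_forward(m, x1)
  o2 <- pcg_forward(m, x1)
  expect_identical(o1$waveform, o2$waveform)
  # two identical windows in one batch give identical outputs
  xb <- array(0, c(1, 64, 2))
  xb[, , 1] <- x1; xb[, , 2] <- x1
  ob <- pcg_forward(m, xb)
  expect_equal(ob$waveform[, , 1], ob$waveform[, , 2], tolerance = 1e-12)
})

test_that("channel mismatches are caught", {
  m <- build_model(model_config(in_channels = 1), seed = 1)
  expect_error(pcg_forward(m, array(rnorm(3 * 64), c(3, 64, 1))), "channels")
})

test_that("parameter count is a pure function of the configuration", {
  m1 <- build_model(model_config(), seed = 1)
  m2 <- build_model(model_config(), seed = 99)
  expect_identical(count_parameters(m1), count_parameters(m2))
  # a 24 -> 1 pointwise conv with bias holds 25 scalars
  expect_length(c(radarpcg:::.init_conv(24, 1, 1)$W,
                  radarpcg:::.init_conv(24, 1, 1)$b), 25)
  # wider models are strictly larger
  big <- build_model(model_config(base_channels = 48), seed = 1)
  expect_gt(count_parameters(big), count_parameters(m1))
  # the 3-channel baseline adds exactly one stem tap per extra channel
  m3 <- build_model(model_config(in_channels = 3), seed = 1)
  expect_equal(count_parameters(m3) - count_parameters(m1), 2 * 24 * 5)
})

test_that("training-mode forward with a fixed seed is reproducible", {
  m <- build_model(model_config(), seed = 4)
  x <- array(rnorm(64 * 2), c(1, 64, 2))
  set.seed(7); a <- radarpcg:::.unet_fwd(m, x, training = TRUE)$waveform
  set.seed(7); b <- radarpcg:::.unet_fwd(m, x, training = TRUE)$waveform
  expect_identical(a, b)
})
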
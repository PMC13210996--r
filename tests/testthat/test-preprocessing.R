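# Pre-processing chain: DACM, displacement conversion, resampling, filtering,
# synchronization, normalization, envelope, windowing.

test_that("DACM reproduces analytic phase ramps, including wrapped ones", {
  n <- 0:99
  x <- exp(1i * 0.1 * n)
  tr <- dacm_unwrap(x)
  expect_equal(tr$delta_psi[-1], rep(0.1, 99), tolerance = 1e-12)
  expect_equal(tr$psi_u[100], 9.9, tolerance = 1e-9)
  # steps of 0.5 rad wrap the atan2 phase ~7 times; DACM stays continuous
  x2 <- exp(1i * 0.5 * n)
  tr2 <- dacm_unwrap(x2)
  expect_equal(tr2$psi_u, 0.5 * n, tolerance = 1e-9)
  expect_gte(max(abs(diff(Arg(x2)))), pi)  # the direct phase does wrap
})

test_that("DACM recovers a sinusoidal chest-motion phase exactly", {
  lambda <- 0.0124913
  fs <- 2000
  n <- 0:19999
  psi <- (4 * pi / lambda) * 0.002 * sin(2 * pi * 0.25 * n / fs)
  expect_lt(max(abs(diff(psi))), pi)
  tr <- dacm_unwrap(exp(1i * psi))
  expect_equal(tr$psi_u - tr$psi_u[1], psi - psi[1], tolerance = 1e-9)
})

test_that("DACM phase-track invariants hold and degenerate input errors", {
  x <- exp(1i * cumsum(runif(50, -1, 1)))
  tr <- dacm_unwrap(x, initial_phase = 2)
  expect_equal(tr$psi_u[1], 2 + tr$delta_psi[1])
  expect_equal(diff(tr$psi_u), tr$delta_psi[-1], tolerance = 1e-12)
  expect_true(all(abs(tr$delta_psi) <= pi))
  expect_error(dacm_unwrap(c(1 + 0i, 0 + 0i, 1i)), "index 2")
})

test_that("phase-to-displacement conversion is the exact linear map", {
  expect_equal(phase_to_displacement(rep(0, 5), 0.0125), rep(0, 5))
  expect_equal(phase_to_displacement(4 * pi, 0.01249), 0.01249)
  psi <- rnorm(20)
  expect_equal(phase_to_displacement(2 * psi, 0.01),
               2 * phase_to_displacement(psi, 0.01))
  expect_error(phase_to_displacement(psi, -1), "wavelength")
})

test_that("resampling preserves tones and lengths", {
  x <- sin(2 * pi * 20 * (0:9999) / 2000)
  y <- resample_to_common(x, 2000, 500)
  expect_length(y, 2500)
  # spectral peak stays at 20 Hz with amplitude within 1%
  interior <- y[200:2300]
  expect_equal(max(abs(interior)), 1, tolerance = 0.01)
  sp <- Mod(fft(y))
  expect_equal(which.max(sp[1:1250]), 20 * length(y) / 500 + 1)
  expect_identical(resample_to_common(x, 500, 500), x)
  expect_length(resample_to_common(numeric(0), 2000, 500), 0)
  expect_error(resample_to_common(x, -1, 500), "positive")
})

test_that("band-pass keeps the heart-sound band and rejects respiration", {
  fs <- 500
  t <- (0:4999) / fs
  expect_equal(bandpass_hs(numeric(100), fs), numeric(100))
  resp <- sin(2 * pi * 0.3 * t)
  expect_lt(sd(bandpass_hs(resp, fs)) / sd(resp), 0.01)
  tone <- sin(2 * pi * 60 * t)
  expect_equal(sd(bandpass_hs(tone, fs)) / sd(tone), 1, tolerance = 0.05)
  expect_error(bandpass_hs(tone, fs, band = c(15, 300)), "Nyquist|inside")
})

test_that("band-pass filtering is idempotent on passband tones", {
  fs <- 500
  tone <- sin(2 * pi * 60 * (0:4999) / fs)
  once <- bandpass_hs(tone, fs)
  twice <- bandpass_hs(once, fs)
  expect_lt(sd(twice - once) / sd(once), 0.1)
})

test_that("synchronization crops to the overlap on the common grid", {
  fs <- 500
  x <- rnorm(1000); tx <- (0:999) / fs
  al <- synchronize(x, tx, x, tx)
  expect_identical(al$x, al$y)
  # radar starts 0.5 s later: reference loses 250 leading samples
  y <- rnorm(1000); ty <- tx
  tx2 <- tx + 0.5
  al2 <- synchronize(x, tx2, y, ty)
  expect_identical(al2$y, y[251:1000])
  expect_length(al2$x, 750)
  expect_error(synchronize(x, tx, y, ty + 10), "overlap")
})

test_that("amplitude normalization contract", {
  expect_equal(normalize_amplitude(c(0, 2, -4)), c(0, 0.5, -1))
  expect_equal(normalize_amplitude(numeric(5)), numeric(5))
  x <- rnorm(100)
  expect_equal(max(abs(normalize_amplitude(x))), 1)
  # idempotent and scale-invariant
  expect_equal(normalize_amplitude(normalize_amplitude(x)),
               normalize_amplitude(x))
  expect_equal(normalize_amplitude(3.7 * x), normalize_amplitude(x))
  expect_error(normalize_amplitude(c(1, NA)), "finite")
})

test_that("finite difference matches its definition and a slow sine's slope", {
  expect_equal(finite_difference(rep(3, 10)), rep(0, 10))
  expect_equal(finite_difference(0:9), c(0, rep(1, 9)))
  fs <- 500
  t <- (0:999) / fs
  s <- sin(2 * pi * 1 * t)
  d <- finite_difference(s) * fs
  # derivative of sin at zero crossing is 2*pi*f
  expect_equal(max(d), 2 * pi, tolerance = 0.01)
  expect_error(finite_difference(1), "length")
})

test_that("homomorphic envelope tracks amplitude modulation", {
  fs <- 500
  t <- (0:4999) / fs
  expect_equal(homomorphic_envelope(numeric(100), fs), numeric(100))
  mod <- 1 + 0.5 * sin(2 * pi * 1 * t)
  x <- mod * sin(2 * pi * 50 * t)
  env <- homomorphic_envelope(x, fs)
  expect_true(all(env >= 0))
  expect_gt(cor(env, mod), 0.99)
  # single burst: envelope peaks within 10 ms of the burst centre
  burst <- exp(-(t - 5)^2 / (2 * 0.03^2)) * sin(2 * pi * 45 * t)
  envb <- homomorphic_envelope(burst, fs)
  expect_lte(abs((which.max(envb) - 1) / fs - 5), 0.010)
})

test_that("windowing yields exact block counts and drops remainders", {
  pair <- structure(list(y_rad = rnorm(5000), fs = 500),
                    class = "preprocessed_pair")
  wb <- window_segments(pair, ns = 2000, hop = 2000)
  expect_equal(wb$starts, c(1L, 2001L))
  wb2 <- window_segments(structure(list(y_rad = rnorm(2000)),
                                   class = "preprocessed_pair"), ns = 2000)
  expect_length(wb2$starts, 1)
  expect_warning(
    wb3 <- window_segments(structure(list(y_rad = rnorm(1950)),
                                     class = "preprocessed_pair"), ns = 2000),
    "shorter")
  expect_length(wb3$starts, 0)
  # 50% hop on 10 s: floor((5000-2000)/1000)+1 = 4 blocks
  expect_length(window_segments(pair, ns = 2000, hop = 1000)$starts, 4)
})

test_that("the full radar chain tracks the reference heart sounds", {
  rec <- clean_recording()
  pp <- preprocess_recording(rec)
  expect_s3_class(pp, "preprocessed_pair")
  expect_equal(pp$fs, 500)
  expect_length(pp$y_pcg, length(pp$y_rad))
  expect_length(pp$labels, length(pp$y_rad))
  expect_lte(max(abs(pp$y_rad)), 1)
  expect_gt(cor(pp$y_rad, pp$y_pcg), 0.95)
})
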
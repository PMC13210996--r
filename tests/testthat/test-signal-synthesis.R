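# Simulator: displacement components, I/Q generation, reference rendering,
# dataset construction.

test_that("zero amplitudes give zero components but valid labels", {
  ph <- physio_config(resp_amplitude = 0, heartbeat_amplitude = 0,
                      hs_amplitude = 0, rbm_std = 0)
  d <- simulate_displacement(ph, duration = 5, fs_raw = 500, seed = 1)
  for (comp in d$components) expect_true(all(comp == 0))
  expect_length(d$labels, 2500)
  expect_true(all(d$labels %in% 0:3))
  expect_true(all(0:3 %in% d$labels))
})

test_that("component scales match their physiological orders of magnitude", {
  ph <- physio_config(hs_amplitude = 10, resp_amplitude = 2,
                      envelope_modulation_depth = 0)
  d <- simulate_displacement(ph, duration = 10, fs_raw = 1000, seed = 2)
  # heart sounds are um-scale, respiration mm-scale
  expect_lte(max(abs(d$components$hs)), 1.5e-5)
  expect_gte(max(abs(d$components$hs)), 5e-6)
  expect_equal(max(abs(d$components$resp)), 2e-3, tolerance = 1e-6)
})

test_that("regular heart at 60 bpm yields one S1 per second and the right label share", {
  ph <- physio_config(heart_rate = 60, hr_jitter = 0)
  fs <- 1000
  d <- simulate_displacement(ph, duration = 10, fs_raw = fs, seed = 3)
  expect_length(d$event_times$s1, 10)
  expect_equal(diff(d$event_times$s1), rep(1, 9), tolerance = 1e-9)
  # S1 label fraction ~ s1_duration / RR, counted from emitted label runs
  r <- rle(d$labels == cardiac_states()[["S1"]])
  s1_runs <- r$lengths[r$values]
  expect_lt(abs(mean(s1_runs) / fs - ph$s1_duration), 2.5 / fs)
  frac <- sum(d$labels == 0) / length(d$labels)
  expect_equal(frac, ph$s1_duration / 1.0, tolerance = 0.01)
})

test_that("labels partition every sample and events sit inside their runs", {
  rec <- clean_recording()
  st_counts <- table(factor(rec$labels, levels = 0:3))
  expect_equal(sum(st_counts), length(rec$iq))
  expect_equal(length(rec$iq), length(rec$labels))
  expect_equal(length(rec$iq), length(rec$total_displacement))
  # every S1 event time falls on an S1-labelled sample
  for (t1 in rec$event_times$s1) {
    idx <- round(t1 * rec$fs_raw) + 1
    expect_equal(rec$labels[idx], cardiac_states()[["S1"]])
  }
  for (t2 in rec$event_times$s2) {
    idx <- round(t2 * rec$fs_raw) + 1
    expect_equal(rec$labels[idx], cardiac_states()[["S2"]])
  }
})

test_that("total displacement is the exact sum of the four components", {
  rec <- clean_recording()
  expect_equal(rec$total_displacement,
               rec$displacement_components$resp +
                 rec$displacement_components$heart +
                 rec$displacement_components$hs +
                 rec$displacement_components$rbm,
               tolerance = 0)
})

test_that("ideal I/Q has constant modulus and the expected phase behaviour", {
  rad <- radar_config(noise_std = 0)
  # constant displacement -> constant sample a * exp(j psi0)
  x <- simulate_iq(rep(0, 100), rad, iq_impairments(), seed = 1)
  expect_equal(Re(x), rep(rad$amplitude * cos(rad$constant_phase), 100))
  expect_equal(Im(x), rep(rad$amplitude * sin(rad$constant_phase), 100))
  # modulus conservation for arbitrary displacement
  dr <- cumsum(rnorm(500, sd = 1e-5))
  x2 <- simulate_iq(dr, rad, iq_impairments(), seed = 2)
  expect_equal(Mod(x2), rep(rad$amplitude, 500), tolerance = 1e-12)
  # a quarter-wavelength step flips the phase by pi
  x3 <- simulate_iq(c(0, rad$wavelength / 4), rad, iq_impairments(), seed = 3)
  dphi <- Arg(x3[2] * Conj(x3[1]))
  expect_equal(abs(dphi), pi, tolerance = 1e-9)
})

test_that("a half-wavelength sweep closes a circle, with AI=1.2 an ellipse", {
  rad <- radar_config(noise_std = 0)
  dr <- seq(0, rad$wavelength / 2, length.out = 400)
  x <- simulate_iq(dr, rad, iq_impairments(), seed = 1)
  expect_equal(max(Mod(x)), 1, tolerance = 1e-9)
  expect_equal(min(Mod(x)), 1, tolerance = 1e-9)
  x2 <- simulate_iq(dr, rad, iq_impairments(AI = 1.2), seed = 1)
  expect_equal(max(abs(Re(x2))), 1.2, tolerance = 1e-3)
  expect_equal(max(abs(Im(x2))), 1.0, tolerance = 1e-3)
})

test_that("reference rendering is band-limited, normalized, and handles silence", {
  zero <- render_reference_pcg(numeric(4000), fs_raw = 2000)
  expect_true(all(zero$pcg == 0))
  expect_true(all(zero$envelope == 0))
  rec <- clean_recording()
  expect_lte(max(abs(rec$reference_pcg)), 1)
  expect_equal(max(abs(rec$reference_pcg)), 1)
  # single S1 burst -> unimodal envelope peaking near the burst centre
  fs <- 2000
  t <- (0:(8 * fs - 1)) / fs
  burst <- 1e-5 * exp(-(t - 4)^2 / (2 * 0.02^2)) * sin(2 * pi * 45 * (t - 4))
  ref <- render_reference_pcg(burst, fs_raw = fs)
  peak_t <- (which.max(ref$envelope) - 1) / 500
  expect_lte(abs(peak_t - 4), 0.010)
})

test_that("dataset generation is deterministic, tagged, and scenario-aware", {
  d1 <- generate_dataset(3, scenarios = c("resting", "apnea"), duration = 8,
                         seed = 9)
  d2 <- generate_dataset(3, scenarios = c("resting", "apnea"), duration = 8,
                         seed = 9)
  expect_identical(d1, d2)
  expect_length(d1, 6)
  ids <- vapply(d1, function(r) r$subject_id, "")
  expect_length(unique(ids), 3)
  expect_error(generate_dataset(2, duration = 8), "subjects")
  apnea <- d1[vapply(d1, function(r) r$scenario, "") == "apnea"]
  for (r in apnea) {
    expect_equal(r$physio$resp_amplitude, 0)
    expect_equal(r$physio$envelope_modulation_depth, 0)
  }
})

test_that("invalid physiological configurations are rejected", {
  expect_error(physio_config(resp_amplitude = -1), "amplitudes")
  expect_error(physio_config(heart_rate = 300, s1_duration = 0.15,
                             s2_duration = 0.1), "RR")
  expect_error(physio_config(s1_center_freq = 200), "15, 150")
  expect_error(simulate_displacement(physio_config(), duration = 1), "duration")
})
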
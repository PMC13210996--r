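# Synthetic Doppler-radar recordings with per-sample cardiac-phase labels.

# Gaussian-windowed tone burst; sigma chosen so +/- 3 sigma spans `duration`.
.hs_burst <- function(t, center, duration, freq, amp) {
  sigma <- duration / 6
  amp * exp(-(t - center)^2 / (2 * sigma^2)) * sin(2 * pi * freq * (t - center))
}

#' Simulate chest-wall displacement components
#'
#' Generates the four displacement contributions measured by a Doppler radar
#' pointed at the chest: respiration (mm-scale sinusoid), heartbeat (mm-scale
#' raised-cosine pulse train), heart sounds (micrometre-scale Gaussian-windowed
#' tone bursts at the S1/S2 instants), and a random-body-movement random walk.
#' The S1/S2 burst amplitudes are modulated by respiration (peak envelope
#' variation) and S2 is rendered as two sub-bursts whose separation follows
#' the inspiratory half of the respiratory cycle (S2 split).
#'
#' @param physio A [physio_config()].
#' @param duration Recording duration in seconds (> 2 RR intervals).
#' @param fs_raw Sampling rate in Hz.
#' @param seed Integer seed controlling beat jitter and the random walk.
#'
#' @return A list with elements `components` (list of numeric vectors `resp`,
#'   `heart`, `hs`, `rbm`, all in metres), `labels` (integer vector of cardiac
#'   state codes, see [cardiac_states()]), `event_times` (list with S1 and S2
#'   centre times in seconds), and `t` (time axis).
#' @export
simulate_displacement <- function(physio, duration, fs_raw = 2000, seed = 1) {
  stopifnot(inherits(physio, "physio_config"), fs_raw > 0)
  rr <- 60 / physio$heart_rate
  if (duration <= 2 * rr) {
    stop("duration must exceed two RR intervals (", signif(2 * rr, 3), " s)")
  }
  n <- round(duration * fs_raw)
  t <- (seq_len(n) - 1) / fs_raw
  br_hz <- physio$breath_rate / 60

  with_seed(seed, {
    # --- beat grid with multiplicative RR jitter
    n_beats_max <- ceiling(duration / rr) + 3
    eps <- rnorm(n_beats_max)
    rr_i <- rr * (1 + physio$hr_jitter * pmax(pmin(eps, 3), -3))
    s1_centers <- cumsum(c(rr / 2, rr_i))
    s1_centers <- s1_centers[s1_centers < duration + rr]

    # --- respiration
    resp <- physio$resp_amplitude * 1e-3 * sin(2 * pi * br_hz * t)

    # --- heartbeat pulse train: smooth 300 ms raised-cosine-squared bump per
    # beat, spectrally compact so the 15 Hz band edge removes it downstream
    heart <- numeric(n)
    pulse_dur <- 0.3
    for (c1 in s1_centers) {
      idx <- which(t >= c1 - pulse_dur / 2 & t < c1 + pulse_dur / 2)
      if (length(idx)) {
        heart[idx] <- heart[idx] + physio$heartbeat_amplitude * 1e-3 *
          (0.5 * (1 + cos(2 * pi * (t[idx] - c1) / pulse_dur)))^2
      }
    }

    # --- heart sounds + labels
    hs <- numeric(n)
    labels <- rep(cardiac_states()[["diastole"]], n)
    amp <- physio$hs_amplitude * 1e-6
    depth <- physio$envelope_modulation_depth
    s1_kept <- c()
    s2_kept <- c()
    to_idx <- function(time) pmin(pmax(round(time * fs_raw) + 1, 1), n)
    for (k in seq_along(s1_centers)) {
      c1 <- s1_centers[k]
      rr_k <- if (k < length(s1_centers)) s1_centers[k + 1] - c1 else rr
      s1_on <- c1 - physio$s1_duration / 2
      s2_on <- s1_on + physio$systole_fraction * rr_k
      c2 <- s2_on + physio$s2_duration / 2
      mod1 <- 1 + depth * sin(2 * pi * br_hz * c1)
      mod2 <- 1 + depth * sin(2 * pi * br_hz * c2)
      split <- physio$s2_split_max * max(0, sin(2 * pi * br_hz * c2))

      hs <- hs + .hs_burst(t, c1, physio$s1_duration, physio$s1_center_freq,
                           amp * mod1)
      hs <- hs + .hs_burst(t, c2 - split / 2, physio$s2_duration,
                           physio$s2_center_freq, amp * mod2 / 2)
      hs <- hs + .hs_burst(t, c2 + split / 2, physio$s2_duration,
                           physio$s2_center_freq, amp * mod2 / 2)

      if (c1 >= 0 && c1 < duration) s1_kept <- c(s1_kept, c1)
      if (c2 >= 0 && c2 < duration) s2_kept <- c(s2_kept, c2)

      st <- cardiac_states()
      i_s1 <- to_idx(s1_on):to_idx(s1_on + physio$s1_duration)
      i_sys <- to_idx(s1_on + physio$s1_duration):to_idx(s2_on)
      i_s2 <- to_idx(s2_on):to_idx(s2_on + physio$s2_duration)
      labels[i_sys] <- st[["systole"]]
      labels[i_s1] <- st[["S1"]]
      labels[i_s2] <- st[["S2"]]
    }

    # --- random body movement: integrated white noise, low-passed to a slow
    # (< 2 Hz) drift so it interferes with the cardiorespiratory band rather
    # than with the heart sounds themselves, rescaled to rbm_std
    if (physio$rbm_std > 0) {
      w <- cumsum(rnorm(n))
      bf <- signal::butter(2, min(2 / (fs_raw / 2), 0.99), type = "low")
      w <- as.numeric(signal::filtfilt(bf, w))
      w <- w - mean(w)
      s <- sd(w)
      rbm <- if (s > 0) w * (physio$rbm_std * 1e-3 / s) else w
    } else {
      rnorm(n) # keep the RNG stream position independent of rbm_std
      rbm <- numeric(n)
    }

    list(components = list(resp = resp, heart = heart, hs = hs, rbm = rbm),
         labels = as.integer(labels),
         event_times = list(s1 = s1_kept, s2 = s2_kept),
         t = t)
  })
}

#' Simulate the radar complex baseband sequence
#'
#' Maps a chest-displacement sequence to the I/Q baseband samples of a CW
#' Doppler radar: the phase is `psi0 + 4 * pi * displacement / lambda`, the
#' quadrature components are distorted by the amplitude mismatches, phase
#' imbalance and DC offsets of `impairments`, and independent Gaussian noise
#' of standard deviation `radar$noise_std` is added to each component.
#'
#' @param total_displacement Displacement sequence in metres.
#' @param radar A [radar_config()].
#' @param impairments An [iq_impairments()].
#' @param seed Integer seed for the additive noise.
#'
#' @return Complex vector of baseband samples.
#' @export
simulate_iq <- function(total_displacement, radar, impairments = iq_impairments(),
                        seed = 1) {
  stopifnot(inherits(radar, "radar_config"), inherits(impairments, "iq_impairments"))
  if (!all(is.finite(total_displacement))) stop("displacement must be finite")
  psi <- radar$constant_phase + 4 * pi * total_displacement / radar$wavelength
  a <- radar$amplitude
  with_seed(seed, {
    n <- length(psi)
    wI <- if (radar$noise_std > 0) rnorm(n, sd = radar$noise_std) else 0
    wQ <- if (radar$noise_std > 0) rnorm(n, sd = radar$noise_std) else 0
    xi <- impairments$AI * a * cos(psi) + impairments$OI + wI
    xq <- impairments$AQ * a * sin(psi + impairments$psi_e) + impairments$OQ + wQ
    complex(real = xi, imaginary = xq)
  })
}

#' Render the reference PCG-like waveform and envelope
#'
#' Stands in for the stethoscope channel of a synchronized radar/PCG
#' acquisition: the clean heart-sound displacement is band-limited to
#' [15, 150] Hz, resampled to 500 Hz, max-abs normalized to [-1, 1], and
#' paired with its homomorphic envelope.
#'
#' @param hs Heart-sound displacement sequence (from [simulate_displacement()]).
#' @param fs_raw Sampling rate of `hs` in Hz.
#' @param fs_out Output rate in Hz (default 500).
#'
#' @return List with `pcg` (waveform in [-1, 1]) and `envelope`.
#' @export
render_reference_pcg <- function(hs, fs_raw = 2000, fs_out = 500) {
  if (all(hs == 0)) {
    n_out <- round(length(hs) * fs_out / fs_raw)
    return(list(pcg = numeric(n_out), envelope = numeric(n_out)))
  }
  y <- bandpass_hs(hs, fs = fs_raw)
  y <- resample_to_common(y, fs_raw, fs_out)
  y <- normalize_amplitude(y)
  list(pcg = y, envelope = homomorphic_envelope(y, fs = fs_out))
}

.scenarios <- c("resting", "apnea", "speaking-like", "movement-like")

# Scenario-specific overrides applied to a drawn physiological configuration.
.apply_scenario <- function(params, scenario) {
  switch(scenario,
    "resting" = params,
    "apnea" = {
      params$resp_amplitude <- 0
      params$envelope_modulation_depth <- 0
      params$s2_split_max <- 0
      params
    },
    "speaking-like" = { params$rbm_std <- 0.2; params },
    "movement-like" = { params$rbm_std <- 0.5; params },
    stop("unknown scenario: ", scenario)
  )
}

#' Generate a labeled synthetic radar dataset
#'
#' Draws per-subject physiological parameters from realistic resting ranges
#' (heart rate 55-95 bpm, breath rate 10-20 bpm, respiration 1-3 mm,
#' heart sounds 8-15 um), applies scenario-specific overrides, and simulates
#' one recording per subject and scenario, each with its own I/Q impairment
#' draw. Deterministic given `seed`; recordings are tagged with subject and
#' scenario for leakage-free subject-wise splitting.
#'
#' @param n_subjects Number of subjects (>= 3 so a train/val/test split exists).
#' @param scenarios Character vector of scenario tags; see Details.
#' @param duration Duration of each recording in seconds.
#' @param seed Master integer seed.
#' @param radar A [radar_config()]; its `noise_std` applies to all recordings.
#'
#' @details Supported scenarios: `"resting"`, `"apnea"` (respiration amplitude
#'   and envelope modulation forced to zero), `"speaking-like"` and
#'   `"movement-like"` (increasing random-body-movement levels).
#'
#' @return List of `synthetic_recording` objects.
#' @export
generate_dataset <- function(n_subjects, scenarios = "resting", duration = 60,
                             seed = 1, radar = radar_config(noise_std = 0.005)) {
  if (n_subjects < 3) stop("n_subjects must be >= 3 for a train/val/test split")
  stopifnot(all(scenarios %in% .scenarios))
  recs <- list()
  for (s in seq_len(n_subjects)) {
    # stay inside 32-bit integer range for any caller-provided seed
    subj_seed <- as.integer((seed * 7919 + s * 104729) %% 2147483629)
    base <- with_seed(subj_seed, list(
      heart_rate = runif(1, 55, 95),
      breath_rate = runif(1, 10, 20),
      resp_amplitude = runif(1, 1, 3),
      heartbeat_amplitude = runif(1, 0.3, 0.7),
      hs_amplitude = runif(1, 8, 15),
      envelope_modulation_depth = runif(1, 0.2, 0.4),
      s2_split_max = runif(1, 0.02, 0.04),
      hr_jitter = runif(1, 0.02, 0.05),
      rbm_std = 0.02
    ))
    for (sc_i in seq_along(scenarios)) {
      sc <- scenarios[sc_i]
      params <- .apply_scenario(base, sc)
      physio <- do.call(physio_config, params)
      rec_seed <- as.integer((subj_seed * 31 + sc_i * 6151) %% 2147483629)
      imp <- with_seed(rec_seed, iq_impairments(
        AI = runif(1, 0.8, 1.2), AQ = runif(1, 0.8, 1.2),
        psi_e = runif(1, -0.3, 0.3),
        OI = runif(1, -0.3, 0.3) * radar$amplitude,
        OQ = runif(1, -0.3, 0.3) * radar$amplitude
      ))
      recs[[length(recs) + 1L]] <- simulate_recording(
        physio, radar, imp, duration = duration, seed = rec_seed,
        subject_id = sprintf("subject%02d", s), scenario = sc
      )
    }
  }
  recs
}

#' Simulate one labeled radar recording
#'
#' Combines [simulate_displacement()], [simulate_iq()] and
#' [render_reference_pcg()] into a complete synthetic recording.
#'
#' @param physio A [physio_config()].
#' @param radar A [radar_config()].
#' @param impairments An [iq_impairments()].
#' @param duration Duration in seconds.
#' @param seed Integer seed.
#' @param subject_id,scenario Metadata tags.
#'
#' @return An object of class `synthetic_recording` with the raw I/Q sequence,
#'   the four displacement components and their sum, the 500 Hz reference
#'   waveform and envelope, per-sample state labels and S1/S2 event times.
#' @export
simulate_recording <- function(physio, radar = radar_config(),
                               impairments = iq_impairments(),
                               duration = 30, seed = 1,
                               subject_id = "subject01", scenario = "resting") {
  disp <- simulate_displacement(physio, duration, radar$fs_raw, seed = seed)
  total <- disp$components$resp + disp$components$heart +
    disp$components$hs + disp$components$rbm
  iq <- simulate_iq(total, radar, impairments, seed = seed + 1L)
  ref <- render_reference_pcg(disp$components$hs, radar$fs_raw)
  structure(list(
    subject_id = subject_id, scenario = scenario,
    fs_raw = radar$fs_raw, iq = iq,
    displacement_components = disp$components,
    total_displacement = total,
    reference_pcg = ref$pcg, reference_envelope = ref$envelope,
    labels = disp$labels, event_times = disp$event_times,
    seed = seed, physio = physio, radar = radar, impairments = impairments
  ), class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat("<synthetic_recording>", x$subject_id, "/", x$scenario,
      sprintf("(%.1f s @ %g Hz, seed %d)\n",
              length(x$iq) / x$fs_raw, x$fs_raw, x$seed))
  invisible(x)
}
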
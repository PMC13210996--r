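# Radar/PCG pre-processing chain: DACM demodulation, displacement conversion,
# resampling, band-pass filtering, synchronization, normalization, and the
# derivative / homomorphic-envelope feature streams.

#' DACM phase unwrapping
#'
#' Differentiate-and-cross-multiply demodulation: the per-sample phase
#' increment is `atan2(xQ[n] xI[n-1] - xI[n] xQ[n-1], xI[n] xI[n-1] + xQ[n] xQ[n-1])`,
#' i.e. the argument of `x[n] * Conj(x[n-1])`, and the unwrapped phase is its
#' cumulative sum. Immune to the 2*pi wrap discontinuities of the direct
#' atan2 phase as long as per-sample steps stay below pi in magnitude.
#'
#' @param iq Complex vector of (compensated) baseband samples.
#' @param initial_phase Value assigned to the unwrapped phase at the first
#'   sample (default 0; only phase variation carries displacement information).
#'
#' @return An object of class `phase_track` with elements `delta_psi`,
#'   `psi_u` and `initial_phase`.
#' @export
dacm_unwrap <- function(iq, initial_phase = 0) {
  if (length(iq) < 1) stop("empty input")
  mag <- Mod(iq)
  if (any(mag == 0)) {
    stop("zero-magnitude sample at index ", which(mag == 0)[1])
  }
  xi <- Re(iq); xq <- Im(iq)
  n <- length(iq)
  dpsi <- numeric(n)
  if (n > 1) {
    i0 <- 1:(n - 1); i1 <- 2:n
    dpsi[i1] <- atan2(xq[i1] * xi[i0] - xi[i1] * xq[i0],
                      xi[i1] * xi[i0] + xq[i1] * xq[i0])
  }
  structure(list(delta_psi = dpsi,
                 psi_u = initial_phase + cumsum(dpsi),
                 initial_phase = initial_phase),
            class = "phase_track")
}

#' Convert unwrapped phase to chest displacement
#'
#' `displacement = wavelength / (4 * pi) * psi_u`: the CW-radar phase is
#' proportional to twice the range, so one wavelength of two-way path change
#' corresponds to 4*pi radians.
#'
#' @param track A `phase_track` from [dacm_unwrap()], or a numeric phase vector.
#' @param wavelength Radar wavelength in metres.
#'
#' @return Displacement sequence in metres.
#' @export
phase_to_displacement <- function(track, wavelength) {
  if (wavelength <= 0) stop("wavelength must be > 0")
  psi <- if (inherits(track, "phase_track")) track$psi_u else track
  wavelength / (4 * pi) * psi
}

#' Resample a signal to a common rate
#'
#' Rational polyphase resampling (anti-aliased) onto the common analysis rate.
#' The output length is `round(length(x) * fs_out / fs_in)`.
#'
#' @param x Numeric vector.
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#'
#' @return Resampled numeric vector.
#' @export
resample_to_common <- function(x, fs_in, fs_out = 500) {
  if (fs_in <= 0 || fs_out <= 0) stop("sampling rates must be positive")
  if (length(x) == 0) return(numeric(0))
  if (fs_in == fs_out) return(x)
  fr <- .rational_ratio(fs_out, fs_in)
  .resample_pq(x, fr[1], fr[2])
}

# Rational polyphase resampling by p/q with a Kaiser-windowed sinc
# anti-aliasing filter and odd-reflection edge padding. Edge handling
# matters here: FIR warm-up transients on the mm-scale respiration component
# would otherwise bury the um-scale heart sounds.
.resample_pq <- function(x, p, q) {
  n <- length(x)
  n_out <- round(n * p / q)
  M <- 20L * max(p, q)                    # half-length of the sinc kernel
  k <- (-M):M
  wc <- 1 / max(p, q)                     # cutoff as fraction of Nyquist
  h <- ifelse(k == 0, wc, sin(pi * wc * k) / (pi * k))
  h <- h * as.numeric(signal::kaiser(2 * M + 1, 8))
  h <- h / sum(h) * p                     # unit DC gain after zero-stuffing

  P <- ceiling((M + 2 * q) / p) + 8L      # input padding per side
  P <- min(P, n - 1L)
  xp <- .odd_reflect(x, P)
  xu <- numeric(length(xp) * p)
  xu[(seq_along(xp) - 1L) * p + 1L] <- xp
  y <- as.numeric(signal::fftfilt(h, c(xu, numeric(2 * M + 2))))
  idx <- P * p + (0:(n_out - 1L)) * q + 1L + M
  y[idx]
}

.odd_reflect <- function(x, p) {
  if (p <= 0) return(x)
  n <- length(x)
  c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
}

# Small continued-fraction rational approximation of a/b.
.rational_ratio <- function(a, b, tol = 1e-9) {
  x <- a / b
  # continued fraction expansion
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  r <- x
  for (i in 1:64) {
    ai <- floor(r)
    p2 <- ai * p1 + p0; q2 <- ai * q1 + q0
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < tol * x || q1 > 1e6) break
    fr <- r - ai
    if (fr < 1e-12) break
    r <- 1 / fr
  }
  c(p1, q1)
}

#' Band-pass filter for the heart-sound band
#'
#' 5th-order Butterworth band-pass, applied forward-backward (zero phase) so
#' that S1/S2 timing is not skewed. Removes the DC, respiration and heartbeat
#' components below 15 Hz and noise above 150 Hz.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param band Two-element passband in Hz (default `c(15, 150)`).
#' @param order Butterworth prototype order (default 5).
#'
#' @return Filtered vector of the same length.
#' @export
bandpass_hs <- function(x, fs = 500, band = c(15, 150), order = 5) {
  if (any(band <= 0) || any(band >= fs / 2)) {
    stop("band edges must lie strictly inside (0, fs/2)")
  }
  if (length(x) == 0) return(numeric(0))
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  # odd-reflection padding: zero-phase filtering free of edge transients
  p <- min(length(x) - 1, round(3 * fs / band[1]))
  y <- as.numeric(signal::filtfilt(bf, .odd_reflect(x, p)))
  if (p > 0) y[(p + 1):(p + length(x))] else y
}

#' Synchronize two streams by their timestamps
#'
#' Crops both streams to their overlapping time range on the common sampling
#' grid. Both streams must share the same sampling rate.
#'
#' @param x,y Numeric vectors.
#' @param tx,ty Timestamp vectors (seconds), one per sample.
#'
#' @return List with aligned `x`, `y` and common `t`, all equal length.
#' @export
synchronize <- function(x, tx, y, ty) {
  stopifnot(length(x) == length(tx), length(y) == length(ty))
  t0 <- max(tx[1], ty[1])
  t1 <- min(tx[length(tx)], ty[length(ty)])
  if (t0 > t1) stop("streams do not overlap in time")
  dtx <- if (length(tx) > 1) tx[2] - tx[1] else 1
  tol <- dtx / 2
  ix <- which(tx >= t0 - tol & tx <= t1 + tol)
  iy <- which(ty >= t0 - tol & ty <= t1 + tol)
  n <- min(length(ix), length(iy))
  ix <- ix[seq_len(n)]; iy <- iy[seq_len(n)]
  list(x = x[ix], y = y[iy], t = tx[ix])
}

#' Normalize amplitude to [-1, 1]
#'
#' Per-recording division by the maximum absolute value. An all-zero input is
#' returned unchanged, so relative S1/S2 amplitude modulation across the
#' recording is preserved and no divide-by-zero can occur.
#'
#' @param x Numeric vector.
#' @return Vector with `max(abs(x)) == 1` (or all zeros).
#' @export
normalize_amplitude <- function(x) {
  if (!all(is.finite(x))) stop("input contains non-finite values")
  m <- max(abs(x))
  if (m == 0) return(x)
  x / m
}

#' First-order finite difference
#'
#' `d[n] = x[n] - x[n-1]` with `d[1] = 0`, preserving length. Emphasizes the
#' fast transients of S1 and S2.
#'
#' @param x Numeric vector of length >= 2.
#' @return Difference sequence of the same length.
#' @export
finite_difference <- function(x) {
  if (length(x) < 2) stop("input must have length >= 2")
  c(0, diff(x))
}

#' Homomorphic envelope
#'
#' `exp(LPF(log(|analytic(x)| + eps)))` with a zero-phase first-order
#' Butterworth low-pass: the smooth amplitude envelope conventionally used to
#' supervise heart-sound segmentation.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param lp_cutoff Low-pass cutoff in Hz (default 8).
#' @param eps Floor added before the logarithm.
#'
#' @return Non-negative envelope sequence; all-zero input gives all zeros.
#' @export
homomorphic_envelope <- function(x, fs = 500, lp_cutoff = 8, eps = 1e-8) {
  if (length(x) < 12) stop("input shorter than the filter warm-up")
  if (all(x == 0)) return(numeric(length(x)))
  env0 <- Mod(.analytic_signal(x))
  bf <- signal::butter(1, lp_cutoff / (fs / 2), type = "low")
  env <- exp(as.numeric(signal::filtfilt(bf, log(env0 + eps))))
  pmax(env, 0)
}

# Analytic signal via the frequency-domain Hilbert construction.
.analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Pre-process one recording into synchronized 500 Hz streams
#'
#' Runs the full radar chain (ellipse-fit I/Q compensation, DACM unwrapping,
#' displacement conversion, resampling to 500 Hz, [15, 150] Hz band-pass,
#' synchronization with the reference channel, per-recording normalization)
#' and assembles the feature streams consumed by the network: the radar
#' heart-sound signal, its first difference, the unfiltered (detrended)
#' displacement, plus reference waveform, envelope and labels when available.
#'
#' If the I/Q trajectory spans too small an arc for a conditioned ellipse fit
#' (e.g. during apnea the chest barely moves), compensation is skipped with a
#' warning; on small arcs the residual impairment mostly rescales amplitude,
#' which the band-pass and normalization absorb.
#'
#' @param rec A `synthetic_recording` (or compatible list with `iq`, `fs_raw`,
#'   and optionally `reference_pcg`, `reference_envelope`, `labels`).
#' @param compensate Apply ellipse-fitting I/Q compensation (default TRUE).
#' @param band Heart-sound passband in Hz.
#' @param fs Common analysis rate in Hz (default 500).
#' @param wavelength Radar wavelength in metres; taken from `rec$radar` when
#'   present.
#'
#' @return An object of class `preprocessed_pair` with streams `y_rad`,
#'   `dy_rad`, `displacement`, and (when available) `y_pcg`, `envelope`,
#'   `labels`, all sampled at `fs`.
#' @export
preprocess_recording <- function(rec, compensate = TRUE, band = c(15, 150),
                                 fs = 500, wavelength = NULL) {
  iq <- rec$iq
  fs_raw <- rec$fs_raw
  if (is.null(wavelength)) {
    wavelength <- if (!is.null(rec$radar)) rec$radar$wavelength else 0.0124913524
  }
  xc <- iq
  if (compensate) {
    # fit on an evenly spaced subsample: the ellipse has 5 parameters and a
    # few thousand samples are plenty
    sub <- iq[unique(round(seq(1, length(iq), length.out = min(length(iq), 4000))))]
    fit <- tryCatch(fit_ellipse(sub), error = function(e) e)
    if (inherits(fit, "error")) {
      warning("I/Q compensation skipped: ", conditionMessage(fit))
    } else {
      xc <- compensate_iq(iq, fit)
    }
  }
  track <- dacm_unwrap(xc)
  disp <- phase_to_displacement(track, wavelength)
  disp <- disp - mean(disp)

  disp_fs <- resample_to_common(disp, fs_raw, fs)
  y_rad <- bandpass_hs(disp_fs, fs = fs, band = band)

  out <- list(fs = fs)
  n <- length(y_rad)
  t_rad <- (seq_len(n) - 1) / fs
  if (!is.null(rec$reference_pcg)) {
    y_pcg <- rec$reference_pcg
    t_pcg <- (seq_along(y_pcg) - 1) / fs
    al <- synchronize(y_rad, t_rad, y_pcg, t_pcg)
    idx <- seq_along(al$x)
    y_rad <- al$x
    out$y_pcg <- normalize_amplitude(al$y)
    if (!is.null(rec$reference_envelope)) {
      out$envelope <- rec$reference_envelope[idx]
    }
    disp_fs <- disp_fs[idx]
    n <- length(y_rad)
  }
  out$y_rad <- normalize_amplitude(y_rad)
  out$dy_rad <- finite_difference(out$y_rad)
  out$displacement <- disp_fs - mean(disp_fs)
  if (!is.null(rec$labels)) {
    # nearest-neighbour transfer of the categorical labels onto the fs grid
    t5 <- (seq_len(n) - 1) / fs
    src <- pmin(pmax(round(t5 * fs_raw) + 1, 1), length(rec$labels))
    out$labels <- rec$labels[src]
  }
  out$subject_id <- rec$subject_id
  out$scenario <- rec$scenario
  structure(out, class = "preprocessed_pair")
}

#' Cut a pre-processed recording into fixed-length analysis windows
#'
#' Blocks of exactly `ns` samples (4 s at 500 Hz by default). The training
#' convention uses a 50% hop for augmentation; evaluation uses non-overlapping
#' windows. A trailing remainder shorter than `ns` is dropped.
#'
#' @param pair A `preprocessed_pair`.
#' @param ns Window length in samples (default 2000).
#' @param hop Hop between window starts in samples (default `ns`).
#'
#' @return An object of class `window_batch`: list with `starts` (1-based
#'   start indices), `ns`, and the originating `pair`.
#' @export
window_segments <- function(pair, ns = 2000, hop = ns) {
  n <- length(pair$y_rad)
  if (n < ns) {
    warning("recording shorter than one window (", n, " < ", ns, " samples)")
    starts <- integer(0)
  } else {
    starts <- seq(1L, n - ns + 1L, by = hop)
  }
  structure(list(starts = as.integer(starts), ns = as.integer(ns), pair = pair),
            class = "window_batch")
}
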
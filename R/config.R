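#' Radar configuration
#'
#' Parameters of the continuous-wave Doppler radar front end. The wavelength
#' is derived from the carrier frequency, and the constant phase offset from
#' the nominal radar-to-chest distance.
#'
#' @param carrier_frequency Carrier frequency in Hz (default 24 GHz).
#' @param nominal_range Nominal radar-to-chest distance R0 in metres.
#' @param amplitude Baseband signal amplitude a (dimensionless).
#' @param noise_std Standard deviation of the additive Gaussian noise applied
#'   independently to the I and Q components.
#' @param fs_raw Raw simulation sampling rate in Hz. Must be at least four
#'   times the highest simulated heart-sound frequency.
#'
#' @return An object of class `radar_config`.
#' @export
radar_config <- function(carrier_frequency = 24e9, nominal_range = 0.5,
                         amplitude = 1, noise_std = 0, fs_raw = 2000) {
  stopifnot(carrier_frequency > 0, nominal_range > 0, amplitude > 0, fs_raw > 0)
  if (noise_std < 0) stop("noise_std must be >= 0")
  wavelength <- .SPEED_OF_LIGHT / carrier_frequency
  structure(list(
    carrier_frequency = carrier_frequency,
    wavelength = wavelength,
    nominal_range = nominal_range,
    amplitude = amplitude,
    noise_std = noise_std,
    fs_raw = fs_raw,
    constant_phase = 4 * pi * nominal_range / wavelength
  ), class = "radar_config")
}

#' I/Q channel impairments
#'
#' Amplitude mismatches, phase imbalance and DC offsets of the quadrature
#' receiver. The identity impairment (1, 1, 0, 0, 0) leaves the circular
#' baseband trajectory untouched; any other setting turns it into an ellipse.
#'
#' @param AI,AQ Amplitude mismatches of the I and Q channels (> 0).
#' @param psi_e Phase imbalance in radians.
#' @param OI,OQ DC offsets of the I and Q channels.
#'
#' @return An object of class `iq_impairments`.
#' @export
iq_impairments <- function(AI = 1, AQ = 1, psi_e = 0, OI = 0, OQ = 0) {
  if (AI <= 0 || AQ <= 0) stop("amplitude mismatches AI and AQ must be > 0")
  structure(list(AI = AI, AQ = AQ, psi_e = psi_e, OI = OI, OQ = OQ),
            class = "iq_impairments")
}

#' Physiological configuration for the displacement simulator
#'
#' Describes the cardiorespiratory motion superimposed on the chest wall:
#' millimetre-scale respiration and heartbeat displacements, micrometre-scale
#' heart-sound bursts, respiratory amplitude modulation of the S1/S2 peaks
#' (peak envelope variation), inspiratory S2 splitting, and a slow
#' random-body-movement drift.
#'
#' @param heart_rate Heart rate in beats per minute.
#' @param breath_rate Breath rate in breaths per minute.
#' @param resp_amplitude Respiration displacement amplitude in mm.
#' @param heartbeat_amplitude Heartbeat (mechanical wall motion) amplitude in mm.
#' @param hs_amplitude Heart-sound burst amplitude in micrometres.
#' @param s1_duration,s2_duration Durations of the S1 and S2 sounds in seconds.
#' @param systole_fraction Fraction of the RR interval from S1 onset to S2
#'   onset (0 < fraction < 1).
#' @param s1_center_freq,s2_center_freq Centre frequencies of the S1 and S2
#'   bursts in Hz; both must lie inside the [15, 150] Hz heart-sound band.
#' @param envelope_modulation_depth Fractional respiratory modulation of the
#'   S1/S2 peak amplitudes, in [0, 1).
#' @param s2_split_max Maximum inspiratory separation between the aortic and
#'   pulmonary components of S2, in seconds.
#' @param rbm_std Random-body-movement random-walk scale in mm.
#' @param hr_jitter Fractional beat-to-beat jitter of the RR interval.
#'
#' @return An object of class `physio_config`.
#' @export
physio_config <- function(heart_rate = 70, breath_rate = 15,
                          resp_amplitude = 2, heartbeat_amplitude = 0.5,
                          hs_amplitude = 10,
                          s1_duration = 0.122, s2_duration = 0.092,
                          systole_fraction = 0.37,
                          s1_center_freq = 45, s2_center_freq = 65,
                          envelope_modulation_depth = 0.3,
                          s2_split_max = 0.03, rbm_std = 0.02,
                          hr_jitter = 0.03) {
  amps <- c(resp_amplitude, heartbeat_amplitude, hs_amplitude, rbm_std,
            s2_split_max, hr_jitter)
  if (any(amps < 0)) stop("all amplitudes and scales must be >= 0")
  stopifnot(heart_rate > 0, breath_rate >= 0,
            s1_duration > 0, s2_duration > 0,
            systole_fraction > 0, systole_fraction < 1,
            envelope_modulation_depth >= 0, envelope_modulation_depth < 1)
  rr <- 60 / heart_rate
  if (s1_duration + s2_duration >= rr) {
    stop("s1_duration + s2_duration must be shorter than the RR interval")
  }
  if (s1_center_freq < 15 || s1_center_freq > 150 ||
      s2_center_freq < 15 || s2_center_freq > 150) {
    stop("S1/S2 centre frequencies must lie within [15, 150] Hz")
  }
  structure(list(
    heart_rate = heart_rate, breath_rate = breath_rate,
    resp_amplitude = resp_amplitude,
    heartbeat_amplitude = heartbeat_amplitude,
    hs_amplitude = hs_amplitude,
    s1_duration = s1_duration, s2_duration = s2_duration,
    systole_fraction = systole_fraction,
    s1_center_freq = s1_center_freq, s2_center_freq = s2_center_freq,
    envelope_modulation_depth = envelope_modulation_depth,
    s2_split_max = s2_split_max, rbm_std = rbm_std, hr_jitter = hr_jitter
  ), class = "physio_config")
}
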
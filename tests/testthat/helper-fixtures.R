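# Shared fixtures: built in code, kept small so the suite stays fast.

# A short, clean (noise-free, identity-impairment) resting recording.
clean_recording <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_recording(
        physio_config(), radar_config(noise_std = 0), iq_impairments(),
        duration = 12, seed = 101)
    }
    cache
  }
})

# Distorted I/Q samples from the quadrature-imbalance model, noise-free.
impaired_iq <- function(psi, imp, amplitude = 1) {
  complex(real = imp$AI * amplitude * cos(psi) + imp$OI,
          imaginary = imp$AQ * amplitude * sin(psi + imp$psi_e) + imp$OQ)
}
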
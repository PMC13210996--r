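# Recording container I/O: persistent storage of (synthetic or imported)
# recordings, WAV export of the 500 Hz reference waveforms, and the thin
# loader for an externally converted copy of the public radar-PCG dataset.

#' Save a collection of recordings
#'
#' Serializes recordings (with their configurations and seeds) to a single
#' container file.
#'
#' @param recordings List of recording objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_recordings <- function(recordings, path) {
  saveRDS(recordings, path)
  invisible(path)
}

#' Load a collection of recordings
#'
#' @param path File written by [save_recordings()].
#' @return List of recording objects.
#' @export
load_recordings <- function(path) {
  if (!file.exists(path)) stop("no such recording container: ", path)
  readRDS(path)
}

#' Write a mono 16-bit PCM WAV file
#'
#' Exports a waveform in [-1, 1] (e.g. a 500 Hz reference PCG) as playable
#' audio. Hand-written RIFF/WAVE writer: values are clipped to [-1, 1] and
#' quantized to 16 bits.
#'
#' @param x Numeric vector in [-1, 1].
#' @param path Output file path.
#' @param fs Sampling rate in Hz (default 500).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs = 500) {
  pcm <- as.integer(round(pmin(pmax(x, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Load a locally converted copy of the public radar-PCG dataset
#'
#' Thin loader for the synchronized 24 GHz radar / digital-stethoscope
#' dataset, after the user has downloaded it and converted each acquisition
#' to CSV. No network access is performed. Expected layout:
#' a directory containing one `<subject>_<scenario>_<k>.csv` file per
#' acquisition with columns `radar_i`, `radar_q` (baseband I/Q at `fs_raw`)
#' and optionally `pcg` (stethoscope channel at the same rate), plus a
#' `manifest.json` with the field `fs_raw`.
#'
#' @param path Directory with the converted acquisitions.
#' @return List of recording objects compatible with
#'   [preprocess_recording()].
#' @export
load_public_dataset <- function(path) {
  if (!dir.exists(path)) {
    stop("dataset directory not found: ", path,
         "\nDownload the public radar-PCG dataset and convert it to the ",
         "documented CSV layout first; see ?load_public_dataset.")
  }
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("missing manifest.json in ", path)
  }
  manifest <- jsonlite::read_json(manifest_path)
  if (is.null(manifest$fs_raw)) stop("manifest.json lacks the fs_raw field")
  fs_raw <- as.numeric(manifest$fs_raw)
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop("no acquisition CSV files in ", path)
  lapply(files, function(f) {
    d <- utils::read.csv(f)
    if (!all(c("radar_i", "radar_q") %in% names(d))) {
      stop("malformed acquisition file (need radar_i, radar_q columns): ", f)
    }
    parts <- strsplit(sub("\\.csv$", "", basename(f)), "_")[[1]]
    rec <- list(
      subject_id = parts[1],
      scenario = if (length(parts) > 1) parts[2] else "unknown",
      fs_raw = fs_raw,
      iq = complex(real = d$radar_i, imaginary = d$radar_q)
    )
    if ("pcg" %in% names(d)) {
      ref <- normalize_amplitude(
        resample_to_common(bandpass_hs(d$pcg, fs = fs_raw), fs_raw, 500))
      rec$reference_pcg <- ref
      rec$reference_envelope <- homomorphic_envelope(ref, 500)
    }
    class(rec) <- "radar_recording"
    rec
  })
}
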
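# Multitask training objective: waveform (L1 + multi-resolution STFT),
# segmentation (class-weighted cross-entropy + soft Dice), envelope (MAE),
# combined as alpha * L_wav + beta * L_seg + gamma * L_env.

#' Loss weights
#'
#' Weights of the waveform, segmentation and envelope objectives in the total
#' multitask loss. Defaults are the balanced setting 0.70 / 0.20 / 0.10.
#'
#' @param alpha,beta,gamma Non-negative weights, not all zero.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 0.70, beta = 0.20, gamma = 0.10) {
  if (alpha < 0 || beta < 0 || gamma < 0) stop("loss weights must be >= 0")
  if (alpha + beta + gamma == 0) stop("loss weights must not all be zero")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "loss_weights")
}

#' Multi-resolution STFT loss configuration
#'
#' Three Hann-windowed resolutions trading temporal against spectral
#' resolution: FFT sizes 32 / 128 / 512 with hop sizes 8 / 32 / 128.
#'
#' @param fft_sizes Integer vector of FFT sizes.
#' @param hop_sizes Integer vector of hop sizes, one per FFT size.
#' @return An object of class `stft_loss_config`.
#' @export
stft_loss_config <- function(fft_sizes = c(32, 128, 512),
                             hop_sizes = c(8, 32, 128)) {
  if (length(fft_sizes) != length(hop_sizes)) {
    stop("fft_sizes and hop_sizes must have equal length")
  }
  if (any(hop_sizes >= fft_sizes)) stop("hop sizes must be smaller than FFT sizes")
  structure(list(fft_sizes = as.integer(fft_sizes),
                 hop_sizes = as.integer(hop_sizes)),
            class = "stft_loss_config")
}

# Periodic Hann window (STFT convention).
.hann <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

# One-sided magnitude spectrogram: rows = frequency bins, cols = frames.
.stft_mag <- function(x, nfft, hop, return_complex = FALSE) {
  n <- length(x)
  if (n < nfft) stop("signal shorter than the FFT size (", nfft, ")")
  starts <- seq(1L, n - nfft + 1L, by = hop)
  frames <- matrix(x[outer(0:(nfft - 1L), starts, "+")], nfft, length(starts))
  frames <- frames * .hann(nfft)
  Z <- mvfft(frames)[1:(nfft %/% 2 + 1), , drop = FALSE]
  if (return_complex) Z else Mod(Z)
}

#' Mean absolute error (L1) loss
#'
#' @param yhat,y Equal-length numeric vectors (or arrays).
#' @return Mean absolute difference.
#' @export
l1_loss <- function(yhat, y) {
  if (length(yhat) != length(y)) stop("length mismatch")
  mean(abs(yhat - y))
}

#' Multi-resolution STFT magnitude loss
#'
#' Mean absolute difference between the Hann-windowed magnitude spectrograms
#' of the two signals, averaged across the configured resolutions. Blind to
#' sign flips (magnitude only).
#'
#' @param yhat,y Equal-length numeric vectors.
#' @param config An [stft_loss_config()].
#' @return Non-negative scalar.
#' @export
multires_stft_loss <- function(yhat, y, config = stft_loss_config()) {
  if (length(yhat) != length(y)) stop("length mismatch")
  if (length(yhat) < max(config$fft_sizes)) {
    stop("signal shorter than the largest FFT size")
  }
  terms <- mapply(function(nfft, hop) {
    mean(abs(.stft_mag(yhat, nfft, hop) - .stft_mag(y, nfft, hop)))
  }, config$fft_sizes, config$hop_sizes)
  mean(terms)
}

#' Waveform reconstruction loss
#'
#' Equal mix of the time-domain L1 loss and the multi-resolution STFT loss:
#' `0.5 * L1 + 0.5 * STFT`.
#'
#' @inheritParams multires_stft_loss
#' @return Non-negative scalar.
#' @export
waveform_loss <- function(yhat, y, config = stft_loss_config()) {
  0.5 * l1_loss(yhat, y) + 0.5 * multires_stft_loss(yhat, y, config)
}

#' Per-class weights from state counts
#'
#' Square root of the inverse relative frequency, `w_c = sqrt(mean(n) / n_c)`,
#' rescaled to unit mean so that rare states (typically S2) receive larger
#' penalties without destabilizing the loss scale.
#'
#' @param counts Vector of 4 positive per-state sample counts
#'   (S1, systole, S2, diastole).
#' @return An object of class `class_weights` (numeric, unit mean).
#' @export
class_weights <- function(counts) {
  if (length(counts) != 4) stop("counts must have length 4")
  if (any(counts <= 0)) {
    stop("all four cardiac phases must be present in the weighting window")
  }
  w <- sqrt(mean(counts) / counts)
  w <- w / mean(w)
  names(w) <- names(cardiac_states())
  structure(w, class = "class_weights")
}

# softmax over the class dimension of a (4, n) matrix
.softmax_classes <- function(z) {
  mx <- apply(z, 2, max)
  e <- exp(z - rep(mx, each = nrow(z)))
  e / rep(colSums(e), each = nrow(z))
}

#' Segmentation loss (weighted cross-entropy + soft Dice)
#'
#' `0.7 * CE + 0.3 * Dice` with per-class weights applied to both terms.
#' The cross-entropy is computed per sample and normalized by the sum of the
#' applied weights; the Dice term is `1 -` the class-weighted average of the
#' smoothed soft Dice coefficients computed from the softmax probabilities.
#'
#' @param logits Array (4, T, B), matrix (4, n) or vector of logits.
#' @param labels Integer state codes in 0..3 (see [cardiac_states()]).
#' @param weights A [class_weights()] vector (default: uniform).
#' @param ce_weight,dice_weight Mixing weights (defaults 0.7 / 0.3).
#' @param eps Dice smoothing constant.
#' @return Non-negative scalar.
#' @export
segmentation_loss <- function(logits, labels, weights = rep(1, 4),
                              ce_weight = 0.7, dice_weight = 0.3, eps = 1e-6) {
  sl <- .segmentation_loss_grad(logits, labels, weights, ce_weight,
                                dice_weight, eps, want_grad = FALSE)
  sl$value
}

.segmentation_loss_grad <- function(logits, labels, weights, ce_weight = 0.7,
                                    dice_weight = 0.3, eps = 1e-6,
                                    want_grad = TRUE) {
  z <- matrix(logits, nrow = 4)
  lab <- as.integer(labels)
  if (ncol(z) != length(lab)) stop("logits / labels shape mismatch")
  if (any(lab < 0 | lab > 3)) stop("labels must lie in 0..3")
  n <- length(lab)
  p <- .softmax_classes(z)
  idx <- cbind(lab + 1L, seq_len(n))
  w_n <- weights[lab + 1L]
  wsum <- sum(w_n)

  ce <- sum(w_n * (-log(pmax(p[idx], 1e-12)))) / wsum

  onehot <- matrix(0, 4, n)
  onehot[idx] <- 1
  s_pc <- rowSums(p * onehot)
  s_p <- rowSums(p)
  s_y <- rowSums(onehot)
  dice_c <- (2 * s_pc + eps) / (s_p + s_y + eps)
  dice <- 1 - sum(weights * dice_c) / sum(weights)

  value <- ce_weight * ce + dice_weight * dice
  if (!want_grad) return(list(value = value, ce = ce, dice = dice))

  # cross-entropy gradient wrt logits
  dz_ce <- p * rep(w_n, each = 4)
  dz_ce[idx] <- dz_ce[idx] - w_n
  dz_ce <- dz_ce / wsum

  # dice gradient wrt probabilities, then through softmax
  denom <- (s_p + s_y + eps)
  ddice_dp <- -(weights / sum(weights)) *
    (2 * onehot * denom - (2 * s_pc + eps)) / denom^2
  dz_dice <- p * (ddice_dp - rep(colSums(ddice_dp * p), each = 4))

  dz <- ce_weight * dz_ce + dice_weight * dz_dice
  list(value = value, ce = ce, dice = dice,
       grad = array(dz, dim = if (is.null(dim(logits))) c(4, n) else dim(logits)))
}

#' Envelope loss
#'
#' Mean absolute error between the reconstructed and reference envelopes.
#'
#' @param ehat,e Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
envelope_loss <- function(ehat, e) l1_loss(ehat, e)

#' Total multitask loss
#'
#' `alpha * L_wav + beta * L_seg + gamma * L_env` with a per-term breakdown.
#'
#' @param outputs List with `waveform`, `envelope` and `logits` (e.g. a
#'   `model_outputs`).
#' @param targets List with `waveform`, `envelope` and `labels`.
#' @param weights A [loss_weights()].
#' @param cls_weights A [class_weights()] vector (default uniform).
#' @param stft_config An [stft_loss_config()].
#' @return List with `total` and the per-term breakdown
#'   (`waveform`, `segmentation`, `envelope`).
#' @export
total_loss <- function(outputs, targets, weights = loss_weights(),
                       cls_weights = rep(1, 4),
                       stft_config = stft_loss_config()) {
  lw <- waveform_loss(as.numeric(outputs$waveform), as.numeric(targets$waveform),
                      stft_config)
  ls <- segmentation_loss(outputs$logits, targets$labels, cls_weights)
  le <- envelope_loss(as.numeric(outputs$envelope), as.numeric(targets$envelope))
  list(total = weights$alpha * lw + weights$beta * ls + weights$gamma * le,
       waveform = lw, segmentation = ls, envelope = le)
}

# ---------------------------------------------------------------------------
# gradient versions used by the trainer (batched, per-window normalization)

# L1 with gradient; x, y arrays of equal shape
.l1_grad <- function(yhat, y) {
  d <- yhat - y
  list(value = mean(abs(d)), grad = array(sign(d) / length(d), dim(yhat)))
}

# multi-resolution STFT loss with gradient wrt yhat, for one signal vector
.stft_grad_one <- function(yhat, y, config) {
  n <- length(yhat)
  val <- 0
  grad <- numeric(n)
  nres <- length(config$fft_sizes)
  for (r in seq_len(nres)) {
    nfft <- config$fft_sizes[r]; hop <- config$hop_sizes[r]
    w <- .hann(nfft)
    starts <- seq(1L, n - nfft + 1L, by = hop)
    idx <- outer(0:(nfft - 1L), starts, "+")
    fh <- matrix(yhat[idx], nfft, length(starts)) * w
    fy <- matrix(y[idx], nfft, length(starts)) * w
    Zh <- mvfft(fh); Zy <- mvfft(fy)
    nb <- nfft %/% 2 + 1
    Mh <- Mod(Zh[1:nb, , drop = FALSE]); My <- Mod(Zy[1:nb, , drop = FALSE])
    nelem <- nb * length(starts)
    val <- val + mean(abs(Mh - My)) / nres
    dM <- sign(Mh - My) / (nelem * nres)
    safe <- pmax(Mh, 1e-20)
    dZtop <- dM * (Zh[1:nb, , drop = FALSE] / safe)
    dZ <- matrix(0 + 0i, nfft, length(starts))
    dZ[1:nb, ] <- dZtop
    dframes <- Re(mvfft(dZ, inverse = TRUE)) * w
    # overlap-add back into the signal gradient
    for (f in seq_along(starts)) {
      rng <- starts[f]:(starts[f] + nfft - 1L)
      grad[rng] <- grad[rng] + dframes[, f]
    }
  }
  list(value = val, grad = grad)
}
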
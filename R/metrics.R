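# Evaluation metrics: log-spectral distance, envelope correlation, confusion
# matrices and F1 scores, per-state run statistics, and event-based S1/S2
# detection scoring with a +/-100 ms tolerance.

#' Log-spectral distance (dB)
#'
#' Frame-wise root-mean-square over frequency bins of
#' `20 * log10(|Y| / |Yhat|)`, averaged over frames. Magnitudes are floored
#' before the ratio so silent bins cannot produce infinities.
#'
#' @param y Reference signal.
#' @param yhat Estimated signal of equal length.
#' @param nfft FFT size (default 256).
#' @param hop Hop size (default 128).
#' @param floor_mag Magnitude floor (default 1e-8).
#' @return LSD in dB (>= 0).
#' @export
lsd <- function(y, yhat, nfft = 256, hop = 128, floor_mag = 1e-8) {
  if (length(y) != length(yhat)) stop("length mismatch")
  My <- pmax(.stft_mag(y, nfft, hop), floor_mag)
  Mh <- pmax(.stft_mag(yhat, nfft, hop), floor_mag)
  r <- 20 * log10(My / Mh)
  mean(sqrt(colMeans(r^2)))
}

#' Pearson correlation between envelopes
#'
#' Standard sample Pearson correlation; invariant to positive affine maps of
#' either argument.
#'
#' @param e,ehat Equal-length numeric vectors with non-zero variance.
#' @return Correlation in [-1, 1].
#' @export
envelope_pearson <- function(e, ehat) {
  if (length(e) != length(ehat)) stop("length mismatch")
  if (length(e) < 2) stop("need at least two samples")
  if (sd(e) == 0 || sd(ehat) == 0) stop("zero-variance input")
  cor(e, ehat)
}

#' Four-state confusion matrix
#'
#' Counts with rows indexed by the reference state and columns by the
#' predicted state (S1, systole, S2, diastole).
#'
#' @param ref,pred Equal-length integer label vectors with codes in 0..3.
#' @return A 4 x 4 integer matrix of class `confusion_matrix4`.
#' @export
confusion_matrix <- function(ref, pred) {
  if (length(ref) != length(pred)) stop("length mismatch")
  if (any(ref < 0 | ref > 3 | pred < 0 | pred > 3)) {
    stop("labels must lie in 0..3")
  }
  lv <- 0:3
  cm <- table(factor(ref, levels = lv), factor(pred, levels = lv))
  cm <- matrix(as.integer(cm), 4, 4,
               dimnames = list(ref = names(cardiac_states()),
                               pred = names(cardiac_states())))
  structure(cm, class = c("confusion_matrix4", "matrix"))
}

#' Row-normalize a confusion matrix
#'
#' @param cm A 4 x 4 confusion matrix.
#' @return Matrix whose rows sum to 1 (rows of absent classes stay 0).
#' @export
row_normalize <- function(cm) {
  rs <- rowSums(cm)
  out <- cm / ifelse(rs == 0, 1, rs)
  unclass(out)
}

#' Segmentation report from a confusion matrix
#'
#' Per-class precision, recall and F1, the unweighted macro-F1, and the
#' micro-F1 aggregating true/false positives and negatives across classes
#' (equal to accuracy for exhaustive single-label streams). Classes with no
#' predictions or no reference samples score 0 for the undefined ratio.
#'
#' @param cm A 4 x 4 confusion matrix (rows = reference, cols = predicted).
#' @return An object of class `segmentation_report`.
#' @export
segmentation_report <- function(cm) {
  if (sum(cm) == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  micro <- 2 * sum(tp) / (2 * sum(tp) + sum(fp) + sum(fn))
  structure(list(precision = precision, recall = recall, f1 = f1,
                 macro_f1 = mean(f1), micro_f1 = micro,
                 confusion = unclass(cm)),
            class = "segmentation_report")
}

#' @export
print.segmentation_report <- function(x, ...) {
  tab <- rbind(precision = x$precision, recall = x$recall, f1 = x$f1)
  print(round(100 * tab, 2))
  cat(sprintf("micro-F1 %.2f%%  macro-F1 %.2f%%\n",
              100 * x$micro_f1, 100 * x$macro_f1))
  invisible(x)
}

#' Per-state duration and occupancy statistics
#'
#' Collects contiguous runs of each state and reports the mean and standard
#' deviation of the run durations plus the percentage of occupied time.
#'
#' @param labels Integer state codes in 0..3.
#' @param fs Sampling rate in Hz.
#' @return Data frame with one row per state: `state`, `mean_duration`,
#'   `sd_duration` (seconds), `share` (percent of samples).
#' @export
state_statistics <- function(labels, fs) {
  if (length(labels) == 0) stop("empty label stream")
  r <- rle(as.integer(labels))
  st <- cardiac_states()
  out <- lapply(names(st), function(nm) {
    code <- st[[nm]]
    runs <- r$lengths[r$values == code]
    data.frame(state = nm,
               mean_duration = if (length(runs)) mean(runs / fs) else NA_real_,
               sd_duration = if (length(runs) > 1) sd(runs / fs) else NA_real_,
               share = 100 * sum(labels == code) / length(labels))
  })
  do.call(rbind, out)
}

#' Extract event times from a label stream
#'
#' Reduces each maximal run of the requested state to its centre time; runs
#' shorter than `min_run` are discarded as spurious.
#'
#' @param labels Integer state codes in 0..3.
#' @param fs Sampling rate in Hz.
#' @param state `"S1"` or `"S2"` (or a state code).
#' @param min_run Minimum run duration in seconds (default 0.02).
#' @return Numeric vector of event times in seconds.
#' @export
extract_events <- function(labels, fs, state = "S1", min_run = 0.02) {
  code <- if (is.character(state)) cardiac_states()[[state]] else as.integer(state)
  r <- rle(as.integer(labels) == code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run * fs
  if (!any(keep)) return(numeric(0))
  # centre of the run, with sample i covering time (i-1)/fs
  ((starts[keep] - 1) + (ends[keep] - 1)) / 2 / fs
}

#' Match predicted and reference events within a tolerance
#'
#' Greedy one-to-one matching in order of increasing time difference within
#' the tolerance window (default +/-100 ms). Matched pairs count as true
#' positives; unmatched predictions as false positives; unmatched references
#' as false negatives.
#'
#' @param pred,ref Numeric event-time vectors (seconds); sorted internally.
#' @param tolerance Matching tolerance in seconds (default 0.100).
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
event_match <- function(pred, ref, tolerance = 0.100) {
  pred <- sort(pred); ref <- sort(ref)
  if (length(pred) == 0 || length(ref) == 0) {
    tp <- 0L
  } else {
    dt <- abs(outer(pred, ref, "-"))
    cand <- which(dt <= tolerance, arr.ind = TRUE)
    if (nrow(cand)) cand <- cand[order(dt[cand]), , drop = FALSE]
    used_p <- logical(length(pred)); used_r <- logical(length(ref))
    tp <- 0L
    for (i in seq_len(nrow(cand))) {
      pi <- cand[i, 1]; ri <- cand[i, 2]
      if (!used_p[pi] && !used_r[ri]) {
        used_p[pi] <- TRUE; used_r[ri] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- length(pred) - tp
  fn <- length(ref) - tp
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(tp = tp, fp = fp, fn = fn,
       precision = precision, recall = recall, f1 = f1)
}

#' Event-based S1/S2 evaluation
#'
#' Applies [extract_events()] and [event_match()] to both sound types and
#' reports per-type and combined F1 scores.
#'
#' @param pred_labels,ref_labels Label streams (codes 0..3) at rate `fs`, or
#'   lists with precomputed `s1` / `s2` event times.
#' @param fs Sampling rate in Hz.
#' @param tolerance Matching tolerance in seconds.
#' @return List with elements `s1`, `s2` (each an [event_match()] result) and
#'   `combined` (pooled counts and F1).
#' @export
event_report <- function(pred_labels, ref_labels, fs = 500, tolerance = 0.100) {
  get_events <- function(x, state) {
    if (is.list(x)) x[[tolower(state)]] else extract_events(x, fs, state)
  }
  s1 <- event_match(get_events(pred_labels, "S1"), get_events(ref_labels, "S1"),
                    tolerance)
  s2 <- event_match(get_events(pred_labels, "S2"), get_events(ref_labels, "S2"),
                    tolerance)
  tp <- s1$tp + s2$tp; fp <- s1$fp + s2$fp; fn <- s1$fn + s2$fn
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(s1 = s1, s2 = s2, combined = list(tp = tp, fp = fp, fn = fn, f1 = f1))
}
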
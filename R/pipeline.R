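# Experiment orchestration: subject-wise splitting, multitask training with
# AdamW, held-out evaluation against the radar-input baseline, and the
# end-to-end synthetic experiment.

#' Experiment configuration
#'
#' Bundles the data, model, loss and optimizer settings of one experiment.
#' Defaults follow the reference training protocol: AdamW with learning rate
#' 5e-5 and weight decay 3e-5, 50 epochs, batch size 32, 4 s windows of 2000
#' samples at 500 Hz, loss weights 0.70/0.20/0.10, and a subject-wise
#' train/validation/test split with one subject each for validation and test.
#'
#' @param input_variant `"radar_hs"` (1-channel final model) or `"baseline3"`
#'   (radar HS + derivative + displacement).
#' @param weights A [loss_weights()].
#' @param learning_rate,weight_decay AdamW settings.
#' @param epochs,batch_size Training schedule.
#' @param window,hop,eval_hop Window length and hops (samples at 500 Hz);
#'   training windows overlap 50% by default, evaluation windows do not.
#' @param n_val,n_test Subjects held out for validation / testing.
#' @param seed Master seed (data order, initialization, dropout).
#' @param model A [model_config()]; its `in_channels` is forced to match
#'   `input_variant`.
#' @param stft An [stft_loss_config()].
#'
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(input_variant = c("radar_hs", "baseline3"),
                              weights = loss_weights(),
                              learning_rate = 5e-5, weight_decay = 3e-5,
                              epochs = 50, batch_size = 32,
                              window = 2000, hop = 1000, eval_hop = 2000,
                              adam_beta2 = 0.999,
                              n_val = 1, n_test = 1, seed = 1,
                              model = model_config(),
                              stft = stft_loss_config()) {
  input_variant <- match.arg(input_variant)
  stopifnot(batch_size >= 1, epochs >= 1, window %% 2^model$depth == 0)
  model$in_channels <- if (input_variant == "radar_hs") 1L else 3L
  structure(list(
    input_variant = input_variant, weights = weights,
    learning_rate = learning_rate, weight_decay = weight_decay,
    epochs = epochs, batch_size = batch_size, window = window, hop = hop,
    eval_hop = eval_hop, n_val = n_val, n_test = n_test, seed = seed,
    adam_beta2 = adam_beta2,
    model = model, stft = stft
  ), class = "experiment_config")
}

#' Subject-wise train/validation/test split
#'
#' Disjoint subject sets, deterministic given the seed, so no subject leaks
#' across splits.
#'
#' @param subject_ids Character vector of unique subject identifiers.
#' @param n_val,n_test Held-out subjects per split.
#' @param seed Integer seed.
#' @return List with `train`, `val`, `test` character vectors.
#' @export
split_subjects <- function(subject_ids, n_val = 1, n_test = 1, seed = 1) {
  ids <- unique(subject_ids)
  if (length(ids) < n_val + n_test + 1) {
    stop("need at least ", n_val + n_test + 1, " subjects")
  }
  ord <- with_seed(seed, sample(ids))
  list(test = ord[seq_len(n_test)],
       val = ord[n_test + seq_len(n_val)],
       train = ord[-(seq_len(n_test + n_val))])
}

#' Enumerate test/validation rotations
#'
#' For each subject used as the test set, enumerates `n_rot` different
#' validation subjects (cyclically), supporting repeated-split evaluation
#' protocols.
#'
#' @param subject_ids Character vector of unique subject identifiers.
#' @param n_rot Validation rotations per test subject.
#' @return List of splits as returned by [split_subjects()].
#' @export
subject_rotations <- function(subject_ids, n_rot = 5) {
  ids <- unique(subject_ids)
  n <- length(ids)
  if (n < 3) stop("need at least 3 subjects")
  out <- list()
  for (i in seq_len(n)) {
    others <- ids[-i]
    for (r in seq_len(min(n_rot, n - 2))) {
      out[[length(out) + 1L]] <- list(test = ids[i], val = others[r],
                                      train = setdiff(others, others[r]))
    }
  }
  out
}

# Assemble the network input matrix (channels x ns) for one window.
.window_input <- function(pair, start, ns, variant) {
  idx <- start:(start + ns - 1L)
  if (variant == "radar_hs") {
    matrix(pair$y_rad[idx], 1, ns)
  } else {
    rbind(pair$y_rad[idx], pair$dy_rad[idx],
          normalize_amplitude(pair$displacement)[idx])
  }
}

.window_targets <- function(pair, start, ns) {
  idx <- start:(start + ns - 1L)
  list(waveform = pair$y_pcg[idx], envelope = pair$envelope[idx],
       labels = pair$labels[idx])
}

# Enumerate (pair index, window start) tuples for a set of pairs.
.enumerate_windows <- function(pairs, ns, hop) {
  out <- list()
  for (i in seq_along(pairs)) {
    n <- length(pairs[[i]]$y_rad)
    if (n < ns) next
    starts <- seq(1L, n - ns + 1L, by = hop)
    out[[i]] <- cbind(pair = i, start = starts)
  }
  do.call(rbind, out)
}

# Stack windows into a batch: input (C, ns, B) and targets.
.assemble_batch <- function(pairs, wins, ns, variant) {
  B <- nrow(wins)
  x <- NULL
  yw <- array(0, c(1, ns, B)); ye <- array(0, c(1, ns, B))
  lb <- matrix(0L, ns, B)
  for (b in seq_len(B)) {
    p <- pairs[[wins[b, 1]]]
    xin <- .window_input(p, wins[b, 2], ns, variant)
    if (is.null(x)) x <- array(0, c(nrow(xin), ns, B))
    x[, , b] <- xin
    tg <- .window_targets(p, wins[b, 2], ns)
    yw[1, , b] <- tg$waveform
    ye[1, , b] <- tg$envelope
    lb[, b] <- tg$labels
  }
  list(x = x, waveform = yw, envelope = ye, labels = lb)
}

# Multitask loss + gradients wrt the three output tensors, for one batch.
.batch_loss <- function(out, batch, w, cw, stft_cfg, want_grad = TRUE) {
  B <- dim(out$waveform)[3]
  ns <- dim(out$waveform)[2]
  # waveform: 0.5 L1 + 0.5 multi-resolution STFT (per window, batch-averaged)
  l1 <- .l1_grad(out$waveform, batch$waveform)
  stft_val <- 0
  stft_grad <- if (want_grad) array(0, dim(out$waveform)) else NULL
  for (b in seq_len(B)) {
    sg <- .stft_grad_one(as.numeric(out$waveform[1, , b]),
                         as.numeric(batch$waveform[1, , b]), stft_cfg)
    stft_val <- stft_val + sg$value / B
    if (want_grad) stft_grad[1, , b] <- sg$grad / B
  }
  lwav <- 0.5 * l1$value + 0.5 * stft_val
  seg <- .segmentation_loss_grad(out$logits, batch$labels, cw,
                                 want_grad = want_grad)
  env <- .l1_grad(out$envelope, batch$envelope)
  total <- w$alpha * lwav + w$beta * seg$value + w$gamma * env$value
  res <- list(total = total, waveform = lwav, segmentation = seg$value,
              envelope = env$value)
  if (want_grad) {
    res$dwav <- w$alpha * (0.5 * l1$grad + 0.5 * stft_grad)
    res$dseg <- w$beta * seg$grad
    res$denv <- w$gamma * env$grad
  }
  res
}

# ---- AdamW -----------------------------------------------------------------

.zeros_like <- function(p) {
  if (is.list(p)) lapply(p, .zeros_like)
  else if (is.null(p)) NULL
  else p * 0
}

.adamw_update <- function(p, g, m, v, lr, wd, b1, b2, eps, bc1, bc2) {
  if (is.list(p)) {
    for (nm in seq_along(p)) {
      key <- if (!is.null(names(p))) names(p)[nm] else nm
      gi <- if (!is.null(names(p)) && !is.null(names(g))) g[[key]] else g[[nm]]
      if (is.null(p[[nm]]) || is.null(gi)) next
      r <- .adamw_update(p[[nm]], gi, m[[nm]], v[[nm]], lr, wd, b1, b2, eps,
                         bc1, bc2)
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    list(p = p, m = m, v = v)
  } else {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    step <- (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p - lr * step - lr * wd * p, m = m, v = v)
  }
}

#' Train the multitask network
#'
#' Subject-wise splitting, per-epoch shuffling, AdamW updates and
#' best-validation checkpoint selection, all deterministically seeded.
#' Class weights for the segmentation loss are accumulated once over the
#' training split before the first epoch.
#'
#' @param config An [experiment_config()].
#' @param pairs List of `preprocessed_pair` objects (with targets).
#' @param split Optional list with `train`, `val`, `test` subject vectors;
#'   computed from `config$seed` when omitted.
#' @param verbose Print per-epoch losses.
#'
#' @return List with `model` (best-validation parameters), `history`
#'   (per-epoch loss breakdown data frame), `class_weights`, and `split`.
#' @export
train <- function(config, pairs, split = NULL, verbose = FALSE) {
  subj <- vapply(pairs, function(p) p$subject_id, "")
  if (is.null(split)) {
    split <- split_subjects(unique(subj), config$n_val, config$n_test,
                            config$seed)
  }
  tr_pairs <- pairs[subj %in% split$train]
  va_pairs <- pairs[subj %in% split$val]
  if (length(tr_pairs) == 0 || length(va_pairs) == 0) {
    stop("empty training or validation split")
  }
  ns <- config$window
  wins_tr <- .enumerate_windows(tr_pairs, ns, config$hop)
  wins_va <- .enumerate_windows(va_pairs, ns, config$eval_hop)
  if (is.null(wins_tr) || nrow(wins_tr) == 0) stop("no training windows")

  cw <- class_weights(vapply(0:3, function(k) {
    sum(vapply(tr_pairs, function(p) sum(p$labels == k), 0))
  }, 0))

  model <- build_model(config$model, seed = config$seed)
  m_state <- .zeros_like(model$params)
  v_state <- .zeros_like(model$params)
  b1 <- 0.9; b2 <- config$adam_beta2 %||% 0.999; eps <- 1e-8
  t_step <- 0L
  best <- list(val = Inf, params = model$params, epoch = 0L)
  hist <- list()

  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(nrow(wins_tr))
      ep_loss <- c(total = 0, waveform = 0, segmentation = 0, envelope = 0)
      nb <- 0L
      for (ofs in seq(1L, nrow(wins_tr), by = config$batch_size)) {
        sel <- ord[ofs:min(ofs + config$batch_size - 1L, nrow(wins_tr))]
        batch <- .assemble_batch(tr_pairs, wins_tr[sel, , drop = FALSE], ns,
                                 config$input_variant)
        fw <- .unet_fwd(model, batch$x, training = TRUE)
        bl <- .batch_loss(fw, batch, config$weights, cw, config$stft)
        grads <- .unet_bwd(model, fw$cache, bl$dwav, bl$denv, bl$dseg)
        t_step <- t_step + 1L
        upd <- .adamw_update(model$params, grads, m_state, v_state,
                             config$learning_rate, config$weight_decay,
                             b1, b2, eps, 1 - b1^t_step, 1 - b2^t_step)
        model$params <- upd$p; m_state <- upd$m; v_state <- upd$v
        ep_loss <- ep_loss + c(bl$total, bl$waveform, bl$segmentation,
                               bl$envelope)
        nb <- nb + 1L
      }
      ep_loss <- ep_loss / nb

      # validation loss (dropout off)
      va_loss <- 0; nv <- 0L
      for (ofs in seq(1L, nrow(wins_va), by = config$batch_size)) {
        sel <- ofs:min(ofs + config$batch_size - 1L, nrow(wins_va))
        batch <- .assemble_batch(va_pairs, wins_va[sel, , drop = FALSE], ns,
                                 config$input_variant)
        fw <- .unet_fwd(model, batch$x, training = FALSE)
        bl <- .batch_loss(fw, batch, config$weights, cw, config$stft,
                          want_grad = FALSE)
        va_loss <- va_loss + bl$total
        nv <- nv + 1L
      }
      va_loss <- va_loss / max(nv, 1L)
      if (va_loss < best$val) {
        best <- list(val = va_loss, params = model$params, epoch = ep)
      }
      hist[[ep]] <- data.frame(epoch = ep, train_total = ep_loss["total"],
                               train_waveform = ep_loss["waveform"],
                               train_segmentation = ep_loss["segmentation"],
                               train_envelope = ep_loss["envelope"],
                               val_total = va_loss, row.names = NULL)
      if (verbose) {
        message(sprintf("epoch %d: train %.4f  val %.4f", ep,
                        ep_loss["total"], va_loss))
      }
    }
  })
  model$params <- best$params
  list(model = model, history = do.call(rbind, hist), class_weights = cw,
       split = split, best_epoch = best$epoch)
}

#' Envelope-threshold baseline segmenter
#'
#' Simple plumbing used to score the radar input signal itself: bursts of the
#' homomorphic envelope above an adaptive threshold become candidate sounds,
#' alternately assigned to S1/S2 using the heuristic that the longer
#' inter-burst gap (diastole) follows S2; the gaps in between become systole
#' and diastole. Intended only as the "radar input" comparison stream, not as
#' a segmentation method.
#'
#' @param y Radar heart-sound signal at rate `fs`.
#' @param fs Sampling rate in Hz.
#' @return Integer label stream (codes 0..3).
#' @export
baseline_segment <- function(y, fs = 500) {
  n <- length(y)
  env <- homomorphic_envelope(y, fs)
  thr <- 0.4 * stats::quantile(env, 0.95)
  above <- env > thr
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 0.02 * fs
  labels <- rep(cardiac_states()[["diastole"]], n)
  if (sum(keep) < 2) return(as.integer(labels))
  bs <- starts[keep]; be <- ends[keep]
  centers <- (bs + be) / 2
  nb <- length(centers)
  gaps <- diff(centers)
  # classify each burst: S2 if the gap after it exceeds the gap before it
  is_s2 <- logical(nb)
  for (i in seq_len(nb)) {
    gb <- if (i > 1) gaps[i - 1] else Inf
    ga <- if (i < nb) gaps[i] else Inf
    is_s2[i] <- ga > gb
  }
  st <- cardiac_states()
  for (i in seq_len(nb)) {
    labels[bs[i]:be[i]] <- if (is_s2[i]) st[["S2"]] else st[["S1"]]
    if (i < nb) {
      mid <- (be[i] + 1):(bs[i + 1] - 1)
      if (length(mid)) {
        labels[mid] <- if (is_s2[i]) st[["diastole"]] else st[["systole"]]
      }
    }
  }
  as.integer(labels)
}

#' Evaluate a trained model on held-out recordings
#'
#' Scores non-overlapping windows with the waveform, envelope and
#' segmentation metrics, both for the model outputs and for the radar-input
#' baseline (the pre-processed radar signal itself, with labels from
#' [baseline_segment()]), and aggregates per subject and per scenario.
#'
#' @param model A trained `pcg_unet`.
#' @param pairs List of `preprocessed_pair` objects to score.
#' @param config The [experiment_config()] used in training.
#' @param train_subjects Optional subject vector for the leakage guard: an
#'   error is raised if any scored subject was trained on.
#'
#' @return An object of class `evaluation_report`: list with `windows`
#'   (per-window data frame), `by_subject`, `by_scenario`, and `aggregate`
#'   (model vs radar-input baseline vs improvement).
#' @export
evaluate <- function(model, pairs, config, train_subjects = NULL) {
  subj <- vapply(pairs, function(p) p$subject_id, "")
  if (!is.null(train_subjects) && any(subj %in% train_subjects)) {
    stop("leakage: subjects ", paste(intersect(subj, train_subjects),
                                     collapse = ", "),
         " appear in both training and evaluation sets")
  }
  ns <- config$window
  rows <- list()
  cm_model <- matrix(0L, 4, 4)
  cm_base <- matrix(0L, 4, 4)
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    base_labels <- baseline_segment(p$y_rad, p$fs)
    wins <- .enumerate_windows(pairs[i], ns, config$eval_hop)
    if (is.null(wins) || nrow(wins) == 0) next
    batch <- .assemble_batch(pairs[i], wins, ns, config$input_variant)
    fw <- .unet_fwd(model, batch$x, training = FALSE)
    for (b in seq_len(nrow(wins))) {
      idx <- wins[b, 2]:(wins[b, 2] + ns - 1L)
      y_ref <- as.numeric(batch$waveform[1, , b])
      # score the reconstruction inside the heart-sound band: the reference
      # and the radar input are band-limited to [15, 150] Hz by construction,
      # so out-of-band bins of a broadband estimate carry no information
      y_hat <- bandpass_hs(as.numeric(fw$waveform[1, , b]), fs = p$fs)
      y_in <- as.numeric(batch$x[1, , b])
      e_ref <- as.numeric(batch$envelope[1, , b])
      e_hat <- as.numeric(fw$envelope[1, , b])
      pred <- max.col(t(matrix(fw$logits[, , b], 4, ns))) - 1L
      labs <- batch$labels[, b]
      cmw <- confusion_matrix(labs, pred)
      cmb <- confusion_matrix(labs, base_labels[idx])
      cm_model <- cm_model + cmw
      cm_base <- cm_base + cmb
      renv <- tryCatch(envelope_pearson(e_ref, e_hat), error = function(e) NA)
      renv_in <- tryCatch(
        envelope_pearson(e_ref, homomorphic_envelope(y_in, p$fs)),
        error = function(e) NA)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = p$subject_id, scenario = p$scenario %||% "unknown",
        window = b,
        lsd_out = lsd(y_ref, y_hat), lsd_in = lsd(y_ref, y_in),
        renv_out = renv, renv_in = renv_in,
        micro_f1_out = segmentation_report(cmw)$micro_f1,
        micro_f1_in = segmentation_report(cmb)$micro_f1)
    }
  }
  if (length(rows) == 0) stop("no windows to evaluate")
  win_df <- do.call(rbind, rows)
  agg <- function(df) {
    data.frame(lsd_out = mean(df$lsd_out), lsd_in = mean(df$lsd_in),
               renv_out = mean(df$renv_out, na.rm = TRUE),
               renv_in = mean(df$renv_in, na.rm = TRUE),
               n_windows = nrow(df))
  }
  by_subject <- do.call(rbind, lapply(split(win_df, win_df$subject), agg))
  by_subject$subject <- rownames(by_subject)
  by_scenario <- do.call(rbind, lapply(split(win_df, win_df$scenario), agg))
  by_scenario$scenario <- rownames(by_scenario)
  rep_model <- segmentation_report(cm_model)
  rep_base <- segmentation_report(cm_base)
  aggregate <- list(
    model = list(lsd = mean(win_df$lsd_out),
                 renv = mean(win_df$renv_out, na.rm = TRUE),
                 micro_f1 = rep_model$micro_f1, macro_f1 = rep_model$macro_f1,
                 f1 = rep_model$f1),
    baseline = list(lsd = mean(win_df$lsd_in),
                    renv = mean(win_df$renv_in, na.rm = TRUE),
                    micro_f1 = rep_base$micro_f1, macro_f1 = rep_base$macro_f1,
                    f1 = rep_base$f1))
  aggregate$improvement <- list(
    lsd = aggregate$baseline$lsd - aggregate$model$lsd,
    renv = aggregate$model$renv - aggregate$baseline$renv,
    micro_f1 = aggregate$model$micro_f1 - aggregate$baseline$micro_f1,
    macro_f1 = aggregate$model$macro_f1 - aggregate$baseline$macro_f1)
  structure(list(windows = win_df, by_subject = by_subject,
                 by_scenario = by_scenario, aggregate = aggregate,
                 confusion_model = cm_model, confusion_baseline = cm_base),
            class = "evaluation_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic experiment end to end
#'
#' Simulate, pre-process, split, train and evaluate; write the metric
#' reports, loss history, configuration snapshot and model checkpoint to a
#' run directory.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if missing).
#' @param n_subjects,duration,scenarios Synthetic dataset shape.
#' @param radar A [radar_config()] for the simulator.
#' @param verbose Print progress.
#'
#' @return Invisibly, a list with the trained model, the evaluation report
#'   and the output paths.
#' @export
run_end_to_end <- function(config, out_dir = tempfile("radarpcg_run"),
                           n_subjects = 8, duration = 90,
                           scenarios = "resting",
                           radar = radar_config(noise_std = 0.005),
                           verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- generate_dataset(n_subjects, scenarios, duration,
                           seed = config$seed, radar = radar)
  pairs <- lapply(recs, preprocess_recording)
  fit <- train(config, pairs, verbose = verbose)
  test_pairs <- pairs[vapply(pairs, function(p) p$subject_id, "") %in%
                        fit$split$test]
  report <- evaluate(fit$model, test_pairs, config,
                     train_subjects = fit$split$train)
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  utils::write.csv(report$windows, file.path(out_dir, "windows.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(aggregate = report$aggregate,
                            split = fit$split,
                            class_weights = as.numeric(fit$class_weights)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(fit$model, file.path(out_dir, "checkpoint.rds"))
  saveRDS(config, file.path(out_dir, "config.rds"))
  invisible(list(model = fit$model, report = report, history = fit$history,
                 split = fit$split, out_dir = out_dir))
}
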
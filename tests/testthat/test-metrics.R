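# Evaluation metrics: LSD, envelope correlation, confusion/F1 machinery,
# state statistics, event extraction and matching.

test_that("LSD identities on constant spectral ratios", {
  set.seed(10)
  y <- rnorm(3000)
  expect_equal(lsd(y, y), 0)
  expect_equal(lsd(y, y / 10), 20, tolerance = 1e-9)
  expect_equal(lsd(y, y / 2), 20 * log10(2), tolerance = 1e-9)
  # symmetric under argument exchange (squared log ratio)
  yh <- rnorm(3000)
  expect_equal(lsd(y, yh), lsd(yh, y), tolerance = 1e-9)
  expect_error(lsd(y, yh[-1]), "mismatch")
})

test_that("envelope correlation is affine-invariant and guarded", {
  e <- abs(rnorm(200))
  expect_equal(envelope_pearson(e, e), 1)
  expect_equal(envelope_pearson(e, -e), -1)
  expect_equal(envelope_pearson(e, 2 * e + 3), 1)
  expect_error(envelope_pearson(e, rep(1, 200)), "variance")
})

test_that("confusion matrix counts and the all-diastole toy example", {
  ref <- c(rep(0L, 10), rep(3L, 90))
  pred <- rep(3L, 100)
  cm <- confusion_matrix(ref, pred)
  expect_equal(sum(cm), 100)
  expect_equal(cm["S1", "diastole"], 10L)
  expect_equal(cm["diastole", "diastole"], 90L)
  expect_equal(unname(rowSums(row_normalize(cm))[c(1, 4)]), c(1, 1))
  ident <- confusion_matrix(ref, ref)
  expect_equal(unname(diag(ident)), c(10L, 0L, 0L, 90L))
  expect_error(confusion_matrix(ref, pred[-1]), "mismatch")
  expect_error(confusion_matrix(c(0L, 5L), c(0L, 1L)), "0..3")
})

test_that("segmentation report reproduces hand-computed F1 values", {
  ref <- c(rep(0L, 10), rep(3L, 90))
  rep_ <- segmentation_report(confusion_matrix(ref, rep(3L, 100)))
  # diastole: precision 90/100, recall 1 -> F1 = 180/190
  expect_equal(unname(rep_$f1["diastole"]), 180 / 190, tolerance = 1e-12)
  expect_equal(unname(rep_$f1["S1"]), 0)
  expect_equal(rep_$micro_f1, 0.90)
  expect_equal(rep_$macro_f1, (180 / 190) / 4)
  perfect <- segmentation_report(confusion_matrix(ref, ref))
  # absent classes score 0 under the zero-division convention
  expect_equal(unname(perfect$f1), c(1, 0, 0, 1))
  expect_equal(perfect$micro_f1, 1)
  expect_error(segmentation_report(matrix(0L, 4, 4)), "empty")
})

test_that("micro-F1 equals accuracy and report matches a per-sample oracle", {
  set.seed(11)
  ref <- sample(0:3, 500, replace = TRUE)
  pred <- ifelse(runif(500) < 0.3, sample(0:3, 500, replace = TRUE), ref)
  rep_ <- segmentation_report(confusion_matrix(ref, pred))
  expect_equal(rep_$micro_f1, mean(ref == pred), tolerance = 1e-12)
  # brute-force per-class oracle
  for (k in 0:3) {
    tp <- sum(ref == k & pred == k)
    fp <- sum(ref != k & pred == k)
    fn <- sum(ref == k & pred != k)
    f1 <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    expect_equal(unname(rep_$f1[k + 1]), f1, tolerance = 1e-12)
  }
  expect_true(rep_$macro_f1 <= max(rep_$f1) && rep_$macro_f1 >= min(rep_$f1))
})

test_that("state statistics recover constructed run durations", {
  fs <- 500
  labels <- rep(c(rep(0L, 61), rep(1L, 97), rep(2L, 46), rep(3L, 196)), 5)
  st <- state_statistics(labels, fs)
  expect_equal(st$mean_duration, c(61, 97, 46, 196) / fs, tolerance = 1e-12)
  expect_equal(sum(st$share), 100)
  single <- state_statistics(rep(2L, 100), fs)
  expect_equal(single$share[single$state == "S2"], 100)
  expect_error(state_statistics(integer(0), fs), "empty")
})

test_that("event extraction takes run midpoints and drops short runs", {
  fs <- 500
  labels <- rep(3L, 1000)
  labels[101:161] <- 0L           # samples 101..161 -> centre 0.26 s
  labels[500:504] <- 0L           # 5 samples = 10 ms, below min_run
  ev <- extract_events(labels, fs, "S1")
  expect_equal(ev, 0.26)
  expect_length(extract_events(rep(3L, 100), fs, "S1"), 0)
})

test_that("event matching is one-to-one within the tolerance window", {
  perfect <- event_match(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$f1, 1)
  miss <- event_match(1.12, 1.0)
  expect_equal(c(miss$tp, miss$fp, miss$fn, miss$f1), c(0, 1, 1, 0))
  # two predictions straddling one reference: only one can match
  both <- event_match(c(0.95, 1.05), 1.0)
  expect_equal(c(both$tp, both$fp), c(1, 1))
  # swapping the arguments swaps FP and FN but preserves TP and F1
  a <- event_match(c(1, 2, 2.5), c(1, 3))
  b <- event_match(c(1, 3), c(1, 2, 2.5))
  expect_equal(a$tp, b$tp)
  expect_equal(a$fp, b$fn)
  expect_equal(a$f1, b$f1)
})

test_that("the event report pools S1 and S2 counts", {
  fs <- 500
  labels <- rep(3L, 3000)
  labels[201:261] <- 0L; labels[601:647] <- 2L
  labels[1201:1261] <- 0L; labels[1601:1647] <- 2L
  er <- event_report(labels, labels, fs)
  expect_equal(er$combined$f1, 1)
  expect_equal(er$s1$tp, 2)
  expect_equal(er$s2$tp, 2)
})
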
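make_pred <- function(center_s, wheeze) {
  data.frame(m = seq_along(center_s) - 1L, start_s = center_s - 0.032,
             center_s = center_s, active = TRUE, wheeze = wheeze)
}

test_that("segment-wise confusion counts match the exhaustive oracle", {
  set.seed(51)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    centers <- (seq_len(n) - 0.5) * 0.032
    # random reference intervals
    n_iv <- sample(0:3, 1)
    iv <- if (n_iv > 0) {
      # carve disjoint intervals out of an ordered grid of breakpoints
      bp <- sort(runif(2 * n_iv, 0, max(centers) + 0.1))
      data.frame(start_s = bp[seq(1, 2 * n_iv, by = 2)],
                 end_s = bp[seq(2, 2 * n_iv, by = 2)],
                 label = "W")
    } else data.frame(start_s = numeric(0), end_s = numeric(0),
                      label = character(0))
    annot <- resp_annotation(intervals = iv)
    pred <- make_pred(centers, runif(n) > 0.5)
    got <- score_segmentwise(pred, annot)$counts
    ref <- vapply(centers, function(tc)
      any(iv$start_s <= tc & tc < iv$end_s), logical(1))
    expect_identical(got, confusion_direct(pred$wheeze, ref))
  }
})

test_that("metrics guard zero denominators as absent, never 0/0 = 0", {
  m <- classification_metrics(c(TP = 2, FN = 2, TN = 0, FP = 0))
  expect_equal(m[["SE"]], 0.5)
  expect_true(is.na(m[["SP"]]))
  expect_equal(m[["AC"]], 0.5)
  perfect <- classification_metrics(c(TP = 5, FN = 0, TN = 5, FP = 0))
  expect_equal(unname(perfect), c(1, 1, 1))
})

test_that("phase-wise scoring follows the one-hit rule", {
  annot <- resp_annotation(
    intervals = data.frame(start_s = 0.5, end_s = 0.8, label = "W"),
    phases = data.frame(start_s = c(0, 1.0), end_s = c(1.0, 2.0),
                        phase = c("exp", "insp")))
  centers <- seq(0.05, 1.95, by = 0.1)
  # one positive segment inside the wheezing phase -> TP; none in the
  # normal phase -> TN
  pred <- make_pred(centers, abs(centers - 0.55) < 0.01)
  got <- score_phasewise(pred, annot)$counts
  expect_identical(got, c(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  # a positive segment in the normal phase -> FP
  pred2 <- make_pred(centers, centers > 1.5 & centers < 1.6)
  got2 <- score_phasewise(pred2, annot)$counts
  expect_identical(got2, c(TP = 0L, TN = 0L, FP = 1L, FN = 1L))
  # all-NORMAL predictions: positives -> FN, negatives -> TN
  pred3 <- make_pred(centers, rep(FALSE, length(centers)))
  got3 <- score_phasewise(pred3, annot)$counts
  expect_identical(got3, c(TP = 0L, TN = 1L, FP = 0L, FN = 1L))
})

test_that("confusion counts conserve reference totals in both scenarios", {
  set.seed(52)
  ds <- generate_recording(sim_config(
    wheezes = data.frame(start_s = c(2, 6), duration_s = c(0.8, 1),
                         f0 = c(300, 500), n_harmonics = 1L,
                         drift = 0, snr_db = 15), seed = 52))
  p <- detect_wheezes(ds$recording, wheeze_config(1))
  seg <- score_segmentwise(p, ds$annotation)$counts
  ref_pos <- sum(vapply(p$center_s, function(tc)
    any(ds$annotation$intervals$start_s <= tc &
          tc < ds$annotation$intervals$end_s), logical(1)))
  expect_identical(seg[["TP"]] + seg[["FN"]], ref_pos)
  expect_identical(sum(seg), nrow(p))
  ph <- score_phasewise(p, ds$annotation)$counts
  n_phases <- sum(ds$annotation$phases$phase %in% c("insp", "exp"))
  expect_identical(sum(ph), n_phases)
})

test_that("phase-wise sensitivity dominates segment-wise sensitivity", {
  set.seed(53)
  ds <- generate_dataset(0, 4, seed = 53)
  cfg <- wheeze_config(2)
  for (d in ds) {
    p <- detect_wheezes(d$recording, cfg)
    se_seg <- score_segmentwise(p, d$annotation)$metrics[["SE"]]
    se_ph <- score_phasewise(p, d$annotation)$metrics[["SE"]]
    if (!is.na(se_seg) && !is.na(se_ph)) expect_gte(se_ph, se_seg)
  }
})

test_that("grid search maximizes SE*SP with deterministic tie-breaking", {
  set.seed(54)
  ds <- generate_recording(sim_config(
    wheezes = data.frame(start_s = 2, duration_s = 1, f0 = 400,
                         n_harmonics = 1L, drift = 5, snr_db = 18),
    seed = 54))
  cfg <- wheeze_config(4)
  f <- list(extract_segment_features(ds$recording, cfg))
  a <- list(ds$annotation)
  fit <- grid_search_train(f, a, cfg, grid = list(C_ent = c(1.2, 1.8, 2.5)))
  # selected objective dominates every grid point
  expect_true(all(fit$auc_max >= fit$roc$objective))
  expect_equal(fit$auc_max,
               max(fit$roc$SE * fit$roc$SP, na.rm = TRUE))
  # the chosen config is the first argmax in grid order
  expect_identical(fit$best_row, which.max(fit$roc$objective))
  # arithmetic of the objective: (0.9, 0.8) loses to (0.85, 0.9)
  expect_lt(0.9 * 0.8, 0.85 * 0.9)
  expect_error(grid_search_train(f, a, cfg, grid = list()), "empty")
})

test_that("leave-one-out on identical recordings is symmetric and pools counts", {
  set.seed(55)
  ds <- generate_recording(sim_config(
    wheezes = data.frame(start_s = 2, duration_s = 1, f0 = 450,
                         n_harmonics = 1L, drift = 0, snr_db = 18),
    seed = 55))
  cfg <- wheeze_config(4)
  f <- extract_segment_features(ds$recording, cfg)
  res <- leave_one_out(list(f, f), list(ds$annotation, ds$annotation),
                       cfg, grid = list(C_ent = c(1.5, 2.5)))
  expect_identical(res$folds$grid_row[1], res$folds$grid_row[2])
  expect_equal(res$folds$AC_seg[1], res$folds$AC_seg[2])
  # pooled counts equal the sum of per-fold counts
  pooled <- res$pooled$segment$all$counts
  per_fold <- score_segmentwise(res$predictions[[1]], ds$annotation)$counts +
    score_segmentwise(res$predictions[[2]], ds$annotation)$counts
  expect_identical(pooled, per_fold)
})

test_that("boundary concentration isolates transition hits", {
  annot <- resp_annotation(
    intervals = data.frame(start_s = 1.0, end_s = 2.0, label = "W"),
    phases = data.frame(start_s = 0, end_s = 3, phase = "exp"))
  centers <- (0:89) * 0.032 + 0.032
  # positives exactly at the onset and in the middle of the interval
  onset_idx <- which.min(abs(centers - 1.0))
  mid_idx <- which.min(abs(centers - 1.5))
  wheeze <- seq_along(centers) %in% c(onset_idx + 1, mid_idx)
  bc <- boundary_concentration(make_pred(centers, wheeze), annot, k = 3)
  expect_identical(bc$n_tp, 2L)
  expect_identical(bc$n_near, 1L)
  expect_equal(bc$fraction, 0.5)
})
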
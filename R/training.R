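# Scoring in the two operating scenarios and threshold training.
#
# Duration-tracking scenario: confusion counts accumulated segment-wise,
# each segment's reference label taken from the annotation at its center
# time. Event-detection scenario: counts accumulated per respiratory phase;
# a phase is scored positive iff it contains at least one positively
# classified segment.

label_at_center <- function(center_s, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(center_s)))
  w <- intervals[intervals$label == "W", , drop = FALSE]
  ref <- rep(FALSE, length(center_s))
  for (i in seq_len(nrow(w)))
    ref <- ref | (center_s >= w$start_s[i] & center_s < w$end_s[i])
  ref
}

confusion_counts <- function(pred, ref) {
  stopifnot(length(pred) == length(ref))
  c(TP = sum(pred & ref), TN = sum(!pred & !ref),
    FP = sum(pred & !ref), FN = sum(!pred & ref))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `SE = TP/(TP+FN)`, `SP = TN/(TN+FP)`, `AC = (TP+TN)/total`. A metric
#' whose denominator is zero is reported as `NA` (absent), never as 0.
#'
#' @param counts named vector/list with `TP`, `TN`, `FP`, `FN`.
#' @return named numeric vector `c(SE, SP, AC)`, fractions in \[0, 1\].
#' @export
classification_metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  tot <- tp + tn + fp + fn
  c(SE = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    SP = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    AC = if (tot > 0) (tp + tn) / tot else NA_real_)
}

#' Segment-wise scoring (duration-tracking scenario)
#'
#' @param predictions data.frame from [classify_segments()] (columns
#'   `center_s`, `wheeze`).
#' @param annot a [resp_annotation()].
#' @return list with `counts` (TP/TN/FP/FN) and `metrics` (SE/SP/AC).
#' @export
score_segmentwise <- function(predictions, annot) {
  stopifnot(inherits(annot, "resp_annotation"),
            all(c("center_s", "wheeze") %in% names(predictions)))
  ref <- label_at_center(predictions$center_s, annot$intervals)
  counts <- confusion_counts(predictions$wheeze, ref)
  list(counts = counts, metrics = classification_metrics(counts))
}

#' Phase-wise scoring (event-detection scenario)
#'
#' Each inspiratory/expiratory phase is one scoring unit. A phase is a
#' reference positive iff it overlaps an annotated wheeze interval; it is a
#' predicted positive iff at least one predicted-positive segment center
#' falls inside it.
#'
#' @inheritParams score_segmentwise
#' @return list with `counts` and `metrics`.
#' @export
score_phasewise <- function(predictions, annot) {
  stopifnot(inherits(annot, "resp_annotation"))
  ph <- annot$phases[annot$phases$phase %in% c("insp", "exp"), , drop = FALSE]
  if (nrow(ph) == 0) stop("annotation carries no respiratory phases")
  w <- annot$intervals[annot$intervals$label == "W", , drop = FALSE]
  ref <- logical(nrow(ph)); pred <- logical(nrow(ph))
  for (i in seq_len(nrow(ph))) {
    if (nrow(w))
      ref[i] <- any(w$start_s < ph$end_s[i] & w$end_s > ph$start_s[i])
    inside <- predictions$center_s >= ph$start_s[i] &
      predictions$center_s < ph$end_s[i]
    pred[i] <- any(predictions$wheeze[inside])
  }
  counts <- confusion_counts(pred, ref)
  list(counts = counts, metrics = classification_metrics(counts))
}

#' Concentration of true positives near wheeze boundaries
#'
#' Fraction of true-positive segments lying within `k` segments of an
#' annotated wheeze-interval boundary. Distance is measured in segment
#' indices: a boundary time maps to the segment whose center is nearest,
#' and a true positive at index `m` is near iff `|m - m_boundary| <= k`
#' for some boundary. A transition detector should concentrate its hits
#' at interval onsets and offsets, driving this fraction toward 1.
#'
#' @param predictions data.frame from [classify_segments()].
#' @param annot a [resp_annotation()] with at least one wheeze interval.
#' @param k neighbourhood half-width in segments (default 3).
#' @return list with `n_tp`, `n_near`, and `fraction` (`NA` if no TPs).
#' @export
boundary_concentration <- function(predictions, annot, k = 3L) {
  w <- annot$intervals[annot$intervals$label == "W", , drop = FALSE]
  if (nrow(w) == 0) stop("annotation has no wheeze intervals")
  ref <- label_at_center(predictions$center_s, annot$intervals)
  tp <- predictions$wheeze & ref
  bounds <- c(w$start_s, w$end_s)
  b_idx <- vapply(bounds, function(b)
    predictions$m[which.min(abs(predictions$center_s - b))], numeric(1))
  near <- vapply(predictions$m, function(m)
    min(abs(b_idx - m)) <= k, logical(1))
  n_tp <- sum(tp); n_near <- sum(tp & near)
  list(n_tp = n_tp, n_near = n_near,
       fraction = if (n_tp > 0) n_near / n_tp else NA_real_)
}

# expand a named list of candidate values into the deterministic
# lexicographic grid order (first parameter varies slowest)
expand_grid_ordered <- function(grid) {
  if (length(grid) == 0) stop("empty training grid")
  g <- rev(expand.grid(rev(grid), KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE))
  if (nrow(g) == 0) stop("empty training grid")
  g
}

apply_grid_row <- function(cfg, row) {
  for (nm in names(row)) cfg[[nm]] <- row[[nm]]
  cfg
}

#' Default training grids
#'
#' Candidate values for each algorithm's trainable thresholds, spanning the
#' permissive-to-strict range of each decision rule.
#'
#' @param algorithm detector id 1-4.
#' @return named list of candidate value vectors.
#' @export
default_grid <- function(algorithm) {
  switch(as.character(algorithm),
    "1" = list(C_m = c(1.0, 1.5, 2.0, 3.0), C_s = c(0.5, 1.0, 2.0)),
    "2" = list(C_narrow = c(0.6, 0.9, 1.2, 1.5), C_wide = c(1.0, 1.5, 2.5)),
    "3" = list(C_T = c(-8, -6, -4, -3, -2, -1.5, -1, -0.5)),
    "4" = list(C_ent = c(1.1, 1.25, 1.5, 2, 3, 4)),
    stop("algorithm must be 1, 2, 3 or 4"))
}

# per-recording confusion counts for every grid point (the shared kernel of
# grid_search_train and leave_one_out); also returns the cached label
# streams so folds can be re-scored without re-classifying
grid_eval <- function(features_list, annotations, cfg, grid) {
  g <- expand_grid_ordered(grid)
  n_rec <- length(features_list)
  counts_seg <- array(0L, dim = c(nrow(g), n_rec, 4L),
                      dimnames = list(NULL, NULL, c("TP", "TN", "FP", "FN")))
  preds <- vector("list", nrow(g))
  for (r in seq_len(nrow(g))) {
    cfg_r <- apply_grid_row(cfg, g[r, , drop = FALSE])
    preds[[r]] <- vector("list", n_rec)
    for (i in seq_len(n_rec)) {
      p <- classify_segments(features_list[[i]], cfg_r)
      preds[[r]][[i]] <- p
      counts_seg[r, i, ] <- score_segmentwise(p, annotations[[i]])$counts
    }
  }
  list(grid = g, counts_seg = counts_seg, preds = preds)
}

auc_from_counts <- function(counts) {
  m <- classification_metrics(as.list(counts))
  se <- m[["SE"]]; sp <- m[["SP"]]
  if (is.na(se) || is.na(sp)) -Inf else se * sp
}

#' Grid-search training of a detector's thresholds
#'
#' Exhaustively evaluates every grid point on the training recordings,
#' scoring segment-wise, and selects the point maximizing the product
#' `SE * SP` (the maximal-area operating point of the ROC cloud). Ties
#' resolve to the first point in deterministic lexicographic grid order.
#'
#' @param features_list list of [extract_segment_features()] outputs.
#' @param annotations list of matching [resp_annotation()]s.
#' @param cfg base [wheeze_config()] (selects the algorithm).
#' @param grid named list of candidate values per trainable threshold;
#'   default [default_grid()].
#' @return list with `config` (trained `wheeze_config`), `auc_max`,
#'   `roc` (data.frame: grid point, FPR, TPR, SE, SP, objective).
#' @export
grid_search_train <- function(features_list, annotations, cfg,
                              grid = default_grid(cfg$algorithm)) {
  ev <- grid_eval(features_list, annotations, cfg, grid)
  score_rows(ev, seq_along(features_list), cfg)
}

score_rows <- function(ev, train_idx, cfg) {
  n_grid <- nrow(ev$grid)
  obj <- numeric(n_grid); se <- numeric(n_grid); sp <- numeric(n_grid)
  for (r in seq_len(n_grid)) {
    tot <- apply(ev$counts_seg[r, train_idx, , drop = FALSE], 3, sum)
    m <- classification_metrics(as.list(tot))
    se[r] <- m[["SE"]]; sp[r] <- m[["SP"]]
    obj[r] <- if (is.na(se[r]) || is.na(sp[r])) -Inf else se[r] * sp[r]
  }
  best <- which.max(obj)   # first maximum in grid order
  roc <- cbind(ev$grid, data.frame(SE = se, SP = sp, TPR = se,
                                   FPR = 1 - sp, objective = obj))
  list(config = apply_grid_row(cfg, ev$grid[best, , drop = FALSE]),
       auc_max = obj[best], best_row = best, roc = roc)
}

#' Leave-one-out training and testing over a recording set
#'
#' For each recording, thresholds are trained by [grid_search_train()] on
#' all other recordings and the held-out recording is scored with the
#' trained configuration, in both scenarios. Confusion counts are pooled
#' over folds, and pooled metrics are reported for wheeze-containing
#' recordings, normal recordings, and all recordings.
#'
#' Internally the per-recording confusion counts of every grid point are
#' computed once and folds aggregate them, which is algebraically identical
#' to refitting per fold.
#'
#' @inheritParams grid_search_train
#' @return list with `folds` (data.frame: fold, chosen grid row, auc_max,
#'   per-fold SE/SP/AC in both scenarios), `pooled` (list per scenario with
#'   counts and metrics for groups `wheeze`, `normal`, `all`), and
#'   `predictions` (list of held-out per-segment predictions).
#' @export
leave_one_out <- function(features_list, annotations, cfg,
                          grid = default_grid(cfg$algorithm)) {
  n_rec <- length(features_list)
  if (n_rec < 2) stop("leave-one-out needs at least 2 recordings")
  stopifnot(length(annotations) == n_rec)
  ev <- grid_eval(features_list, annotations, cfg, grid)
  has_wheeze <- vapply(annotations, function(a)
    any(a$intervals$label == "W"), logical(1))

  zero <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  pooled <- list(
    segment = list(wheeze = zero, normal = zero, all = zero),
    phase = list(wheeze = zero, normal = zero, all = zero))
  folds <- vector("list", n_rec)
  held_out <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    fit <- score_rows(ev, setdiff(seq_len(n_rec), i), cfg)
    p <- ev$preds[[fit$best_row]][[i]]
    held_out[[i]] <- p
    seg <- score_segmentwise(p, annotations[[i]])
    phs <- score_phasewise(p, annotations[[i]])
    grp <- if (has_wheeze[i]) "wheeze" else "normal"
    for (sc in c("segment", "phase")) {
      cts <- if (sc == "segment") seg$counts else phs$counts
      pooled[[sc]][[grp]] <- pooled[[sc]][[grp]] + cts
      pooled[[sc]][["all"]] <- pooled[[sc]][["all"]] + cts
    }
    folds[[i]] <- data.frame(
      fold = i, id = features_list[[i]]$id, grid_row = fit$best_row,
      auc_max = fit$auc_max,
      SE_seg = seg$metrics[["SE"]], SP_seg = seg$metrics[["SP"]],
      AC_seg = seg$metrics[["AC"]],
      SE_phase = phs$metrics[["SE"]], SP_phase = phs$metrics[["SP"]],
      AC_phase = phs$metrics[["AC"]])
  }
  pooled_metrics <- lapply(pooled, function(sc)
    lapply(sc, function(cts)
      list(counts = cts, metrics = classification_metrics(as.list(cts)))))
  list(folds = do.call(rbind, folds), pooled = pooled_metrics,
       predictions = held_out)
}
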
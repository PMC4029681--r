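# The four decision trees. All share the energy-gate root (pause detection,
# early termination); the branches are algorithm specific:
#   1 - crest tracking, moment-based crest model
#   2 - crest tracking, energy-based crest model
#   3 - tonality-run tracking
#   4 - peak-entropy change detection
# Classification is split in two stages: extract_segment_features() computes
# the threshold-independent per-segment features once per recording, and
# classify_segments() applies one parameterization - so grid-search training
# re-runs only the cheap stage.

#' Classifier configuration
#'
#' All tunable parameters of the four detectors, with defaults matching the
#' analysis grid of a 512-sample segment at 8 kHz with 50% overlap.
#' Trainable thresholds (see [default_grid()]) are: `C_m`, `C_s` (algorithm
#' 1), `C_narrow`, `C_wide` (algorithm 2), `C_T` (algorithm 3), `C_ent`
#' (algorithm 4).
#'
#' @param algorithm detector id, 1-4.
#' @param N segment length in samples.
#' @param overlap fractional segment overlap.
#' @param sample_rate analysis rate in Hz.
#' @param window analysis window name.
#' @param f_lo,f_hi analysis band in Hz.
#' @param C_pause energy-gate fraction in \[0, 1\]: a segment is active iff
#'   its energy exceeds `E_min + C_pause * (E_max - E_min)` over the recent
#'   energy history.
#' @param M_E energy-history depth in segments (covers >= 1 respiratory
#'   cycle).
#' @param B_crest crest bandwidth in bins (algorithms 1-2).
#' @param C_m,C_s moment-model coefficients (algorithm 1).
#' @param B_narrow,B_wide surrounding bandwidths in Hz (algorithm 2).
#' @param C_narrow,C_wide energy-ratio thresholds (algorithm 2).
#' @param C_crests maximal accepted crest count per segment (algorithms 1-2).
#' @param M_cont continuity depth in segments; also the minimal wheeze
#'   duration `M_dur_min` (algorithms 1-3).
#' @param C_cont per-lag continuity thresholds in bins, length `M_cont`.
#' @param M_dur_max maximal wheeze duration in segments (about one
#'   respiratory cycle).
#' @param C_T tonality threshold; a segment is tonal iff `T < C_T`
#'   (algorithm 3).
#' @param C_ent entropy-ratio threshold `>= 1`; a segment is flagged iff
#'   `max(r, 1/r) > C_ent` (algorithm 4).
#' @return a `wheeze_config` list.
#' @export
wheeze_config <- function(algorithm = 1L,
                          N = 512L, overlap = 0.5, sample_rate = 8000,
                          window = "hamming",
                          f_lo = 60, f_hi = 950,
                          C_pause = 0.1, M_E = 156L,
                          B_crest = 6L, C_m = 1.5, C_s = 1.0,
                          B_narrow = 125, B_wide = 187.5,
                          C_narrow = 1.2, C_wide = 1.5,
                          C_crests = 7L,
                          M_cont = 4L, C_cont = rep(3, M_cont),
                          M_dur_max = 125L,
                          C_T = -2.0, C_ent = 2.0) {
  if (!algorithm %in% 1:4) stop("algorithm must be 1, 2, 3 or 4")
  if (C_pause < 0 || C_pause > 1) stop("C_pause must be in [0, 1]")
  if (length(C_cont) != M_cont) stop("C_cont must have length M_cont")
  if (M_dur_max <= M_cont) stop("M_dur_max must exceed M_dur_min = M_cont")
  if (C_ent < 1) stop("C_ent must be >= 1")
  structure(list(algorithm = as.integer(algorithm), N = as.integer(N),
                 overlap = overlap, sample_rate = sample_rate,
                 window = window, f_lo = f_lo, f_hi = f_hi,
                 C_pause = C_pause, M_E = as.integer(M_E),
                 B_crest = as.integer(B_crest), C_m = C_m, C_s = C_s,
                 B_narrow = B_narrow, B_wide = B_wide,
                 C_narrow = C_narrow, C_wide = C_wide,
                 C_crests = as.integer(C_crests),
                 M_cont = as.integer(M_cont), C_cont = as.numeric(C_cont),
                 M_dur_min = as.integer(M_cont),
                 M_dur_max = as.integer(M_dur_max),
                 C_T = C_T, C_ent = C_ent),
            class = "wheeze_config")
}

#' Save / load a classifier configuration
#' @param cfg a [wheeze_config()].
#' @param path YAML file path.
#' @return `read_config` returns a `wheeze_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "wheeze_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(wheeze_config,
          cfg[setdiff(names(cfg), "M_dur_min")])
}

#' Energy gate: pause detection at the decision-tree root
#'
#' A segment belongs to a respiratory phase (is "active") iff its energy
#' exceeds `E_min + C_pause * (E_max - E_min)` over the recent energy
#' history; otherwise it is an inter-respiratory pause and classified
#' NORMAL without further feature extraction. Pause detection requires
#' energy contrast: when the history's dynamic range is below 3 dB
#' (`E_max <= 2 * E_min`, which covers the degenerate `E_min == E_max`)
#' there is no pause to find and the gate fails open (active). Breath
#' versus pause contrast in real recordings is far larger.
#'
#' @param E current segment energy.
#' @param E_min,E_max extrema from [energy_bounds()].
#' @param C_pause gate fraction in \[0, 1\].
#' @return `TRUE` (active) or `FALSE` (pause).
#' @export
energy_gate <- function(E, E_min, E_max, C_pause = 0.1) {
  if (E_min > E_max) stop("E_min must not exceed E_max")
  if (E_max <= 2 * E_min) return(TRUE)   # < 3 dB contrast: no pause to find
  E > E_min + C_pause * (E_max - E_min)
}

#' Extract per-segment features of a recording
#'
#' Runs the STFT front-end over the segment grid and computes every
#' threshold-independent feature: band power spectra, segment energies,
#' spectral peaks, tonality index and peak entropy. The result feeds
#' [classify_segments()] (and, repeatedly, the training grid search).
#'
#' @param rec a [resp_recording()].
#' @param cfg a [wheeze_config()] (grid and band parameters are used; the
#'   trainable thresholds are not).
#' @return a `segment_features` object: list with `m`, `start_time`,
#'   `center_time`, `energy`, `band` (the `band_selection`), `P` (band
#'   power matrix, n_b x n_seg), `peaks` (list of `peak_set`), `tonality`
#'   (vector, `NA` for the first two segments), `entropy` (vector), and
#'   `hop_s`.
#' @export
extract_segment_features <- function(rec, cfg = wheeze_config()) {
  frames <- frame_segments(rec, cfg$N, cfg$overlap)
  n_seg <- length(frames$m)
  band <- select_band(rec$sample_rate / cfg$N, cfg$f_lo, cfg$f_hi, N = cfg$N)
  P <- matrix(0, nrow = band$n_b, ncol = n_seg)
  energy <- numeric(n_seg)
  tonality <- rep(NA_real_, n_seg)
  entropy <- numeric(n_seg)
  peaks <- vector("list", n_seg)
  tstate <- tonality_state()
  for (j in seq_len(n_seg)) {
    fr <- analyze_segment(frames$samples[, j], rec$sample_rate,
                          window = cfg$window, need_phase = TRUE)
    P[, j] <- fr$P[band$idx]
    energy[j] <- sum(P[, j])
    peaks[[j]] <- find_spectral_peaks(fr, band)
    entropy[j] <- as.numeric(peak_entropy(peaks[[j]]))
    if (j >= 3) tonality[j] <- tonal_index(fr, tstate, band)
    tstate <- push_tonality(tstate, fr, band)
  }
  structure(list(m = frames$m, start_time = frames$start_time,
                 center_time = frames$start_time + cfg$N /
                   (2 * rec$sample_rate),
                 energy = energy, band = band, P = P, peaks = peaks,
                 tonality = tonality, entropy = entropy,
                 hop_s = frames$hop / rec$sample_rate,
                 id = rec$id),
            class = "segment_features")
}

# active/pause gate over the whole stream (running extrema over the last
# M_E + 1 energies, current segment included)
gate_stream <- function(energy, M_E, C_pause) {
  n <- length(energy)
  active <- logical(n)
  for (j in seq_len(n)) {
    w <- energy[max(1L, j - M_E):j]
    active[j] <- energy_gate(energy[j], min(w), max(w), C_pause)
  }
  active
}

band_frame <- function(feats, j) {
  # reconstitute a minimal spectrum_frame view for crest detectors: power
  # values outside the band are never touched by them, so only band bins
  # are filled.
  P <- numeric(feats$band$k_hi + 1L)
  P[feats$band$idx] <- feats$P[, j]
  structure(list(P = P, A = sqrt(P), Phi = NULL,
                 N = NA_integer_, bin_hz = feats$band$bin_hz),
            class = "spectrum_frame")
}

#' Classify a feature stream segment-wise
#'
#' Applies one of the four decision trees to precomputed
#' [extract_segment_features()] output. Pause-gated segments are NORMAL
#' under every algorithm.
#'
#' @param feats a `segment_features` object.
#' @param cfg a [wheeze_config()]; `cfg$algorithm` selects the tree.
#' @return data.frame with columns `m`, `start_s`, `center_s`, `active`
#'   (energy gate), and `wheeze` (logical prediction).
#' @export
classify_segments <- function(feats, cfg) {
  stopifnot(inherits(feats, "segment_features"),
            inherits(cfg, "wheeze_config"))
  n <- length(feats$m)
  active <- gate_stream(feats$energy, cfg$M_E, cfg$C_pause)
  wheeze <- logical(n)

  if (cfg$algorithm %in% c(1L, 2L)) {
    tracks <- list()
    for (j in seq_len(n)) {
      if (!active[j]) { tracks <- list(); next }
      fr <- band_frame(feats, j)
      crests <- if (cfg$algorithm == 1L)
        detect_crests_moments(fr, feats$peaks[[j]], feats$band,
                              cfg$B_crest, cfg$C_m, cfg$C_s)
      else
        detect_crests_energy(fr, feats$peaks[[j]], feats$band,
                             cfg$B_crest, cfg$B_narrow, cfg$B_wide,
                             cfg$C_narrow, cfg$C_wide)
      if (crests$n_c < 1L || crests$n_c > cfg$C_crests) {
        # count gate failed: segment is NORMAL, but live tracks are kept
        # frozen so one noisy segment does not reset wheeze durations
        next
      }
      tracks <- update_crest_tracks(tracks, crests, cfg$M_cont, cfg$C_cont)
      durs <- vapply(tracks, function(t) t$dm, integer(1))
      cont <- vapply(tracks, function(t) t$continuous, logical(1))
      wheeze[j] <- any(cont & durs >= cfg$M_dur_min & durs <= cfg$M_dur_max)
    }
  } else if (cfg$algorithm == 3L) {
    run <- 0L
    for (j in seq_len(n)) {
      tonal <- active[j] && !is.na(feats$tonality[j]) &&
        feats$tonality[j] < cfg$C_T
      run <- if (tonal) run + 1L else 0L
      wheeze[j] <- tonal && run >= cfg$M_dur_min && run <= cfg$M_dur_max
    }
  } else {
    en_prev <- NA_real_
    for (j in seq_len(n)) {
      if (!active[j]) { en_prev <- NA_real_; next }
      r <- if (is.na(en_prev)) NA_real_ else
        entropy_ratio(feats$entropy[j], en_prev)
      wheeze[j] <- !is.na(r) && r > 0 && max(r, 1 / r) > cfg$C_ent
      en_prev <- feats$entropy[j]
    }
  }

  data.frame(m = feats$m, start_s = feats$start_time,
             center_s = feats$center_time, active = active,
             wheeze = wheeze)
}

#' Detect wheezes in a recording
#'
#' Convenience wrapper: [extract_segment_features()] followed by
#' [classify_segments()].
#'
#' @param rec a [resp_recording()].
#' @param cfg a [wheeze_config()].
#' @return the per-segment prediction data.frame of [classify_segments()].
#' @export
detect_wheezes <- function(rec, cfg = wheeze_config()) {
  classify_segments(extract_segment_features(rec, cfg), cfg)
}
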
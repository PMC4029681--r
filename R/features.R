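# Per-segment spectral features and temporal crest features.
# All band arithmetic uses 0-based bin indices externally (matching the DFT
# convention) and 1-based indices internally via band$idx.

WHEEZER_EPS <- 1e-12
TONALITY_CLAMP <- 30

#' Segment energy over the analysis band
#'
#' Sum of the power spectrum over the selected band; the root feature of all
#' four decision trees, used to identify inter-respiratory pauses.
#'
#' @param frame a `spectrum_frame` from [analyze_segment()].
#' @param band a `band_selection` from [select_band()].
#' @return non-negative scalar energy.
#' @export
segment_energy <- function(frame, band) {
  sum(frame$P[band$idx])
}

#' Ring buffer of recent segment energies
#'
#' Stores the last `M_E + 1` segment energies (the current segment and its
#' `M_E` predecessors). `M_E` should cover at least one respiratory cycle so
#' that the stored extrema always bracket both a breath and a pause.
#'
#' @param M_E history depth in segments (default 156, about 5 s at a 32 ms
#'   hop).
#' @return an `energy_history` object.
#' @export
energy_history <- function(M_E = 156L) {
  structure(list(values = numeric(0), M_E = as.integer(M_E)),
            class = "energy_history")
}

#' Push a segment energy into the history
#' @param hist an [energy_history()].
#' @param e segment energy.
#' @return the updated history.
#' @export
push_energy <- function(hist, e) {
  stopifnot(inherits(hist, "energy_history"))
  v <- c(hist$values, e)
  keep <- hist$M_E + 1L
  if (length(v) > keep) v <- v[(length(v) - keep + 1L):length(v)]
  hist$values <- v
  hist
}

#' Energy extrema over the stored history
#' @param hist an [energy_history()] with at least one stored value.
#' @return named numeric vector `c(E_min, E_max)`.
#' @export
energy_bounds <- function(hist) {
  stopifnot(inherits(hist, "energy_history"))
  if (length(hist$values) == 0) stop("energy history is empty")
  c(E_min = min(hist$values), E_max = max(hist$values))
}

# --- tonality ----------------------------------------------------------------

#' Two-segment spectral history for the tonality index
#'
#' Holds the amplitude and phase spectra (over the analysis band) of the two
#' preceding segments, from which the current segment's spectrum is linearly
#' extrapolated.
#'
#' @return a `tonality_state` object; prime it with [push_tonality()] twice
#'   before calling [tonal_index()].
#' @export
tonality_state <- function() {
  structure(list(A1 = NULL, Phi1 = NULL, A2 = NULL, Phi2 = NULL),
            class = "tonality_state")
}

#' Push a segment's band spectra into the tonality history
#' @param state a [tonality_state()].
#' @param frame a `spectrum_frame` computed with `need_phase = TRUE`.
#' @param band a `band_selection`.
#' @return the updated state.
#' @export
push_tonality <- function(state, frame, band) {
  stopifnot(inherits(state, "tonality_state"))
  if (is.null(frame$Phi)) stop("frame lacks a phase spectrum")
  state$A2 <- state$A1; state$Phi2 <- state$Phi1
  state$A1 <- frame$A[band$idx]; state$Phi1 <- frame$Phi[band$idx]
  state
}

#' Tonality index of a segment
#'
#' Linearly extrapolates each band bin's amplitude and phase from the two
#' preceding segments (`A_hat = 2 A[m-1] - A[m-2]`, likewise for phase),
#' weights each bin by its prediction error
#' `W = sqrt((Re - Re_hat)^2 + (Im - Im_hat)^2) / (A + |A_hat|)`,
#' and returns `T = log2((E_w + eps) / (E + eps))` where `E_w` is the
#' error-weighted band energy. Predictable (tonal) content drives `E_w`
#' toward 0 and `T` strongly negative; noise stays near 0. `T` is clamped
#' to \[-30, 30\].
#'
#' @param frame `spectrum_frame` with phase (`need_phase = TRUE`).
#' @param state a primed [tonality_state()] (two segments pushed).
#' @param band a `band_selection`.
#' @return scalar tonality index `T`.
#' @export
tonal_index <- function(frame, state, band) {
  stopifnot(inherits(state, "tonality_state"))
  if (is.null(state$A2)) stop("tonality state not primed with two segments")
  if (is.null(frame$Phi)) stop("frame lacks a phase spectrum")
  A <- frame$A[band$idx]; Phi <- frame$Phi[band$idx]
  P <- frame$P[band$idx]
  A_hat <- 2 * state$A1 - state$A2
  Phi_hat <- 2 * state$Phi1 - state$Phi2
  dRe <- A * cos(Phi) - A_hat * cos(Phi_hat)
  dIm <- A * sin(Phi) - A_hat * sin(Phi_hat)
  W <- sqrt(dRe^2 + dIm^2) / (A + abs(A_hat) + WHEEZER_EPS)
  E <- sum(P)
  E_w <- sum(W * P)
  T_ <- log2((E_w + WHEEZER_EPS) / (E + WHEEZER_EPS))
  max(-TONALITY_CLAMP, min(TONALITY_CLAMP, T_))
}

# --- spectral peaks and entropy ---------------------------------------------

#' Strict local maxima of the band power spectrum
#'
#' A bin is a peak iff its power strictly exceeds both neighbours; the band
#' edge bins are excluded (no outer neighbour inside the band).
#'
#' @param frame a `spectrum_frame`.
#' @param band a `band_selection` at least 3 bins wide.
#' @return a `peak_set`: list with 0-based `k_peak` (ascending), magnitudes
#'   `P_peak`, and count `n_p`.
#' @export
find_spectral_peaks <- function(frame, band) {
  if (band$n_b < 3) stop("band must span at least 3 bins")
  p <- frame$P[band$idx]
  i <- 2:(band$n_b - 1L)
  is_peak <- p[i] > p[i - 1L] & p[i] > p[i + 1L]
  hit <- i[is_peak]
  structure(list(k_peak = band$k_lo + hit - 1L,
                 P_peak = p[hit],
                 n_p = length(hit)),
            class = "peak_set")
}

#' Shannon entropy of the normalized spectral peaks
#'
#' Peak magnitudes are normalized to a probability mass function and the
#' entropy `-sum(p * log2(p))` in bits is returned. Grouping of spectral
#' energy into few peaks (wheeze) lowers the entropy; `0 <= En <= log2(n_p)`.
#' An empty peak set or zero total mass yields 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param peaks a `peak_set` from [find_spectral_peaks()].
#' @return entropy in bits.
#' @export
peak_entropy <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  tot <- sum(peaks$P_peak)
  if (peaks$n_p == 0L || tot <= 0) {
    return(structure(0, degenerate = TRUE))
  }
  p <- peaks$P_peak / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Ratio of entropies of two successive segments
#'
#' `En[m] / En[m-1]`; if the previous entropy is (near) zero the ratio is
#' undefined and `NA_real_` is returned (classifiers treat it as
#' no-transition).
#'
#' @param en_current,en_previous entropies in bits.
#' @return the ratio, or `NA_real_` when undefined.
#' @export
entropy_ratio <- function(en_current, en_previous) {
  if (is.na(en_previous) || en_previous < WHEEZER_EPS) return(NA_real_)
  en_current / en_previous
}

# --- crest detection ---------------------------------------------------------

crest_window_idx <- function(k, half_width, band) {
  lo <- max(band$k_lo, k - half_width)
  hi <- min(band$k_hi, k + half_width)
  seq.int(lo, hi) + 1L
}

#' Crest detection by low-order statistical moments
#'
#' For each spectral peak, the `B_crest + 1` bins centred on it (clipped to
#' the analysis band) form its local band. The peak is accepted as a crest
#' iff its magnitude exceeds `C_m * mean(band) + C_s * sd(band)`, with the
#' population (1/n) standard deviation.
#'
#' @param frame a `spectrum_frame`.
#' @param peaks a `peak_set`.
#' @param band the analysis `band_selection`.
#' @param B_crest crest bandwidth in bins (even, >= 2; default 6).
#' @param C_m,C_s trained mean and standard-deviation coefficients.
#' @return a `crest_set`: list with 0-based `k_crest`, `P_crest`, count
#'   `n_c`, a subset of `peaks`.
#' @export
detect_crests_moments <- function(frame, peaks, band, B_crest = 6L,
                                  C_m = 1.5, C_s = 1.0) {
  if (B_crest < 2 || B_crest %% 2 != 0) stop("B_crest must be even and >= 2")
  keep <- logical(peaks$n_p)
  for (i in seq_len(peaks$n_p)) {
    v <- frame$P[crest_window_idx(peaks$k_peak[i], B_crest %/% 2L, band)]
    mu <- mean(v)
    sd_pop <- sqrt(mean(v^2) - mu^2)
    keep[i] <- peaks$P_peak[i] > C_m * mu + C_s * sd_pop
  }
  new_crest_set(peaks, keep)
}

#' Crest detection by localized energy ratios
#'
#' Around each peak three concentric bands are laid out: the crest band
#' (`B_crest + 1` bins) and two annular surroundings whose widths are given
#' in Hz (`B_narrow < B_wide`, crest bins excluded from both). The peak is
#' accepted iff `E_crest / E_narrow > C_narrow` and
#' `E_crest / E_wide > C_wide`. A zero annulus energy (pure tone on silence)
#' accepts the peak.
#'
#' @param frame a `spectrum_frame`.
#' @param peaks a `peak_set`.
#' @param band the analysis `band_selection`.
#' @param B_crest crest bandwidth in bins (even, >= 2).
#' @param B_narrow,B_wide surrounding bandwidths in Hz; must exceed the
#'   crest bandwidth, `B_crest * bin_hz < B_narrow < B_wide`.
#' @param C_narrow,C_wide trained energy-ratio thresholds.
#' @return a `crest_set`.
#' @export
detect_crests_energy <- function(frame, peaks, band, B_crest = 6L,
                                 B_narrow = 125, B_wide = 187.5,
                                 C_narrow = 1.2, C_wide = 1.5) {
  if (B_crest < 2 || B_crest %% 2 != 0) stop("B_crest must be even and >= 2")
  half_n <- floor((B_narrow / band$bin_hz) / 2)
  half_w <- floor((B_wide / band$bin_hz) / 2)
  half_c <- B_crest %/% 2L
  if (!(half_c < half_n && half_n < half_w))
    stop("bands must nest: B_crest < B_narrow < B_wide (in bins)")
  keep <- logical(peaks$n_p)
  for (i in seq_len(peaks$n_p)) {
    k <- peaks$k_peak[i]
    crest_idx <- crest_window_idx(k, half_c, band)
    E_crest <- sum(frame$P[crest_idx])
    E_narrow <- sum(frame$P[setdiff(crest_window_idx(k, half_n, band),
                                    crest_idx)])
    E_wide <- sum(frame$P[setdiff(crest_window_idx(k, half_w, band),
                                  crest_idx)])
    ok_n <- if (E_narrow <= 0) TRUE else E_crest / E_narrow > C_narrow
    ok_w <- if (E_wide <= 0) TRUE else E_crest / E_wide > C_wide
    keep[i] <- ok_n && ok_w
  }
  new_crest_set(peaks, keep)
}

new_crest_set <- function(peaks, keep) {
  structure(list(k_crest = peaks$k_peak[keep],
                 P_crest = peaks$P_peak[keep],
                 n_c = sum(keep)),
            class = "crest_set")
}

# --- temporal crest tracking -------------------------------------------------

#' Advance the crest tracks by one segment
#'
#' Each crest (ascending frequency) is greedily matched to the nearest live
#' unmatched track by absolute bin distance, provided the distance is below
#' the lag-1 continuity threshold `C_cont[1]`; ties resolve to the
#' lower-frequency track. A matched track appends the crest bin to its
#' history and increments its duration; its per-lag frequency deviations
#' `|k[m] - k[m-j]|, j = 1 ... min(M_cont, duration - 1)` are compared
#' against `C_cont[j]`, and the track is flagged continuous iff all pass.
#' Unmatched crests spawn new tracks (duration 1); unmatched tracks die.
#'
#' @param tracks list of track records (as returned by this function), or
#'   `list()` to start.
#' @param crests a `crest_set` for the current segment.
#' @param M_cont continuity depth in segments.
#' @param C_cont numeric vector of length `M_cont`, per-lag deviation
#'   thresholds in bins.
#' @return updated list of tracks; each track is a list with `bin` (current
#'   0-based bin), `bins` (recent history, newest last, up to `M_cont + 1`),
#'   `dm` (duration in segments), `continuous` (flag).
#' @export
update_crest_tracks <- function(tracks, crests, M_cont = 4L,
                                C_cont = rep(3, 4)) {
  if (length(C_cont) != M_cont) stop("C_cont must have length M_cont")
  track_bins <- vapply(tracks, function(t) t$bin, numeric(1))
  matched_track <- integer(0)
  assignment <- rep(NA_integer_, crests$n_c)  # crest i -> track index
  for (i in seq_len(crests$n_c)) {            # ascending frequency order
    free <- setdiff(seq_along(tracks), matched_track)
    if (length(free) == 0) next
    d <- abs(track_bins[free] - crests$k_crest[i])
    best <- min(d)
    if (best >= C_cont[1]) next               # too far: spawn a new track
    cand <- free[d == best]
    pick <- cand[which.min(track_bins[cand])] # tie -> lower frequency
    assignment[i] <- pick
    matched_track <- c(matched_track, pick)
  }
  out <- vector("list", crests$n_c)
  for (i in seq_len(crests$n_c)) {
    k <- crests$k_crest[i]
    if (is.na(assignment[i])) {
      out[[i]] <- list(bin = k, bins = k, dm = 1L, continuous = TRUE)
    } else {
      tr <- tracks[[assignment[i]]]
      bins <- c(tr$bins, k)
      if (length(bins) > M_cont + 1L)
        bins <- bins[(length(bins) - M_cont):length(bins)]
      dm <- tr$dm + 1L
      n_lag <- min(M_cont, dm - 1L, length(bins) - 1L)
      dev <- abs(k - bins[length(bins) - seq_len(n_lag)])
      out[[i]] <- list(bin = k, bins = bins, dm = dm,
                       continuous = all(dev < C_cont[seq_len(n_lag)]))
    }
  }
  out
}
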
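# Independent oracles and fixture builders shared across the suite.

# brute-force O(N^2) DFT
dft_direct <- function(x) {
  N <- length(x)
  n <- 0:(N - 1)
  vapply(0:(N - 1), function(k)
    sum(x * exp(-2i * pi * n * k / N)), complex(1))
}

# brute-force local-maximum scan over a band power vector (1-based offsets,
# edges excluded)
peaks_direct <- function(p) {
  hits <- integer(0)
  for (i in 2:(length(p) - 1))
    if (p[i] > p[i - 1] && p[i] > p[i + 1]) hits <- c(hits, i)
  hits
}

entropy_direct <- function(mags) {
  if (length(mags) == 0 || sum(mags) <= 0) return(0)
  p <- mags / sum(mags)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# exhaustive pairwise confusion counting
confusion_direct <- function(pred, ref) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] && ref[i]) tp <- tp + 1L
    else if (!pred[i] && !ref[i]) tn <- tn + 1L
    else if (pred[i] && !ref[i]) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

# a spectrum_frame with prescribed one-sided power values
fake_frame <- function(P, bin_hz = 15.625) {
  structure(list(X = complex(real = sqrt(P)), P = P, A = sqrt(P),
                 Phi = NULL, N = 2L * (length(P) - 1L), bin_hz = bin_hz),
            class = "spectrum_frame")
}

fake_band <- function(k_lo, k_hi, bin_hz = 15.625) {
  structure(list(k_lo = as.integer(k_lo), k_hi = as.integer(k_hi),
                 n_b = as.integer(k_hi - k_lo + 1L),
                 idx = seq.int(k_lo, k_hi) + 1L, bin_hz = bin_hz),
            class = "band_selection")
}

fake_peaks <- function(k, P) {
  structure(list(k_peak = as.integer(k), P_peak = P, n_p = length(k)),
            class = "peak_set")
}

# pure-tone recording (for detector traces)
tone_recording <- function(f0 = 400, duration = 2, fs = 8000, amp = 1,
                           id = "tone") {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  resp_recording(amp * sin(2 * pi * f0 * t), fs, id = id)
}

# random crest set ordered by bin
random_crests <- function(k) {
  k <- sort(unique(as.integer(k)))
  structure(list(k_crest = k, P_crest = rep(1, length(k)),
                 n_c = length(k)),
            class = "crest_set")
}
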
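#' Periodic Hamming window
#'
#' The periodic (DFT-even) Hamming window `0.54 - 0.46 cos(2 pi n / N)`,
#' `n = 0 ... N-1`, the STFT convention for overlapped analysis.
#'
#' @param N window length in samples.
#' @return numeric vector of length `N`.
#' @export
hamming_window <- function(N) {
  n <- seq_len(N) - 1L
  0.54 - 0.46 * cos(2 * pi * n / N)
}

analysis_window <- function(window, N) {
  if (is.numeric(window)) {
    if (length(window) != N) stop("window length must equal segment length")
    return(as.numeric(window))
  }
  switch(match.arg(window, c("hamming", "rectangular")),
         hamming = hamming_window(N),
         rectangular = rep(1, N))
}

#' One-sided spectrum of a windowed segment
#'
#' Windows the segment, takes its DFT, and keeps the one-sided spectrum
#' (bins `0 ... N/2`, stored 1-based as elements `1 ... N/2 + 1`). The power
#' spectrum `P[k] = Re(X[k])^2 + Im(X[k])^2` and amplitude spectrum
#' `A[k] = sqrt(P[k])` are always filled; the phase spectrum (radians,
#' `atan2` convention, range (-pi, pi]) only when `need_phase = TRUE`
#' (required by the tonality detector only).
#'
#' @param seg numeric vector, one analysis segment.
#' @param sample_rate sampling rate in Hz.
#' @param window `"hamming"` (default), `"rectangular"`, or a numeric vector
#'   of the same length as `seg`.
#' @param need_phase compute the phase spectrum?
#' @return object of class `spectrum_frame`: list with complex `X`, `P`,
#'   `A`, `Phi` (or NULL), `N`, and `bin_hz` (Hz per bin).
#' @export
analyze_segment <- function(seg, sample_rate, window = "hamming",
                            need_phase = FALSE) {
  seg <- as.numeric(seg)
  N <- length(seg)
  if (N < 2) stop("segment too short")
  w <- analysis_window(window, N)
  X_full <- stats::fft(seg * w)
  half <- N %/% 2 + 1L
  X <- X_full[seq_len(half)]
  P <- Re(X)^2 + Im(X)^2
  structure(list(X = X, P = P, A = sqrt(P),
                 Phi = if (need_phase) atan2(Im(X), Re(X)) else NULL,
                 N = N, bin_hz = sample_rate / N),
            class = "spectrum_frame")
}

#' Select the analysis band of a spectrum
#'
#' Returns the inclusive one-sided bin range covering `[f_lo, f_hi]`:
#' `k_lo = ceiling(f_lo / bin_hz)`, `k_hi = floor(f_hi / bin_hz)` (0-based
#' bins). The default band 60-950 Hz excludes heart sounds (concentrated
#' below 60 Hz) while covering the wheeze range; at N = 512 and 8 kHz it
#' yields the characteristic band width of 57 bins.
#'
#' @param bin_hz Hz per DFT bin, or a `spectrum_frame` from
#'   [analyze_segment()].
#' @param f_lo,f_hi band limits in Hz, `0 <= f_lo < f_hi <= Nyquist`.
#' @param N segment length (needed to check against Nyquist when `bin_hz`
#'   is a number; taken from the frame otherwise).
#' @return object of class `band_selection`: list with 0-based `k_lo`,
#'   `k_hi`, band width `n_b`, 1-based index vector `idx` into one-sided
#'   spectra, and `bin_hz`.
#' @export
select_band <- function(bin_hz, f_lo = 60, f_hi = 950, N = NULL) {
  if (inherits(bin_hz, "spectrum_frame")) {
    N <- bin_hz$N
    bin_hz <- bin_hz$bin_hz
  }
  if (is.null(N)) stop("N required when bin_hz is given as a number")
  nyquist <- bin_hz * (N / 2)
  if (f_lo < 0 || f_hi > nyquist + 1e-9 || f_lo >= f_hi)
    stop("band limits must satisfy 0 <= f_lo < f_hi <= Nyquist")
  k_lo <- as.integer(ceiling(f_lo / bin_hz))
  k_hi <- as.integer(floor(f_hi / bin_hz))
  if (k_hi < k_lo) stop("empty analysis band")
  structure(list(k_lo = k_lo, k_hi = k_hi, n_b = k_hi - k_lo + 1L,
                 idx = seq.int(k_lo, k_hi) + 1L, bin_hz = bin_hz),
            class = "band_selection")
}
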
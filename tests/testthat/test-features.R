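test_that("segment energy equals direct band summation", {
  set.seed(31)
  band <- fake_band(4, 60)
  expect_equal(segment_energy(fake_frame(numeric(257)), band), 0)
  P <- numeric(257); P[band$idx] <- 1
  expect_equal(segment_energy(fake_frame(P), band), 57)
  for (i in 1:20) {
    P <- runif(257)
    expect_equal(segment_energy(fake_frame(P), band), sum(P[5:61]))
  }
})

test_that("energy history keeps a bounded window and exposes its extrema", {
  h <- energy_history(M_E = 3)
  expect_error(energy_bounds(h), "empty")
  h <- push_energy(h, 3)
  expect_equal(energy_bounds(h), c(E_min = 3, E_max = 3))
  for (e in c(5, 1, 4)) h <- push_energy(h, e)
  expect_equal(energy_bounds(h), c(E_min = 1, E_max = 5))
  # sliding-window oracle over a long random push sequence
  set.seed(32)
  e_all <- runif(100)
  h <- energy_history(M_E = 10)
  for (i in seq_along(e_all)) {
    h <- push_energy(h, e_all[i])
    w <- e_all[max(1, i - 10):i]
    expect_equal(unname(energy_bounds(h)), c(min(w), max(w)))
  }
})

test_that("tonality index separates predictable tones from noise", {
  band <- fake_band(4, 60)
  fs <- 8000; N <- 512
  make_frame <- function(x)
    analyze_segment(x, fs, window = "hamming", need_phase = TRUE)
  # stationary bin-centered tone: three 50%-overlapped segments
  f0 <- 16 * fs / N    # exactly bin 16
  t <- (0:(2 * N - 1)) / fs
  x <- sin(2 * pi * f0 * t)
  segs <- lapply(0:2, function(m) x[m * 256 + 1:N])
  st <- tonality_state()
  st <- push_tonality(st, make_frame(segs[[1]]), band)
  st <- push_tonality(st, make_frame(segs[[2]]), band)
  T_tone <- tonal_index(make_frame(segs[[3]]), st, band)
  expect_lt(T_tone, -20)   # near-perfect prediction, clamped toward -30

  # all-zero spectra: defined as 0 by the epsilon guard
  st0 <- tonality_state()
  z <- make_frame(numeric(N))
  st0 <- push_tonality(push_tonality(st0, z, band), z, band)
  expect_equal(tonal_index(z, st0, band), 0)

  # population medians: tone << noise
  set.seed(33)
  run_T <- function(xs) {
    st <- tonality_state(); out <- numeric(0)
    for (j in seq_along(xs)) {
      fr <- make_frame(xs[[j]])
      if (j >= 3) out <- c(out, tonal_index(fr, st, band))
      st <- push_tonality(st, fr, band)
    }
    out
  }
  n_seg <- 50
  long <- sin(2 * pi * 400 * (0:((n_seg + 1) * 256 + 255)) / fs)
  tone_segs <- lapply(0:(n_seg - 1), function(m) long[m * 256 + 1:N])
  noise_segs <- lapply(seq_len(n_seg), function(i) rnorm(N))
  expect_lt(median(run_T(tone_segs)), median(run_T(noise_segs)))
  # noise-like content has near-zero tonality
  expect_gt(median(run_T(noise_segs)), -2)
})

test_that("tonality state must be primed with two segments", {
  band <- fake_band(4, 60)
  fr <- analyze_segment(rnorm(512), 8000, need_phase = TRUE)
  st <- push_tonality(tonality_state(), fr, band)
  expect_error(tonal_index(fr, st, band), "primed")
})

test_that("peak finding matches an exhaustive scan (random spectra)", {
  set.seed(34)
  band <- fake_band(4, 60)
  for (i in 1:100) {
    P <- numeric(257)
    P[band$idx] <- sample(1:50, 57, replace = TRUE)  # ties exercised
    pk <- find_spectral_peaks(fake_frame(P), band)
    ref <- peaks_direct(P[band$idx])
    expect_identical(pk$k_peak, as.integer(4 + ref - 1))
    expect_equal(pk$P_peak, P[band$idx][ref])
    expect_identical(pk$n_p, length(ref))
  }
})

test_that("peak finding on canonical shapes", {
  band <- fake_band(0, 4, bin_hz = 10)
  P5 <- function(v) fake_frame(c(v, numeric(0)))
  pk <- find_spectral_peaks(P5(c(1, 3, 2, 5, 4)), band)
  expect_identical(pk$k_peak, c(1L, 3L))
  expect_equal(pk$P_peak, c(3, 5))
  expect_identical(find_spectral_peaks(P5(c(1, 2, 3, 4, 5)), band)$n_p, 0L)
  expect_identical(find_spectral_peaks(P5(rep(2, 5)), band)$n_p, 0L)
})

test_that("peak entropy: closed forms and the log2(n) bound", {
  expect_equal(as.numeric(peak_entropy(fake_peaks(5, 3))), 0)
  expect_equal(as.numeric(peak_entropy(fake_peaks(1:4, rep(7, 4)))), 2)
  expect_equal(as.numeric(peak_entropy(fake_peaks(1:3, c(2, 1, 1)))), 1.5)
  set.seed(35)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    mags <- runif(n, 0.1, 10)
    en <- as.numeric(peak_entropy(fake_peaks(seq_len(n), mags)))
    expect_equal(en, entropy_direct(mags))
    expect_lte(en, log2(n) + 1e-12)
    expect_gte(en, 0)
  }
  # equality at the bound iff magnitudes equal
  expect_equal(as.numeric(peak_entropy(fake_peaks(1:8, rep(1, 8)))), 3)
  deg <- peak_entropy(fake_peaks(integer(0), numeric(0)))
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
})

test_that("entropy ratio and its undefined guard", {
  expect_equal(entropy_ratio(2, 2), 1)
  expect_equal(entropy_ratio(1, 2), 0.5)
  expect_true(is.na(entropy_ratio(1, 0)))
})

test_that("moment-based crest acceptance matches hand arithmetic", {
  # band values {1,1,1,10,1,1,1} centered on the peak
  P <- numeric(257)
  P[31 + 1 + (-3:3)] <- c(1, 1, 1, 10, 1, 1, 1)
  band <- fake_band(4, 60)
  peaks <- find_spectral_peaks(fake_frame(P), band)
  expect_identical(peaks$k_peak, 31L)
  cs <- detect_crests_moments(fake_frame(P), peaks, band,
                              B_crest = 6, C_m = 1.5, C_s = 1.0)
  expect_identical(cs$n_c, 1L)   # threshold ~6.46 < 10
  # population sd assumption: mean 15/7, sd sqrt(106/7 - (15/7)^2)
  thr <- 1.5 * (15 / 7) + sqrt(106 / 7 - (15 / 7)^2)
  expect_lt(thr, 10)
  # strict version with larger coefficients rejects
  cs2 <- detect_crests_moments(fake_frame(P), peaks, band,
                               B_crest = 6, C_m = 3, C_s = 2.5)
  expect_identical(cs2$n_c, 0L)
})

test_that("crest detectors return subsets of the peak set; zero thresholds degenerate", {
  set.seed(36)
  band <- fake_band(4, 60)
  for (i in 1:100) {
    P <- numeric(257); P[band$idx] <- rexp(57)
    fr <- fake_frame(P)
    peaks <- find_spectral_peaks(fr, band)
    cs <- detect_crests_moments(fr, peaks, band, 6, runif(1, 0.5, 3),
                                runif(1, 0, 2))
    expect_true(all(cs$k_crest %in% peaks$k_peak))
    ce <- detect_crests_energy(fr, peaks, band, 6, 125, 187.5,
                               runif(1, 0.2, 2), runif(1, 0.2, 2))
    expect_true(all(ce$k_crest %in% peaks$k_peak))
    # brute-force re-decision for the moments detector
    cm <- 1.2; csd <- 0.8
    got <- detect_crests_moments(fr, peaks, band, 6, cm, csd)
    keep <- vapply(seq_len(peaks$n_p), function(j) {
      k <- peaks$k_peak[j]
      v <- P[(max(4, k - 3):min(60, k + 3)) + 1]
      mu <- mean(v); sdp <- sqrt(mean((v - mu)^2))
      peaks$P_peak[j] > cm * mu + csd * sdp
    }, logical(1))
    expect_identical(got$k_crest, peaks$k_peak[keep])
    # zero coefficients accept every peak
    all_in <- detect_crests_moments(fr, peaks, band, 6, 0, 0)
    expect_identical(all_in$k_crest, peaks$k_peak)
  }
})

test_that("energy-based crest acceptance follows annular ratios", {
  band <- fake_band(0, 100, bin_hz = 15.625)
  # crest of high power at bin 50, low surroundings
  P <- rep(0.1, 257)
  P[50 + 1 + (-3:3)] <- c(1, 3, 8, 20, 8, 3, 1)
  fr <- fake_frame(P)
  peaks <- fake_peaks(50, 20)
  acc <- detect_crests_energy(fr, peaks, band, 6, 125, 187.5, 1.2, 1.5)
  expect_identical(acc$n_c, 1L)
  # flat spectrum with a narrow crest band: each ratio equals
  # crest-bin count / annulus-bin count (3/6 and 3/10) < 1 -> rejected
  flat <- fake_frame(rep(2, 257))
  pf <- fake_peaks(50, 2)
  rej <- detect_crests_energy(flat, pf, band, 2, 125, 187.5, 1.0, 1.0)
  expect_identical(rej$n_c, 0L)
  # silence outside the crest: guard accepts
  Pz <- numeric(257); Pz[50 + 1 + (-3:3)] <- 5
  guard <- detect_crests_energy(fake_frame(Pz), fake_peaks(50, 5), band,
                                6, 125, 187.5, 1.2, 1.5)
  expect_identical(guard$n_c, 1L)
})

test_that("crest tracks: persistence, jumps, and the tie rule", {
  # same bin for 5 segments: one track, duration 5, deviations 0
  tracks <- list()
  for (i in 1:5)
    tracks <- update_crest_tracks(tracks, random_crests(30), 4, rep(3, 4))
  expect_length(tracks, 1)
  expect_identical(tracks[[1]]$dm, 5L)
  expect_true(tracks[[1]]$continuous)

  # 10-bin jump with thresholds 3: old track dies, duration resets
  tracks <- list()
  for (i in 1:3)
    tracks <- update_crest_tracks(tracks, random_crests(30), 4, rep(3, 4))
  tracks <- update_crest_tracks(tracks, random_crests(40), 4, rep(3, 4))
  expect_length(tracks, 1)
  expect_identical(tracks[[1]]$dm, 1L)

  # two crests equidistant from two tracks: lowest frequency first
  tracks <- update_crest_tracks(list(), random_crests(c(20, 24)), 4, rep(3, 4))
  tracks <- update_crest_tracks(tracks, random_crests(c(22, 26)), 4, rep(3, 4))
  # crest 22 is distance 2 from both track 20 and 24 -> takes track 20;
  # crest 26 then matches track 24
  expect_identical(vapply(tracks, function(t) t$dm, integer(1)), c(2L, 2L))
  expect_identical(tracks[[1]]$bins, c(20L, 22L))
  expect_identical(tracks[[2]]$bins, c(24L, 26L))
})

test_that("a slow chirp within the lag-1 threshold survives as one track", {
  # drift of 1 bin per segment, C_cont[1] = 3
  tracks <- list()
  for (i in 0:19)
    tracks <- update_crest_tracks(tracks, random_crests(20 + i), 4,
                                  c(3, 5, 7, 9))
  expect_length(tracks, 1)
  expect_identical(tracks[[1]]$dm, 20L)
  expect_true(tracks[[1]]$continuous)
})
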
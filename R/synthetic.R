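# Seeded generator of annotated synthetic respiratory recordings.
# Background: band-limited colored noise (4th-order Butterworth band-pass,
# default emphasis 100-250 Hz, plus a small broadband floor) amplitude-
# modulated by a respiratory-cycle envelope (inspiration louder and at
# least as long as expiration, near-silent inter-respiratory pauses,
# raised-cosine phase ramps). Wheezes: 1-3 slowly drifting harmonic
# components superimposed at a controlled local SNR measured against the
# background within the wheeze interval.

#' Simulation configuration
#'
#' @param n_cycles number of respiratory cycles.
#' @param sample_rate sampling rate in Hz.
#' @param insp_s,exp_s,pause_s phase durations in seconds.
#' @param ie_ratio inspiration/expiration amplitude ratio (> 1: inspiration
#'   louder).
#' @param pause_level pause amplitude relative to inspiration.
#' @param noise_band noise emphasis band in Hz, `c(lo, hi)`.
#' @param noise_floor broadband white-noise floor relative to the shaped
#'   noise (amplitude fraction).
#' @param ramp_s raised-cosine ramp length at each phase boundary, seconds.
#' @param wheezes data.frame with one row per wheeze: `start_s`,
#'   `duration_s`, `f0` (fundamental, Hz), `n_harmonics` (1-3), `drift`
#'   (Hz/s of the fundamental), `snr_db` (local SNR in dB).
#' @param seed integer seed; a fixed seed reproduces the waveform exactly.
#' @param id recording label.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cycles = 3L, sample_rate = 8000,
                       insp_s = 1.5, exp_s = 1.5, pause_s = 1.0,
                       ie_ratio = 2, pause_level = 0.03,
                       noise_band = c(100, 250), noise_floor = 0.05,
                       ramp_s = 0.1,
                       wheezes = empty_wheezes(),
                       seed = 1L, id = "sim") {
  stopifnot(insp_s > 0, exp_s > 0, pause_s >= 0, ie_ratio >= 1,
            noise_band[1] > 0, noise_band[2] > noise_band[1],
            noise_band[2] < sample_rate / 2)
  duration <- n_cycles * (insp_s + exp_s + pause_s)
  if (nrow(wheezes)) {
    stopifnot(all(wheezes$duration_s > 0),
              all(wheezes$n_harmonics %in% 1:3),
              all(wheezes$f0 >= 100), all(wheezes$f0 <= 1500))
    if (any(wheezes$start_s < 0) ||
        any(wheezes$start_s + wheezes$duration_s > duration))
      stop("wheeze extends past the recording duration")
    if (any(wheezes$f0 * wheezes$n_harmonics +
            abs(wheezes$drift) * wheezes$duration_s >= sample_rate / 2))
      stop("wheeze harmonics exceed the Nyquist frequency")
  }
  structure(list(n_cycles = as.integer(n_cycles), sample_rate = sample_rate,
                 insp_s = insp_s, exp_s = exp_s, pause_s = pause_s,
                 ie_ratio = ie_ratio, pause_level = pause_level,
                 noise_band = noise_band, noise_floor = noise_floor,
                 ramp_s = ramp_s, wheezes = wheezes,
                 seed = as.integer(seed), id = id,
                 duration = duration),
            class = "sim_config")
}

empty_wheezes <- function()
  data.frame(start_s = numeric(0), duration_s = numeric(0),
             f0 = numeric(0), n_harmonics = integer(0),
             drift = numeric(0), snr_db = numeric(0))

# raised-cosine on/off ramps within a phase of n samples
phase_envelope <- function(n, amp, ramp_n) {
  env <- rep(amp, n)
  r <- min(ramp_n, n %/% 2)
  if (r > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    env[seq_len(r)] <- amp * up
    env[(n - r + 1L):n] <- amp * rev(up)
  }
  env
}

#' Generate one annotated synthetic respiratory recording
#'
#' @param cfg a [sim_config()].
#' @return list with `recording` (a [resp_recording()], peak-normalized),
#'   `annotation` (a [resp_annotation()] carrying exact wheeze intervals
#'   and phase boundaries), and `peak` (the pre-normalization amplitude
#'   scale).
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  fs <- cfg$sample_rate
  n_total <- round(cfg$duration * fs)
  ramp_n <- round(cfg$ramp_s * fs)

  # respiratory-cycle envelope and phase annotation
  env <- numeric(0)
  phases <- list()
  t0 <- 0
  phase_spec <- list(c("insp", cfg$insp_s, 1),
                     c("exp", cfg$exp_s, 1 / cfg$ie_ratio),
                     c("pause", cfg$pause_s, cfg$pause_level))
  for (cyc in seq_len(cfg$n_cycles)) {
    for (ph in phase_spec) {
      dur <- as.numeric(ph[2]); amp <- as.numeric(ph[3])
      n <- round(dur * fs)
      if (n > 0) {
        env <- c(env, phase_envelope(n, amp, ramp_n))
        phases[[length(phases) + 1L]] <-
          data.frame(start_s = t0, end_s = t0 + dur, phase = ph[1])
        t0 <- t0 + dur
      }
    }
  }
  env <- env[seq_len(min(length(env), n_total))]
  if (length(env) < n_total) env <- c(env, rep(cfg$pause_level,
                                               n_total - length(env)))

  # colored background noise
  white <- stats::rnorm(n_total)
  bf <- signal::butter(2, cfg$noise_band / (fs / 2), type = "pass")
  shaped <- as.numeric(signal::filter(bf, white))
  shaped <- shaped / stats::sd(shaped)
  noise <- (shaped + cfg$noise_floor * stats::rnorm(n_total)) * env

  x <- noise
  intervals <- empty_intervals()
  wz <- cfg$wheezes
  for (i in seq_len(nrow(wz))) {
    i0 <- max(1L, round(wz$start_s[i] * fs) + 1L)
    i1 <- min(n_total, round((wz$start_s[i] + wz$duration_s[i]) * fs))
    idx <- i0:i1
    tt <- (seq_along(idx) - 1L) / fs
    # fundamental with linear drift; harmonic amplitudes roll off as 1/h
    phase0 <- stats::runif(wz$n_harmonics[i], 0, 2 * pi)
    inst_phase <- 2 * pi * (wz$f0[i] * tt + 0.5 * wz$drift[i] * tt^2)
    tone <- numeric(length(idx))
    for (h in seq_len(wz$n_harmonics[i]))
      tone <- tone + sin(h * inst_phase + phase0[h]) / h
    edge <- phase_envelope(length(idx), 1, round(0.02 * fs))
    tone <- tone * edge
    p_noise <- mean(noise[idx]^2)
    p_tone <- mean(tone^2)
    if (p_tone > 0 && p_noise > 0)
      tone <- tone * sqrt(p_noise * 10^(wz$snr_db[i] / 10) / p_tone)
    x[idx] <- x[idx] + tone
    intervals <- rbind(intervals,
                       data.frame(start_s = wz$start_s[i],
                                  end_s = wz$start_s[i] + wz$duration_s[i],
                                  label = "W"))
  }

  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  list(recording = resp_recording(x, fs, id = cfg$id),
       annotation = resp_annotation(intervals = intervals,
                                    phases = do.call(rbind, phases)),
       peak = peak)  # normalization scale, for reconstructing raw layers
}

#' Generate a dataset of annotated synthetic recordings
#'
#' Normal recordings carry only the cyclostationary breath noise; wheeze
#' recordings additionally contain 2-3 wheezes placed inside expiratory
#' phases, with fundamentals, harmonic counts, durations and drifts drawn
#' from `ranges`. Per-recording seeds are derived deterministically from
#' `seed`, so the whole dataset is reproducible from the master seed.
#'
#' @param n_normal,n_wheeze recording counts per class.
#' @param ranges named list of draw ranges: `f0` (Hz), `duration_s`,
#'   `drift` (Hz/s), `snr_db` (dB), `n_harmonics` (choices). Defaults:
#'   f0 200-800 Hz, duration 0.5-1.2 s, drift -25 to 25 Hz/s, SNR fixed at
#'   15 dB, 1-2 harmonics.
#' @param seed master seed.
#' @return list of `list(recording=, annotation=)` pairs, wheeze
#'   recordings first (`W01 ...`), then normal (`N01 ...`).
#' @export
generate_dataset <- function(n_normal = 13L, n_wheeze = 13L,
                             ranges = list(), seed = 1L) {
  rng <- utils::modifyList(
    list(f0 = c(200, 800), duration_s = c(0.5, 1.2),
         drift = c(-25, 25), snr_db = c(15, 15), n_harmonics = 1:2),
    ranges)
  out <- vector("list", n_wheeze + n_normal)
  k <- 0L
  for (i in seq_len(n_wheeze)) {
    k <- k + 1L
    seed_i <- (seed + 7919L * k) %% 2147483647L
    set.seed(seed_i)
    base <- sim_config(seed = seed_i)         # phase timing of the default cycle
    n_wz <- sample(2:3, 1)
    cycles <- sort(sample(seq_len(base$n_cycles), n_wz))
    cycle_len <- base$insp_s + base$exp_s + base$pause_s
    wz <- do.call(rbind, lapply(cycles, function(cy) {
      dur <- stats::runif(1, rng$duration_s[1], rng$duration_s[2])
      exp_start <- (cy - 1) * cycle_len + base$insp_s
      margin <- base$exp_s - dur - 0.1
      start <- exp_start + 0.05 + stats::runif(1, 0, max(0, margin))
      data.frame(start_s = start, duration_s = dur,
                 f0 = stats::runif(1, rng$f0[1], rng$f0[2]),
                 n_harmonics = sample(rng$n_harmonics, 1),
                 drift = stats::runif(1, rng$drift[1], rng$drift[2]),
                 snr_db = stats::runif(1, rng$snr_db[1], rng$snr_db[2]))
    }))
    out[[k]] <- generate_recording(
      sim_config(wheezes = wz, seed = seed_i,
                 id = sprintf("W%02d", i)))
  }
  for (i in seq_len(n_normal)) {
    k <- k + 1L
    seed_i <- (seed + 7919L * k) %% 2147483647L
    out[[k]] <- generate_recording(
      sim_config(seed = seed_i, id = sprintf("N%02d", i)))
  }
  out
}
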
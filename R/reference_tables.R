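# Reference benchmark figures from the published evaluation campaign of
# the four detectors on a 16-bit fixed-point DSP (TMS320C5505 at 100 MHz,
# 64 ms segments with 50% overlap, leave-one-out training on a 26-recording
# clinical/web-sourced dataset). The package does not profile hardware;
# these figures are inputs to the efficiency bookkeeping.

#' Reference DSP cycle counts per detector
#'
#' Average worst-case clock cycles spent classifying one signal segment on
#' a reference 100 MHz fixed-point DSP implementation, and the cycle budget
#' between successive segments (32 ms at 100 MHz = 3.2e6 cycles).
#'
#' @return data.frame with columns `algorithm`, `cycles_exec`.
#' @export
reference_cycle_counts <- function() {
  data.frame(algorithm = 1:4,
             cycles_exec = c(77287, 82888, 98957, 59998))
}

#' Reference cycle budget between successive segments
#' @return 3.2e6 (cycles), as a number.
#' @export
reference_cycle_budget <- function() 3.2e6

#' Reference classification accuracies of the four detectors
#'
#' Overall (whole-database) sensitivity, specificity and accuracy of each
#' detector after leave-one-out training, in percent, for the two operating
#' scenarios: `dur` (segment-wise wheeze-duration tracking) and `event`
#' (respiratory-phase-wise occurrence detection).
#'
#' @return data.frame with columns `algorithm`, `scenario`, `SE`, `SP`,
#'   `AC` (percent).
#' @export
reference_accuracies <- function() {
  data.frame(
    algorithm = rep(1:4, 2),
    scenario = rep(c("dur", "event"), each = 4),
    SE = c(86.30, 87.51, 80.10, 82.54, 98.46, 96.92, 76.92, 87.69),
    SP = c(89.50, 93.42, 70.56, 83.64, 81.08, 91.21, 89.86, 73.28),
    AC = c(89.01, 92.53, 71.98, 83.79, 86.39, 92.96, 85.92, 76.52))
}

#' Reference recording inventory
#'
#' Bookkeeping of the 26-recording reference dataset (13 normal, 13
#' wheeze-containing): duration, number of 50%-overlapped 64 ms segments,
#' respiratory phases, annotated wheeze intervals, and original sampling
#' rate. The recordings themselves are not distributable; the inventory
#' drives the dataset arithmetic of the two scoring scenarios.
#'
#' @return data.frame with columns `label`, `duration_s`, `segments`,
#'   `phases`, `wheeze_intervals` (`NA` for normal recordings),
#'   `sample_rate_khz`.
#' @export
reference_inventory <- function() {
  normal <- data.frame(
    label = sprintf("N%02d", 1:13),
    duration_s = c(12.76, 13.48, 10.09, 6.48, 3.12, 6.32, 5.33, 5.34,
                   12.86, 10.09, 20.00, 9.99, 25.76),
    segments = c(398L, 421L, 315L, 202L, 97L, 197L, 166L, 167L, 402L,
                 315L, 625L, 312L, 805L),
    phases = c(8L, 8L, 6L, 4L, 2L, 4L, 4L, 4L, 6L, 11L, 10L, 4L, 11L),
    wheeze_intervals = NA_integer_,
    sample_rate_khz = c(44.1, 44.1, 11.025, 11.025, 11.025, 11.025,
                        11.025, 11.025, 8, 11.025, 8, 11.025, 44.1))
  wheeze <- data.frame(
    label = sprintf("W%02d", 1:13),
    duration_s = c(11.89, 26.73, 15.83, 4.60, 8.04, 10.10, 20.00, 7.52,
                   9.48, 10.15, 29.96, 10.60, 9.70),
    segments = c(371L, 835L, 494L, 143L, 251L, 315L, 625L, 235L, 296L,
                 317L, 936L, 331L, 303L),
    phases = c(11L, 10L, 16L, 4L, 7L, 9L, 12L, 6L, 6L, 8L, 30L, 6L, 6L),
    wheeze_intervals = c(7L, 5L, 7L, 3L, 3L, 4L, 6L, 3L, 3L, 4L, 15L,
                         2L, 3L),
    sample_rate_khz = c(44.1, 22.05, 22.05, 11.025, 11.025, 11.025, 8,
                        11.025, 44.1, 8, 44.1, 8, 8))
  rbind(normal, wheeze)
}

#' Dataset arithmetic of the reference inventory
#'
#' Totals used by the two scoring scenarios: segment counts per class for
#' the duration-tracking scenario, and respiratory-phase positives /
#' negatives for the event-detection scenario (a phase is a positive iff
#' the recording's annotation places a wheeze interval in it; every
#' annotated wheeze interval of the reference set lies in a distinct
#' phase, so positives equal the wheeze-interval total).
#'
#' @param inventory an inventory data.frame; default
#'   [reference_inventory()].
#' @return named list: `segments_normal`, `segments_wheeze`,
#'   `phases_normal_recordings`, `phases_wheeze_recordings`,
#'   `wheeze_intervals`, `event_positives`, `event_negatives`.
#' @export
inventory_summary <- function(inventory = reference_inventory()) {
  is_wheeze <- !is.na(inventory$wheeze_intervals)
  wheeze_intervals <- sum(inventory$wheeze_intervals[is_wheeze])
  phases_w <- sum(inventory$phases[is_wheeze])
  phases_n <- sum(inventory$phases[!is_wheeze])
  positives <- wheeze_intervals
  list(segments_normal = sum(inventory$segments[!is_wheeze]),
       segments_wheeze = sum(inventory$segments[is_wheeze]),
       phases_normal_recordings = phases_n,
       phases_wheeze_recordings = phases_w,
       wheeze_intervals = wheeze_intervals,
       event_positives = positives,
       event_negatives = phases_w - positives + phases_n)
}
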
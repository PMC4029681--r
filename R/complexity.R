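# Executable operation-count model of the feature-extraction pipeline, for
# complexity budgeting on fixed-point embedded targets. Costs are worst-case
# multiplication/addition counts per signal segment, with multiplicative
# constants kept and additive constants dropped. Elementary functions
# (division, sqrt, log2, trigonometry) are costed for iterative
# approximations (Newton-Raphson, Newton, Taylor), with per-function
# iteration counts as parameters. All arithmetic is exact integer.

#' Parameters of the operation-count model
#'
#' @param N segment length (power of two; radix-2 FFT).
#' @param N_b analysis band width in bins.
#' @param N_p worst-case spectral peak count per segment.
#' @param B_crest crest bandwidth in bins.
#' @param N_c worst-case crest count.
#' @param M_cont continuity depth in segments.
#' @param B_narrow,B_wide surrounding bandwidths in bins.
#' @param N_itNR Newton-Raphson iterations (division).
#' @param N_itN Newton iterations (square root).
#' @param N_itTL Taylor terms (log2).
#' @param N_itTS,N_itTC,N_itTA Taylor terms (sin, cos, arctg).
#' @return a `complexity_params` list. Defaults are the characteristic
#'   parameter set of a 512-sample segment with a 57-bin band.
#' @export
complexity_params <- function(N = 512L, N_b = 57L, N_p = 20L,
                              B_crest = 6L, N_c = 7L, M_cont = 4L,
                              B_narrow = 8L, B_wide = 12L,
                              N_itNR = 3L, N_itN = 5L, N_itTL = 5L,
                              N_itTS = 3L, N_itTC = 3L, N_itTA = 3L) {
  p <- lapply(list(N = N, N_b = N_b, N_p = N_p, B_crest = B_crest,
                   N_c = N_c, M_cont = M_cont, B_narrow = B_narrow,
                   B_wide = B_wide, N_itNR = N_itNR, N_itN = N_itN,
                   N_itTL = N_itTL, N_itTS = N_itTS, N_itTC = N_itTC,
                   N_itTA = N_itTA), as.integer)
  if (any(unlist(p) <= 0L)) stop("all complexity parameters must be positive")
  if (bitwAnd(p$N, p$N - 1L) != 0L) stop("N must be a power of two")
  structure(p, class = "complexity_params")
}

op_count <- function(mults, adds) {
  c(mults = as.integer(round(mults)), adds = as.integer(round(adds)))
}

#' Operation count of one program block
#'
#' Block ids: elementary functions `division`, `sqrt`, `log2`, `sin`,
#' `cos`, `arctg`; front-end `windowing`, `stft`, `power_spectrum`,
#' `amplitude_spectrum`, `phase_spectrum`; features `energy`, `tonality`,
#' `peaks`, `entropy`, `crests_moments`, `crests_energy`, `continuity`.
#'
#' @param block block id (see above).
#' @param params a [complexity_params()].
#' @return integer vector `c(mults, adds)`.
#' @export
block_cost <- function(block, params = complexity_params()) {
  stopifnot(inherits(params, "complexity_params"))
  with(params, switch(block,
    division = op_count(3 * N_itNR, N_itNR),
    sqrt     = op_count(2 * N_itN, 2 * N_itN),
    log2     = op_count(N_itTL * (N_itTL + 1) / 2, N_itTL),
    sin      = op_count((2 * N_itTS - 1)^2, N_itTS),
    cos      = op_count((2 * N_itTC - 2) * (2 * N_itTC - 1), N_itTC),
    arctg    = op_count((2 * N_itTA - 1)^2, N_itTA),
    windowing = op_count(N, 0),
    stft     = op_count(2 * N * log2(N), 3 * N * log2(N)),
    power_spectrum = op_count(2 * N_b, N_b),
    amplitude_spectrum = op_count(2 * N_b * N_itN, 2 * N_b * N_itN),
    phase_spectrum = op_count(N_b * ((2 * N_itTA - 1)^2 + 3 * N_itNR + 1),
                              N_b * (N_itNR + N_itTA - 1)),
    energy   = op_count(N_b, 3 * N_b),
    tonality = op_count(
      N_b * ((2 * N_itTC - 2) * (2 * N_itTC - 1) + (2 * N_itTA - 1)^2 +
               2 * N_itN + 3 * N_itNR + 5) + N_itTL * (N_itTL + 1) / 2,
      N_b * (N_itTC + N_itTA + 2 * N_itN + N_itNR + 1) + N_itNR + N_itTL),
    peaks    = op_count(0, 2 * N_b + N_p^2),
    entropy  = op_count(N_p * (N_itTL * (N_itTL + 1) + 3) + 3 * N_itNR,
                        N_p * (2 * (N_itTL - 1) + N_itNR + 1) + N_itNR),
    crests_moments = op_count(N_p * (3 * B_crest + 2 * N_itN + 2),
                              N_p * (3 * B_crest + 2 * N_itN - 2)),
    crests_energy = op_count(
      N_p * (B_crest + B_narrow + B_wide + 2 * (3 * N_itNR + 1)),
      N_p * (B_crest + B_narrow + B_wide + 2 * (N_itNR + 1) - 3)),
    continuity = op_count(0, M_cont * N_c^2 + 3 * N_c),
    stop("unknown program block: ", block)))
}

#' Program blocks composing each detector
#' @param algorithm detector id 1-4.
#' @return character vector of block ids.
#' @export
algorithm_blocks <- function(algorithm) {
  common <- c("windowing", "stft", "power_spectrum", "energy")
  switch(as.character(algorithm),
    "1" = c(common, "peaks", "crests_moments", "continuity"),
    "2" = c(common, "peaks", "crests_energy", "continuity"),
    "3" = c(common, "amplitude_spectrum", "phase_spectrum", "tonality"),
    "4" = c(common, "peaks", "entropy"),
    stop("algorithm must be 1, 2, 3 or 4"))
}

#' Total operation count of a detector
#'
#' The per-segment worst-case cost of one detector, the sum of the costs of
#' its constituent program blocks.
#'
#' @param algorithm detector id 1-4.
#' @param params a [complexity_params()].
#' @return integer vector `c(mults, adds)`.
#' @export
algorithm_cost <- function(algorithm, params = complexity_params()) {
  costs <- vapply(algorithm_blocks(algorithm), block_cost,
                  integer(2), params = params)
  op_count(sum(costs["mults", ]), sum(costs["adds", ]))
}

#' Processing duty-cycle
#'
#' Percentage of the inter-segment interval spent executing the classifier:
#' `100 * cycles_exec / cycles_total`. The default budget is 3.2e6 cycles
#' (a 100 MHz core with 32 ms between successive 50%-overlapped 64 ms
#' segments).
#'
#' @param cycles_exec average cycles per classified segment (measured on
#'   the target; this package treats it as an input).
#' @param cycles_total cycle budget between successive segments.
#' @return duty cycle in percent.
#' @export
duty_cycle <- function(cycles_exec, cycles_total = 3.2e6) {
  if (cycles_exec <= 0) stop("cycles_exec must be positive")
  if (cycles_exec > cycles_total)
    stop("cycles_exec exceeds the cycle budget")
  100 * cycles_exec / cycles_total
}

#' Code execution efficiency
#'
#' Accuracy-per-activity metrics: each classification metric (in percent)
#' divided by the processing duty-cycle (in percent),
#' `mu_X = X / D_exec`. At `D_exec = 100` the metrics are returned
#' unchanged.
#'
#' @param metrics named numeric vector (percent), e.g. `c(SE=, SP=, AC=)`.
#' @param d_exec processing duty-cycle in percent (see [duty_cycle()]).
#' @return named vector of efficiency values (`mu_` prefix).
#' @export
efficiency_metrics <- function(metrics, d_exec) {
  if (d_exec <= 0) stop("d_exec must be positive")
  out <- metrics / d_exec
  names(out) <- paste0("mu_", names(metrics))
  out
}

#' Block-by-block complexity report for one detector
#'
#' @param algorithm detector id 1-4.
#' @param params a [complexity_params()].
#' @param cycles_exec optional measured cycles per segment; adds duty-cycle
#'   output.
#' @param cycles_total cycle budget (see [duty_cycle()]).
#' @return data.frame with one row per block plus a `total` row: `block`,
#'   `mults`, `adds`, `ops`.
#' @export
budget_report <- function(algorithm, params = complexity_params(),
                          cycles_exec = NULL, cycles_total = 3.2e6) {
  blocks <- algorithm_blocks(algorithm)
  rows <- lapply(blocks, function(b) {
    cst <- block_cost(b, params)
    data.frame(block = b, mults = cst[["mults"]], adds = cst[["adds"]],
               ops = sum(cst))
  })
  tot <- algorithm_cost(algorithm, params)
  out <- rbind(do.call(rbind, rows),
               data.frame(block = "total", mults = tot[["mults"]],
                          adds = tot[["adds"]], ops = sum(tot)))
  if (!is.null(cycles_exec))
    attr(out, "d_exec") <- duty_cycle(cycles_exec, cycles_total)
  out
}
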
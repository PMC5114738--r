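#' Simulate a T1-weighted image series for one tissue
#'
#' Propagates a spin state through all events of an acquisition schedule in
#' time order, carrying the magnetization across heartbeats (including the
#' incomplete recovery between MOLLI Look-Locker blocks). Each readout event
#' either runs the full bSSFP block ([bssfp_readout()]) or, with
#' `ideal_readout = TRUE`, samples the instantaneous longitudinal
#' magnetization at the readout onset without perturbing it.
#'
#' @param tissue A [spin_state()] holding the tissue relaxation parameters;
#'   the simulation starts from equilibrium regardless of the state's
#'   current magnetization.
#' @param schedule An `acquisition_schedule` from [schedule_molli()],
#'   [schedule_sasha()] or [schedule_sapphire()].
#' @param cfg A [readout_config()].
#' @param ideal_readout If `TRUE`, images are ideal samples of Mz (no readout
#'   perturbation).
#' @param inversion_efficiency Efficiency of inversion preparations in
#'   `[0, 1]`.
#' @param wet List of WET saturation options passed to [wet_saturation()]
#'   (`angles`, `delay`, `b1_scale`); `list(ideal = TRUE)` requests perfect
#'   saturation.
#' @return A `t1_series`: list with `signals` (signed contrast values),
#'   `magnitude` (absolute values, the measured quantity), `recovery_times`,
#'   `sequence_id`, `polarity_known = FALSE`, `prep_meta` and `true_t1`.
#' @examples
#' s <- simulate_series(spin_state(t1 = 1000, t2 = 45),
#'                      schedule_sasha(rr = 1000), ideal_readout = TRUE)
#' round(s$signals, 4)
#' @export
simulate_series <- function(tissue, schedule, cfg = readout_config(),
                            ideal_readout = FALSE,
                            inversion_efficiency = 0.96,
                            wet = list()) {
  state <- spin_state(mz = tissue$m0, m0 = tissue$m0, t1 = tissue$t1,
                      t2 = tissue$t2, delta_f = tissue$delta_f)
  ro <- readout_duration(cfg)
  n <- schedule$n_images
  signals <- numeric(n)
  tcur <- 0
  wet_ideal <- isTRUE(wet$ideal)
  wet_args <- wet[names(wet) %in% c("angles", "delay", "b1_scale")]
  for (ev in schedule$events) {
    if (ev$time < tcur - 1e-9)
      stop("overlapping events: preparation scheduled inside a readout block")
    state <- relax(state, max(0, ev$time - tcur))
    tcur <- ev$time
    if (ev$kind == "saturation") {
      if (wet_ideal) {
        state <- crush(state)
        state$mz <- 0
      } else {
        state <- do.call(wet_saturation, c(list(state), wet_args))$state
      }
    } else if (ev$kind == "inversion") {
      state <- adiabatic_inversion(state, inversion_efficiency)$state
    } else if (ev$kind == "readout") {
      if (ideal_readout) {
        signals[ev$image] <- state$mz
      } else {
        r <- bssfp_readout(state, cfg)
        signals[ev$image] <- r$signal_signed
        state <- r$state
        tcur <- tcur + ro
      }
    } else stop("unknown event kind: ", ev$kind)
  }
  structure(list(signals = signals,
                 magnitude = abs(signals),
                 recovery_times = schedule$recovery_times,
                 sequence_id = schedule$sequence_id,
                 scheme = schedule$scheme,
                 polarity_known = FALSE,
                 prep_meta = schedule$prep_meta,
                 true_t1 = tissue$t1),
            class = "t1_series")
}

#' @export
print.t1_series <- function(x, ...) {
  cat(sprintf("<t1_series> %s, %d images%s\n", x$sequence_id,
              length(x$signals),
              if (!is.null(x$true_t1)) sprintf(", true T1 = %g ms", x$true_t1) else ""))
  df <- data.frame(recovery_ms = x$recovery_times, signal = round(x$signals, 5))
  print(df, row.names = FALSE)
  invisible(x)
}
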
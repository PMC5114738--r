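#' Acquisition schedules
#'
#' An `acquisition_schedule` is an ordered list of preparation and readout
#' events with absolute timestamps (ms from the first R-wave), one recovery
#' time per image, and the R-R interval that generated it.
#'
#' Recovery times are referenced to the readout onset: the delay between the
#' last preparation pulse and the start of the single-shot image acquisition.
#' With a full-resolution linear readout every image carries an identical
#' driven bSSFP segment from onset to the central k-space line, so the free
#' amplitude/modulation terms of the three-parameter relaxometry models
#' absorb the readout transfer exactly; see the package vignette for why
#' this reference point is used.
#'
#' @name acquisition_schedule
#' @keywords internal
NULL

new_schedule <- function(sequence_id, events, recovery_times, rr, scheme = NULL,
                         prep_meta = list()) {
  ord <- order(vapply(events, `[[`, numeric(1), "time"))
  events <- events[ord]
  tt <- vapply(events, `[[`, numeric(1), "time")
  if (any(diff(tt) <= 0)) stop("schedule events must have strictly increasing times")
  structure(list(sequence_id = sequence_id, scheme = scheme, events = events,
                 recovery_times = recovery_times, rr = rr,
                 n_images = length(recovery_times), prep_meta = prep_meta),
            class = "acquisition_schedule")
}

sched_event <- function(time, kind, image = NA_integer_, recovery = NA_real_) {
  list(time = time, kind = kind, image = image, recovery = recovery)
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat(sprintf("<acquisition_schedule> %s%s: %d images over %d events, R-R = %g ms\n",
              x$sequence_id, if (!is.null(x$scheme)) paste0(" ", x$scheme) else "",
              x$n_images, length(x$events), x$rr))
  rt <- x$recovery_times
  cat("  recovery times (ms):", paste(ifelse(is.finite(rt), sprintf("%.1f", rt), "Inf"),
                                      collapse = ", "), "\n")
  invisible(x)
}

#' MOLLI acquisition schedule
#'
#' Builds a Modified Look-Locker inversion-recovery schedule. In the
#' `"5(3)3"` scheme (native imaging) five images are read in consecutive
#' heartbeats after the first inversion, three pause beats follow, and a
#' second inversion precedes three further images; `"4(1)3(1)2"`
#' (post-contrast) uses three Look-Locker blocks of 4, 3 and 2 images with
#' single pause beats. For block k the inversion is placed
#' `ti1 + (k-1) * dti` ms before the first image's readout onset and
#' subsequent images follow at one R-R increments, so the effective
#' inversion times are `ti_k + (j-1) * rr`.
#'
#' @param rr R-R interval in ms.
#' @param scheme `"5(3)3"` or `"4(1)3(1)2"`.
#' @param ti1 First inversion time in ms.
#' @param dti Inversion-time increment between Look-Locker blocks in ms.
#' @param cfg Readout configuration, used to validate that a full readout
#'   fits into one heartbeat.
#' @return An `acquisition_schedule` with 8 (`5(3)3`) or 9 (`4(1)3(1)2`)
#'   images.
#' @examples
#' schedule_molli(rr = 1000)$recovery_times
#' @export
schedule_molli <- function(rr, scheme = c("5(3)3", "4(1)3(1)2"),
                           ti1 = 100, dti = 80, cfg = readout_config()) {
  scheme <- match.arg(scheme)
  if (ti1 <= 0) stop("ti1 must be positive")
  if (rr <= readout_duration(cfg))
    stop("R-R interval shorter than the readout block")
  blocks <- if (scheme == "5(3)3") list(c(5, 3), c(3, 0))
            else list(c(4, 1), c(3, 1), c(2, 0))
  events <- list()
  recovery <- numeric(0)
  beat <- 1L   # beat whose onset hosts the next first-of-block image
  img <- 0L
  for (b in seq_along(blocks)) {
    n_img <- blocks[[b]][1]; n_pause <- blocks[[b]][2]
    ti <- ti1 + (b - 1) * dti
    t_first <- beat * rr
    t_inv <- t_first - ti
    if (t_inv < 0) stop("inversion time precedes the schedule start")
    events <- c(events, list(sched_event(t_inv, "inversion")))
    for (j in seq_len(n_img)) {
      img <- img + 1L
      events <- c(events, list(sched_event(t_first + (j - 1) * rr, "readout",
                                           image = img,
                                           recovery = ti + (j - 1) * rr)))
      recovery <- c(recovery, ti + (j - 1) * rr)
    }
    beat <- beat + n_img + n_pause
  }
  new_schedule("MOLLI", events, recovery, rr, scheme = scheme,
               prep_meta = list(ti1 = ti1, dti = dti))
}

#' SASHA acquisition schedule
#'
#' Saturation-recovery single-shot acquisition: one unprepared image in the
#' first heartbeat followed by `n_images - 1` saturation-prepared images,
#' one per heartbeat, with recovery times linearly spaced between `ts_min`
#' and `ts_max`. The readout onset sits at a fixed trigger position in the
#' beat (`rr - readout duration`, i.e. the readout ends at the next R-wave)
#' and the saturation is placed the recovery time before it.
#'
#' @param rr R-R interval in ms.
#' @param ts_min Minimal recovery time in ms (default 113).
#' @param n_images Total image count (default 10; the first is unprepared).
#' @param ts_max Maximal recovery time in ms; defaults to
#'   `rr - readout_duration(cfg) - 10`, which places the preparation of the
#'   longest recovery 10 ms after the R-wave (a guard that keeps preparation
#'   events distinct).
#' @param cfg Readout configuration.
#' @return An `acquisition_schedule` with `n_images` images, the first with
#'   infinite recovery time.
#' @examples
#' schedule_sasha(rr = 1000)$recovery_times
#' @export
schedule_sasha <- function(rr, ts_min = 113, n_images = 10, ts_max = NULL,
                           cfg = readout_config()) {
  ro <- readout_duration(cfg)
  if (is.null(ts_max)) ts_max <- rr - ro - 10
  if (ts_max <= ts_min) stop("ts_max must exceed ts_min")
  if (n_images < 2) stop("need at least one prepared image")
  ts <- seq(ts_min, ts_max, length.out = n_images - 1)
  onset0 <- rr - ro   # fixed trigger position within each beat
  events <- list(sched_event(onset0, "readout", image = 1L, recovery = Inf))
  for (k in seq_along(ts)) {
    t0 <- k * rr                  # start of beat k+1
    onset <- t0 + onset0
    events <- c(events,
                list(sched_event(onset - ts[k], "saturation"),
                     sched_event(onset, "readout", image = k + 1L,
                                 recovery = ts[k])))
  }
  new_schedule("SASHA", events, c(Inf, ts), rr,
               prep_meta = list(ts_min = ts_min, ts_max = ts_max))
}

#' SAPPHIRE acquisition schedule
#'
#' Saturation-pulse-prepared heart-rate-independent inversion recovery: each
#' prepared image is preceded by a saturation at the R-wave and an adiabatic
#' inversion placed so that the inversion-to-readout recovery time takes the
#' same linearly spaced values as SASHA. The saturation-to-onset interval is
#' identical for every image (the fixed trigger position), which is what
#' makes the recovery curve a single three-parameter exponential.
#'
#' @inheritParams schedule_sasha
#' @return An `acquisition_schedule`; every prepared image carries a
#'   saturation and an inversion event, and `prep_meta$sat_to_onset` records
#'   the constant saturation-to-readout interval needed by the anchored
#'   SAPPHIRE fit.
#' @examples
#' sched <- schedule_sapphire(rr = 1000)
#' sched$prep_meta$sat_to_onset
#' @export
schedule_sapphire <- function(rr, ts_min = 113, n_images = 10, ts_max = NULL,
                              cfg = readout_config()) {
  ro <- readout_duration(cfg)
  if (is.null(ts_max)) ts_max <- rr - ro - 10
  if (ts_max <= ts_min) stop("ts_max must exceed ts_min")
  if (n_images < 2) stop("need at least one prepared image")
  ts <- seq(ts_min, ts_max, length.out = n_images - 1)
  onset0 <- rr - ro
  if (max(ts) > onset0 + 1e-9)
    stop("inversion would precede the saturation at the R-wave")
  events <- list(sched_event(onset0, "readout", image = 1L, recovery = Inf))
  for (k in seq_along(ts)) {
    t0 <- k * rr
    onset <- t0 + onset0
    events <- c(events,
                list(sched_event(t0, "saturation"),
                     sched_event(onset - ts[k], "inversion"),
                     sched_event(onset, "readout", image = k + 1L,
                                 recovery = ts[k])))
  }
  new_schedule("SAPPHIRE", events, c(Inf, ts), rr,
               prep_meta = list(ts_min = ts_min, ts_max = ts_max,
                                sat_to_onset = onset0))
}

#' Serialize a schedule to JSON
#'
#' @param schedule An `acquisition_schedule`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
schedule_to_json <- function(schedule, path = NULL) {
  ev <- data.frame(
    time = vapply(schedule$events, `[[`, numeric(1), "time"),
    kind = vapply(schedule$events, `[[`, character(1), "kind"),
    image = vapply(schedule$events, `[[`, integer(1), "image")
  )
  obj <- list(sequence_id = schedule$sequence_id, scheme = schedule$scheme,
              rr = schedule$rr, n_images = schedule$n_images,
              recovery_times = ifelse(is.finite(schedule$recovery_times),
                                      schedule$recovery_times, -1),
              events = ev, prep_meta = schedule$prep_meta)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
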
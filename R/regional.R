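#' AHA 16-segment assignment
#'
#' Assigns every myocardial pixel of a phantom slice to its AHA segment:
#' six 60-degree sectors on basal (segments 1-6) and mid-ventricular
#' (7-12) slices, four 90-degree sectors on the apical slice (13-16).
#' Sectors run counterclockwise starting at the anterior RV insertion
#' point; the apical sectors are rotated so the anterior apical segment is
#' centred on the insertion direction. A pixel exactly on a sector boundary
#' is assigned to the lower-numbered sector.
#'
#' @param phantom A `digital_phantom`.
#' @param slice_level Optional override of the phantom's slice label.
#' @return An integer matrix of segment ids (`NA` outside the myocardium).
#' @examples
#' ph <- make_phantom(nx = 64, ny = 64, r_endo = 10, r_epi = 15, slice = "mid")
#' sort(unique(na.omit(as.vector(assign_segments(ph)))))
#' @export
assign_segments <- function(phantom, slice_level = NULL) {
  g <- phantom$geometry
  if (is.null(g$rv_insertion_deg)) stop("RV insertion angle is required")
  slice <- if (is.null(slice_level)) g$slice else slice_level
  base_id <- c(basal = 0L, mid = 6L, apical = 12L)[[slice]]
  n_sec <- if (slice == "apical") 4L else 6L
  width <- 360 / n_sec
  lab <- phantom$label_map
  d <- dim(lab)
  cx <- g$center[1]; cy <- g$center[2]
  x <- matrix(seq_len(d[1]), d[1], d[2]) - cx
  y <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cy
  # math angle of the insertion: clockwise-from-12 convention
  ins <- 90 - g$rv_insertion_deg
  theta <- (atan2(y, x) * 180 / pi - ins) %% 360   # ccw from the insertion
  if (slice == "apical") theta <- (theta + 45) %% 360
  # boundary tie rule: theta exactly on k*width belongs to sector k (lower)
  idx <- ceiling(theta / width)
  idx[idx == 0L] <- 1L
  seg <- matrix(NA_integer_, d[1], d[2])
  myo <- lab == 2L
  seg[myo] <- base_id + as.integer(idx[myo])
  seg
}

#' Per-segment statistics of a parameter map
#'
#' Computes the mean and sample standard deviation of valid pixels per AHA
#' segment. The intra-segment SD is the study's precision measure. A
#' segment is flagged excluded when its valid-pixel fraction falls below
#' `min_valid_fraction` (emulating artifact-based segment exclusion).
#'
#' @param map A `parameter_map`.
#' @param labels Segment-id matrix from [assign_segments()].
#' @param subject_id,sequence_id,session,slice Identifiers copied into the
#'   output rows.
#' @param min_valid_fraction Exclusion threshold on the valid-pixel fraction.
#' @return A data frame (class `segment_table`) with one row per segment:
#'   `subject_id, sequence_id, session, slice, segment_id, mean_t1, sd_t1,
#'   n_pixels, excluded`.
#' @export
segment_stats <- function(map, labels, subject_id = NA, sequence_id = NULL,
                          session = NA, slice = NA,
                          min_valid_fraction = 0.5) {
  if (is.null(sequence_id)) sequence_id <- map$sequence_id
  segs <- sort(unique(stats::na.omit(as.vector(labels))))
  rows <- lapply(segs, function(sg) {
    in_seg <- !is.na(labels) & labels == sg
    ok <- in_seg & map$valid_mask
    v <- map$values[ok]
    excl <- sum(ok) < min_valid_fraction * sum(in_seg) || sum(ok) < 1
    data.frame(subject_id = subject_id, sequence_id = sequence_id,
               session = session, slice = slice, segment_id = sg,
               mean_t1 = if (length(v)) mean(v) else NA_real_,
               sd_t1 = if (length(v) > 1) stats::sd(v) else if (length(v)) 0 else NA_real_,
               n_pixels = sum(ok), excluded = excl,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("segment_table", "data.frame")
  out
}

#' Gadolinium concentration from a T1 pair
#'
#' `c = (1/T1_post - 1/T1_native) / r1`, with T1 in ms converted to seconds
#' and the relaxivity `r1` in 1/(mmol/L)/s; the result is in mmol/L.
#'
#' @param t1_native,t1_post T1 in ms (> 0).
#' @param r1 Relaxivity (default 3.5 per mmol/L per s).
#' @return Concentration in mmol/L.
#' @examples
#' # myocardium, typical inversion-recovery values at 3T, in umol/L:
#' 1000 * compute_concentration(1182.6, 541.1)
#' @export
compute_concentration <- function(t1_native, t1_post, r1 = 3.5) {
  if (any(t1_native <= 0) || any(t1_post <= 0))
    stop("T1 must be positive")
  (1000 / t1_post - 1000 / t1_native) / r1
}

#' Extracellular volume fraction
#'
#' `ECV = (1 - hct) * (dR1_myo / dR1_blood)` with
#' `dR1 = 1/T1_post - 1/T1_native`.
#'
#' @param t1_myo_native,t1_myo_post,t1_blood_native,t1_blood_post T1 (ms).
#' @param hct Hematocrit fraction in (0, 1).
#' @return ECV as a fraction.
#' @examples
#' compute_ecv(1182.6, 541.1, 1781.4, 349.1, hct = 0.40)
#' @export
compute_ecv <- function(t1_myo_native, t1_myo_post,
                        t1_blood_native, t1_blood_post, hct) {
  if (any(hct <= 0) || any(hct >= 1)) stop("hct must lie in (0, 1)")
  if (any(c(t1_myo_native, t1_myo_post, t1_blood_native, t1_blood_post) <= 0))
    stop("T1 must be positive")
  dr1_myo <- 1 / t1_myo_post - 1 / t1_myo_native
  dr1_blood <- 1 / t1_blood_post - 1 / t1_blood_native
  if (any(dr1_blood <= 0)) stop("no blood enhancement: dR1_blood <= 0")
  (1 - hct) * dr1_myo / dr1_blood
}

#' Cohort bullseye summary
#'
#' Aggregates a segment table across subjects into a 16-segment summary of
#' mean T1, precision (mean intra-segment SD) and, when ECV records are
#' supplied, mean ECV, plus slice-level and global averages. Slice and
#' global averages are unweighted means of the segment means. Excluded
#' segment rows are ignored.
#'
#' @param tables A `segment_table` (rows from several subjects can simply be
#'   row-bound).
#' @param ecv Optional data frame with `segment_id` and `ecv` columns.
#' @return A list of class `bullseye` with `segments` (per-segment cohort
#'   means), `slices` (basal/mid/apical averages) and `global` averages.
#' @export
bullseye_table <- function(tables, ecv = NULL) {
  tab <- tables[!tables$excluded & !is.na(tables$mean_t1), , drop = FALSE]
  if (!nrow(tab)) stop("no usable segment rows")
  agg <- stats::aggregate(cbind(mean_t1, sd_t1) ~ segment_id, data = tab, FUN = mean)
  names(agg) <- c("segment_id", "t1", "precision")
  if (!is.null(ecv)) {
    eagg <- stats::aggregate(ecv ~ segment_id, data = ecv, FUN = mean)
    agg <- merge(agg, eagg, by = "segment_id", all.x = TRUE)
  }
  slice_of <- function(sg) c("basal", "mid", "apical")[findInterval(sg, c(1, 7, 13))]
  agg$slice <- slice_of(agg$segment_id)
  num <- setdiff(names(agg), c("segment_id", "slice"))
  slices <- stats::aggregate(agg[num], by = list(slice = agg$slice), FUN = mean)
  global <- colMeans(agg[num])
  structure(list(segments = agg, slices = slices, global = global),
            class = "bullseye")
}

#' @export
print.bullseye <- function(x, ...) {
  cat("<bullseye> global:",
      paste(sprintf("%s = %.3g", names(x$global), x$global), collapse = ", "), "\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Plot a bullseye summary
#'
#' Draws the standard 16-segment polar plot (basal ring outside, apical
#' inside) coloured by the chosen statistic.
#'
#' @param x A `bullseye`.
#' @param what Column of the segment summary to display.
#' @param ... Unused.
#' @return Invisibly `x`.
#' @export
plot.bullseye <- function(x, what = "t1", ...) {
  seg <- x$segments
  vals <- seg[[what]]
  pal <- grDevices::hcl.colors(64, "viridis")
  col_of <- function(v) pal[pmax(1, pmin(64, round(1 + 63 * (v - min(vals)) /
                                                     max(1e-12, diff(range(vals))))))]
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("%s (global %.3g)", what, x$global[[what]]))
  rings <- list(basal = c(0.75, 1), mid = c(0.5, 0.75), apical = c(0.25, 0.5))
  for (i in seq_len(nrow(seg))) {
    sg <- seg$segment_id[i]
    ring <- rings[[seg$slice[i]]]
    n_sec <- if (sg > 12) 4 else 6
    j <- (sg - 1) %% 6
    if (sg > 12) j <- (sg - 13)
    off <- if (sg > 12) 45 else 0
    a0 <- (90 + off + j * 360 / n_sec) * pi / 180
    a1 <- a0 + 2 * pi / n_sec
    th <- seq(a0, a1, length.out = 20)
    xs <- c(ring[2] * cos(th), ring[1] * cos(rev(th)))
    ys <- c(ring[2] * sin(th), ring[1] * sin(rev(th)))
    graphics::polygon(xs, ys, col = col_of(vals[i]), border = "white")
  }
  graphics::text(0, 0, sprintf("%.3g", x$global[[what]]))
  invisible(x)
}
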
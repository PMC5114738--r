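#' Digital short-axis cardiac phantom
#'
#' Builds a two-dimensional short-axis slice phantom: an LV blood-pool disc,
#' a closed myocardial annulus, a crescent-shaped RV blood pool and
#' background, with per-pixel T1/T2/M0/off-resonance maps. Basal, mid and
#' apical slice levels are concentric rescalings of one geometry.
#'
#' Label codes: 0 background, 1 LV blood, 2 myocardium, 3 RV blood.
#'
#' @param nx,ny Grid size in pixels. Defaults match a 440 x 375 mm^2 field
#'   of view at 1.7 x 1.7 mm^2 resolution.
#' @param pixel_mm Pixel size in mm.
#' @param r_endo,r_epi Endo- and epicardial radii in pixels (0 < endo < epi).
#' @param rv_insertion_deg Angle of the anterior RV insertion point in
#'   degrees, measured clockwise from 12 o'clock; 0 places the insertion at
#'   12 o'clock.
#' @param slice `"basal"`, `"mid"` or `"apical"`; radii are scaled by
#'   1, 0.85 and 0.7 respectively.
#' @param t1_myo,t2_myo T1/T2 of myocardium in ms (defaults at the 3T
#'   saturation-recovery scale).
#' @param t1_blood,t2_blood T1/T2 of blood in ms.
#' @param delta_f Off-resonance in Hz (uniform).
#' @return An object of class `digital_phantom` with `label_map`, `t1_map`,
#'   `t2_map`, `m0_map`, `df_map` (matrices `nx` x `ny`), and `geometry`.
#' @examples
#' ph <- make_phantom(nx = 64, ny = 64, r_endo = 10, r_epi = 15)
#' table(ph$label_map)
#' @export
make_phantom <- function(nx = 259, ny = 221, pixel_mm = 1.7,
                         r_endo = 13, r_epi = 20,
                         rv_insertion_deg = 0, slice = c("mid", "basal", "apical"),
                         t1_myo = 1550, t2_myo = 45,
                         t1_blood = 1980, t2_blood = 250,
                         delta_f = 0) {
  slice <- match.arg(slice)
  if (r_endo <= 0 || r_epi <= r_endo)
    stop("need 0 < r_endo < r_epi")
  scale <- c(basal = 1, mid = 0.85, apical = 0.7)[[slice]]
  re <- r_endo * scale; rp <- r_epi * scale
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  x <- matrix(seq_len(nx), nx, ny) - cx
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE) - cy
  r <- sqrt(x^2 + y^2)
  lab <- matrix(0L, nx, ny)
  lab[r <= rp] <- 2L
  lab[r <= re] <- 1L
  # RV blood: crescent hugging the anterior/septal wall
  rv_c <- rp * 1.6
  ins <- (90 - rv_insertion_deg) * pi / 180   # math angle of the insertion
  # place the RV center 90 deg counterclockwise of the insertion (septal side)
  rvx <- rv_c * cos(ins + pi / 2); rvy <- rv_c * sin(ins + pi / 2)
  rrv <- sqrt((x - rvx)^2 + (y - rvy)^2)
  lab[rrv <= rp * 0.9 & lab == 0L] <- 3L
  t1 <- matrix(NA_real_, nx, ny); t2 <- t1
  t1[lab == 2L] <- t1_myo;   t2[lab == 2L] <- t2_myo
  t1[lab %in% c(1L, 3L)] <- t1_blood; t2[lab %in% c(1L, 3L)] <- t2_blood
  m0 <- matrix(0, nx, ny); m0[lab != 0L] <- 1
  df <- matrix(delta_f, nx, ny)
  structure(list(label_map = lab, t1_map = t1, t2_map = t2, m0_map = m0,
                 df_map = df,
                 geometry = list(center = c(cx, cy), r_endo = re, r_epi = rp,
                                 rv_insertion_deg = rv_insertion_deg,
                                 slice = slice, pixel_mm = pixel_mm)),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<digital_phantom> %d x %d px (%.1f mm), %s slice\n",
              nrow(x$label_map), ncol(x$label_map), g$pixel_mm, g$slice))
  cat(sprintf("  endo/epi radii %.1f/%.1f px, RV insertion %g deg\n",
              g$r_endo, g$r_epi, g$rv_insertion_deg))
  cat("  pixels:", paste(sprintf("%s=%d", c("background", "LV blood", "myocardium", "RV blood"),
                                 tabulate(x$label_map + 1L, 4L)), collapse = ", "), "\n")
  invisible(x)
}

#' Sample a virtual volunteer cohort
#'
#' Draws per-subject tissue and physiology parameters emulating a young
#' healthy cohort imaged natively and at two post-contrast time points
#' (about 15 and 25 min after a gadolinium bolus). Native T1 means/SDs
#' default to the 3T saturation-recovery scale; the post-contrast state is
#' generated from a blood gadolinium concentration that washes out
#' exponentially between the two sessions, with the myocardial concentration
#' tied to blood through the partition coefficient `lambda_gd` (fast-exchange
#' two-compartment assumption). Post-contrast T1 follows
#' `1/T1_post = 1/T1_native + r1 c` with relaxivity `r1` in 1/(mmol/L)/s.
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed; the cohort is reproducible byte-for-byte.
#' @param native_t1_myo_mean,native_t1_myo_sd Native myocardial T1 (ms).
#' @param native_t1_blood_mean,native_t1_blood_sd Native blood T1 (ms).
#' @param hct_mean,hct_sd Hematocrit fraction, truncated to (0.25, 0.55).
#' @param lambda_mean,lambda_sd Gadolinium partition coefficient.
#' @param conc15_mean,conc15_sd Blood gadolinium concentration at the first
#'   post-contrast session (mmol/L).
#' @param washout_tau Washout time constant in minutes; the second session
#'   (10 min later) has `c25 = c15 exp(-10/washout_tau)`.
#' @param rr_mean,rr_sd R-R interval (ms).
#' @param r1 Gadolinium relaxivity in 1/(mmol/L)/s.
#' @return A data frame of class `subject_cohort`, one row per subject, with
#'   ground-truth T1 for myocardium and blood in all three sessions, the
#'   ground-truth ECV `(1 - hct) * lambda_gd`, and concentrations.
#' @examples
#' cohort <- sample_cohort(5, seed = 1)
#' cohort[, c("subject_id", "native_t1_myo", "hct", "ecv_truth")]
#' @export
sample_cohort <- function(n_subjects = 20, seed = 1,
                          native_t1_myo_mean = 1550, native_t1_myo_sd = 45,
                          native_t1_blood_mean = 1980, native_t1_blood_sd = 130,
                          hct_mean = 0.42, hct_sd = 0.03,
                          lambda_mean = 0.44, lambda_sd = 0.04,
                          conc15_mean = 0.62, conc15_sd = 0.08,
                          washout_tau = 35,
                          rr_mean = 1000, rr_sd = 70,
                          r1 = 3.5) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  stopifnot(native_t1_myo_mean > 0, native_t1_blood_mean > 0,
            hct_mean > 0, hct_mean < 1, lambda_mean > 0, lambda_mean < 1,
            conc15_mean > 0, washout_tau > 0, r1 > 0)
  set.seed(seed)
  rtrunc <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= lo | x >= hi))
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  t1_myo <- rtrunc(n_subjects, native_t1_myo_mean, native_t1_myo_sd, 500, 3000)
  t1_blood <- rtrunc(n_subjects, native_t1_blood_mean, native_t1_blood_sd, 800, 3500)
  hct <- rtrunc(n_subjects, hct_mean, hct_sd, 0.25, 0.55)
  lambda <- rtrunc(n_subjects, lambda_mean, lambda_sd, 0.2, 0.7)
  c15 <- rtrunc(n_subjects, conc15_mean, conc15_sd, 0.1, 1.5)
  c25 <- c15 * exp(-10 / washout_tau)
  rr <- round(rtrunc(n_subjects, rr_mean, rr_sd, 600, 1400))
  post_t1 <- function(t1_native, conc) {
    # R1 in 1/s; T1 in ms
    1000 / (1000 / t1_native + r1 * conc)
  }
  df <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    hct = hct,
    native_t1_myo = t1_myo,
    native_t1_blood = t1_blood,
    lambda_gd = lambda,
    blood_conc_15 = c15,
    blood_conc_25 = c25,
    myo_conc_15 = lambda * c15,
    myo_conc_25 = lambda * c25,
    rr = rr,
    stringsAsFactors = FALSE
  )
  df$post15_t1_myo <- post_t1(t1_myo, df$myo_conc_15)
  df$post15_t1_blood <- post_t1(t1_blood, c15)
  df$post25_t1_myo <- post_t1(t1_myo, df$myo_conc_25)
  df$post25_t1_blood <- post_t1(t1_blood, c25)
  df$ecv_truth <- (1 - hct) * lambda
  df$seed <- seed + seq_len(n_subjects)
  class(df) <- c("subject_cohort", "data.frame")
  df
}

#' Add Rician noise to signals or image stacks
#'
#' Adds zero-mean Gaussian noise of SD `reference / snr` to the two
#' quadrature channels and takes the magnitude (Rician observation model).
#' Noise is applied in image space, after "reconstruction".
#'
#' @param x A numeric vector/array of signal magnitudes, or a `t1_series`.
#' @param snr Signal-to-noise ratio; `Inf` returns the input unchanged.
#' @param seed Optional integer seed for reproducibility.
#' @param reference Signal level defining the noise scale (default: the
#'   maximum absolute signal in `x`). For matched-noise comparisons across
#'   sequences pass a common reference, e.g. the unprepared native
#'   myocardial signal.
#' @param sigma Per-channel noise SD; overrides `snr`/`reference` if given.
#' @return Same type as `x`, with magnitude signals.
#' @export
add_noise <- function(x, snr = 40, seed = NULL, reference = NULL, sigma = NULL) {
  if (inherits(x, "t1_series")) {
    x$magnitude <- add_noise(abs(x$signals), snr = snr, seed = seed,
                             reference = if (is.null(reference))
                               max(abs(x$signals)) else reference,
                             sigma = sigma)
    x$signals <- x$magnitude      # polarity is lost in magnitude data
    x$polarity_known <- FALSE
    x$noisy <- TRUE
    return(x)
  }
  if (is.null(sigma)) {
    if (snr <= 0) stop("snr must be positive")
    if (is.infinite(snr)) return(x)
    if (is.null(reference)) reference <- max(abs(x))
    sigma <- reference / snr
  }
  if (sigma == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  n1 <- stats::rnorm(length(x), 0, sigma)
  n2 <- stats::rnorm(length(x), 0, sigma)
  out <- sqrt((abs(x) + n1)^2 + n2^2)
  attributes(out) <- attributes(x)
  out
}
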
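#' Image series container
#'
#' Stacks per-pixel T1-weighted magnitude images with their per-image
#' recovery-time metadata.
#'
#' @param data Numeric array `nx x ny x n_images` of magnitude signals.
#' @param recovery_times Recovery time per image (ms; `Inf` for unprepared).
#' @param sequence_id `"MOLLI"`, `"SASHA"` or `"SAPPHIRE"`.
#' @param prep_meta Preparation metadata list (e.g. `sat_to_onset` for
#'   SAPPHIRE).
#' @param scheme Optional MOLLI scheme label.
#' @return An object of class `image_series`.
#' @export
image_series <- function(data, recovery_times, sequence_id,
                         prep_meta = list(), scheme = NULL) {
  if (length(dim(data)) != 3)
    stop("data must be an nx x ny x n_images array")
  if (dim(data)[3] != length(recovery_times))
    stop("one recovery time per image is required")
  structure(list(data = data, recovery_times = recovery_times,
                 sequence_id = sequence_id, prep_meta = prep_meta,
                 scheme = scheme),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_series> %s, %d x %d px, %d images\n",
              x$sequence_id, d[1], d[2], d[3]))
  invisible(x)
}

#' Render an image series for a uniform-tissue phantom
#'
#' Combines one simulated series per tissue into a pixelwise image stack on
#' a [make_phantom()] geometry: every myocardial pixel carries the
#' myocardial series, blood pixels the blood series, background stays zero.
#'
#' @param phantom A `digital_phantom`.
#' @param myo_series,blood_series `t1_series` objects for myocardium and
#'   blood (magnitudes are used).
#' @return An `image_series`.
#' @export
phantom_series <- function(phantom, myo_series, blood_series) {
  n <- length(myo_series$magnitude)
  if (length(blood_series$magnitude) != n)
    stop("tissue series must have equal length")
  d <- dim(phantom$label_map)
  arr <- array(0, c(d, n))
  myo <- phantom$label_map == 2L
  blood <- phantom$label_map == 1L | phantom$label_map == 3L
  for (i in seq_len(n)) {
    plane <- matrix(0, d[1], d[2])
    plane[myo] <- myo_series$magnitude[i]
    plane[blood] <- blood_series$magnitude[i]
    arr[, , i] <- plane
  }
  image_series(arr, myo_series$recovery_times, myo_series$sequence_id,
               prep_meta = myo_series$prep_meta, scheme = myo_series$scheme)
}

#' Pixelwise T1 map estimation
#'
#' Fits every non-background pixel of an image series with the model
#' matching its sequence and assembles a parameter map with validity mask
#' and diagnostics. Pixels are considered valid when the fit converged, the
#' normalized residual sum of squares (`rss / sum(signal^2)`) is below
#' `rss_threshold` and T1 lies inside `t1_range`.
#'
#' Identical signal vectors (for instance every myocardial pixel of a
#' noiseless uniform phantom) are fitted once and the result replicated.
#' The pixelwise engine shares the coarse T1 grid across pixels and refines
#' each pixel by vectorized golden-section iterations; agreement with the
#' reference single-series fit [t1_fit()] is part of the test suite.
#'
#' @param series An `image_series`.
#' @param sequence_id Optional override of `series$sequence_id`.
#' @param mask Logical matrix of pixels to fit (default: any pixel with a
#'   nonzero signal).
#' @param rss_threshold Normalized rss validity threshold.
#' @param t1_range Admissible T1 range in ms.
#' @param sapphire_model SAPPHIRE fit form (see [t1_fit()]).
#' @param noise_sigma Known per-channel noise SD of the Rician magnitude
#'   data. When given, the Rician signal inflation predicted by the fitted
#'   curve is subtracted from the data and the fit repeated (first-order
#'   noise-floor de-biasing); leave `NULL` for noiseless data.
#' @return An object of class `parameter_map`: `values` (T1 in ms, `NA`
#'   outside the mask), `valid_mask`, and `diagnostics` (per-pixel rss and
#'   convergence).
#' @export
make_map <- function(series, sequence_id = NULL, mask = NULL,
                     rss_threshold = 0.05, t1_range = c(1, 5000),
                     sapphire_model = c("free", "anchored"),
                     noise_sigma = NULL) {
  sapphire_model <- match.arg(sapphire_model)
  if (!inherits(series, "image_series")) stop("series must be an image_series")
  seq_id <- if (is.null(sequence_id)) series$sequence_id else sequence_id
  if (is.null(seq_id)) stop("sequence_id metadata is required")
  d <- dim(series$data)
  n_img <- d[3]
  if (n_img != length(series$recovery_times))
    stop("recovery-time metadata does not match the image count")
  sig <- matrix(series$data, d[1] * d[2], n_img)
  if (is.null(mask)) mask <- matrix(rowSums(abs(sig)) > 0, d[1], d[2])
  idx <- which(as.vector(mask))
  values <- matrix(NA_real_, d[1], d[2])
  valid <- matrix(FALSE, d[1], d[2])
  rss <- matrix(NA_real_, d[1], d[2])
  conv <- matrix(FALSE, d[1], d[2])
  if (length(idx)) {
    S <- sig[idx, , drop = FALSE]
    key <- apply(S, 1, paste, collapse = "\r")
    groups <- match(key, unique(key))
    Su <- S[!duplicated(key), , drop = FALSE]
    res <- fit_pixel_matrix(series$recovery_times, Su, seq_id,
                            sat_to_onset = series$prep_meta$sat_to_onset,
                            sapphire_model = sapphire_model,
                            t1_range = t1_range, noise_sigma = noise_sigma)
    t1v <- res$t1[groups]
    rssv <- res$rss[groups]
    convv <- res$converged[groups]
    nrm <- rowSums(S^2)
    okay <- convv & (rssv / pmax(nrm, .Machine$double.eps)) < rss_threshold &
      t1v >= t1_range[1] & t1v <= t1_range[2]
    values[idx] <- t1v
    valid[idx] <- okay & is.finite(t1v)
    rss[idx] <- rssv
    conv[idx] <- convv
  }
  structure(list(values = values, valid_mask = valid,
                 diagnostics = list(rss = rss, converged = conv),
                 sequence_id = seq_id),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf("<parameter_map> %s, %d x %d px, %d valid pixels\n",
              x$sequence_id, nrow(x$values), ncol(x$values), sum(x$valid_mask)))
  if (length(v))
    cat(sprintf("  valid T1: mean %.1f ms, SD %.1f ms\n", mean(v), stats::sd(v)))
  invisible(x)
}

# Rician expectation of a magnitude measurement with true amplitude mu
rice_mean <- function(mu, sigma) {
  mu <- abs(mu)
  x <- mu^2 / (2 * sigma^2)
  out <- sqrt(mu^2 + sigma^2)       # large-argument limit
  small <- x <= 50
  if (any(small)) {
    xs <- x[small]
    out[small] <- sigma * sqrt(pi / 2) * exp(-xs / 2) *
      ((1 + xs) * besselI(xs / 2, 0) + xs * besselI(xs / 2, 1))
  }
  out
}

# Vectorized variable-projection fit over many pixels sharing one time grid.
# With noise_sigma given, the Rician inflation predicted by the fitted curve
# is subtracted from the magnitudes and the fit repeated (first-order
# noise-floor de-biasing). Returns per-pixel t1, rss, converged.
fit_pixel_matrix <- function(times, S, sequence_id,
                             sat_to_onset = NULL,
                             sapphire_model = "free",
                             t1_range = c(1, 5000), n_grid = 50,
                             noise_sigma = NULL, debias_iterations = 2) {
  npix <- nrow(S)
  model <- switch(sequence_id, MOLLI = "molli", SASHA = "sr",
                  SAPPHIRE = "sapphire", stop("unknown sequence_id"))
  if (model == "sapphire") {
    if (sapphire_model == "free") {
      fin0 <- is.finite(times)
      times <- times[fin0]; S <- S[, fin0, drop = FALSE]
    }
    if (sapphire_model != "free" && is.null(sat_to_onset))
      stop("anchored SAPPHIRE needs sat_to_onset")
  }
  ord <- order(times)
  t <- times[ord]; S <- S[, ord, drop = FALSE]
  restore <- model %in% c("molli", "sapphire")
  if (restore) S <- abs(S)
  fin <- is.finite(t)
  fin_idx <- which(fin)
  anchored <- model == "sapphire" && sapphire_model == "anchored"
  D <- sat_to_onset
  grid <- exp(seq(log(t1_range[1]), log(t1_range[2]), length.out = n_grid))
  gr <- (sqrt(5) - 1) / 2

  basis_cols <- function(T1) {
    if (anchored) {
      e <- ifelse(fin, exp(-t / T1), 0)
      me <- ifelse(fin, (1 - exp(-(D - t) / T1)) * e, 0)
      list(x1 = 1 - e, x2 = -me)
    } else {
      list(x1 = rep(1, length(t)), x2 = ifelse(fin, exp(-t / T1), 0))
    }
  }
  # profiled rss for all pixels at one T1: rss = ss - (c1*y1 + c2*y2)
  rss_at <- function(T1, Sk) {
    b <- basis_cols(T1)
    a11 <- sum(b$x1 * b$x1); a12 <- sum(b$x1 * b$x2); a22 <- sum(b$x2 * b$x2)
    det <- a11 * a22 - a12 * a12
    if (abs(det) < 1e-300) return(rep(Inf, nrow(Sk)))
    y1 <- as.vector(Sk %*% b$x1); y2 <- as.vector(Sk %*% b$x2)
    c1 <- (a22 * y1 - a12 * y2) / det
    c2 <- (a11 * y2 - a12 * y1) / det
    ss <- rowSums(Sk^2)
    pmax(ss - c1 * y1 - c2 * y2, 0)
  }
  # rss (and coefficients) where each pixel has its own T1
  per_pixel <- function(T1vec, Sk, want_coef = FALSE) {
    if (anchored) {
      E <- exp(-outer(t, 1 / T1vec))
      E[!fin, ] <- 0
      ME <- (1 - exp(-outer(D - t, 1 / T1vec))) * E
      ME[!fin, ] <- 0
      X1 <- 1 - E; X2 <- -ME
    } else {
      E <- exp(-outer(t, 1 / T1vec))
      E[!fin, ] <- 0
      X1 <- matrix(1, length(t), length(T1vec)); X2 <- E
    }
    a11 <- colSums(X1 * X1); a12 <- colSums(X1 * X2); a22 <- colSums(X2 * X2)
    det <- a11 * a22 - a12 * a12
    y1 <- colSums(t(Sk) * X1); y2 <- colSums(t(Sk) * X2)
    c1 <- (a22 * y1 - a12 * y2) / det
    c2 <- (a11 * y2 - a12 * y1) / det
    ss <- rowSums(Sk^2)
    rss <- ss - c1 * y1 - c2 * y2
    rss[!is.finite(rss)] <- Inf
    out <- list(rss = pmax(rss, 0), c1 = c1, c2 = c2)
    if (want_coef) out$mu <- t(X1) * c1 + t(X2) * c2   # npix x n prediction
    out
  }

  fit_pass <- function(Scur) {
    k_max <- if (restore) {
      pmin(apply(Scur, 1, which.min) + 1L, sum(fin))
    } else rep(0L, npix)
    kk <- if (restore) 0:max(k_max) else 0L
    best_rss <- rep(Inf, npix)
    best_i <- rep(1L, npix)
    best_k <- rep(0L, npix)
    for (k in kk) {
      Sk <- Scur
      if (k > 0) Sk[, fin_idx[seq_len(k)]] <- -Sk[, fin_idx[seq_len(k)]]
      R <- vapply(grid, function(T1) rss_at(T1, Sk), numeric(npix))
      if (npix == 1) R <- matrix(R, 1)
      i_min <- max.col(-R, ties.method = "first")
      r_min <- R[cbind(seq_len(npix), i_min)]
      improved <- r_min < best_rss & (k == 0 | k <= k_max)
      best_rss[improved] <- r_min[improved]
      best_i[improved] <- i_min[improved]
      best_k[improved] <- k
    }
    Sflip <- Scur
    for (k in setdiff(unique(best_k), 0L)) {
      rows <- best_k == k
      Sflip[rows, fin_idx[seq_len(k)]] <- -Sflip[rows, fin_idx[seq_len(k)]]
    }
    # golden-section refinement, each pixel in its own bracket
    a <- grid[pmax(best_i - 1L, 1L)]
    b <- grid[pmin(best_i + 1L, n_grid)]
    c1v <- b - gr * (b - a); d1v <- a + gr * (b - a)
    fc <- per_pixel(c1v, Sflip)$rss
    fd <- per_pixel(d1v, Sflip)$rss
    for (it in 1:40) {
      left <- fc < fd
      b[left] <- d1v[left]
      a[!left] <- c1v[!left]
      c1v <- b - gr * (b - a); d1v <- a + gr * (b - a)
      fc <- per_pixel(c1v, Sflip)$rss
      fd <- per_pixel(d1v, Sflip)$rss
      if (max(b - a) < 1e-4) break
    }
    T1hat <- (a + b) / 2
    sol <- per_pixel(T1hat, Sflip, want_coef = TRUE)
    list(t1_app = T1hat, rss = sol$rss, c1 = sol$c1, c2 = sol$c2,
         mu = sol$mu, k = best_k, at_bound = best_i == 1L | best_i == n_grid)
  }

  pass <- fit_pass(S)
  if (!is.null(noise_sigma) && noise_sigma > 0) {
    for (it in seq_len(debias_iterations)) {
      infl <- rice_mean(pass$mu, noise_sigma) - abs(pass$mu)
      pass <- fit_pass(pmax(S - infl, 0))
    }
  }
  if (model == "molli") {
    aamp <- pass$c1; bamp <- -pass$c2
    t1 <- pass$t1_app * (bamp / aamp - 1)
  } else {
    t1 <- pass$t1_app
  }
  converged <- is.finite(t1) & t1 > 0 & !pass$at_bound
  list(t1 = t1, t1_app = pass$t1_app, rss = pass$rss, converged = converged,
       polarity_index = pass$k, mu_hat = pass$mu)
}

#' Write a parameter map (or image series) as NIfTI with a JSON sidecar
#'
#' Requires the suggested RNifti package. The sidecar records recovery
#' times, sequence id and preparation metadata.
#'
#' @param x A `parameter_map` or `image_series`.
#' @param path Output path without extension; writes `<path>.nii.gz` and
#'   `<path>.json`.
#' @param pixel_mm Pixel size recorded in the NIfTI header.
#' @return Invisibly, the paths written.
#' @export
write_nifti_map <- function(x, path, pixel_mm = 1.7) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI export")
  if (inherits(x, "parameter_map")) {
    arr <- x$values
    meta <- list(kind = "parameter_map", sequence_id = x$sequence_id,
                 units = "ms")
  } else if (inherits(x, "image_series")) {
    arr <- x$data
    meta <- list(kind = "image_series", sequence_id = x$sequence_id,
                 recovery_times = ifelse(is.finite(x$recovery_times),
                                         x$recovery_times, -1),
                 prep_meta = x$prep_meta)
  } else stop("unsupported object")
  img <- RNifti::asNifti(arr, datatype = "float")
  meta$pixel_mm <- pixel_mm
  nii <- paste0(path, ".nii.gz")
  RNifti::writeNifti(img, nii)
  js <- paste0(path, ".json")
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(nii, js))
}
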
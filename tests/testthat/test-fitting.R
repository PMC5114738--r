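test_that("saturation-recovery fit is exact on model data", {
  t <- c(113, 200, 350, 600, 1000, 1800, Inf)
  s <- 1.3 * (1 - 0.97 * exp(-t / 1000)); s[!is.finite(t)] <- 1.3
  f <- fit_sr(t, s)
  expect_equal(f$t1, 1000, tolerance = 1e-6)
  expect_equal(f$a, 1.3, tolerance = 1e-6)
  expect_equal(f$b, 0.97, tolerance = 1e-6)
  expect_true(f$converged)
  expect_lt(f$rss, 1e-10 * sum(s^2))
  # closed form: at t = T1 with b = 1 the signal is a(1 - 1/e)
  expect_equal(predict(fit_sr(t, 1 - exp(-t / 700)), 700),
               1 - exp(-1), tolerance = 1e-6)
})

test_that("fits are scale- and time-unit covariant", {
  t <- c(113, 240, 480, 900, 1600, Inf)
  s <- 2 * (1 - 0.9 * exp(-t / 1200)); s[!is.finite(t)] <- 2
  f1 <- fit_sr(t, s)
  f2 <- fit_sr(t, 5 * s)
  expect_equal(f2$t1, f1$t1, tolerance = 1e-8)
  expect_equal(f2$a, 5 * f1$a, tolerance = 1e-6)
  expect_equal(f2$b, f1$b, tolerance = 1e-8)
  f3 <- fit_sr(t / 2, s)
  expect_equal(f3$t1, f1$t1 / 2, tolerance = 1e-6)
})

test_that("MOLLI fit restores polarity and applies the Look-Locker correction", {
  # the correction identity: t1 = t1_app * (b/a - 1)
  t <- sort(c(100 + 0:4 * 1000, 180 + 0:2 * 1000))
  s <- 1 - 2 * exp(-t / 775)
  f <- fit_molli(t, abs(s))
  expect_equal(f$t1_app, 775, tolerance = 1e-4)
  expect_equal(f$t1, f$t1_app * (f$b / f$a - 1), tolerance = 1e-12)
  expect_equal(f$t1, 775, tolerance = 1e-3)

  s2 <- 1 - 1.8 * exp(-t / 900)
  f2 <- fit_molli(t, abs(s2))
  expect_equal(f2$t1, 900 * 0.8, tolerance = 1e-3)

  # polarity: exactly the truly negative points are flipped (T1 = 1200)
  s3 <- 1 - 2 * exp(-t / 1200)
  f3 <- fit_molli(t, abs(s3))
  expect_equal(f3$polarity_index, sum(s3 < 0))
  expect_equal(f3$t1, 1200, tolerance = 1e-3)
  # no flip beyond the zero crossing
  expect_lte(f3$polarity_index, max(which(s3 < 0)))
})

test_that("SAPPHIRE fits recover model data in all three forms", {
  D <- 625.6
  ts <- seq(113, 615.6, length.out = 9)
  m <- 1 - exp(-(D - ts) / 1550)
  mz <- 1 - (1 + 0.96 * m) * exp(-ts / 1550)
  t_all <- c(Inf, ts); s_all <- c(1, mz)
  fa <- fit_sapphire(t_all, abs(s_all), prep_meta = list(sat_to_onset = D),
                     sapphire_model = "anchored")
  expect_equal(fa$t1, 1550, tolerance = 1e-5)
  expect_equal(fa$b, 0.96, tolerance = 1e-4)   # recovered inversion factor
  # free form on the prepared points (drops the unprepared image)
  ff <- fit_sapphire(t_all, abs(s_all), sapphire_model = "free")
  expect_equal(ff$n_points, 9)
  expect_equal(ff$t1, 1550, tolerance = 1e-4)
  # b -> 2 limit: inversion of fully recovered magnetization is plain IR
  tIR <- c(113, 300, 700, 1400, 2600)
  sIR <- 1 - 2 * exp(-tIR / 800)
  fIR <- fit_sapphire(tIR, abs(sIR), sapphire_model = "free")
  expect_equal(fIR$t1, 800, tolerance = 1e-4)
  expect_equal(fIR$b, 2, tolerance = 1e-4)
})

test_that("variable-projection fit agrees with Levenberg-Marquardt", {
  skip_if_not_installed("minpack.lm")
  set.seed(7)
  t <- c(113, 200, 350, 600, 1000, 1800, 3000, Inf)
  for (i in 1:10) {
    a <- runif(1, 0.5, 2); b <- runif(1, 0.8, 1.05); T1 <- runif(1, 200, 2500)
    s <- a * (1 - b * exp(-t / T1)); s[!is.finite(t)] <- a
    s <- s + rnorm(length(s), 0, 0.01)
    mine <- fit_sr(t, s)
    tf <- ifelse(is.finite(t), t, 1e9)
    lm <- minpack.lm::nlsLM(s ~ aa * (1 - bb * exp(-tf / tt)),
                            start = list(aa = max(s), bb = 1, tt = 1000),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
    expect_equal(mine$t1, coef(lm)[["tt"]], tolerance = 1e-4)
    expect_equal(mine$rss, sum(residuals(lm)^2), tolerance = 1e-6)
  }
})

test_that("Monte-Carlo noise keeps the median SR fit within 1 percent", {
  set.seed(21)
  ts <- c(Inf, seq(113, 615.6, length.out = 9))
  mu <- 1 - exp(-ts / 1550); mu[!is.finite(ts)] <- 1
  S <- rician_samples(mu, 1 / 40, 2000)
  res <- srt1map:::fit_pixel_matrix(ts, S, "SASHA", noise_sigma = 1 / 40)
  ok <- res$converged
  expect_gt(mean(ok), 0.95)
  expect_lt(abs(stats::median(res$t1[ok]) - 1550) / 1550, 0.01)
})

test_that("t1fit methods behave like a model object", {
  t <- c(113, 260, 520, 900, 1500, Inf)
  s <- 1 - 0.95 * exp(-t / 1100); s[!is.finite(t)] <- 1
  f <- fit_sr(t, s)
  expect_named(coef(f), c("a", "b", "t1"))
  expect_equal(unname(coef(f)["t1"]), f$t1)
  expect_equal(fitted(f), predict(f), tolerance = 1e-12)
  expect_lt(max(abs(residuals(f))), 1e-7)
  expect_output(print(f), "SR fit")
  expect_output(print(summary(f)), "normalized rss")
  sims <- simulate(f, nsim = 3, seed = 1, sigma = 0.02)
  expect_equal(dim(sims), c(length(t), 3))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f, pch = 19))
})

test_that("degenerate inputs are rejected or masked", {
  expect_error(fit_sr(c(100, 200, 300), c(1, 2, 3)), "at least 4")
  expect_error(fit_sr(c(100, 100, 300, 400), rep(1, 4)), "distinct")
  expect_error(t1_fit(1:5, 1:4), "equal length")
  expect_error(fit_sapphire(c(113, 300, 700, 1400), c(1, 1, 1, 1),
                            sapphire_model = "anchored"), "sat_to_onset")
})

test_that("pixelwise map engine matches the single-series fit", {
  set.seed(3)
  ts <- c(Inf, seq(113, 615.6, length.out = 9))
  mu <- 1 - exp(-ts / 1300); mu[!is.finite(ts)] <- 1
  S <- rician_samples(mu, 0.02, 25)
  res <- srt1map:::fit_pixel_matrix(ts, S, "SASHA")
  for (i in seq_len(5)) {
    single <- fit_sr(ts, S[i, ])
    expect_equal(res$t1[i], single$t1, tolerance = 1e-4)
    expect_equal(res$rss[i], single$rss, tolerance = 1e-6)
  }
  # MOLLI path with polarity restoration
  tm <- sort(c(100 + 0:4 * 1000, 180 + 0:2 * 1000))
  mum <- abs(1 - 2 * exp(-tm / 1100))
  Sm <- rician_samples(mum, 0.02, 25)
  resm <- srt1map:::fit_pixel_matrix(tm, Sm, "MOLLI")
  for (i in seq_len(5)) {
    single <- fit_molli(tm, Sm[i, ])
    expect_equal(resm$t1[i], single$t1, tolerance = 1e-3)
  }
})

test_that("parameter maps flag invalid pixels and recover uniform phantoms", {
  ph <- tiny_phantom()
  ser <- ideal_series("SASHA", 1550)
  serb <- ideal_series("SASHA", 1980, t2 = 250)
  stack <- phantom_series(ph, ser, serb)
  map <- make_map(stack)
  myo <- ph$label_map == 2L
  expect_true(all(map$valid_mask[myo]))
  expect_equal(unique(map$values[myo]), 1550, tolerance = 1e-4)
  expect_equal(mean(map$values[ph$label_map == 1L]), 1980, tolerance = 1e-3)
  # all-zero pixels stay outside the mask
  expect_true(all(is.na(map$values[ph$label_map == 0L])))
  # an all-zero pixel inside the mask is masked invalid
  stack2 <- stack
  stack2$data[24, 24, ] <- 0
  map2 <- make_map(stack2, mask = ph$label_map != 0L)
  expect_false(map2$valid_mask[24, 24])
})
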
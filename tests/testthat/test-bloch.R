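test_that("free relaxation follows the closed-form recovery", {
  s <- spin_state(mz = 0, t1 = 1000, t2 = 45)
  expect_equal(relax(s, 1000)$mz, 1 - exp(-1))
  # inversion-recovery closed form at myocardial T1
  s2 <- spin_state(mz = -1, t1 = 1550, t2 = 45)
  expect_equal(relax(s2, 113)$mz, 1 - 2 * exp(-113 / 1550), tolerance = 1e-12)
  expect_equal(relax(s2, 113)$mz, -0.85938, tolerance = 1e-5)
  # equilibrium limit
  expect_equal(relax(s, 1e7)$mz, 1, tolerance = 1e-12)
  expect_error(relax(s, -1), "non-negative")
})

test_that("relaxation is a semigroup and transverse decay uses T2", {
  s <- apply_rf(spin_state(t1 = 800, t2 = 60, delta_f = 35), 47, phase = 20)
  one <- relax(relax(s, 120), 340)
  two <- relax(s, 460)
  expect_equal(one$mz, two$mz, tolerance = 1e-12)
  expect_equal(one$mx, two$mx, tolerance = 1e-12)
  expect_equal(one$my, two$my, tolerance = 1e-12)
  expect_equal(mxy(relax(s, 60)), mxy(s) * exp(-1), tolerance = 1e-12)
})

test_that("RF rotations preserve the vector norm and hit textbook angles", {
  s <- spin_state()
  s90 <- apply_rf(s, 90)
  expect_equal(s90$mz, 0, tolerance = 1e-12)
  expect_equal(mxy(s90), 1, tolerance = 1e-12)
  expect_equal(apply_rf(s, 180)$mz, -1, tolerance = 1e-12)
  expect_equal(apply_rf(s, 35)$mz, cos(35 * pi / 180), tolerance = 1e-12)
  # norm conservation for arbitrary states and phases
  set.seed(1)
  for (i in 1:20) {
    st <- spin_state(mz = runif(1, -1, 1), mx = runif(1, -0.5, 0.5),
                     my = runif(1, -0.5, 0.5))
    rot <- apply_rf(st, runif(1, 0, 360), runif(1, 0, 360))
    expect_equal(rot$mx^2 + rot$my^2 + rot$mz^2,
                 st$mx^2 + st$my^2 + st$mz^2, tolerance = 1e-12)
  }
})

test_that("physical states stay bounded through arbitrary event chains", {
  set.seed(42)
  for (i in 1:25) {
    s <- spin_state(t1 = runif(1, 100, 2500), t2 = runif(1, 20, 250),
                    delta_f = runif(1, -100, 100))
    for (j in 1:15) {
      op <- sample(c("rf", "relax", "wet", "inv"), 1)
      s <- switch(op,
                  rf = apply_rf(s, runif(1, 0, 180), runif(1, 0, 360)),
                  relax = relax(s, runif(1, 0, 2000)),
                  wet = wet_saturation(s)$state,
                  inv = adiabatic_inversion(s, runif(1))$state)
      expect_lte(abs(s$mz), s$m0 + 1e-12)
      expect_gte(mxy(s), 0)
    }
  }
})

test_that("WET saturation nulls magnetization across the T1 range", {
  # ideal single 90 with crusher
  one <- wet_saturation(spin_state(t1 = 1000, t2 = 45), angles = 90)
  expect_equal(one$state$mz, 0, tolerance = 1e-12)
  expect_equal(one$efficacy, 1, tolerance = 1e-12)
  # no excitation leaves the state untouched
  off <- wet_saturation(spin_state(t1 = 1000, t2 = 45), b1_scale = 0)
  expect_equal(off$state$mz, 1)
  expect_equal(off$efficacy, 0)
  # composite module: mean efficacy over a broad T1 grid exceeds 99 %
  grid <- seq(100, 2300, by = 100)
  eff <- vapply(grid, function(t1)
    wet_saturation(spin_state(t1 = t1, t2 = 45))$efficacy, numeric(1))
  expect_gte(mean(eff), 0.99)
  # efficacy is also robust to moderate transmit-field error
  eff_b1 <- vapply(c(0.8, 0.9, 1.1, 1.2), function(b1)
    mean(vapply(grid, function(t1)
      wet_saturation(spin_state(t1 = t1, t2 = 45), b1_scale = b1)$efficacy,
      numeric(1))), numeric(1))
  expect_true(all(eff_b1 > 0.95))
})

test_that("adiabatic inversion scales Mz and reports its efficacy", {
  s <- spin_state()
  expect_equal(adiabatic_inversion(s, 1)$state$mz, -1)
  expect_equal(adiabatic_inversion(s, 1)$efficacy, 1)
  r <- adiabatic_inversion(s, 0.9)
  expect_equal(r$state$mz, -0.9)
  expect_equal(r$efficacy, 0.95)
  expect_equal(adiabatic_inversion(spin_state(mz = 0.5), 1)$state$mz, -0.5)
  expect_error(adiabatic_inversion(s, 1.2), "\\[0, 1\\]")
})

test_that("bSSFP readout matches an independent pulse-by-pulse oracle", {
  cfg <- readout_config()
  expect_equal(bssfp_readout(spin_state(), cfg)$t_center, (5 + 70) * 2.6)

  # flip = 0: no signal, pure relaxation over the block duration
  cfg0 <- readout_config(flip = 0)
  s <- spin_state(mz = 0.4, t1 = 900, t2 = 50)
  r0 <- bssfp_readout(s, cfg0)
  expect_equal(r0$signal, 0)
  expect_equal(r0$state$mz, relax(s, (139 + 5) * 2.6)$mz, tolerance = 1e-12)

  # independent oracle: explicit rotation matrices and scalar relaxation
  oracle <- function(mz0, t1, t2, df, cfg) {
    kb <- function(n, beta) {
      tt <- seq_len(n) / n
      (tt) * besselI(beta * sqrt(pmax(0, 1 - (1 - tt)^2)), 0) / besselI(beta, 0)
    }
    flips <- c(cfg$flip * kb(cfg$n_startup, cfg$beta), rep(cfg$flip, cfg$n_lines))
    M <- c(0, 0, mz0)
    rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
    dec <- function(M, dt) {
      ph <- 2 * pi * df * dt / 1000
      Rz <- matrix(c(cos(ph), -sin(ph), 0, sin(ph), cos(ph), 0, 0, 0, 1), 3, byrow = TRUE)
      M <- Rz %*% M
      c(M[1] * exp(-dt / t2), M[2] * exp(-dt / t2), 1 + (M[3] - 1) * exp(-dt / t1))
    }
    ic <- cfg$n_startup + ceiling(cfg$n_lines / 2)
    sig <- NA
    for (i in seq_along(flips)) {
      a <- flips[i] * pi / 180 * (if (i %% 2 == 1) 1 else -1)
      M <- rot_x(a) %*% M
      M <- dec(M, cfg$te)
      if (i == ic) sig <- sqrt(M[1]^2 + M[2]^2)
      M <- dec(M, cfg$tr - cfg$te)
    }
    sig
  }
  for (df in c(0, 40)) {
    got <- bssfp_readout(spin_state(t1 = 1550, t2 = 45, delta_f = df), cfg)$signal
    want <- oracle(1, 1550, 45, df, cfg)
    expect_equal(got, want, tolerance = 1e-9)
  }

  # T1, T2 -> infinity: matches the rotation-only recursion
  cfg_small <- readout_config(n_lines = 21, n_startup = 0)
  got <- bssfp_readout(spin_state(t1 = 1e12, t2 = 1e12), cfg_small)$signal
  want <- oracle(1, 1e12, 1e12, 0, cfg_small)
  expect_equal(got, want, tolerance = 1e-9)
})
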
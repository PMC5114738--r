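# shared helpers for building small simulated inputs

ideal_series <- function(sequence, t1, t2 = 45, rr = 1000, scheme = "5(3)3",
                         inversion_efficiency = 1) {
  sched <- switch(sequence,
                  MOLLI = schedule_molli(rr, scheme = scheme),
                  SASHA = schedule_sasha(rr),
                  SAPPHIRE = schedule_sapphire(rr))
  simulate_series(spin_state(t1 = t1, t2 = t2), sched,
                  ideal_readout = TRUE,
                  inversion_efficiency = inversion_efficiency,
                  wet = list(ideal = TRUE))
}

full_series <- function(sequence, t1, t2 = 45, rr = 1000, scheme = "5(3)3",
                        inversion_efficiency = 0.96) {
  sched <- switch(sequence,
                  MOLLI = schedule_molli(rr, scheme = scheme),
                  SASHA = schedule_sasha(rr),
                  SAPPHIRE = schedule_sapphire(rr))
  simulate_series(spin_state(t1 = t1, t2 = t2), sched,
                  inversion_efficiency = inversion_efficiency)
}

rician_samples <- function(mu, sigma, n_rep) {
  n <- length(mu)
  MU <- matrix(mu, n_rep, n, byrow = TRUE)
  sqrt((MU + matrix(stats::rnorm(n_rep * n, 0, sigma), n_rep, n))^2 +
         matrix(stats::rnorm(n_rep * n, 0, sigma), n_rep, n)^2)
}

tiny_phantom <- function(slice = "mid", nx = 48, ny = 48) {
  make_phantom(nx = nx, ny = ny, r_endo = 7, r_epi = 11, slice = slice)
}
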
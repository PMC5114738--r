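test_that("mean comparison gates pairwise tests on the omnibus result", {
  set.seed(2)
  base <- rnorm(12, 1550, 40)
  same <- cbind(A = base, B = base, C = base)
  r0 <- compare_means(same + rnorm(36, 0, 1e-6))
  expect_false(r0$significant)
  expect_null(r0$pairwise)

  shifted <- cbind(A = base, B = base + 300, C = base + 600) +
    rnorm(36, 0, 5)
  r1 <- compare_means(shifted)
  expect_true(r1$significant)
  expect_lt(r1$omnibus$p, 0.05)
  expect_equal(nrow(r1$pairwise), 3)
  expect_true(all(r1$pairwise$p < 0.05))
  expect_error(compare_means(shifted[1:2, ]), "at least")
})

test_that("repeated-measures ANOVA F matches a from-scratch decomposition", {
  set.seed(4)
  for (i in 1:5) {
    m <- matrix(rnorm(30, 1500, 50), 10, 3,
                dimnames = list(NULL, c("A", "B", "C")))
    r <- compare_means(m)
    # brute-force two-way decomposition without replication
    grand <- mean(m)
    ss_seq <- nrow(m) * sum((colMeans(m) - grand)^2)
    ss_sub <- ncol(m) * sum((rowMeans(m) - grand)^2)
    ss_tot <- sum((m - grand)^2)
    ss_err <- ss_tot - ss_seq - ss_sub
    f_oracle <- (ss_seq / (ncol(m) - 1)) /
      (ss_err / ((nrow(m) - 1) * (ncol(m) - 1)))
    expect_equal(r$omnibus$statistic, f_oracle, tolerance = 1e-10)
    p_oracle <- stats::pf(f_oracle, ncol(m) - 1,
                          (nrow(m) - 1) * (ncol(m) - 1), lower.tail = FALSE)
    expect_equal(r$omnibus$p, p_oracle, tolerance = 1e-10)
  }
})

test_that("variance comparison uses Bartlett then paired variance ratios", {
  set.seed(8)
  x <- rnorm(20, 0, 10)
  equal <- cbind(A = x + rnorm(20, 0, 3), B = x + rnorm(20, 0, 3),
                 C = x + rnorm(20, 0, 3))
  r0 <- compare_variances(equal)
  expect_s3_class(r0, "method_comparison")
  scaled <- equal; scaled[, "C"] <- equal[, "C"] * 4
  r1 <- compare_variances(scaled)
  expect_true(r1$significant)
  ratio_ac <- r1$pairwise$var_ratio[r1$pairwise$b == "C" &
                                      r1$pairwise$a == "A"]
  expect_lt(ratio_ac, 0.5)
  expect_lt(r1$pairwise$p[r1$pairwise$b == "C" & r1$pairwise$a == "A"], 0.05)
  # identical columns: variance ratio is exactly 1 (Bartlett needs jitter)
  pm <- suppressWarnings(srt1map:::pitman_morgan(equal[, 1], equal[, 1] * 1))
  expect_true(is.na(pm$statistic) || abs(pm$statistic) < 1e-6)
  expect_equal(stats::var(equal[, 1]) / stats::var(equal[, 1]), 1)
  expect_error(compare_variances(cbind(A = rep(1, 20), B = rnorm(20))),
               "zero-variance")
})

test_that("Pitman-Morgan test holds its type-I error and detects scale shifts", {
  set.seed(11)
  reject <- replicate(400, {
    x <- rnorm(20); y <- 0.6 * x + rnorm(20, 0, 0.8)
    srt1map:::pitman_morgan(x, y)$p < 0.05
  })
  expect_lt(abs(mean(reject) - 0.05), 0.04)
  power <- replicate(200, {
    x <- rnorm(20); y <- 3 * (0.6 * x + rnorm(20, 0, 0.8))
    srt1map:::pitman_morgan(x, y)$p < 0.05
  })
  expect_gt(mean(power), 0.8)
})

test_that("ordinal comparison runs Kruskal-Wallis with gated Mann-Whitney U", {
  same <- cbind(A = rep(c(3, 4), 10), B = rep(c(3, 4), 10))
  expect_false(compare_ordinal(same)$significant)
  sep <- cbind(A = rep(4, 12), B = rep(1, 12))
  r <- compare_ordinal(sep)
  expect_true(r$significant)
  expect_equal(r$pairwise$U, 144)   # complete separation: U = n1 * n2
  expect_lt(r$pairwise$p, 1e-4)
  # degenerate all-tied input is flagged, not an error
  r2 <- compare_ordinal(cbind(A = rep(2, 5), B = rep(2, 5)))
  expect_true(isTRUE(r2$degenerate))

  # U matches the rank-sum enumeration on a small instance
  a <- c(1, 2, 4); b <- c(3, 5, 6)
  u_hand <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  wt <- stats::wilcox.test(a, b)
  expect_equal(unname(wt$statistic), u_hand)
})

test_that("agreement analysis computes the geometric mean of |differences|", {
  a <- agreement_analysis(c(10, 20, 30), c(6, 11, 14))
  expect_equal(a$geometric_mean, prod(c(4, 9, 16))^(1 / 3), tolerance = 1e-12)
  expect_equal(round(a$geometric_mean, 2), 8.32)
  expect_true(a$ci[1] < a$geometric_mean && a$geometric_mean < a$ci[2])
  # identical vectors: reported as zero under the flooring rule
  z <- agreement_analysis(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$geometric_mean, 0)
  # equal reader error across sequences: log-difference ANOVA is null-like
  set.seed(13)
  pvals <- replicate(200, {
    d1 <- abs(rnorm(20, 0, 5)); d2 <- abs(rnorm(20, 0, 5)); d3 <- abs(rnorm(20, 0, 5))
    r <- agreement_analysis(c(d1, d2, d3), rep(0, 60),
                            groups = rep(c("A", "B", "C"), each = 20))
    r$anova_log$p
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.045)
})

test_that("consistency ICC matches its ANOVA oracle and anchor invariance", {
  m <- cbind(a = c(1500, 1540, 1470, 1600), b = c(1500, 1540, 1470, 1600))
  expect_equal(icc_winer(m)$icc, 1)
  # adding a per-rater constant leaves the consistency ICC at 1
  m2 <- m; m2[, 2] <- m2[, 2] + 50
  expect_equal(icc_winer(m2)$icc, 1)
  # but shifts the agreement statistic
  ag <- agreement_analysis(m2[, 1], m2[, 2])
  expect_equal(ag$geometric_mean, 50)

  set.seed(17)
  for (i in 1:5) {
    r <- matrix(rnorm(20, 1500, 60), 10, 2)
    got <- icc_winer(r)
    # from-scratch two-way mean squares
    n <- nrow(r); k <- ncol(r)
    aov_tab <- summary(stats::aov(val ~ target + rater,
                                  data = data.frame(val = as.vector(r),
                                                    target = factor(rep(1:n, k)),
                                                    rater = factor(rep(1:k, each = n)))))[[1]]
    bms <- aov_tab["target", "Mean Sq"]; ems <- aov_tab["Residuals", "Mean Sq"]
    expect_equal(got$icc, (bms - ems) / (bms + (k - 1) * ems), tolerance = 1e-10)
    expect_true(got$ci[1] <= got$icc && got$icc <= got$ci[2])
    expect_true(all(abs(c(got$icc, got$ci)) <= 1 + 1e-9))
  }
  expect_error(icc_winer(m[1:2, ]), "at least 3")
})

test_that("ICC comparison reports a two-tailed F-ratio with the 0.017 threshold", {
  set.seed(19)
  r1 <- icc_winer(matrix(rnorm(40, 1500, 60), 20, 2))
  r2 <- icc_winer(matrix(rnorm(40, 1500, 60), 20, 2))
  cmp <- icc_compare(r1, r2)
  expect_equal(cmp$threshold, 0.017)
  expect_true(cmp$p >= 0 && cmp$p <= 1)
  self <- icc_compare(r1, r1)
  expect_equal(self$ratio, 1)
  expect_false(self$significant)
})
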
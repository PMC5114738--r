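#' Compare per-subject means across sequences
#'
#' Omnibus-then-pairwise chain for per-subject summary values: a
#' repeated-measures one-way ANOVA across the sequence columns (subjects as
#' blocks), followed — only when the omnibus test is significant — by all
#' pairwise paired t-tests. A plain one-way ANOVA on the columns is also
#' available.
#'
#' @param values Numeric matrix, subjects x sequences, with sequence names
#'   as column names; no missing cells.
#' @param alpha Omnibus significance level gating the pairwise tests.
#' @param type `"repeated"` (default) or `"oneway"`.
#' @return A `method_comparison` list: `omnibus` (statistic, df, p, test
#'   name), `pairwise` (data frame or `NULL` when not gated in),
#'   `significant`, `alpha`.
#' @export
compare_means <- function(values, alpha = 0.05, type = c("repeated", "oneway")) {
  type <- match.arg(type)
  values <- as.matrix(values)
  if (ncol(values) < 2 || nrow(values) < 3)
    stop("need at least 2 sequences and 3 subjects")
  if (anyNA(values)) stop("missing cells are not supported")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("seq", seq_len(ncol(values)))
  long <- data.frame(
    value = as.vector(values),
    sequence = factor(rep(colnames(values), each = nrow(values))),
    subject = factor(rep(seq_len(nrow(values)), ncol(values)))
  )
  if (type == "repeated") {
    fit <- stats::aov(value ~ sequence + subject, data = long)
    tab <- summary(fit)[[1]]
    i <- grep("^sequence", rownames(tab))
    stat <- tab[i, "F value"]; p <- tab[i, "Pr(>F)"]
    df <- c(tab[i, "Df"], tab[grep("^Residuals", rownames(tab)), "Df"])
    test <- "repeated-measures ANOVA"
  } else {
    fit <- stats::aov(value ~ sequence, data = long)
    tab <- summary(fit)[[1]]
    stat <- tab[1, "F value"]; p <- tab[1, "Pr(>F)"]
    df <- tab[, "Df"]
    test <- "one-way ANOVA"
  }
  pairwise <- NULL
  if (is.finite(p) && p < alpha) {
    cmb <- utils::combn(colnames(values), 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- cmb[1, j]; b <- cmb[2, j]
      tt <- stats::t.test(values[, a], values[, b], paired = TRUE)
      data.frame(a = a, b = b, statistic = unname(tt$statistic),
                 p = tt$p.value, mean_diff = unname(tt$estimate),
                 stringsAsFactors = FALSE)
    }))
    pairwise$p_threshold_bonferroni <- alpha / ncol(cmb)
  }
  structure(list(omnibus = list(test = test, statistic = unname(stat),
                                df = unname(df), p = unname(p)),
                 pairwise = pairwise, significant = is.finite(p) && p < alpha,
                 alpha = alpha),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  o <- x$omnibus
  cat(sprintf("<method_comparison> %s: statistic = %.4g, p = %.4g\n",
              o$test, o$statistic, o$p))
  if (!is.null(x$pairwise)) {
    cat("  pairwise tests (gated by omnibus p <", x$alpha, "):\n")
    print(x$pairwise, row.names = FALSE)
  } else cat("  omnibus not significant; no pairwise tests run\n")
  invisible(x)
}

#' Compare inter-subject variances across sequences
#'
#' Bartlett's test across the sequence columns, followed — when significant
#' — by pairwise Pitman-Morgan paired variance-ratio tests (the paired
#' analogue of the F-test: a t-test on the correlation between sums and
#' differences of the paired columns).
#'
#' @inheritParams compare_means
#' @return A `method_comparison`; pairwise rows carry the variance ratio
#'   and the Pitman-Morgan p value.
#' @export
compare_variances <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  if (ncol(values) < 2 || nrow(values) < 3)
    stop("need at least 2 sequences and 3 subjects")
  if (anyNA(values)) stop("missing cells are not supported")
  if (any(apply(values, 2, stats::var) == 0))
    stop("Bartlett's test is undefined for a zero-variance column")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("seq", seq_len(ncol(values)))
  bt <- stats::bartlett.test(as.data.frame(values))
  p <- bt$p.value
  pairwise <- NULL
  if (is.finite(p) && p < alpha) {
    cmb <- utils::combn(colnames(values), 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- values[, cmb[1, j]]; b <- values[, cmb[2, j]]
      pm <- pitman_morgan(a, b)
      data.frame(a = cmb[1, j], b = cmb[2, j],
                 var_ratio = stats::var(a) / stats::var(b),
                 statistic = pm$statistic, p = pm$p,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(omnibus = list(test = "Bartlett",
                                statistic = unname(bt$statistic),
                                df = unname(bt$parameter), p = unname(p)),
                 pairwise = pairwise, significant = is.finite(p) && p < alpha,
                 alpha = alpha),
            class = "method_comparison")
}

# Pitman-Morgan test for equality of variances of paired samples
pitman_morgan <- function(x, y) {
  n <- length(x)
  r <- stats::cor(x + y, x - y)
  stat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(stat), df = n - 2)
  list(statistic = stat, p = p)
}

#' Compare ordinal scores across sequences
#'
#' Kruskal-Wallis omnibus test on the score columns, followed — when
#' significant — by pairwise Mann-Whitney U tests (tie-corrected, normal
#' approximation via [stats::wilcox.test()]).
#'
#' @param scores Numeric matrix, subjects x sequences, on an ordinal scale.
#' @param alpha Omnibus significance level.
#' @return A `method_comparison`; pairwise rows carry the U statistic.
#' @export
compare_ordinal <- function(scores, alpha = 0.05) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("seq", seq_len(ncol(scores)))
  if (length(unique(as.vector(scores))) < 2) {
    return(structure(list(omnibus = list(test = "Kruskal-Wallis",
                                         statistic = 0, df = ncol(scores) - 1,
                                         p = 1),
                          pairwise = NULL, significant = FALSE,
                          alpha = alpha, degenerate = TRUE),
                     class = "method_comparison"))
  }
  groups <- factor(rep(colnames(scores), each = nrow(scores)))
  kw <- stats::kruskal.test(as.vector(scores), groups)
  p <- kw$p.value
  pairwise <- NULL
  if (is.finite(p) && p < alpha) {
    cmb <- utils::combn(colnames(scores), 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      wt <- suppressWarnings(stats::wilcox.test(scores[, cmb[1, j]],
                                                scores[, cmb[2, j]]))
      data.frame(a = cmb[1, j], b = cmb[2, j],
                 U = unname(wt$statistic), p = wt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(omnibus = list(test = "Kruskal-Wallis",
                                statistic = unname(kw$statistic),
                                df = unname(kw$parameter), p = unname(p)),
                 pairwise = pairwise, significant = is.finite(p) && p < alpha,
                 alpha = alpha),
            class = "method_comparison")
}

#' Observer agreement via the geometric mean of absolute differences
#'
#' Computes the absolute differences between two paired T1 vectors, their
#' geometric mean with a 95 % interval on the log scale (back-transformed),
#' and — when several sequences' difference sets are supplied through
#' `groups` — a one-way ANOVA of the log-transformed absolute differences
#' across sequences.
#'
#' Zero differences are floored at `epsilon` before taking logs; when all
#' differences are below `epsilon` the geometric mean is reported as 0.
#'
#' @param t1_set1,t1_set2 Paired T1 vectors (ms).
#' @param groups Optional factor of the same length assigning each pair to
#'   a sequence, enabling the cross-method ANOVA.
#' @param epsilon Flooring constant in ms.
#' @return A list of class `agreement` with `differences`, `geometric_mean`,
#'   `ci` (95 % interval), and optionally `anova_log` (statistic, p).
#' @examples
#' agreement_analysis(c(1500, 1520, 1490), c(1504, 1511, 1506))
#' @export
agreement_analysis <- function(t1_set1, t1_set2, groups = NULL,
                               epsilon = 0.001) {
  if (length(t1_set1) != length(t1_set2))
    stop("paired vectors must have equal length")
  d <- abs(t1_set1 - t1_set2)
  dl <- pmax(d, epsilon)
  m <- mean(log(dl)); s <- stats::sd(log(dl)); n <- length(dl)
  gm <- if (all(d < epsilon)) 0 else exp(m)
  ci <- if (n > 1 && s > 0)
    exp(m + c(-1, 1) * stats::qt(0.975, n - 1) * s) else c(gm, gm)
  out <- list(differences = d, geometric_mean = gm, ci = ci, n = n)
  if (!is.null(groups)) {
    groups <- factor(groups)
    fit <- stats::aov(log(dl) ~ groups)
    tab <- summary(fit)[[1]]
    out$anova_log <- list(statistic = tab[1, "F value"], p = tab[1, "Pr(>F)"])
  }
  class(out) <- "agreement"
  out
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf("<agreement> geometric mean |diff| = %.2f [%.2f-%.2f], n = %d\n",
              x$geometric_mean, x$ci[1], x$ci[2], x$n))
  if (!is.null(x$anova_log))
    cat(sprintf("  ANOVA on log|diff|: F = %.3g, p = %.3g\n",
                x$anova_log$statistic, x$anova_log$p))
  invisible(x)
}

#' Intraclass correlation coefficient (two-way consistency form)
#'
#' Consistency ICC from the two-way ANOVA decomposition with raters as a
#' fixed anchor effect (Winer's formulation):
#' `ICC = (BMS - EMS) / (BMS + (k-1) EMS)` with BMS the between-target and
#' EMS the residual mean square. Because the rater (anchor) effect is
#' removed, the ICC is insensitive to a constant shift between raters. The
#' 95 % confidence interval follows from F-distribution bounds on
#' `F0 = BMS/EMS`.
#'
#' @param ratings Numeric matrix, targets x raters (>= 3 targets, >= 2
#'   raters), no missing values.
#' @param conf_level Confidence level of the interval.
#' @return A list of class `icc` with `icc`, `ci`, `f0`, `df`, and the mean
#'   squares.
#' @examples
#' m <- cbind(a = c(1500, 1540, 1470, 1600), b = c(1504, 1538, 1480, 1597))
#' icc_winer(m)$icc
#' @export
icc_winer <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3 || k < 2) stop("need at least 3 targets and 2 raters")
  if (anyNA(ratings)) stop("missing ratings are not supported")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  bms <- k * sum((row_m - grand)^2) / (n - 1)
  jms <- n * sum((col_m - grand)^2) / (k - 1)
  resid <- ratings - outer(row_m, rep(1, k)) -
    outer(rep(1, n), col_m) + grand
  ems <- sum(resid^2) / ((n - 1) * (k - 1))
  if (bms <= 0 || (bms == 0 && ems == 0))
    stop("ICC undefined: no between-target variance")
  if (ems == 0) {
    icc <- 1; ci <- c(1, 1); f0 <- Inf
  } else {
    icc <- (bms - ems) / (bms + (k - 1) * ems)
    f0 <- bms / ems
    alpha <- 1 - conf_level
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- f0 / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f0 * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  structure(list(icc = icc, ci = ci, f0 = f0,
                 df = c(n - 1, (n - 1) * (k - 1)),
                 bms = bms, jms = jms, ems = ems, n = n, k = k),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("<icc> consistency ICC = %.4f [%.4f-%.4f] (n = %d targets, k = %d raters)\n",
              x$icc, x$ci[1], x$ci[2], x$n, x$k))
  invisible(x)
}

#' Compare two ICCs by a two-tailed F statistic
#'
#' Compares the reliability of two rating studies through the ratio of
#' their ANOVA F statistics `F0 = BMS/EMS`. Under equal reliability the
#' ratio is referred to an F distribution with the two studies'
#' between-target degrees of freedom (an approximation, since each F0 is
#' itself F-distributed); the two-tailed p value is reported together with
#' the Bonferroni-corrected significance threshold used for three pairwise
#' sequence comparisons (p < 0.017).
#'
#' @param icc1,icc2 Objects from [icc_winer()].
#' @param threshold Significance threshold after Bonferroni correction.
#' @return A list with `ratio`, `p`, `threshold`, `significant`.
#' @export
icc_compare <- function(icc1, icc2, threshold = 0.017) {
  w <- icc1$f0 / icc2$f0
  p <- 2 * min(stats::pf(w, icc1$df[1], icc2$df[1]),
               1 - stats::pf(w, icc1$df[1], icc2$df[1]))
  list(ratio = w, p = p, threshold = threshold, significant = p < threshold)
}
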
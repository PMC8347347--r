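# The cohort-level statistical battery: normality testing, two-group
# comparisons, two-way ANOVA with Tukey post-hoc, Hedges' g, subgroup
# selection against the control distribution, and seeded bootstrap
# confidence intervals for Pearson correlations.

# Kolmogorov-Smirnov distance of a sample from the normal with estimated
# mean and SD (the Lilliefors statistic).
lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  max(max(seq_len(n) / n - p), max(p - (seq_len(n) - 1) / n))
}

#' Monte-Carlo null distribution of the Lilliefors statistic
#'
#' Because mean and SD are estimated from the sample, the statistic's null
#' distribution is not the classical Kolmogorov-Smirnov one; it depends only
#' on the sample size and is obtained here by simulation.  The table can be
#' reused across many tests of the same size.
#'
#' @param n Sample size.
#' @param n_sim Number of null simulations.
#' @param seed Optional RNG seed for reproducibility.
#' @return Numeric vector of `n_sim` null statistics.
#' @export
lilliefors_null <- function(n, n_sim = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(n * n_sim), nrow = n)
  mu <- colMeans(m)
  s <- sqrt((colSums(m^2) - n * mu^2) / (n - 1))
  z <- apply((m - rep(mu, each = n)) / rep(s, each = n), 2L, sort)
  pp <- pnorm(z)
  i <- seq_len(n)
  pmax(apply(i / n - pp, 2L, max), apply(pp - (i - 1) / n, 2L, max))
}

#' Lilliefors test of normality
#'
#' Kolmogorov-Smirnov test against a normal distribution with mean and SD
#' estimated from the sample, with the p-value taken from a seeded
#' Monte-Carlo null distribution (`(1 + #{D* >= D}) / (n_sim + 1)`).
#'
#' @param x Numeric sample (`n >= 4`, non-constant).
#' @param n_sim Number of Monte-Carlo null simulations.
#' @param seed Optional RNG seed.
#' @param null_stats Optional precomputed null table from
#'   [lilliefors_null()] for this sample size (avoids re-simulation when
#'   testing many samples of equal size).
#' @return A `stat_test_result` list: `method`, `statistic`, `p_value`, `n`.
#' @export
lilliefors_test <- function(x, n_sim = 10000, seed = NULL, null_stats = NULL) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) stop("Lilliefors test needs at least 4 observations")
  if (sd(x) == 0) stop("constant sample: normality test undefined")
  d <- lilliefors_stat(x)
  if (is.null(null_stats)) null_stats <- lilliefors_null(n, n_sim, seed)
  p <- (1 + sum(null_stats >= d)) / (length(null_stats) + 1)
  structure(list(method = "Lilliefors (Monte-Carlo)", statistic = d,
                 p_value = p, n = n),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g (n = %s)\n",
              x$method, x$statistic, x$p_value,
              paste(unlist(x[intersect(c("n", "n1", "n2", "df"), names(x))]),
                    collapse = "/")))
  invisible(x)
}

#' Two-group comparison with normality-dependent test choice
#'
#' Both samples are first screened with the Lilliefors test at level
#' `alpha`.  If neither rejects normality, a two-tailed two-sample Student's
#' t-test is used; otherwise a rank-based test.  For the two independent
#' groups of a case-control design the rank test is the Wilcoxon rank-sum
#' (Mann-Whitney) test; a paired signed-rank variant is available with
#' `paired = TRUE`.  The method actually applied is recorded in the result.
#'
#' @param x,y Numeric samples (each `n >= 4`).
#' @param alpha Significance level for the normality screen.
#' @param paired Use the paired signed-rank/paired-t variants.
#' @param n_sim Monte-Carlo simulations per normality test.
#' @param seed Optional RNG seed for the normality nulls.
#' @return A `stat_test_result` with fields `method`, `statistic`,
#'   `p_value`, `n1`, `n2`, `normal_p` (the two screening p-values).
#' @export
compare_two_groups <- function(x, y, alpha = 0.05, paired = FALSE,
                               n_sim = 2000, seed = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 4 || length(y) < 4)
    stop("each group needs at least 4 observations")
  if (!is.null(seed)) set.seed(seed)
  identical_samples <- sd(c(x, y)) == 0
  if (identical_samples) {
    return(structure(list(method = "degenerate (no variance)", statistic = 0,
                          p_value = 1, n1 = length(x), n2 = length(y),
                          normal_p = c(NA_real_, NA_real_)),
                     class = "stat_test_result"))
  }
  norm_p <- vapply(list(x, y), function(s) {
    if (sd(s) == 0) return(0)   # constant sample: treat as non-normal
    lilliefors_test(s, n_sim = n_sim)$p_value
  }, numeric(1))
  if (all(norm_p > alpha)) {
    ht <- t.test(x, y, paired = paired, var.equal = TRUE)
    method <- if (paired) "paired t-test" else "Student's t-test (two-sample)"
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, paired = paired))
    method <- if (paired) "Wilcoxon signed-rank (paired)"
              else "Wilcoxon rank-sum (Mann-Whitney)"
  }
  structure(list(method = method, statistic = unname(ht$statistic),
                 p_value = ht$p.value, n1 = length(x), n2 = length(y),
                 normal_p = norm_p),
            class = "stat_test_result")
}

#' Two-way ANOVA with Tukey post-hoc for the Group x Side design
#'
#' Fits `value ~ group * side` on the (normally balanced) 2x2 layout of one
#' value per subject-side, and returns the F table together with
#' Tukey-adjusted pairwise comparisons.  If the response is constant the
#' F statistics are undefined; the table is then returned with F = 0 and
#' p = 1 and flagged `zero_variance`.
#'
#' @param value Numeric response, one value per subject-side.
#' @param group Factor-like: `PD` / `control`.
#' @param side Factor-like: side role (more-/less-affected or
#'   dominant/non-dominant).
#' @return A `gait_anova` list: `table` (term, df, sumsq, meansq, F, p),
#'   `tukey` (from [stats::TukeyHSD()]), `zero_variance`, `fit`.
#' @export
gait_anova <- function(value, group, side) {
  group <- factor(group)
  side <- factor(side)
  if (nlevels(group) < 2 || nlevels(side) < 2 || any(table(group, side) == 0))
    stop("empty cell in the Group x Side layout")
  df <- data.frame(value = value, group = group, side = side)
  fit <- aov(value ~ group * side, data = df)
  s <- summary(fit)[[1L]]
  tab <- data.frame(term = trimws(rownames(s)), df = s$Df, sumsq = s$`Sum Sq`,
                    meansq = s$`Mean Sq`, F = s$`F value`, p = s$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  zero_var <- isTRUE(all.equal(var(value), 0)) ||
    any(!is.finite(tab$F[-nrow(tab)]))
  if (zero_var) {
    tab$F[-nrow(tab)] <- 0
    tab$p[-nrow(tab)] <- 1
  }
  tukey <- if (zero_var) NULL else TukeyHSD(fit)
  structure(list(table = tab, tukey = tukey, zero_variance = zero_var,
                 fit = fit),
            class = "gait_anova")
}

#' @export
print.gait_anova <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Hedges' g standardised mean difference
#'
#' `g = (M1 - M2) / SD*_pooled`, where the pooled SD uses the
#' degrees-of-freedom weighting
#' `SD*_pooled = sqrt(((n1-1) SD1^2 + (n2-1) SD2^2) / (n1 + n2 - 2))`.
#' With `correct = TRUE` (the default) the small-sample bias correction
#' `J = 1 - 3 / (4 (n1 + n2) - 9)` multiplies the quotient, as is standard
#' for sample sizes of about 20 and below.  Sign convention: first argument
#' minus second.
#'
#' @param x,y Numeric samples (`n >= 2` each, pooled SD > 0).
#' @param correct Apply the small-sample correction factor J.
#' @return An `effect_size` list: `g`, `g_uncorrected`, `n1`, `n2`,
#'   `correction_applied`.
#' @export
hedges_g <- function(x, y, correct = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 observations")
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  if (sp == 0) stop("pooled SD is zero: effect size undefined")
  g0 <- (mean(x) - mean(y)) / sp
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  structure(list(g = if (correct) j * g0 else g0, g_uncorrected = g0,
                 n1 = n1, n2 = n2, correction_applied = correct),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Hedges' g = %.3f (uncorrected %.3f; n = %d/%d; correction %s)\n",
              x$g, x$g_uncorrected, x$n1, x$n2,
              if (x$correction_applied) "applied" else "not applied"))
  invisible(x)
}

#' Select the above-control subgroup of patients
#'
#' The control reference level is the mean plus one sample standard
#' deviation of the controls' speed-normalised atypical percentage (each
#' control contributing the average of its dominant and non-dominant
#' sides).  Patients strictly above that threshold form the subgroup with
#' an abnormal amount of atypical cycles.
#'
#' @param atyp_pd Per-patient Atyp values (normally from the more-affected
#'   side).
#' @param atyp_control Per-control Atyp values (side-averaged).
#' @return List with `threshold`, `selected` (logical mask over `atyp_pd`)
#'   and `n_selected`.
#' @export
select_subgroup <- function(atyp_pd, atyp_control) {
  atyp_control <- atyp_control[!is.na(atyp_control)]
  if (length(atyp_control) < 2)
    stop("need at least 2 control values to define the threshold")
  threshold <- mean(atyp_control) + sd(atyp_control)
  selected <- !is.na(atyp_pd) & atyp_pd > threshold
  list(threshold = threshold, selected = selected, n_selected = sum(selected))
}

# Vectorised Pearson correlations of resampled pairs: idx is an n x B matrix
# of row indices into (x, y).  Resamples with zero variance give NA.
boot_cor <- function(x, y, idx) {
  n <- nrow(idx)
  xb <- matrix(x[idx], nrow = n)
  yb <- matrix(y[idx], nrow = n)
  sx <- colSums(xb); sy <- colSums(yb)
  sxx <- colSums(xb^2) - sx^2 / n
  syy <- colSums(yb^2) - sy^2 / n
  sxy <- colSums(xb * yb) - sx * sy / n
  den <- sqrt(sxx * syy)
  r <- ifelse(den > 0, sxy / den, NA_real_)
  pmin(1, pmax(-1, r))
}

#' Pearson correlation with seeded bootstrap confidence interval
#'
#' The correlation coefficient comes from the least-squares fit of `y` on
#' `x`; its two-sided p-value from the t distribution of r.  The 95%
#' confidence interval is obtained by resampling the pairs with replacement
#' `n_boot` times under a fixed seed.  The default interval is
#' bias-corrected and accelerated (BCa, with jackknife acceleration); a
#' plain percentile interval is available.  Degenerate resamples (zero
#' variance) are dropped from the interval computation; if the bootstrap
#' distribution is a point mass or the bias correction is undefined, the
#' percentile interval is used as fallback.
#'
#' @param x,y Paired numeric vectors (`n >= 3`, non-constant).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional RNG seed; the bootstrap is bit-reproducible for a
#'   fixed seed.
#' @param ci_type `"bca"` (default) or `"percentile"`.
#' @param conf Confidence level.
#' @return A `correlation_result` list: `r`, `p_value`, `ci_low`, `ci_high`,
#'   `n`, `n_boot`, `ci_type`, `seed`.
#' @export
pearson_bootstrap <- function(x, y, n_boot = 1000, seed = NULL,
                              ci_type = c("bca", "percentile"), conf = 0.95) {
  ci_type <- match.arg(ci_type)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  rb <- boot_cor(x, y, idx)
  rb <- rb[!is.na(rb)]
  alpha <- (1 - conf) / 2
  used <- ci_type
  if (!length(rb)) {
    ci <- c(r, r)
  } else if (diff(range(rb)) == 0) {
    ci <- range(rb)
    used <- "degenerate"
  } else if (ci_type == "percentile") {
    ci <- unname(quantile(rb, c(alpha, 1 - alpha)))
  } else {
    prop <- mean(rb < r)
    if (prop == 0 || prop == 1) {
      ci <- unname(quantile(rb, c(alpha, 1 - alpha)))
      used <- "percentile (BCa undefined)"
    } else {
      z0 <- qnorm(prop)
      theta_i <- vapply(seq_len(n), function(i) cor(x[-i], y[-i]), numeric(1))
      d <- mean(theta_i) - theta_i
      denom <- 6 * sum(d^2)^1.5
      a <- if (denom == 0) 0 else sum(d^3) / denom
      zq <- qnorm(c(alpha, 1 - alpha))
      adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
      ci <- unname(quantile(rb, adj))
    }
  }
  ci <- pmin(1, pmax(-1, ci))
  structure(list(r = r, p_value = p, ci_low = ci[1L], ci_high = ci[2L],
                 n = n, n_boot = n_boot, ci_type = used, seed = seed),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (p = %.4g, n = %d); bootstrap 95%% CI [%.3f, %.3f] (%s, %d resamples)\n",
              x$r, x$p_value, x$n, x$ci_low, x$ci_high, x$ci_type, x$n_boot))
  invisible(x)
}
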
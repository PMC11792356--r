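#' Group summary
#'
#' Sufficient statistics of one group for one outcome.
#'
#' @param label group label.
#' @param n integer sample size >= 2.
#' @param mean sample mean.
#' @param sd nonnegative sample standard deviation.
#' @return an object of class `group_summary`.
#' @export
group_summary <- function(label, n, mean, sd) {
  stopifnot(n >= 2, is.finite(mean), is.finite(sd), sd >= 0)
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

summarize_values <- function(values, label) {
  group_summary(label, length(values), mean(values), stats::sd(values))
}

#' Cohen's d for two groups
#'
#' Standardized absolute mean difference using the equal-n pooled SD
#' `sqrt((sd_a^2 + sd_b^2) / 2)`.
#'
#' @param a,b [group_summary()] objects (or numeric vectors of raw values,
#'   which are summarized first).
#' @return nonnegative effect size.
#' @examples
#' cohens_d(group_summary("affected", 23, 9.9, 5.0),
#'          group_summary("unaffected", 23, 6.2, 3.5))
#' @export
cohens_d <- function(a, b) {
  if (is.numeric(a)) a <- summarize_values(a, "a")
  if (is.numeric(b)) b <- summarize_values(b, "b")
  pooled <- sqrt((a$sd^2 + b$sd^2) / 2)
  if (pooled == 0) stop("both groups have zero SD: effect size undefined")
  abs(a$mean - b$mean) / pooled
}

#' Pooled-variance independent t-test from summary statistics
#'
#' Student's two-sided two-sample t-test with pooled variance, computed from
#' each group's (n, mean, sd). Returns the mean difference (`a - b`), its
#' 95% confidence interval, t statistic, degrees of freedom
#' `n_a + n_b - 2`, p-value, and Cohen's d.
#'
#' @param a,b [group_summary()] objects or numeric vectors of raw values.
#' @param conf_level confidence level for the interval (default 0.95).
#' @param welch if `TRUE`, use the Welch (unequal-variance) form instead.
#' @param outcome outcome name carried into the result.
#' @return an object of class `comparison_result`.
#' @examples
#' pooled_t_test(group_summary("affected", 23, 118.8, 44.5),
#'               group_summary("unaffected", 23, 141.4, 37.8))
#' @export
pooled_t_test <- function(a, b, conf_level = 0.95, welch = FALSE,
                          outcome = "outcome") {
  if (is.numeric(a)) a <- summarize_values(a, "a")
  if (is.numeric(b)) b <- summarize_values(b, "b")
  diff <- a$mean - b$mean
  if (welch) {
    se <- sqrt(a$sd^2 / a$n + b$sd^2 / b$n)
    df <- se^4 / ((a$sd^2 / a$n)^2 / (a$n - 1) + (b$sd^2 / b$n)^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  if (se == 0) {
    if (diff == 0) {
      t_stat <- 0; p <- 1
    } else {
      warning("zero pooled variance with unequal means: p set to 0")
      t_stat <- sign(diff) * Inf; p <- 0
    }
    ci <- c(diff, diff)
  } else {
    t_stat <- diff / se
    p <- 2 * stats::pt(-abs(t_stat), df)
    tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
    ci <- diff + c(-1, 1) * tcrit * se
  }
  structure(list(outcome = outcome,
                 group_a = a$label, group_b = b$label,
                 mean_a = a$mean, sd_a = a$sd, n_a = a$n,
                 mean_b = b$mean, sd_b = b$sd, n_b = b$n,
                 mean_difference = diff,
                 ci_low = ci[1], ci_high = ci[2],
                 t_stat = t_stat, df = df, p_value = p,
                 cohens_d = tryCatch(cohens_d(a, b),
                                     error = function(e) NA_real_),
                 conf_level = conf_level, welch = welch),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: %s vs %s\n",
              x$outcome, x$group_a, x$group_b))
  cat(sprintf("  %s vs %s; difference %s [%s, %s]\n",
              paste0(fmt_num(x$mean_a, 2), " +/- ", fmt_num(x$sd_a, 2)),
              paste0(fmt_num(x$mean_b, 2), " +/- ", fmt_num(x$sd_b, 2)),
              fmt_num(x$mean_difference, 2), fmt_num(x$ci_low, 2),
              fmt_num(x$ci_high, 2)))
  cat(sprintf("  t(%s) = %s, p = %s, Cohen's d = %s\n",
              fmt_num(x$df, 1), fmt_num(x$t_stat, 3),
              format.pval(x$p_value, digits = 3), fmt_num(x$cohens_d, 2)))
  invisible(x)
}

#' @export
as.data.frame.comparison_result <- function(x, ...) {
  data.frame(outcome = x$outcome,
             mean_a = x$mean_a, sd_a = x$sd_a, n_a = x$n_a,
             mean_b = x$mean_b, sd_b = x$sd_b, n_b = x$n_b,
             mean_difference = x$mean_difference,
             ci_low = x$ci_low, ci_high = x$ci_high,
             t_stat = x$t_stat, df = x$df, p_value = x$p_value,
             cohens_d = x$cohens_d, stringsAsFactors = FALSE)
}

#' Power specification for a two-sample t-test
#'
#' @param alpha two-sided significance level in (0, 1), default 0.05.
#' @param power target power in (0, 1), default 0.80.
#' @param min_difference smallest between-group mean difference to detect
#'   (> 0), in outcome units.
#' @param sd per-group standard deviation (> 0), same units.
#' @return an object of class `power_spec`.
#' @export
power_spec <- function(alpha = 0.05, power = 0.80, min_difference, sd) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  stopifnot(min_difference > 0, sd > 0)
  structure(list(alpha = alpha, power = power,
                 min_difference = min_difference, sd = sd),
            class = "power_spec")
}

# Two-sided two-sample t power at per-group size n, via the noncentral t.
t_test_power <- function(n, delta, sd, alpha) {
  df <- 2 * n - 2
  ncp <- delta / (sd * sqrt(2 / n))
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + 1 - stats::pt(tcrit, df, ncp)
}

#' Required per-group sample size
#'
#' Smallest integer per-group n for which a two-sided pooled two-sample
#' t-test attains the target power at effect size
#' `min_difference / sd`, evaluated by noncentral-t iteration.
#'
#' @param spec a [power_spec()].
#' @param n_max search ceiling (error if exceeded).
#' @return integer sample size per group.
#' @examples
#' required_sample_size(power_spec(0.05, 0.80, min_difference = 3.0, sd = 3.5))
#' @export
required_sample_size <- function(spec, n_max = 1e6) {
  stopifnot(inherits(spec, "power_spec"))
  n <- 2L
  while (t_test_power(n, spec$min_difference, spec$sd, spec$alpha) < spec$power) {
    n <- n + 1L
    if (n > n_max) stop("required sample size exceeds n_max")
  }
  n
}

#' Normality screening by Kolmogorov-Smirnov and skewness
#'
#' Lilliefors-corrected KS test (parameters estimated from the sample) plus
#' the adjusted Fisher-Pearson sample skewness. Following common practice
#' for moderate samples, a distribution is called normal iff its skewness
#' lies in `[-1, 1]`; the KS p-value is reported alongside but does not
#' gate the decision.
#'
#' @param values numeric vector, at least 3 values.
#' @param label outcome label.
#' @return an object of class `normality_result` with fields `outcome`,
#'   `ks_p`, `skewness`, `is_normal`.
#' @export
normality_screen <- function(values, label = "outcome") {
  values <- as.numeric(values)
  if (length(values) < 3) stop("need at least 3 values")
  n <- length(values)
  m <- mean(values); s <- stats::sd(values)
  g1 <- if (s == 0) 0 else mean((values - m)^3) / (mean((values - m)^2))^1.5
  skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
  ks_p <- if (n >= 5 && s > 0) {
    nortest::lillie.test(values)$p.value
  } else if (s > 0) {
    suppressWarnings(stats::ks.test(values, "pnorm", m, s)$p.value)
  } else NA_real_
  structure(list(outcome = label, ks_p = ks_p, skewness = skew,
                 is_normal = abs(skew) <= 1.0),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("<normality_result> %s: skewness %s (%s), KS p = %s\n",
              x$outcome, fmt_num(x$skewness, 3),
              if (x$is_normal) "normal" else "non-normal",
              if (is.na(x$ks_p)) "NA" else format.pval(x$ks_p, digits = 3)))
  invisible(x)
}

#' Batch two-group comparison table
#'
#' Runs [pooled_t_test()] (and Cohen's d) for every outcome of a two-group
#' table. Accepts either summary input — columns `outcome, group, n, mean,
#' sd` — or raw input — columns `group, outcome, value` (raw columns are
#' summarized first, so both paths give identical results for the same
#' sufficient statistics).
#'
#' @param data data frame in summary or raw layout (layout auto-detected).
#' @param group_order optional length-2 character giving which group is the
#'   minuend (`a`) and subtrahend (`b`); defaults to order of appearance.
#' @param welch use the Welch test instead of the pooled test.
#' @return data frame with one row per outcome (the fields of
#'   `comparison_result`).
#' @export
compare_table <- function(data, group_order = NULL, welch = FALSE) {
  stopifnot(is.data.frame(data))
  summary_mode <- all(c("outcome", "group", "n", "mean", "sd") %in% names(data))
  raw_mode <- all(c("outcome", "group", "value") %in% names(data))
  if (!summary_mode && !raw_mode)
    stop("data must have columns outcome/group/n/mean/sd or outcome/group/value")
  outcomes <- unique(data$outcome)
  if (is.null(group_order)) group_order <- unique(as.character(data$group))
  if (length(group_order) != 2) stop("exactly two groups are required")
  rows <- lapply(outcomes, function(oc) {
    d <- data[data$outcome == oc, , drop = FALSE]
    gs <- lapply(group_order, function(g) {
      dg <- d[as.character(d$group) == g, , drop = FALSE]
      if (nrow(dg) == 0)
        stop(sprintf("outcome '%s': missing group '%s'", oc, g))
      if (summary_mode) {
        group_summary(g, dg$n[1], dg$mean[1], dg$sd[1])
      } else {
        summarize_values(dg$value, g)
      }
    })
    as.data.frame(pooled_t_test(gs[[1]], gs[[2]], welch = welch, outcome = oc))
  })
  do.call(rbind, rows)
}

#' Reference two-group outcome table for a BMI-matched knee-OA cohort
#'
#' Printed group summaries (mean, SD, n = 23 per group) for the eleven
#' outcomes of a published cross-sectional comparison of people with and
#' without knee osteoarthritis matched by BMI, age and sex: demographics,
#' WOMAC subscales, performance tests, knee-extensor torque, and thigh
#' interMAT/intraMAT volumes. Useful as input to [compare_table()] and as a
#' reference point for cohort simulations.
#'
#' @return data frame with columns `outcome`, `group`
#'   (`affected`/`unaffected`), `n`, `mean`, `sd`.
#' @export
koa_reference_table <- function() {
  out <- c("age_y", "bmi_kg_m2", "womac_pain", "womac_function",
           "cst30_reps", "fpwt40_m_s", "sct12_s",
           "torque_norm_nm_kg100", "torque_nm",
           "intermat_cm3", "intramat_cm3")
  aff <- cbind(mean = c(61.9, 27.0, 8.0, 26.6, 9.9, 1.6, 17.5, 157.9, 118.8,
                        21.7, 9.9),
               sd = c(9.5, 2.5, 3.3, 11.7, 2.7, 0.3, 11.1, 45.1, 44.5,
                      9.9, 5.0))
  una <- cbind(mean = c(62.0, 26.7, 0.1, 1.8, 14.0, 1.9, 10.8, 206.0, 141.4,
                        18.7, 6.2),
               sd = c(9.8, 1.6, 0.3, 1.5, 2.2, 0.3, 2.1, 40.8, 37.8,
                      10.6, 3.5))
  data.frame(outcome = rep(out, 2),
             group = rep(c("affected", "unaffected"), each = length(out)),
             n = 23L,
             mean = c(aff[, "mean"], una[, "mean"]),
             sd = c(aff[, "sd"], una[, "sd"]),
             stringsAsFactors = FALSE)
}
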
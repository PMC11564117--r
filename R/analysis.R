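#' Quality-control filter on bead measurements
#'
#' A bead is excluded when the standard deviation of its line amplitudes is
#' greater than or equal to `ratio` times their mean (default `ratio = 0.5`:
#' SD at least half the mean marks uneven or artifactual rims). The boundary
#' is inclusive. Beads with no valid lines are excluded as unmeasurable, and
#' zero-signal beads (`mean = 0`, `sd = 0`) trip the rule by `0 >= 0` and are
#' recorded with reason `"zero_signal"`. Excluded beads are flagged for
#' optional human review, never corrected automatically.
#'
#' @param measurements list of `bead_measurement` (see [summarize_bead()]).
#' @param ratio SD-to-mean exclusion threshold, in `(0, 1]`.
#' @return list with `passed` and `excluded`, each a list of
#'   `bead_measurement` with `qc_pass`/`qc_reason` filled in.
#' @export
qc_filter <- function(measurements, ratio = 0.5) {
  if (ratio <= 0 || ratio > 1) stopf("qc ratio must be in (0, 1]")
  out <- lapply(measurements, function(m) {
    if (m$n_valid_lines == 0) {
      m$qc_pass <- FALSE; m$qc_reason <- "no_valid_lines"
    } else if (m$mean_amplitude == 0 && m$sd_amplitude == 0) {
      m$qc_pass <- FALSE; m$qc_reason <- "zero_signal"
    } else if (m$sd_amplitude >= ratio * m$mean_amplitude) {
      m$qc_pass <- FALSE; m$qc_reason <- "high_sd"
    } else {
      m$qc_pass <- TRUE; m$qc_reason <- "pass"
    }
    m
  })
  pass <- vapply(out, `[[`, logical(1), "qc_pass")
  list(passed = out[pass], excluded = out[!pass])
}

#' Normalize per-bead means to the control condition
#'
#' Divides every bead's mean amplitude by the arithmetic mean of the control
#' condition's (QC-passing) bead means, removing inter-experiment gain
#' differences. The control's normalized mean is exactly 1 by construction.
#'
#' @param condition_means named list: condition name -> numeric vector of
#'   QC-passing per-bead mean amplitudes.
#' @param control name of the control condition.
#' @return named list of normalized vectors, with the control average in
#'   attribute `control_mean`.
#' @export
normalize_to_control <- function(condition_means, control) {
  if (!control %in% names(condition_means))
    stopf("control condition '%s' not present", control)
  ctrl <- condition_means[[control]]
  if (length(ctrl) == 0)
    stopf("control condition '%s' has no QC-passing beads", control)
  ctrl_mean <- mean(ctrl)
  if (!is.finite(ctrl_mean) || ctrl_mean == 0)
    stopf("control condition '%s' has non-positive mean", control)
  out <- lapply(condition_means, function(v) v / ctrl_mean)
  attr(out, "control_mean") <- ctrl_mean
  out
}

#' Significance stars
#'
#' Star coding at the thresholds used throughout the assay's reporting:
#' `*` p < 0.05, `**` p < 0.005, `***` p < 0.001, `****` p < 0.0001,
#' otherwise `ns`.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
significance_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) NA_character_
    else if (x < 1e-4) "****"
    else if (x < 1e-3) "***"
    else if (x < 5e-3) "**"
    else if (x < 0.05) "*"
    else "ns"
  }, character(1))
}

# Two-sided Dunnett-adjusted p for observed statistic t0 among k comparisons
# sharing a control: 1 - P(max_j |T_j| < |t0|), T multivariate t with
# correlation lambda_i * lambda_j and error df. pmvt's quasi-Monte-Carlo
# integration runs under a fixed local RNG state so results are reproducible.
dunnett_p_adjust <- function(t0, lambda, df) {
  k <- length(lambda)
  if (!is.finite(t0)) return(if (is.na(t0)) NA_real_ else 0)
  if (k == 1) return(2 * pt(abs(t0), df, lower.tail = FALSE))
  corr <- outer(lambda, lambda)
  diag(corr) <- 1
  with_seed(20260918L, {
    pr <- mvtnorm::pmvt(lower = rep(-abs(t0), k), upper = rep(abs(t0), k),
                        corr = corr, df = as.integer(df),
                        algorithm = mvtnorm::GenzBretz(abseps = 1e-7,
                                                       maxpts = 100000L))
  })
  min(max(1 - as.numeric(pr), 0), 1)
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' Fits a one-way fixed-effects ANOVA across all groups and compares each
#' non-control group against the shared control with Dunnett's procedure:
#' statistics `t_i = (m_i - m_0) / (s * sqrt(1/n_i + 1/n_0))` with the pooled
#' error variance `s^2` (df `N - k`), adjusted two-sided via the multivariate
#' t distribution with correlation `sqrt(n_i n_j / ((n_i + n_0)(n_j + n_0)))`.
#'
#' @param groups named list of numeric vectors (e.g. normalized bead means),
#'   each of length at least 2; must include `control`.
#' @param control name of the control group.
#' @param alpha familywise significance level (reporting only).
#' @return an object of class `stats_report`: `test_name`, `group_sizes`,
#'   `statistic` (ANOVA F), `df`, `comparisons` (data frame: group,
#'   estimate, t, p_adj, stars), `control`, `alpha`.
#' @export
anova_dunnett <- function(groups, control, alpha = 0.05) {
  if (length(groups) < 2) stopf("need at least 2 groups")
  if (!control %in% names(groups)) stopf("control '%s' not among groups", control)
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2))
    stopf("every group needs n >= 2 (offending: %s)",
          paste(names(groups)[ns < 2], collapse = ", "))
  if (!all(vapply(groups, function(v) all(is.finite(v)), logical(1))))
    stopf("groups must contain only finite values")

  k <- length(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  sse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  ssb <- sum(ns * (means - sum(ns * means) / N)^2)
  df1 <- k - 1L; df2 <- N - k
  mse <- sse / df2
  f_stat <- if (mse > 0) (ssb / df1) / mse else if (ssb == 0) 0 else Inf

  trt <- setdiff(names(groups), control)
  n0 <- ns[[control]]
  lambda <- sqrt(ns[trt] / (ns[trt] + n0))
  se <- sqrt(mse * (1 / ns[trt] + 1 / n0))
  est <- means[trt] - means[[control]]
  t_obs <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf * sign(est)))
  p_adj <- vapply(seq_along(trt), function(i)
    dunnett_p_adjust(t_obs[i], lambda, df2), numeric(1))
  p_adj[t_obs == 0 & se == 0] <- 1  # degenerate all-equal input

  comparisons <- data.frame(group = trt, estimate = as.numeric(est),
                            t = as.numeric(t_obs), p_adj = p_adj,
                            stars = significance_stars(p_adj),
                            row.names = NULL)
  structure(list(test_name = "one-way ANOVA + Dunnett",
                 group_sizes = ns, statistic = f_stat,
                 df = c(df1 = df1, df2 = df2), comparisons = comparisons,
                 control = control, alpha = alpha),
            class = "stats_report")
}

#' Welch's two-sample t-test
#'
#' Two-tailed unpaired comparison with the Welch degrees-of-freedom
#' correction, reported with the same star coding as [anova_dunnett()].
#'
#' @param group_a,group_b numeric vectors, each n >= 2.
#' @param alpha significance level (reporting only).
#' @return a `stats_report` with a single comparison.
#' @export
welch_ttest <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stopf("both groups need n >= 2")
  if (!all(is.finite(c(group_a, group_b))))
    stopf("groups must contain only finite values")
  if (sd(group_a) == 0 && sd(group_b) == 0 && mean(group_a) == mean(group_b)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(group_a) +
                 length(group_b) - 2), p.value = 1,
               estimate = c(mean(group_a), mean(group_b)))
  } else {
    tt <- t.test(group_a, group_b, var.equal = FALSE)
  }
  comparisons <- data.frame(group = "b_vs_a",
                            estimate = unname(tt$estimate[1] - tt$estimate[2]),
                            t = unname(tt$statistic), p_adj = tt$p.value,
                            stars = significance_stars(tt$p.value),
                            row.names = NULL)
  structure(list(test_name = "Welch t-test",
                 group_sizes = c(a = length(group_a), b = length(group_b)),
                 statistic = unname(tt$statistic),
                 df = c(df = unname(tt$parameter)), comparisons = comparisons,
                 control = "a", alpha = alpha),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(x$test_name, "\n")
  cat("groups (n):", paste(sprintf("%s=%d", names(x$group_sizes),
                                   x$group_sizes), collapse = ", "), "\n")
  cat(sprintf("statistic = %.4g, df = %s\n", x$statistic,
              paste(x$df, collapse = ", ")))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}
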
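# Group statistics as declared in the study design: two-tailed Student's t
# (pooled variance) for two groups, one-way ANOVA with multiple-comparison
# post-hoc corrections for more, Pearson chi-squared on positive/negative
# counts with Wilson 95% CIs for proportions.

#' Compare group means
#'
#' Two groups: two-tailed Student's t test with pooled variance (Welch by
#' `var_equal = FALSE`). More than two: one-way ANOVA, followed by all-pairs
#' post-hoc comparisons (Tukey HSD by default; Bonferroni or Holm use
#' pairwise pooled-variance t tests with the corresponding adjustment).
#' Identical constant samples in every group give t = 0, p = 1 rather than
#' an error.
#'
#' @param values numeric vector of measurements
#' @param groups group label per measurement (>= 2 groups, each n >= 2)
#' @param posthoc `"tukey"`, `"bonferroni"` or `"holm"`
#' @param var_equal pool variances for the two-group t test?
#' @param conf_level confidence level for intervals
#' @return a `group_comparison` list: `test, statistic, df, p_value,
#'   estimates` (per-group mean, sd, n), `conf_int` (two-group case),
#'   `posthoc` (multi-group case)
#' @export
compare_means <- function(values, groups,
                          posthoc = c("tukey", "bonferroni", "holm"),
                          var_equal = TRUE, conf_level = 0.95) {
  posthoc <- match.arg(posthoc)
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("every group needs n >= 2")
  est <- data.frame(group = levels(groups),
                    mean = as.vector(tapply(values, groups, mean)),
                    sd = as.vector(tapply(values, groups, stats::sd)),
                    n = as.vector(table(groups)))
  if (nlevels(groups) == 2L) {
    v1 <- values[groups == levels(groups)[1]]
    v2 <- values[groups == levels(groups)[2]]
    if (stats::sd(v1) == 0 && stats::sd(v2) == 0 && mean(v1) == mean(v2)) {
      res <- list(test = "student_t_two_tailed", statistic = 0,
                  df = length(values) - 2L, p_value = 1, estimates = est,
                  conf_int = c(0, 0))
    } else {
      tt <- stats::t.test(v1, v2, var.equal = var_equal,
                          conf.level = conf_level)
      res <- list(test = if (var_equal) "student_t_two_tailed" else "welch_t",
                  statistic = unname(tt$statistic), df = unname(tt$parameter),
                  p_value = tt$p.value, estimates = est,
                  conf_int = unname(tt$conf.int))
    }
  } else {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    ph <- if (posthoc == "tukey") {
      tk <- stats::TukeyHSD(fit, conf.level = conf_level)$groups
      data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                 lwr = tk[, "lwr"], upr = tk[, "upr"],
                 p_adj = tk[, "p adj"], row.names = NULL)
    } else {
      pw <- stats::pairwise.t.test(values, groups, p.adjust.method = posthoc,
                                   pool.sd = TRUE)
      m <- pw$p.value
      idx <- which(!is.na(m), arr.ind = TRUE)
      data.frame(comparison = paste(rownames(m)[idx[, 1]],
                                    colnames(m)[idx[, 2]], sep = "-"),
                 diff = NA_real_, lwr = NA_real_, upr = NA_real_,
                 p_adj = m[idx], row.names = NULL)
    }
    res <- list(test = "anova_posthoc",
                statistic = an[["F value"]][1], df = an[["Df"]],
                p_value = an[["Pr(>F)"]][1], estimates = est, posthoc = ph)
  }
  structure(res, class = "group_comparison")
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x successes
#' @param n trials
#' @param conf_level confidence level
#' @return length-2 vector `c(lower, upper)`
#' @export
wilson_ci <- function(x, n, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, centre - half), min(1, centre + half))
}

#' Compare positive-cell proportions between groups
#'
#' Pearson chi-squared test on the groups x {positive, negative} count table
#' (no continuity correction by default), with per-group proportions and
#' Wilson 95% confidence intervals.
#'
#' @param positives,totals integer vectors, one entry per group
#' @param groups optional group names
#' @param correct apply Yates continuity correction?
#' @param conf_level confidence level for the Wilson intervals
#' @return a `group_comparison` list with `estimates` columns `group,
#'   positive, total, proportion, ci_lower, ci_upper`
#' @export
compare_proportions <- function(positives, totals, groups = NULL,
                                correct = FALSE, conf_level = 0.95) {
  if (any(totals < 1)) stop("every group needs a total of at least 1")
  stopifnot(length(positives) == length(totals), all(positives <= totals),
            all(positives >= 0))
  groups <- groups %||% paste0("group", seq_along(totals))
  tab <- cbind(positive = positives, negative = totals - positives)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  cis <- t(vapply(seq_along(totals), function(i)
    wilson_ci(positives[i], totals[i], conf_level), numeric(2)))
  est <- data.frame(group = groups, positive = positives, total = totals,
                    proportion = positives / totals,
                    ci_lower = cis[, 1], ci_upper = cis[, 2])
  structure(list(test = "chi_squared", statistic = unname(chi$statistic),
                 df = unname(chi$parameter), p_value = chi$p.value,
                 estimates = est),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<%s>  statistic = %.4g, df = %s, p = %.4g\n", x$test,
              x$statistic, paste(x$df, collapse = "/"), x$p_value))
  print(x$estimates)
  invisible(x)
}
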
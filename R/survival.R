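# Kaplan-Meier survival analysis with log-rank (Mantel-Cox) group tests and
# lifespan-change summaries (median and maximum lifespan relative to a
# control group), built on the survival package's product-limit estimator.

#' Kaplan-Meier survival analysis
#'
#' Fits the product-limit estimator per group, extracts step curves, median
#' survival (smallest time with `S(t) <= 0.5`; reported as `NA` / not
#' reached when every observation is censored) and maximum lifespan (the
#' largest event time), reports the percent change of both versus the
#' control group, and performs pairwise log-rank (Mantel-Cox) tests of each
#' group against control.
#'
#' @param table data.frame `animal_id, group, day, event` (`event` 1 = death,
#'   0 = censored; `day > 0`)
#' @param control control group name (baseline of the percent changes)
#' @return a `survival_report`: list with `curves` (per group: `time, surv`
#'   step function, `median`, `max_lifespan`), `lifespan` (data.frame
#'   `group, median, max_lifespan, pct_change_median, pct_change_max`) and
#'   `logrank` (data.frame `group, chisq, df, p_value` vs control)
#' @export
survival_analysis <- function(table, control) {
  stopifnot(all(c("group", "day", "event") %in% names(table)),
            all(table$day > 0), all(table$event %in% 0:1))
  if (!control %in% table$group)
    stop("control group '", control, "' not present")
  groups <- unique(table$group)
  fit <- survival::survfit(survival::Surv(day, event) ~ group, data = table)
  strata_names <- if (is.null(fit$strata)) stats::setNames(length(fit$time),
    paste0("group=", groups[1])) else fit$strata
  idx <- rep(names(strata_names), strata_names)
  curves <- list()
  for (g in groups) {
    sel <- idx == paste0("group=", g)
    tm <- fit$time[sel]; sv <- fit$surv[sel]
    events <- table$day[table$group == g & table$event == 1]
    med <- if (any(sv <= 0.5)) min(tm[sv <= 0.5]) else NA_real_
    curves[[g]] <- list(group = g,
                        time = c(0, tm), surv = c(1, sv),
                        median = med,
                        max_lifespan = if (length(events)) max(events)
                                       else NA_real_)
  }
  ls_df <- data.frame(
    group = groups,
    median = vapply(groups, function(g) curves[[g]]$median, numeric(1)),
    max_lifespan = vapply(groups, function(g) curves[[g]]$max_lifespan,
                          numeric(1)))
  m0 <- ls_df$median[ls_df$group == control]
  x0 <- ls_df$max_lifespan[ls_df$group == control]
  ls_df$pct_change_median <- 100 * (ls_df$median - m0) / m0
  ls_df$pct_change_max <- 100 * (ls_df$max_lifespan - x0) / x0

  others <- setdiff(groups, control)
  lr <- do.call(rbind, lapply(others, function(g) {
    sub <- table[table$group %in% c(control, g), ]
    # degenerate cohorts (e.g. every animal dying on the same day in both
    # groups) have zero log-rank variance; report NA rather than fail
    sd <- tryCatch(
      survival::survdiff(survival::Surv(day, event) ~ group, data = sub),
      error = function(e) NULL)
    if (is.null(sd))
      return(data.frame(group = g, chisq = NA_real_, df = NA_integer_,
                        p_value = NA_real_))
    data.frame(group = g, chisq = sd$chisq, df = length(sd$n) - 1,
               p_value = stats::pchisq(sd$chisq, length(sd$n) - 1,
                                       lower.tail = FALSE))
  }))
  structure(list(curves = curves, lifespan = ls_df, logrank = lr,
                 control = control),
            class = "survival_report")
}

#' @export
print.survival_report <- function(x, ...) {
  cat("Kaplan-Meier survival analysis (control: ", x$control, ")\n", sep = "")
  print(x$lifespan)
  if (!is.null(x$logrank) && nrow(x$logrank)) {
    cat("log-rank (Mantel-Cox) vs control:\n")
    print(x$logrank)
  }
  invisible(x)
}
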
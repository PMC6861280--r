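# Relative quantification of qPCR Ct tables by the comparative-Ct method:
# delta-Ct against a reference gene (Rplp0 for mRNA/dilncRNA assays, mir17
# for small-RNA assays), fold change E^-(ddCt) against the calibrator-group
# mean, amplification efficiency E = 2 by default.

#' Collapse technical replicates of a Ct table
#'
#' Reactions are run in triplicate; this computes the mean and sd Ct per
#' (sample, target) reaction and flags reactions whose replicate range
#' exceeds `max_spread` cycles. Undetermined Cts (`NA`) are dropped by
#' default or imputed at `impute_cycle`; a reaction with no determined
#' replicate is kept as a missing-value record.
#'
#' @param table data.frame with columns `sample_id, group, target, replicate,
#'   ct` (extra columns such as `strand`/`assay_class` are carried through)
#' @param max_spread maximum admissible replicate range (cycles)
#' @param undetermined `"drop"` or `"impute"`
#' @param impute_cycle Ct assigned to undetermined reactions when imputing
#' @return data.frame `sample_id, group, target, ..., ct_mean, ct_sd,
#'   n_replicates, flagged`
#' @export
collapse_replicates <- function(table, max_spread = 0.5,
                                undetermined = c("drop", "impute"),
                                impute_cycle = 40) {
  undetermined <- match.arg(undetermined)
  stopifnot(all(c("sample_id", "target", "ct") %in% names(table)))
  if (undetermined == "impute") table$ct[is.na(table$ct)] <- impute_cycle
  meta_cols <- intersect(c("group", "strand", "assay_class"), names(table))
  key <- interaction(table$sample_id, table$target, drop = TRUE)
  rows <- lapply(split(table, key), function(d) {
    ct <- d$ct[!is.na(d$ct)]
    out <- d[1, c("sample_id", "target", meta_cols), drop = FALSE]
    out$ct_mean <- if (length(ct)) mean(ct) else NA_real_
    out$ct_sd <- if (length(ct) > 1) stats::sd(ct) else 0
    out$n_replicates <- length(ct)
    out$flagged <- length(ct) > 1 && diff(range(ct)) > max_spread
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative expression by the comparative-Ct method
#'
#' Per sample, `dCt = Ct(target) - Ct(reference)`; the fold change versus
#' the calibrator group is `E^-(dCt - mean dCt of the calibrator group)`,
#' computed per target, so the calibrator group's mean fold is 1 by
#' construction. Samples missing the reference gene are excluded with a
#' warning.
#'
#' @param collapsed output of [collapse_replicates()]
#' @param reference reference gene id (e.g. `"Rplp0"`, or `"mir17"` for
#'   small-RNA assays)
#' @param calibrator calibrator group name
#' @param efficiency amplification efficiency base (2 = perfect doubling)
#' @return data.frame `sample_id, group, target, strand, dct, fold,
#'   reference`
#' @export
relative_expression <- function(collapsed, reference, calibrator,
                                efficiency = 2) {
  stopifnot(all(c("sample_id", "group", "target", "ct_mean") %in%
                  names(collapsed)))
  ref <- collapsed[collapsed$target == reference & !is.na(collapsed$ct_mean), ]
  if (!nrow(ref)) stop("reference gene '", reference, "' not found")
  tgt <- collapsed[collapsed$target != reference & !is.na(collapsed$ct_mean), ]
  ref_ct <- stats::setNames(ref$ct_mean, ref$sample_id)
  missing_ref <- setdiff(unique(tgt$sample_id), names(ref_ct))
  if (length(missing_ref)) {
    warning("excluding sample(s) without reference measurements: ",
            paste(missing_ref, collapse = ", "))
    tgt <- tgt[!tgt$sample_id %in% missing_ref, ]
  }
  tgt$dct <- tgt$ct_mean - ref_ct[tgt$sample_id]
  if (!any(tgt$group == calibrator))
    stop("calibrator group '", calibrator, "' not present")
  out <- do.call(rbind, lapply(split(tgt, tgt$target), function(d) {
    cal_mean <- mean(d$dct[d$group == calibrator])
    d$fold <- efficiency^-(d$dct - cal_mean)
    d
  }))
  out$reference <- reference
  keep <- intersect(c("sample_id", "group", "target", "strand", "assay_class",
                      "dct", "fold", "reference"), names(out))
  out <- out[, keep]
  rownames(out) <- NULL
  out
}

#' Per-group relative-expression summary
#'
#' Mean fold change, sd and n per (group, target, strand) — the quantities
#' plotted as bar height and s.d. error bars.
#'
#' @param expr output of [relative_expression()]
#' @return data.frame `group, target, strand, mean_fold, sd_fold, n`
#' @export
group_summary <- function(expr) {
  stopifnot(nrow(expr) >= 1)
  strand <- if ("strand" %in% names(expr)) expr$strand else "none"
  key <- interaction(expr$group, expr$target, strand, drop = TRUE)
  rows <- lapply(split(expr, key), function(d) {
    data.frame(group = d$group[1], target = d$target[1],
               strand = if ("strand" %in% names(d)) d$strand[1] else "none",
               mean_fold = mean(d$fold),
               sd_fold = if (nrow(d) > 1) stats::sd(d$fold) else 0,
               n = nrow(d))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
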
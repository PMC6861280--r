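#!/usr/bin/env Rscript
# Relative quantification of the simulated Ct table: replicate collapse,
# delta-delta-Ct folds against the lamin A calibrator (Rplp0 reference),
# per-group summaries and two-tailed Student's t per target.

suppressMessages(library(telophen))
if (!file.exists("results/ct_table.csv"))
  stop("run analysis/01_simulate.R first")

ct <- read.csv("results/ct_table.csv")
col <- collapse_replicates(ct, max_spread = 0.5)
if (any(col$flagged))
  cat("flagged", sum(col$flagged), "reactions with replicate spread > 0.5\n")

expr <- relative_expression(col, reference = "Rplp0", calibrator = "laminA")
write.csv(expr, "results/qpcr_folds.csv", row.names = FALSE)
gs <- group_summary(expr)
write.csv(gs, "results/qpcr_summary.csv", row.names = FALSE)

cat("Fold change vs lamin A (mean +/- sd):\n")
print(gs)
truth <- read.csv("results/ct_truth.csv")
for (tg in unique(expr$target)) {
  d <- expr[expr$target == tg, ]
  cmp <- compare_means(d$fold, d$group)
  tf <- truth$true_fold[truth$target == tg & truth$group == "progerin"]
  cat(sprintf("%-9s true fold %.1f  estimated %.2f  t = %.2f, p = %.3g\n",
              tg, tf, mean(d$fold[d$group == "progerin"]),
              cmp$statistic, cmp$p_value))
}
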
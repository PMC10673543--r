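#!/usr/bin/env Rscript

# Step 3: cohort statistics.
#
# (a) Recomputes the three published summary comparisons (tumor weight and
#     week-1 / week-2 pHe) from their printed mean +- SD and n, with the
#     pooled unpaired Student t.
# (b) Tests the simulated cohort: recovered per-animal mean pHe and acidity
#     score between arms; tumor-volume trajectories via two-way ANOVA with
#     Bonferroni-adjusted per-day contrasts; Shapiro-Wilk normality checks;
#     Kaplan-Meier survival with the log-rank test.
#
# Output: results/stats/printed_comparisons.tsv, phe_comparison.tsv,
#         volume_{volume,report}.{tsv,txt}
#
# Run from the repository root:  Rscript analysis/03_stats.R

suppressPackageStartupMessages(library(acidocest))

procdir <- "results/proc"; simdir <- "results/sim"
outdir <- "results/stats"
if (!file.exists(file.path(procdir, "summary.tsv")))
  stop("run analysis/02_process.R first")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

message("== published summary comparisons (printed mean +- SD, n = 6) ==")
printed <- data.frame(
  quantity = c("tumor_weight_g", "pHe_week1", "pHe_week2"),
  mean_ctrl = c(1.16, 6.83, 6.89), sd_ctrl = c(0.15, 0.02, 0.04),
  mean_trt = c(0.74, 6.76, 6.77), sd_trt = c(0.09, 0.03, 0.04))
printed$t <- printed$p <- NA_real_
for (i in seq_len(nrow(printed))) {
  tt <- t_test_from_summary(
    summary_stat("control", printed$mean_ctrl[i], printed$sd_ctrl[i], 6),
    summary_stat("treated", printed$mean_trt[i], printed$sd_trt[i], 6))
  printed$t[i] <- tt$t; printed$p[i] <- tt$p
  message(sprintf("  %-14s t = %5.2f (df 10), p = %.2e  %s",
                  printed$quantity[i], tt$t, tt$p,
                  if (tt$p < 0.001) "[p < 0.001]" else ""))
}
utils::write.table(printed, file.path(outdir, "printed_comparisons.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)

message("== simulated cohort: recovered pHe and acidity by arm ==")
summ <- utils::read.table(file.path(procdir, "summary.tsv"), header = TRUE,
                          sep = "\t")
tab <- read_cohort_tsv(file.path(simdir, "cohort.tsv"))
grp <- tab$group[match(summ$animal_id, tab$animal_id)]
rows <- list()
for (qty in c("mean_pHe", "acidity_score")) {
  s <- split(summ[[qty]], grp)
  sw_p <- vapply(s, function(x) shapiro_wilk(x)$p, 0)
  tt <- t_test_from_summary(
    summary_stat("control", mean(s$control), sd(s$control), length(s$control)),
    summary_stat("treated", mean(s$treated), sd(s$treated), length(s$treated)))
  rows[[qty]] <- data.frame(
    quantity = qty,
    control = sprintf("%.3f +- %.3f", mean(s$control), sd(s$control)),
    treated = sprintf("%.3f +- %.3f", mean(s$treated), sd(s$treated)),
    shapiro_min_p = min(sw_p), t = tt$t, p = tt$p)
  message(sprintf("  %-14s control %s, treated %s, t = %.2f, p = %.2e",
                  qty, rows[[qty]]$control, rows[[qty]]$treated, tt$t, tt$p))
}
utils::write.table(do.call(rbind, rows),
                   file.path(outdir, "phe_comparison.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)

message("== tumor volume + survival ==")
rep <- cohort_report(tab, out_prefix = file.path(outdir, "volume"),
                     longitudinal = "two_way_anova")
last <- max(rep$volume$summaries$day)
v_last <- rep$volume$summaries[rep$volume$summaries$day == last, ]
message(sprintf("  day %d volume: %s", last,
                paste(sprintf("%s %.0f +- %.0f mm^3", v_last$group,
                              v_last$mean, v_last$sd), collapse = ", ")))
message(sprintf("  survival log-rank p = %.4g%s", rep$survival$logrank_p,
                if (rep$survival$unstable) " (unstable)" else ""))
message("Done: reports under ", outdir)
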
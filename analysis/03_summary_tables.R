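#!/usr/bin/env Rscript

# Step 3: condense the cohort results into plain-text summary tables.
# Requires step 2 to have been run.
#
# Reads:  results/cohort/subject_metrics.csv
# Writes: results/cohort/summary.md

suppressPackageStartupMessages(library(nirscoupling))

metrics_path <- file.path("results", "cohort", "subject_metrics.csv")
if (!file.exists(metrics_path)) {
  stop("run analysis/02_cohort_pipeline.R first", call. = FALSE)
}
metrics <- as.data.frame(data.table::fread(metrics_path))

vars <- c("mean_toi", "cs_lpfc_vlf", "cs_lpfc_lf", "cs_rpfc_vlf", "cs_rpfc_lf")
lines <- c("# Cohort summary", "",
           sprintf("%d subjects; groups: %s", nrow(metrics),
                   paste(sprintf("%s n=%d", names(table(metrics$group)),
                                 table(metrics$group)), collapse = ", ")),
           "", "## Group means (SD)", "",
           paste0("| variable | ", paste(c("NC", "MCI", "CI"), collapse = " | "), " |"),
           "|---|---|---|---|")
for (v in vars) {
  cells <- vapply(c("NC", "MCI", "CI"), function(g) {
    x <- metrics[[v]][metrics$group == g]
    sprintf("%.4g (%.2g)", mean(x), sd(x))
  }, character(1))
  lines <- c(lines, paste0("| ", v, " | ", paste(cells, collapse = " | "), " |"))
}

lines <- c(lines, "", "## ANOVA with Bonferroni pairwise tests", "")
rep <- group_report(metrics, n_boot = 2000, seed = 20260)
for (v in vars) {
  a <- rep$variables[[v]]$anova
  if (is.character(a)) { lines <- c(lines, sprintf("- %s: %s", v, a)); next }
  pw <- paste(sprintf("%s p=%.3g%s", a$pairwise$comparison, a$pairwise$p,
                      ifelse(a$pairwise$significant, " *", "")),
              collapse = "; ")
  lines <- c(lines, sprintf("- %s: F=%.2f, p=%.3g; %s", v, a$anova_f,
                            a$anova_p, pw))
}

lines <- c(lines, "", "## Correlation with MoCA", "")
for (v in vars) {
  ct <- rep$correlations[[v]]
  if (is.character(ct)) next
  lines <- c(lines, sprintf("- %s: r=%.3f, p=%.3g", v, ct$r, ct$p))
}

lines <- c(lines, "", "## ROC (NC vs MCI)", "")
for (v in names(rep$roc)) {
  r <- rep$roc[[v]]
  lines <- c(lines,
             sprintf("- %s: AUC=%.2f (95%% CI %.2f-%.2f), threshold=%.4g, sens=%.0f%%, spec=%.0f%%",
                     v, r$auc, r$ci[1], r$ci[2], r$threshold,
                     100 * r$sensitivity, 100 * r$specificity))
}

writeLines(lines, file.path("results", "cohort", "summary.md"))
cat(paste(lines, collapse = "\n"), "\n")
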
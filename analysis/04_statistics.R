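#!/usr/bin/env Rscript
# Stage 4 - the statistical battery.
#
# On the harmonized tables: (a) the inter-vs-intra conservation correlations
# per group, (b) agreement between the interhemispheric measures, (c) the
# clinical battery (measures and ratios vs GMF/WMF/LVF/EDSS/SDMT in MS),
# each Bonferroni-corrected within its family; and the three-group
# (HC / low / high EDSS and SDMT) ANOVAs with Tukey HSD post hoc tests on
# age/sex-residualized values. Also checks the planted coupling against the
# generator's latent ground truth.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "config.R"))

metrics <- read.csv(file.path(results_dir, "harmonized_metrics.csv"))
records <- read.csv(file.path(results_dir, "harmonized_records.csv"))
gt <- jsonlite::read_json(file.path(results_dir, "ground_truth.json"),
                          simplifyVector = TRUE)

battery <- run_correlation_battery(metrics, records)
write.csv(battery, file.path(results_dir, "correlations.csv"),
          row.names = FALSE)

cat("== conservation of inter/intra connectivity (age+sex partialled) ==\n")
cons <- battery[battery$family == "inter_vs_intra", ]
for (i in seq_len(nrow(cons))) {
  cat(sprintf("  %-42s r=%+.3f  p_corr=%.2g\n", cons$pair[i], cons$r[i],
              cons$p_corrected[i]))
}

est <- partial_correlation(metrics$commissural_ratio, metrics$eff_mean,
                           records[, c("age", "sex")])
oracle <- cor(gt$subjects$p_inter_bio, gt$subjects$intra_strength)
cat(sprintf("\nplanted coupling: estimated r=%+.3f vs latent oracle r=%+.3f\n",
            est$r, oracle))

cat("\n== clinical battery (MS, Bonferroni m=40) ==\n")
clin <- battery[battery$family == "clinical" & battery$p_corrected < 0.05, ]
for (i in seq_len(nrow(clin))) {
  cat(sprintf("  %-42s r=%+.3f  p_corr=%.2g\n", clin$pair[i], clin$r[i],
              clin$p_corrected[i]))
}

cmp <- run_group_comparisons(metrics, records, study_config)
write.csv(cmp$anova, file.path(results_dir, "anova.csv"), row.names = FALSE)
write.csv(cmp$tukey, file.path(results_dir, "tukey.csv"), row.names = FALSE)

cat("\n== three-group comparisons (corrected p < 0.05) ==\n")
sig <- cmp$anova[cmp$anova$p_corrected < 0.05, ]
cat(sprintf("  %d of %d measure x split ANOVAs significant\n", nrow(sig),
            nrow(cmp$anova)))
for (split in unique(sig$split)) {
  rows <- sig[sig$split == split, ]
  cat(sprintf("  %s: %s\n", split, paste(rows$measure, collapse = ", ")))
}
cat("\nfull tables in", results_dir, "\n")
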
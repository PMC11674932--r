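#!/usr/bin/env Rscript
# Stage 2 - hemispheric connectivity measures.
#
# Regenerates the cohort connectomes deterministically from the stage-1
# seed, then runs the per-subject measurement chain: length-normalize the
# streamline weights, restrict to the 60 cortical regions, and compute the
# interhemispheric (commissural ratio, CC area ratio) and intrahemispheric
# (per-hemisphere mean shortest path length and efficiency on the
# inverse-weight distance graph) measures plus the four inter/intra ratios.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(), value = TRUE)[1])), "config.R"))

cohort <- generate_cohort(study_config$cohort)
metrics <- cohort_metrics(cohort$connectomes, cohort$records,
                          cc_exponent = study_config$cc_exponent,
                          midline = study_config$midline)
write.csv(metrics, file.path(results_dir, "metrics.csv"), row.names = FALSE)

cat(sprintf("measured %d subjects\n", nrow(metrics)))
for (v in c("commissural_ratio", "cc_ratio", "spl_mean", "eff_mean")) {
  cat(sprintf("  %-18s mean %.4g  sd %.4g\n", v, mean(metrics[[v]]),
              sd(metrics[[v]])))
}
ms <- cohort$records$diagnosis == "MS"
cat(sprintf("commissural ratio HC %.4f vs MS %.4f (raw, pre-harmonization)\n",
            mean(metrics$commissural_ratio[!ms]),
            mean(metrics$commissural_ratio[ms])))
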
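# Shared settings for the numbered analysis drivers.
# The cohort is regenerated deterministically from this seed at each stage
# that needs connectome matrices, so the run directory stays light.

library(hemiconn)

analysis_seed <- 20260923 %% 99991
results_dir <- "results"
figures_dir <- file.path(results_dir, "figures")

study_config <- pipeline_config(
  cohort = cohort_config(seed = analysis_seed)  # 697 subjects, 7 centers
)

dir.create(figures_dir, recursive = TRUE, showWarnings = FALSE)
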
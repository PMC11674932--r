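# hemiconn

Hemispheric structural-connectivity conservation analysis for multi-center
diffusion-MRI cohorts, with a fully synthetic study emulating a 7-center
multiple-sclerosis (MS) dataset.

Mammalian brains show a *conservation principle* of structural connectivity:
across individuals, interhemispheric and intrahemispheric connectivity are
inversely related — brains with a larger share of commissural (hemisphere-
crossing) connections tend to have weaker within-hemisphere networks, and
vice versa. `hemiconn` implements the full analysis needed to study this
principle, and how a disease such as MS interacts with it, in a multicenter
setting:

* **Connectome processing** — from a symmetric SIFT2-style streamline-weight
  matrix `W` and fiber-length matrix `L` over a labeled parcellation (60
  cortical regions, 30 per hemisphere, plus subcortical regions):
  length-normalize (`W_ij / L_ij`), restrict to cortical regions, and build
  the inverse-weight distance graph `d(i,j) = 1 / W_ij`.
* **Interhemispheric measures** — the commissural ratio

      CR = (sum of weight crossing hemispheres) / (total weight),

  and the volumetric corpus-callosum area ratio

      CCratio = CC_area / BrainVol^(2/3)

  (the 2/3 exponent makes the quantity an area-over-area ratio; it is an
  argument).
* **Intrahemispheric measures** — per-hemisphere mean shortest path length
  and efficiency on the distance graph, averaged over hemispheres:

      SPL = sum_{i<j} d(i,j) / (N(N-1)/2),
      Eff = sum_{i<j} 1/d(i,j) / (N(N-1)/2),

  with unreachable pairs excluded from SPL (and counted) and contributing 0
  to efficiency; plus the four inter/intra ratios (CR, CCratio) x (SPL, Eff).
* **Harmonization** — a parametric empirical-Bayes location/scale batch
  correction (ComBat) across acquisition centers with age, sex and diagnosis
  as preserved covariates, an explicit fit/apply split, JSON model
  serialization, and a PCA center-separation diagnostic.
* **Statistics** — covariate residualization, partial correlations with
  Bonferroni correction by analysis family, clinical group splits
  (EDSS cutoff 3, SDMT cutoff 40), and three-group one-way ANOVA with Tukey
  HSD post hoc tests.
* **Synthetic cohort generator** — no public data accompany the analysis
  this package implements, so the generator is a first-class, tested module.
  It draws multi-center cohorts of connectomes plus subject records with a
  *planted* inter/intra coupling, per-center batch effects, and disease
  effects on interhemispheric connectivity, white-matter fraction, lesion
  volume fraction, EDSS and SDMT. The generative model (a logistic
  streamline-budget model; see the methods vignette) is this package's own
  construction, and its planted parameters are exposed as ground truth so
  every downstream stage can be validated against what was simulated.

## Worked example

```r
library(hemiconn)

cfg <- cohort_config(n_subjects = 697, seed = 42)   # 7 centers, ~70% MS
coh <- generate_cohort(cfg)
met <- cohort_metrics(coh$connectomes, coh$records) # per-subject measures
harm <- harmonize_cohort(met, coh$records)          # ComBat across centers

partial_correlation(harm$metrics$commissural_ratio,
                    harm$metrics$eff_mean,
                    harm$records[, c("age", "sex")])
```

The analysis drivers under `analysis/` run the whole study in order and
narrate what they find:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort + ground truth
Rscript analysis/02_compute_metrics.R   # hemispheric measures
Rscript analysis/03_harmonize.R         # ComBat + PCA diagnostic
Rscript analysis/04_statistics.R        # correlation battery + ANOVAs
```

On the default seeded study (697 subjects) stage 4 prints, among others:

```
== conservation of inter/intra connectivity (age+sex partialled) ==
  commissural_ratio vs spl_mean | HC         r=+0.385  p_corr=2.4e-07
  commissural_ratio vs eff_mean | HC         r=-0.385  p_corr=2.3e-07
  commissural_ratio vs spl_mean | MS         r=+0.360  p_corr=8.9e-16
  commissural_ratio vs eff_mean | MS         r=-0.367  p_corr=2e-16

planted coupling: estimated r=-0.392 vs latent oracle r=-0.379
```

Read: in both groups a higher commissural share goes with a *longer* mean
shortest path (weaker intrahemispheric connectivity) and *lower* efficiency
— the inverse inter/intra relationship — and the strength estimated from the
measured connectomes agrees with the correlation planted in the generator's
latent variables. Stage 3 reports the center-separation statistic of the
first principal component collapsing (here 17.6 before ComBat to 0.2 after),
and `results/` holds the tidy CSV tables behind every printed line.

Equivalent single-call orchestration, with logging, an auditable report and
byte-identical reruns under a fixed seed:

```r
run_pipeline(pipeline_config(cohort = cohort_config(seed = 42)), "results/run")
```

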
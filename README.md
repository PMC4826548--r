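# heteromiR

Heterogeneity-aware microRNA biomarker discovery for multifocal tumors.

## The problem

Hepatocellular carcinoma (HCC) frequently presents as several distinct tumor
foci in one liver, and those foci can be clonally unrelated, with very
different expression profiles. A prognostic biomarker built from one biopsy
per patient — or from a patient-level average — can miss the focus that
actually drives recurrence. `heteromiR` is for biostatisticians and
computational biologists building recurrence biomarkers from cohorts in which
each patient contributes one or more tumor samples (e.g. microRNA microarray
profiles of transplant explants).

The package works sample-first and only then aggregates to patients:

1. **Sample subgroup discovery.** Two-group k-means (Lloyd, Euclidean, best
   of `n_init` restarts) on the unscaled log2 expression matrix. The cluster
   enriched for samples from recurrent patients is oriented as *cluster 1*.
   Per-sample distance diagnostics are summarized as an M/A pair,

   M = d2 − d1,  A = (d1 + d2) / 2,

   where d1, d2 are the distances to the two oriented centers; M ≥ 0 exactly
   for cluster-1 samples.
2. **Patient grouping.** Each patient becomes `C1_ONLY`, `C2_ONLY` or
   `MIXED` (samples in both clusters) — the within-patient heterogeneity
   construct.
3. **Patient-disjoint training.** POOR = samples of recurrent `C1_ONLY`
   patients; GOOD = samples of non-recurrent `C2_ONLY` patients; everything
   else (notably all samples of `MIXED` patients) is held out. No patient can
   span the train/test boundary.
4. **Feature selection.** Each feature is discretized into its training
   quartile intervals [min,Q1), [Q1,Q2), [Q2,Q3), [Q3,∞) and ranked by the
   plug-in mutual information with the class label,

   I(X;Y) = Σ_y Σ_x p(x,y) log( p(x,y) / (p(x) p(y)) ),

   in nats (bits available); the top k (default 5) features form the panel.
5. **Biomarker classification.** Nearest class-center calls per sample over
   the panel; patients are POOR / MIXED / GOOD by the all/all/else rule.
   Gaussian naive Bayes and a radial-kernel SVM (cost 1000) from `e1071`
   serve as reference classifiers.
6. **Survival evaluation.** Kaplan-Meier curves, multi-group log-rank tests
   and Cox proportional-hazards models (Efron ties, Wald CIs) over the
   patient groups, optionally combined with Milan transplant-criteria status
   (within-Milan patients are never subdivided by expression).
7. **Min/max baseline.** The earlier patient-level summarization — per
   patient, the minimum and maximum of each panel feature across samples —
   clustered and evaluated the same way, for side-by-side hazard-ratio
   comparison.

A synthetic multifocal-cohort generator (`simulate_cohort()`) with planted
marker features, latent prognosis states, exponential recurrence hazards and
administrative censoring provides ground truth for every stage.

## Worked example

```r
library(heteromiR)

cfg <- sim_config(n_patients = 89, marker_effect = 6, seed = 42)
sim <- simulate_cohort(cfg)
s2p <- setNames(sim$samples$patient_id, sim$samples$sample_id)
rec <- setNames(sim$patients$recurrence, sim$patients$patient_id)

fit    <- fit_two_means(sim$expr, n_init = 25, seed = 42)
model  <- orient_clusters(fit, sim$expr, s2p, rec)
groups <- group_patients(model$assignment, s2p)
attr(groups, "group_counts")
#> C1_ONLY C2_ONLY   MIXED
#>      16      64       9

training <- build_training_labels(groups, model$assignment, s2p, rec)
training
#> mir_training: 26 POOR + 118 GOOD training samples, 44 test samples (pure-patient rule)

labs   <- setNames(training$train$class, training$train$sample_id)
scores <- mi_scores(sim$expr[training$train$sample_id, ], labs)
sel    <- rank_and_select(scores, k = 5)
head(scores, 6)
#>   feature_id    mi rank degenerate
#> 1   mir_0063 0.325    1      FALSE
#> 2   mir_0124 0.325    1      FALSE
#> ...
#> 6   mir_0844 0.062    2      FALSE

bm     <- fit_biomarker(sim$expr, training, sel)
pcalls <- classify_patients(assign_samples(bm, sim$expr), s2p)
table(pcalls)
#>  GOOD MIXED  POOR
#>    64     9    16

strata <- build_strata(groups, scheme = "cluster")
idx <- match(groups$patient_id, sim$patients$patient_id)
logrank_test(sim$patients$time_months[idx], sim$patients$event[idx],
             strata[groups$patient_id])
#> log-rank: chisq = 102 on 2 df, p = 7.2e-23 (3 groups)

cox_fit(sim$patients$time_months[idx], sim$patients$event[idx],
        cbind(poor_like = as.numeric(strata[groups$patient_id] != "C2_ONLY")))
#>        term coef   hr ci_low ci_high    se  p_value
#> 1 poor_like  3.2 24.5   10.4    57.5 0.436 2.34e-13
```

The five selected features are exactly the generator's planted markers; the
16 + 9 patients carrying at least one poor-prognosis sample recur at roughly
25 times the hazard of the purely good-prognosis patients in this simulation.
The patient-level classification from the 5-feature panel reproduces the
full-feature grouping (16/64/9) exactly.

`run_full_pipeline()` chains all stages from one config, writing stage TSVs,
an M/A plot, KM curves and a deterministic JSON summary;
`inst/cli/run_pipeline.R` is a thin command-line wrapper around it.

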
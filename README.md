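# grfclust

Sensor-free gait classification from force-plate data, for clinical movement
analysis. `grfclust` quantifies how closely a patient's three-axis ground
reaction force (GRF) during one stance phase matches a healthy reference, and
clusters patients into gait-pattern groups from those similarities alone — no
markers, no wearables, just one step on a force plate.

## The method

For each stance phase the three GRF components — medial-lateral (ML),
anterior-posterior (AP), vertical (V) — are resampled to a 101-point
percent-of-stance grid in body-weight units and compared against a healthy
reference template (standardized so the mean absolute value of each healthy
mean curve is 1). Two indices are computed per axis:

- **Trend similarity** — the Pearson correlation
  R = Σᵢ(Hᵢ−H̄)(Pᵢ−P̄) / √(Σᵢ(Hᵢ−H̄)² Σᵢ(Pᵢ−P̄)²): does the waveform have the
  right *shape*?
- **Scale similarity** — the SMAPE score 1 − SMAPE, with
  SMAPE = (1/N) Σᵢ |Hᵢ−Pᵢ| / ((|Hᵢ|+|Pᵢ|)/2): does it have the right
  *magnitude*?

The six features (2 indices × 3 axes) are clustered with a Gaussian mixture
model p(x) = Σₖ πₖ N(x | μₖ, Σₖ) fitted by an in-package EM algorithm
(k-means++ starts, multiple restarts, variance floor). The number of
components is selected by BIC and cross-checked with k-means, the elbow
method and silhouette scores; a per-subject consistency report verifies that
all trials of one subject land in the same group.

A synthetic cohort generator produces realistic stance-phase GRF waveforms
with two patient archetypes — shape-preserving/magnitude-attenuated and
shape-distorted — so the whole pipeline is testable end to end with known
ground truth. A published 16-patient hip osteoarthritis feature table ships
with the package (`load_hip_oa_features()`).

## Worked example

```r
library(grfclust)

cfg <- pipeline_config(cohort = cohort_spec(seed = 0), seed = 0)
report <- run_pipeline(cfg)

report$selection$table
#>   K log_likelihood n_params       bic converged
#> 1 1       198.4609       12 -350.4675      TRUE
#> 2 2       468.2873       25 -839.7945      TRUE
#> 3 3       489.7254       38 -832.3451      TRUE
#> 4 4       511.9628       51 -826.4944      TRUE
#> 5 5       526.3108       64 -804.8647      TRUE

table(report$assignments$group)
#> Group1 Group2
#>     24     24

attr(report$consistency, "all_consistent")
#> [1] TRUE
```

The BIC minimum at K = 2 recovers the two simulated gait archetypes; the 48
patient trials split 24/24, and every subject's three trials land in the same
group (the intra-validation check). Subjects with attenuated-magnitude gait
show high trend similarity but low scale scores; shape-distorted subjects
show reduced trend similarity — the two signatures the clustering separates.

To run from a shell: `Rscript inst/scripts/grfclust-pipeline.R simulate --out
cohort/` then `... run --in cohort/ --out results/`.

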
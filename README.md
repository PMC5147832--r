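# bloodEWAS

Cell-type-resolved epigenome-wide association analysis of cigarette smoking
in blood DNA methylation.

Smoking leaves strong, reproducible methylation marks in whole-blood DNA
(AHRR, F2RL3, GPR15, ...), but whole blood is a mixture of leukocyte
lineages: a whole-blood signal confounds *within-cell* methylation change
with *shifts in cell composition* (smokers carry more granulocytes and fewer
lymphocytes), and cell-restricted effects are diluted by the lineages they
do not touch. `bloodEWAS` implements the full analysis chain needed to
resolve this, and a synthetic-cohort generator with planted lineage-specific
effects so every step can be validated against known truth.

## What it computes

**Robust EWAS on M-values.** Beta values (methylation fractions,
β ∈ [0, 1]) are transformed to M-values, M = log2(β / (1 − β)), and each
probe is fit by Huber robust regression (IRLS, tuning constant k = 1.345,
per-iteration MAD scale):

    M_probe ~ exposure + age + sex + race + cell-type fractions

with exposure either current-smoking status, pack-years, or years smoked.
Two-sided p-values come from the t distribution with n − p df; the
genome-wide line is Bonferroni, α / (probes tested). Group delta-beta
(smoker − never mean β) and a Welch t-test accompany every probe.

**Reference-based cell-composition estimation.** Leukocyte fractions are
estimated per sample by projecting betas at lineage-discriminating probes
onto a reference panel: minimize ‖β − R·w‖² subject to w ≥ 0, Σw = 1. The
solver enumerates constraint support sets and is exact; estimated fractions
enter the EWAS design (one column dropped to avoid simplex collinearity).

**Stratified duration rank-change.** Among the top-K any-smoking CpGs,
current smokers are split at 22 cigarettes/day; years-smoked association is
fit per probe within each stratum, probes are ranked by p within stratum,
and rank_light − rank_heavy sorts out CpGs tracking smoking duration
specifically in heavy smokers.

**Cell-type effect profiling.** For candidate CpGs, per-cell-type
delta-beta and Welch p across purified CD14+/CD15+/CD19+/CD4T/CD8T/CD56
matrices (plus whole-blood and PBMC mixtures), hierarchical clustering of
the effect or significance profiles, rule-based response-pattern labels
(pan-cell, myeloid, myeloid+B, lymphoid, T-only, monocyte-only), mixture
back-projection Δ_wb = Σc wcS βcS − Σc wcN βcN predicting the whole-blood
delta from cell-type effects and compositions, cotinine dose-response
regression, and ΔΔCt qPCR fold changes (FC = 2^−ΔΔCt).

## Worked example

```r
library(bloodEWAS)

sim  <- simulate_cohort(n_never = 30, n_current = 60, n_probes = 500,
                        n_per_class = c(myeloid_plus_B = 5, lymphoid = 5),
                        seed = 42)
comp <- estimate_composition(sim$whole_blood, sim$panel, k_per_type = 20)
fit  <- ewas(sim$whole_blood, sim$sheet, compositions = comp)
summary(fit, n_top = 5)
```

```
Smoking EWAS (robust regression on M-values)
  exposure: status  covariates: age, sex, race 
  composition-adjusted (dropped CD15 to avoid collinearity)
  probes tested: 500  Bonferroni threshold: 1e-04  significant: 9 

Top probes by p-value:
   probe_id exposure_coefficient standard_error t_statistic   p_value
 cg00000462               -1.361        0.06872      -19.81 1.369e-32
 cg00000323               -1.383        0.07083      -19.52 3.665e-32
 cg00000253               -1.148        0.05946      -19.31 7.524e-32
 cg00000269               -1.400        0.07562      -18.51 1.204e-30
 cg00000245               -1.327        0.08426      -15.75 3.076e-26
 delta_beta   ttest_p n_used rank
    -0.2474 1.616e-27     90    1
    -0.2330 4.834e-24     90    2
    -0.1574 4.853e-23     90    3
    -0.1726 7.554e-21     90    4
    -0.2198 1.349e-34     90    5
```

Nine of the ten planted CpGs reach the Bonferroni line (1e-04 = 0.05/500);
the exposure coefficients recover the planted logit-scale effects (−1.5 for
the myeloid+B class, −0.8 lymphoid) and delta_beta shows the corresponding
beta-scale drop (≈ −25 and −15 percentage points at these baselines).
Profiling the top hits across the purified cell-type matrices recovers the
planted response patterns:

```r
cand <- head(fit$results$probe_id, 10)
prof <- celltype_association(c(sim$celltype_betas,
                               list(whole_blood = sim$whole_blood)),
                             sim$sheet, cand)
table(classify_response_pattern(prof))
```

```
      lymphoid myeloid_plus_B           none 
             4              5              1 
```

`run_pipeline(default_config())` chains all stages (simulate → deconvolve →
EWAS → duration rank-change → profiles) and writes every table, a run
report, and seed/config-hash metadata under the output directory.

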
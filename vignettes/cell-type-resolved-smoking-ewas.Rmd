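---
title: "Methods: cell-type-resolved smoking EWAS on synthetic blood methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-resolved smoking EWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodEWAS)
```

## The problem

Cigarette smoking produces some of the largest known environmental effects
on blood DNA methylation. Whole-blood measurements, however, average over
leukocyte lineages, which creates two distinct failure modes for an
epigenome-wide association study (EWAS):

1. **Compositional confounding.** Smokers' blood contains relatively more
   granulocytes and fewer lymphocytes. Any CpG whose baseline methylation
   differs between lineages will then show a group difference in whole
   blood even with no within-cell change at all.
2. **Dilution.** A CpG that responds to smoke only in, say, T cells is
   attenuated in whole blood by roughly the complement of the T-cell weight
   and may not reach significance there.

`bloodEWAS` implements the standard remedy — per-probe robust regression on
M-values with reference-based cell-composition adjustment — together with
the downstream analyses that resolve effects by lineage, and a generative
model of the whole study so each claim can be tested against planted truth.

## Statistical model

### Scale

Regression is done on M-values, $M = \log_2\{\beta/(1-\beta)\}$, whose
variance is approximately constant across the methylation range; group
differences are reported on the beta scale (delta-beta), which is the
interpretable "percentage methylation" unit. Betas are clipped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$ before the
transform: the bound is small enough to be inert for any observable beta on
a ~250-sample array experiment while keeping boundary values finite. Both
transforms and the round-trip identity are exposed (`beta_to_m`,
`m_to_beta`).

### Per-probe robust fit

For each probe the M-values are fit by Huber M-estimation via iteratively
reweighted least squares (`huber_fit`):

* tuning constant $k = 1.345$ — 95% efficiency under Gaussian errors, the
  conventional compromise between efficiency and outlier resistance;
* residual scale re-estimated each iteration as the normalized median
  absolute deviation about zero;
* at most 50 iterations, convergence when no coefficient moves by more than
  $10^{-8}$. Each IRLS step is a majorize-minimize update at fixed scale,
  so the Huber objective cannot increase within an iteration; the
  `trace = TRUE` option records the pre/post objectives and the test suite
  asserts this descent property.

Standard errors use the classical M-estimator asymptotics
($K^2 s^2 \sum\psi^2/(n-p)\,/\,\bar{\psi'}^2 (X'X)^{-1}$), and p-values the
t reference distribution with $n - p$ degrees of freedom. On data without
outliers the fit reproduces ordinary least squares; on contaminated data it
matches `MASS::rlm`, which serves as an independent cross-check in the test
suite rather than as the implementation.

### Design

The design matrix contains the exposure (a current/never indicator,
pack-years, cigarettes/day, or years smoked), one-hot-encoded demographic
covariates (first level as reference), and — when compositions are supplied
— the estimated cell-type fractions with the largest-mean cell type dropped,
because fractions on the simplex sum to one and would otherwise be collinear
with the intercept. The dropped type is recorded on the fitted object.
Missing betas are dropped per probe; rank-deficient designs are an error
naming the collinear columns.

The family-wise threshold is Bonferroni, $\alpha$ divided by the number of
probes actually tested after filtering — the denominator is always the
retained-probe count of the run at hand, recorded in the output metadata,
rather than any fixed array constant.

### Composition estimation

`estimate_composition` solves, per sample,

$$\hat{w} = \arg\min_{w \ge 0,\ \sum w = 1} \lVert \beta - R\,w \rVert^2$$

where $R$ holds the reference panel's mean betas at lineage-discriminating
probes (top-gap probes per cell type, 50 hyper- plus 50 hypomethylated by
default, ties broken lexicographically). Because leukocyte panels are small
(≤ ~12 cell types), the solver simply enumerates all support sets of the
non-negativity constraint and solves each equality-constrained subproblem
through its KKT system — the returned solution is the exact global optimum,
not an iterate, which is why the test suite can demand agreement with a
brute-force simplex grid search to the grid resolution and exact recovery
on noiseless mixtures. An option relaxes $\sum w = 1$ to $\le 1$ (via a
zero-signal slack component) for samples that may contain cells absent from
the panel. Missing betas at selected probes are imputed as the panel row
mean, with a reported count. Identical reference columns make weights
unidentifiable and raise an error naming the collinear cell types.

### Stratified duration rank-change

To find CpGs tracking *duration* of smoking specifically in heavy smokers,
`stratified_rank_change` takes the top-K probes of the any-smoking EWAS
(K = 1000 by default), splits current smokers at 22 cigarettes/day (the
configurable heavy cutoff; `NULL` uses the rounded within-run smoker
median, and "heavy" is ≥ cutoff), fits the years-smoked model per probe
within each stratum with the same covariate set (compositions retained by
default, droppable by argument), ranks by ascending p within stratum with
lexicographic tie-breaks, and reports the signed change
`rank_light − rank_heavy` (plus its absolute value) in descending order.

A candid note on power: when the candidate set carries no shared dose
signal, the two strata rank essentially independent noise, the null rank
changes span nearly the full ±(K−1) range, and a probe that is rank 1 in
the heavy stratum still lands in the middle of the list on average. The
acceptance experiment (one planted heavy-only probe among 999 nulls)
measures exactly this: the planted probe wins the heavy stratum virtually
always, yet reaches the top 5 of the rank-change list only ~10% of the
time. On real candidate sets — probes pre-selected for smoking association,
whose duration signal is correlated between strata — null rank changes
shrink and the statistic becomes informative. The procedure is therefore a
screening device conditional on a well-chosen candidate set, not a
calibrated test, and the package deliberately reports signed and absolute
changes so downstream users can inspect both tails.

### Cell-type profiles, clustering, patterns

`celltype_association` computes per-probe delta-beta and Welch p in every
supplied matrix (purified cell types; whole blood and PBMC mixtures as
extra columns). Clustering (`cluster_profiles`) is agglomerative with
Euclidean distance and average linkage by default (configurable), on signed
delta-beta or $-\log_{10} p$; rows are canonically ordered by probe id
first so the tree is invariant to input order, and the tree is exported as
Newick text.

Response-pattern labels (`classify_response_pattern`) are a total,
deterministic function of the per-cell-type significance vector at an
unadjusted per-test $\alpha = 0.05$ — appropriate for a small purified-cell
study where the label is descriptive, not confirmatory. Rules are evaluated
most-specific-first: pan-cell (all types), myeloid (both myeloid types, no
lymphoid), myeloid+B (myeloid and B, no T — the AHRR-like profile), T-only,
monocyte-only, lymphoid (significant only within T/B/NK — the GPR15-like
profile), none. Evaluating the "only"-style rules before the broader
lymphoid rule is what keeps a T-only vector labelled T-only rather than
swallowed by the lymphoid rule; vectors matching no rule (e.g. granulocyte
only) fall to "none".

The mixture identity
$$\Delta_{wb} \;=\; \sum_c w_c^{S}\,\beta_c^{S} \;-\; \sum_c w_c^{N}\,\beta_c^{N}$$
(`predict_wholeblood_delta`) decomposes a whole-blood group difference into
within-cell effects and compositional shift: with equal compositions it
reduces to $\sum_c w_c \Delta_c$ (hence the attenuation of cell-restricted
effects), and with zero within-cell effects to
$\sum_c (w_c^S - w_c^N)\beta_c$ (pure confounding). On noiseless synthetic
data the identity holds to machine precision, which the tests assert at
$10^{-12}$.

Cotinine dose-response uses ordinary least squares of beta on
log2-transformed serum cotinine with a 0.1 ng/mL detection floor before the
log (non-detects otherwise explode the transform); qPCR fold changes use
the textbook ΔΔCt method normalized to the reference gene and calibrated to
the never-smoker mean ΔCt within each cell type × gene stratum.

## The synthetic cohort

The generator is first-class, tested code: it defines the study conditions
under which every statistical claim above is validated.

* **Subjects** (`simulate_subjects`): defaults of 81 never- and 172 current
  smokers for whole-blood runs, 14/20 for the purified-cell design.
  Cigarettes/day spans light (5–21) and heavy (22–60) use around the
  22/day cutoff with a configurable heavy fraction (default 0.5); years
  smoked ~ N(17, 8.5) truncated to [2, 42]; pack-years is exactly
  (cigarettes/day ÷ 20) × years; cotinine rises multiplicatively with dose
  (≈ 8 ng/mL per cigarette/day, log-normal spread) and is a few ng/mL in
  never-smokers.
* **Reference panel** (`simulate_reference_panel`): per-type baselines from
  a shared bimodal-with-intermediate-shoulder beta distribution (array
  betas pile up near 0 and 1), jittered per cell type by 0.5 logits to give
  every probe genuine cross-lineage differences; plus designated marker
  probes near one pole in exactly one type and the opposite pole elsewhere
  (pole ranges chosen so marker gaps exceed 0.8 beta).
* **Planted effects** (`simulate_effect_truth`): lineage-targeted logit
  shifts — myeloid and myeloid+B −1.5 logits (≈ −24 beta points from a
  0.85 baseline, the AHRR-like magnitude), lymphoid and T-only −0.8
  (≈ −10 points), monocyte-only +0.8, pan-cell −1.0, and duration probes at
  −0.05 logit per year smoked applied only at/above the heavy cutoff.
  Effects are planted on mid-methylation probes (mean baseline in
  [0.25, 0.75]): saturated CpGs cannot exhibit such beta shifts, and real
  smoking-responsive loci sit in this range.
* **Noise** is Gaussian on the logit scale (SD 0.35 by default,
  independent across probes and cells), which keeps betas strictly inside
  (0, 1) and reproduces the heteroskedastic, baseline-dependent spread of
  beta values.
* **Composition** (`simulate_compositions`): group-specific Dirichlet draws
  (concentration 150) with never-smoker means ~8/51/8/20/9/4% for
  CD14/CD15/CD19/CD4T/CD8T/CD56 and smokers shifted +3 points toward
  granulocytes at the lymphocytes' expense — the direction and magnitude of
  smokers' blood-count differences. Whole blood is the exact convex
  combination of the cell-type matrices; PBMC synthesis multiplies the
  granulocyte weight by a retention factor (default 0.05; granulocytes are
  largely lost in PBMC preparation) and renormalizes.
* **Reproducibility**: one global seed fans out to fixed per-stage
  substreams, so any stage can be regenerated independently and a full
  pipeline run is byte-identical under the same config and seed.

What the generator does **not** emulate: probe-type chemistry differences
(type I/II bias), batch effects, genetic (mQTL) variation, correlated
probes within DMRs, or within-lineage heterogeneity. Passing tests
therefore demonstrate correctness of the statistical machinery under a
clean mixture-plus-logit-noise model, not robustness to the full artifact
spectrum of array data; normalization and batch correction are assumed done
upstream of this package (only clipping and SNP-probe exclusion filtering
are in scope here).

## Validation experiments and problem sizes

The acceptance layer (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) recomputes, at the study-default conditions:

* composition recovery over 100 noisy 6-type mixtures (logit noise 0.1) and
  agreement with a 0.005-step simplex grid search on 3-type instances;
* null calibration of the EWAS at 2000 probes × 250 subjects (type-I error
  at 0.05, Kolmogorov–Smirnov uniformity), using equal group composition
  means, since a composition shift is real mixture-level signal and belongs
  to the next experiment;
* confounding control on probes whose expected compositional whole-blood
  delta exceeds 0.008 beta: unadjusted fits flag them far above the nominal
  rate, composition-adjusted fits return to it;
* exact mixture conservation on a noiseless cohort;
* the duration rank-change experiment (50 replicates of one planted probe
  among 999 nulls, ~86 smokers per stratum) — reported honestly at its
  ~10% top-5 rate for the reasons discussed above;
* clustering and pattern-label recovery of planted myeloid vs lymphoid
  classes over 20 seeds (purified-cell design, 14 + 20 subjects);
* the blood-count worked examples and exact unit identities.

These problem sizes (hundreds to a few thousand probes) were chosen so the
full validation runs in minutes on one core while keeping every per-test
sample size at the study's actual values; only the probe dimension is
scaled down, which affects Bonferroni denominators (always recomputed) but
not per-probe power.

## Known limitations

* The rank-change screen's null distribution depends on the candidate set,
  as discussed; it is reported unthresholded.
* The pattern rules assume the panel's lineage vocabulary
  (CD14/CD15/Mono/Neu/Gran, CD19/Bcell, CD4T/CD8T/CD2T, CD56/NK); other
  labels need an explicit lineage map.
* The exhaustive deconvolution solver is exponential in the number of cell
  types and capped at 14; leukocyte panels are far below this, but the
  solver is not intended for high-resolution single-cell reference
  matrices.
* Bonferroni is the only multiplicity correction offered, by design.
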
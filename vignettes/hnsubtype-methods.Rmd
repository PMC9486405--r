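---
title: "Balanced centroid subtyping and stratified survival analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced centroid subtyping and stratified survival analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hnsubtype)
```

`hnsubtype` implements an expression-based subtyping and prognostic
pipeline for head and neck squamous cell carcinoma (HNSCC): a balanced
nearest-centroid classifier for the four bulk-expression subtypes (basal,
mesenchymal, classical, atypical), an HPV caller from viral read counts,
and a stratified survival engine centred on the clinical question of
whether the mesenchymal subtype marks poor prognosis in node-negative oral
cavity disease. This vignette records the model, its assumptions, the
tunable parameters, and the design decisions taken where more than one
reading was defensible.

## The classifier

### Distance and call strength

Expression is handled on the log2 scale (upper-quartile normalised
abundances, `log2(v + 1)` with the conventional pseudocount of 1 so zero
maps to zero; whether the original analyses used an offset is not
documented, so the pseudocount is an argument of `log2_transform()`).

A sample profile $x$ restricted to the model's genes is compared with each
subtype centroid $c_k$ by the correlation distance

$$d(x, c_k) = 1 - r(x, c_k) \in [0, 2],$$

and assigned to the closest centroid. Two consequences of using raw
Pearson correlation deliberately shape the implementation:

* **Affine invariance.** $r$ is unchanged by $x \mapsto a x + b$ with
  $a > 0$, so per-sample scaling or shifting (library-size or array
  effects that act uniformly across genes) cannot change a call. The
  sample is *not* re-centred gene-wise before correlating — doing so would
  buy a little accuracy on weak signatures at the cost of this invariance.
* **Degenerate profiles are visible.** A zero-variance sample vector has
  no defined correlation; it receives distance 1 to every centroid and a
  `zero_variance` flag rather than being dropped, because a silent
  exclusion is worse than a flagged non-call.

Exact ties (possible, e.g., when two centroids are proportional) go to the
subtype listed first in the model's subtype order, and the call is
flagged.

Call strength is the centroid form of the silhouette,
$s = (b - a)/\max(a, b)$ with $a$ the distance to the assigned centroid
and $b$ the smallest distance to any other centroid, so $s \in [-1, 1]$.
Whether the original call strength used centroid distances or the full
pairwise silhouette is not stated in the public record; the centroid form
is implemented because it matches the centroid framework and is computable
one sample at a time, and the choice is documented here rather than hidden.

### Balanced gene selection

Training scores every gene $g$ for every class $k$ with the ClaNC-style
statistic

$$t_{kg} = \frac{\bar{x}_{kg} - \bar{x}_g}{m_k \, s_g}, \qquad
  m_k = \sqrt{1/n_k - 1/n},$$

where $s_g$ is the pooled within-class standard deviation floored at
`sd_floor` (default 0.05 log2 units) so the statistic is finite even for
constant genes. Rather than taking extreme absolute values of $t_{kg}$,
selection is *balanced*: each of the $K$ classes receives
`total_genes / K` genes, exactly half with the largest $t_{kg}$ ("high"
genes) and half with the most negative ("low" genes). Each gene belongs
to one class only. Contention — a gene extreme for two classes — is
resolved by claiming in round-robin over ranks (every class claims its
rank-1 high and low gene, then rank 2, and so on, skipping claimed
genes). The round-robin is our choice where the order of claiming is
otherwise unspecified; it avoids giving the first-listed subtype a
systematic advantage. Ties within a class ranking are broken by gene
identifier, for determinism.

### Coefficients and sample exclusion

Centroid coefficients are medians, not means: each selected gene is
centred by its overall median across the retained training samples, and
the class coefficient is the within-class median of the centred values.
Before computing them, the `floor(q · n_k)` samples with the lowest
gold-standard call strength are excluded per class (default $q = 0.20$;
a class of 50 loses exactly 10). `floor` is used so that a small class is
never emptied at the default $q$ unless $n_k < 5$. The exclusion is
applied only at coefficient computation, not during gene selection —
the sentence structure of the published description suggests that order,
and it keeps selection and robustification separable.

The per-gene centring constants are stored in the model and serialised
with it, so a model file round-trips losslessly and classification of new
data needs no information beyond the model file.

### Size selection

The reduced model is built from a candidate pool: all gold-standard
classifier genes plus up to `candidate_extra_genes` (default 348)
additional genes "of high mean and variance", read here as: genes with
above-median mean expression, ranked by variance. The precise published
criterion (joint vs marginal, thresholds) is not recoverable, so this
concrete reading is isolated behind the configuration. Stratified
`cv_folds`-fold cross-validation (default 5, folds stratified by gold
call, seeded) estimates agreement with the gold calls per candidate size;
the smallest size within `agreement_tol` (default 0.01) of the best is
chosen. The published design fixed the size at 88 genes — 22 per subtype,
11 high and 11 low — and that is the default `total_genes`, used directly
when no candidate-size grid is supplied.

The same machinery with $K = 2$ drives
`train_binary_node_predictor()`, an expression-based predictor of nodal
positivity reported with resubstitution and cross-validated accuracy. It
exposes the mechanism; no claim is made that its feature count or
validation split matches any published predictor.

## HPV calling

A tumor is called HPV-positive when its read count for HPV type 16, 18,
33 or 35 *strictly exceeds* 1,000 counts — the threshold treated as
evidence of ongoing viral replication. The rule thresholds each type
separately (`rule = "any"`); whether the original criterion applied to
per-type or total HPV-aligned counts is ambiguous, so a summing rule is
available (`rule = "sum"`) but is not the default. The threshold is
configurable; exactly 1,000 counts is negative under the strict
inequality.

## Cohort statistics

`descriptive_table()` summarises the cohort within site-group ×
nodal-status × mesenchymal-status strata (counts, within-stratum
percentages over non-missing values, median age), mirroring the layout of
published descriptive tables; percentages are additionally rounded to
whole percent for display, with full precision kept. Missing values are
excluded pairwise per test and always counted in the output, never
silently dropped.

For 2×2 association claims the default policy runs the uncorrected
Pearson chi-square when all expected counts are at least 5 and Fisher's
exact test otherwise; published reports typically name both tests without
mapping them to individual p-values, so `test_association(..., "both")`
reports both. One caution established while testing: the uncorrected
chi-square and the two-sided Fisher p can differ by more than 0.1 in the
middle of the p scale even when all expected counts exceed 20 — the two
only agree to ~0.02 once cell counts reach the thousands. The package
therefore never treats the two as interchangeable at moderate n.

`published_cohort_counts()` ships the per-stratum sample counts of a
published TCGA HNSCC cohort (n = 418) as package data, letting the
headline contingency quantities — 67% vs 55% nodal positivity by
mesenchymal status (chi-square p ≈ 0.03), and the 82% vs 49% nodal
positivity of T3–T4 vs T1–T2 mesenchymal oral-cavity tumors — be
recomputed from printed counts without access to patient-level data.

## Survival analysis

All survival work first truncates follow-up at the horizon (default 36
months): times strictly beyond the horizon become censored observations
at the horizon; an event at exactly the horizon is kept as an event
(truncation applies to times *longer than* the horizon). Kaplan–Meier
estimation, log-rank tests and Cox fits delegate to the `survival`
package; ties are handled by Efron's method by default (Breslow available
for comparison with older software), and hazard ratios are reported per
non-reference level with Wald intervals.

`subgroup_survival_analysis()` reproduces the stratified layout of the
oral-cavity analysis: univariate fits within the oral-cavity N0 and N+
strata for gender, smoking, HPV status, radiation, T stage (T1–T2 vs
T3–T4), overall stage (I–II vs III–IV), mesenchymal status and age;
multivariate fits of T stage + subtype (N0) and subtype + age (N+),
mirroring the published multivariate cells — which covariates entered
each multivariate model is only inferable from the populated cells, so
the lists are configuration, not hard-coded truth. Age is dichotomised at
the observed cohort median and the reference row labelled with the
observed low range (e.g. "19-61"), the rule implied by published tables
that label the reference category that way. Kaplan–Meier curves and
log-rank tests are produced for the four subtype × node groups within the
oral-cavity, non-oral-cavity and non-oral-cavity HPV-negative subsets.
Strata smaller than `min_stratum` (default 10, the size at which a
published stratum was itself interpreted cautiously) are flagged, never
suppressed.

## The synthetic-cohort generator

No generative model is published for these data; every distributional
choice in `sim_config()` is a transparent stand-in chosen for
testability, and recovery results on synthetic cohorts validate the
*implementation*, not the biology of real tumors.

* **Expression** is simulated directly on the log2 scale: gene-specific
  baselines drawn once from U(4, 12) log2 units (a realistic bulk RNA-seq
  spread), Gaussian noise with `noise_sd` (default 1), and disjoint
  marker blocks per subtype, half shifted up and half down by
  `marker_effect_size · noise_sd` (default effect 4). Simulating post-log2
  avoids inventing count-level dispersion the classifier never sees; the
  half-up/half-down architecture makes the balanced selection directly
  testable. Not modelled: count noise, batch effects, tumor purity,
  correlated gene programs — so passing recovery tests says nothing about
  classification accuracy on real tumors with those features.
* **Clinical covariates** follow the published cohort's marginals:
  subtype mix 0.30/0.26/0.18/0.26, nodal positivity 0.67 for mesenchymal
  vs 0.55 otherwise, site frequencies dominated by the oral cavity,
  ~15% HPV positivity; radiation probability depends on nodal status.
* **Survival** uses exponential event times — hazard
  `hazard_rate_baseline` (default 0.01/month, ≈30% event probability by
  36 months in the reference arm) times 2.4 for node-positive disease and
  2.4 for node-negative mesenchymal disease, reflecting the headline
  finding that node-negative mesenchymal disease carries node-positive
  risk — with administrative censoring only, at 36 months. Exponential
  times give closed-form oracles (median = ln 2 / λ) for the tests.
* **HPV counts**: positive samples get one infecting type drawn uniformly
  from [5,000, 50,000] counts, all other counts from [0, 100], straddling
  the 1,000 threshold so truth is exactly recoverable.
* **Seeding**: one integer seed governs the full cohort; each stage
  (expression, clinical, survival, HPV) draws from a fixed offset of that
  seed, so stages are individually reproducible and jointly independent,
  and identical configurations give byte-identical files.

## Numerical choices and degenerate inputs

* Upper-quartile normalisation uses the type-7 (linear interpolation)
  quantile over each sample's *positive* values; an all-zero sample is an
  error naming the sample. The published normalisation names the method
  but not the quantile estimator; type 7 is R's default convention.
* Classifier genes missing from a matrix are dropped from both sample
  vector and centroid (no imputation — correlation distance tolerates
  modest loss, imputation would invent signal), with a hard floor of 80%
  presence; gene symbols are matched verbatim and case-sensitively.
* Zero pooled variance is floored (`sd_floor`), zero-variance samples are
  flagged, a silhouette with $a = b = 0$ returns 0 with a flag, a
  log-rank test with no events returns statistic 0 and p = 1, and Cox
  non-convergence or apparent separation raises an explicit error rather
  than returning a diverged fit.

## Problem sizes used by the test-suite and acceptance runs

Recovery and calibration properties are checked at sizes chosen to make
the statistics decisive while keeping runs desk-scale: classifier
recovery on 200-sample cohorts with 40 marker genes per subtype and 500
noise genes (accuracy ≥ 95% at effect size 4); hazard-ratio coverage over
200 replicates of 400-sample node-negative cohorts (Wald CI covers the
true 2.4 in ≥ 90%); log-rank null calibration over 1,000 replicates of
two 500-sample arms (rejection 5% ± 1.5% at α = 0.05); Fisher-vs-
enumeration equality exhaustively for all 2×2 tables with n ≤ 16 plus a
seeded sample of 600 tables up to n = 40. These sizes are the package's
own choices and are stated here so they can be scaled up by anyone
wanting tighter Monte-Carlo error.

## Known limitations

* The published 88-gene list cannot be reproduced without the original
  TCGA expression matrices; the trainer reproduces the *procedure* and
  its structural guarantees, not the specific gene identities.
* The generator's independence assumptions (genes independent given
  subtype, covariates independent given subtype and node) are stronger
  than real data; association tests on synthetic cohorts are calibrated,
  not realistic.
* No batch correction or cross-annotation gene mapping: matrices from
  different platforms must be reconciled upstream.
* No competing risks, time-varying covariates, or proportional-hazards
  diagnostics beyond convergence checks.
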
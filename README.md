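# hnsubtype

Molecular subtyping and prognostic analysis for head and neck squamous cell
carcinoma (HNSCC), aimed at the HPV-negative oral cavity setting where the
**mesenchymal** expression subtype marks otherwise low-risk, node-negative
disease with poor survival.

HNSCC tumors fall into four reproducible bulk-expression subtypes — basal,
mesenchymal, classical, atypical. `hnsubtype` provides, as a set of
pipe-friendly tibble-in / tibble-out functions:

* **A balanced nearest-centroid subtype classifier.** A sample *x* is
  assigned to the subtype *k* minimising the correlation distance
  *d(x, c_k) = 1 − r(x, c_k)*, with *r* the Pearson correlation against
  centroid *c_k*. Call confidence is the centroid silhouette
  *s = (b − a) / max(a, b)*, where *a* is the distance to the assigned
  centroid and *b* the distance to the nearest other centroid.
* **A balanced ClaNC-style trainer** for reduced gene signatures. Genes are
  scored per class by *t_kg = (x̄_kg − x̄_g) / (m_k · s_g)* with
  *m_k = √(1/n_k − 1/n)* and *s_g* the (floored) pooled within-class
  standard deviation; each class receives an **equal number of high and low
  genes**, claimed round-robin so every gene belongs to exactly one class.
  Centroid coefficients are within-class medians of each gene after
  centring by its overall median, computed after excluding the 20% of
  samples per class with the weakest gold-standard call strength. Signature
  size is chosen by stratified five-fold cross-validation against the
  gold-standard calls (default fixed at the published 88 genes, 22 per
  subtype, 11 up + 11 down).
* **An HPV status caller**: a tumor is HPV-positive when reads for HPV type
  16, 18, 33 or 35 exceed 1,000 counts.
* **Cohort statistics and survival analysis**: stratified descriptive
  tables, chi-square / Fisher / Kruskal–Wallis association tests,
  Kaplan–Meier curves, log-rank tests and Cox proportional-hazards fits,
  all with overall survival truncated and censored at 36 months.
* **A synthetic-cohort generator** embedding the structure the analysis
  assumes — four marker-block subtypes over Gaussian log2 noise,
  subtype-dependent nodal positivity (0.67 mesenchymal vs 0.55 otherwise)
  and a hazard ratio of 2.4 for node-negative mesenchymal disease — so the
  entire pipeline is testable without access to controlled clinical data.

## Worked example

```r
library(hnsubtype)

cfg  <- sim_config(n_samples = 200, seed = 7)
sim  <- simulate_cohort(cfg)

gold <- train_centroid_model(sim$expression,
                             sim$truth[, c("sample_id", "subtype")],
                             total_genes = 160)
fit  <- build_reduced_classifier(sim$expression, gold,
                                 training_config(seed = 7))
glance(fit$model)
#> # A tibble: 1 × 4
#>   n_genes n_subtypes genes_per_subtype balanced
#> 1      88          4 22/22/22/22       TRUE

calls <- classify_samples(sim$expression, fit$model)
head(calls[, 1:5], 4)
#>   sample_id subtype   call_strength tie   zero_variance
#> 1 S0001     classical         0.523 FALSE FALSE
#> 2 S0002     atypical          0.601 FALSE FALSE
#> 3 S0003     classical         0.539 FALSE FALSE
#> 4 S0004     basal             0.709 FALSE FALSE
mean(calls$subtype == sim$truth$subtype)
#> [1] 1
```

The trained model carries exactly 88 genes split 22 per subtype with a
balanced 11-up / 11-down structure, and at the generator's default effect
size it recovers every true label. On the survival side, a node-negative
cohort simulated with the embedded mesenchymal hazard ratio of 2.4 gives

```r
tidy(cox_fit(cohort, "mesenchymal_binary"))
#>   term               level       reference           n n_events    hr ci_low ci_high  p_value
#> 1 mesenchymal_binary mesenchymal non_mesenchymal  2000      798  2.32   2.01    2.68 3.77e-30
```

i.e. the Wald interval covers the configured truth. `autoplot()` methods
draw the Kaplan–Meier curves, the cross-validation curve and hazard-ratio
forest plots; `cmd_simulate()` / `cmd_train()` / `cmd_classify()` /
`cmd_hpv_call()` / `cmd_analyze()` run the same stages against files, and
`inst/cli/hnsubtype.R` exposes them as shell subcommands.

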
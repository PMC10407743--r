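# tissuetrace

Many Mendelian diseases damage only specific tissues even though their
causal genes are expressed broadly. `tissuetrace` scores, per tissue, the
risk that a protein-coding gene underlies a disease manifesting in that
tissue. It engineers interpretable tissue-based gene features from
multi-omics inputs, trains a two-layer stacked classifier per tissue,
explains predictions with additive Shapley attributions aggregated by
feature family and tissue of origin, and prioritizes patient candidate
genes by leave-candidates-out scoring. A synthetic-cohort generator with
planted, recorded signal makes the whole pipeline runnable and testable
without access to controlled data.

It is written for computational geneticists and methods developers who
want a complete, reproducible implementation of tissue-aware gene
prioritization that they can run on their own expression compendia, PPI
networks, and disease-gene curations.

## The model in brief

**Features.** Counts are TMM-normalized; a gene is expressed in a tissue
at cpm ≥ 7 in at least half its samples. Preferential expression
standardizes tissue medians:

    pref[g,t] = (med e[g,t] − median_t' med e[g,t']) / IQR_t' med e[g,t']

Per tissue the feature table carries expression and preferential
expression, nine PPI-neighborhood counts (including tissue-specific
interactors, pairs co-expressed in ≤ 20% of tissues), four summaries of
tissue-differential interaction scores, paralog dosage ratios, four
summaries of differential GO process activity (terms of 3–100 genes), an
eQTL q-value, plus developmental organ × timepoint expression,
developmental variability, and 64-dimensional random-walk network
embeddings of the general and every tissue interactome.

**Preprocessing.** Chained Bayesian-ridge imputation (100 nearest
features, 10 sweeps), Yeo-Johnson symmetrization of the expression
families, min-max scaling to [−1, 1] — with every fitted statistic frozen
for later application to withheld genes.

**Learner.** Five base learners (gradient-boosted forest, random forest,
logistic regression, logistic-initiated boosting, and a (10, 10) ReLU
perceptron) scored out-of-fold under stratified 10-fold cross-validation,
scaled to [0, 10], and stacked by a neural meta-learner. Performance is
reported as AUC and area under the precision–recall curve.

**Interpretation and patients.** TreeSHAP attributions on the
gradient-boosted interpretability model, normalized per model and summed
by feature family or tissue of origin; patient candidate genes are
entirely withheld from every fitted statistic, scored by a model trained
on the remaining genes, and ranked against an expression-level baseline
(one-sided Wilcoxon signed-rank comparison).

## Worked example

```r
library(tissuetrace)

# a compact synthetic cohort with planted tissue signal
bundle <- generate_cohort(cohort_config(
  n_genes = 500, tissues = c("blood", "brain", "heart", "liver"),
  samples_per_tissue = 10, positives_per_tissue = 20,
  frac_disease_genes = 0.3, n_go_terms = 60, seed = 3))

fx   <- build_features(bundle)            # gene x feature table
prep <- preprocess_features(fx$table)     # impute + transform + scale
labs <- label_genes_for_tissue(bundle$associations,
                               rownames(prep$table$values), "brain")
cv   <- trace_cv(prep$table, labs, trace_config(seed = 5))
cv
#> stacked CV scores: 299 genes (18 positives), meta AUC 0.996, auPRC 0.903
glance(cv)[, 1:4]
#> # A tibble: 6 x 4
#>   learner   auc  auprc expected_auprc
#> 1 xgb     0.455 0.0628         0.0602
#> 2 rf      1.000 0.994          0.0602
#> 3 lr      1     1              0.0602
#> 4 lrgb    1     1              0.0602
#> 5 mlp     0.995 0.925          0.0602
#> 6 meta    0.996 0.903          0.0602
```

The planted positives are recovered essentially perfectly by the stack
(meta AUC 0.996 against a prevalence baseline of 0.06); the weighted
boosted learner is near-constant at this scale — a documented consequence
of the published 0.01 positive class weight — and the meta-learner learns
to ignore it. Explaining the tissue model shows where the signal lives:

```r
imp <- tissue_importances(prep$table, labs, trace_config(seed = 2))
aggregate_importances(imp, "family")
#> # A tibble: 10 x 2
#>    group                    value
#>  1 process_activity             1
#>  2 dev_variability              0
#>  ...
```

Here the planted GO-module mechanism dominates: all of the normalized
Shapley importance falls on process-activity features. Ranking a
simulated patient's 30 candidates in the affected tissue:

```r
cases <- generate_patient_cases(bundle, n_patients = 1,
                                candidates_per_patient = 30, seed = 9)
score_candidates(fx$table, bundle$associations, cases[1, ],
                 trace_config(seed = 4))
#> candidate ranking (22 candidates, verified gene rank 1)
```

The verified gene — planted, and withheld from training along with every
other candidate (eight of the thirty drawn candidates fall outside the
retained gene universe and are reported as unscored) — comes back at
rank 1; the expression-level baseline ranks it 13th.

`autoplot()` methods are available for cross-validation results, tissue
importances, and patient benchmarks; `tidy()`/`glance()` return tibbles
for downstream analysis. A thin command-line interface over the same
functions lives at `inst/scripts/tissuetrace-cli.R` (subcommands
`simulate`, `build-features`, `preprocess`, `train`, `explain`,
`rank-patient`, `benchmark`).

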
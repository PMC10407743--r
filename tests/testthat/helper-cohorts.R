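# Shared fixtures, built lazily once per test run and cached.

.tt_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .tt_cache)) {
    assign(key, force(expr), envir = .tt_cache)
  }
  get(key, envir = .tt_cache)
}

# A small 4-tissue cohort exercised by many unit tests.
small_cohort <- function() {
  cached("small_cohort", generate_cohort(cohort_config(
    n_genes = 500, tissues = c("blood", "brain", "heart", "liver"),
    samples_per_tissue = 10, positives_per_tissue = 20,
    frac_disease_genes = 0.3, n_go_terms = 60, seed = 3
  )))
}

small_features <- function() {
  cached("small_features", suppressWarnings(build_features(small_cohort())))
}

small_prep <- function() {
  cached("small_prep",
         suppressWarnings(preprocess_features(small_features()$table)))
}

small_labels <- function(tissue = "brain") {
  genes <- rownames(small_prep()$table$values)
  suppressWarnings(
    label_genes_for_tissue(small_cohort()$associations, genes, tissue))
}

# A random feature matrix wrapped as a feature_table.
random_table <- function(n = 60, p = 10, seed = 1, families = "expression") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("g%03d", seq_len(n)),
                              sprintf("f%03d", seq_len(p))))
  feature_table(m, tibble::tibble(
    feature = colnames(m),
    family = rep_len(families, p),
    tissue = "general"
  ))
}
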
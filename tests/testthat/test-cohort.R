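test_that("fixed seed gives a bit-identical bundle", {
  cfg <- cohort_config(n_genes = 300, tissues = c("a", "b", "c", "d"),
                       samples_per_tissue = 6, positives_per_tissue = 8,
                       n_go_terms = 30, seed = 5)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1, b2)
})

test_that("config invariants are enforced with the offending field named", {
  expect_error(cohort_config(frac_disease_genes = 1.2),
               "frac_disease_genes")
  expect_error(cohort_config(go_term_size_range = c(2, 100)),
               "go_term_size_range")
  expect_error(cohort_config(go_term_size_range = c(3, 150)),
               "go_term_size_range")
  expect_error(cohort_config(n_genes = 100, positives_per_tissue = 70),
               "positives_per_tissue")
  expect_error(
    cohort_config(effect_sizes = list(pref_expr_shift = 1)),
    "effect_sizes")
})

test_that("truth bookkeeping lists the planted positives per tissue", {
  b <- small_cohort()
  counts <- table(b$truth$tissue)
  expect_equal(unname(counts), rep(20L, 4L), ignore_attr = TRUE)
  expect_true(all(b$truth$gene %in% rownames(b$counts)))
  expect_true(all(c(b$ppi_edges$gene_a, b$ppi_edges$gene_b) %in%
                    rownames(b$counts)))
})

test_that("zero effect sizes leave positives indistinguishable", {
  cfg <- cohort_config(
    n_genes = 600, tissues = c("a", "b", "c", "d"),
    samples_per_tissue = 10, positives_per_tissue = 25,
    frac_disease_genes = 0.3, n_go_terms = 40,
    effect_sizes = list(pref_expr_shift = 0, process_shift = 0,
                        ppi_density_boost = 0),
    seed = 13)
  b <- generate_cohort(cfg)
  norm <- tmm_normalize(b$counts)
  med <- tissue_medians(norm, b$samples)
  pos <- intersect(b$truth$gene[b$truth$tissue == "a"], rownames(med))
  neg <- setdiff(rownames(med), b$truth$gene)
  p <- wilcox.test(med[pos, "a"], med[neg, "a"])$p.value
  expect_gt(p, 0.01)
})

test_that("stronger expression shifts raise positives' preferential expression", {
  mean_pos_pref <- vapply(c(0.5, 1.5, 3), function(shift) {
    cfg <- cohort_config(
      n_genes = 400, tissues = c("a", "b", "c", "d"),
      samples_per_tissue = 8, positives_per_tissue = 15,
      frac_disease_genes = 0.3, n_go_terms = 30,
      effect_sizes = list(pref_expr_shift = shift, process_shift = 0,
                          ppi_density_boost = 0),
      seed = 17)
    b <- generate_cohort(cfg)
    norm <- tmm_normalize(b$counts)
    med <- tissue_medians(norm, b$samples)
    pref <- suppressWarnings(preferential_expression(med))$pref
    idx <- cbind(match(b$truth$gene, rownames(pref)),
                 match(b$truth$tissue, colnames(pref)))
    mean(pref[idx], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_pos_pref) > 0))
})

test_that("patient cases have a verified gene among the candidates", {
  b <- small_cohort()
  cases <- generate_patient_cases(b, n_patients = 6,
                                  candidates_per_patient = 25, seed = 2)
  expect_equal(nrow(cases), 6L)
  for (i in seq_len(nrow(cases))) {
    cand <- cases$candidates[[i]]
    expect_length(cand, 25L)
    expect_true(cases$verified_gene[i] %in% cand)
    pos_t <- b$truth$gene[b$truth$tissue == cases$tissue[i]]
    expect_true(cases$verified_gene[i] %in% pos_t)
    expect_length(intersect(setdiff(cand, cases$verified_gene[i]), pos_t), 0)
  }
  expect_identical(cases, generate_patient_cases(
    b, n_patients = 6, candidates_per_patient = 25, seed = 2))
  expect_error(generate_patient_cases(b, 2, candidates_per_patient = 1),
               "no decoys")
})
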
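# Helpers shared by feature tests: a tiny deterministic 3-tissue setting.
tiny_med <- function() {
  m <- rbind(g1 = c(10, 2, 2), g2 = c(4, 4, 4), g3 = c(1, 8, 3))
  colnames(m) <- c("ta", "tb", "tc")
  m
}

test_that("expression features copy summaries and zero-fill unexpressed", {
  med <- tiny_med()
  expressed <- med >= 4
  pref <- suppressWarnings(preferential_expression(med))
  fr <- expression_features(med, expressed, pref)
  expect_equal(ncol(fr$values), 6L)  # 3 expression + 3 preferential
  expect_equal(fr$values["g1", "expr@ta"], 10)
  expect_equal(fr$values["g1", "expr@tb"], 0)  # not expressed -> zero
  expect_equal(fr$values["g3", "pref@tb"], pref$pref["g3", "tb"])
  expect_setequal(unique(fr$meta$family),
                  c("expression", "preferential_expression"))
})

test_that("developmental fragments add organ x timepoint and CV columns", {
  b <- small_cohort()
  fx <- small_features()
  n_t <- 4; n_cells <- 7 * 5
  expect_equal(sum(fx$table$meta$family == "developmental_expression"),
               n_cells)
  expect_equal(sum(fx$table$meta$family == "dev_variability"), 7L)
  expect_equal(ncol(fx$table$values),
               expected_feature_count(
                 n_t, length(unique(b$eqtl_q$tissue))))
})

test_that("eQTL features are identity copies with missingness preserved", {
  eqtl <- tibble::tibble(gene = c("g1", "g1", "g2"),
                         tissue = c("liver", "heart", "liver"),
                         q = c(0.003, 0.2, 0.5))
  fr <- eqtl_features(eqtl, c("g1", "g2", "g3"))
  expect_equal(ncol(fr$values), 2L)
  expect_equal(fr$values["g1", "eqtl@liver"], 0.003)
  expect_true(is.na(fr$values["g3", "eqtl@liver"]))  # missing, never 1.0
  expect_error(eqtl_features(dplyr::mutate(eqtl, q = q + 1), c("g1", "g2")),
               "\\[0, 1\\]")
})

test_that("PPI counts on a 3-node path match hand counting", {
  edges <- tibble::tibble(gene_a = c("A", "A"), gene_b = c("B", "C"))
  expressed <- rbind(A = c(TRUE, TRUE, FALSE), B = c(TRUE, FALSE, TRUE),
                     C = c(FALSE, TRUE, TRUE))
  colnames(expressed) <- c("t1", "t2", "t3")
  pref <- expressed & FALSE
  fr <- ppi_count_features(edges, expressed, pref)
  expect_equal(fr$values["A", "ppi_tissue@t1"], 1)  # only B co-expressed
  expect_equal(fr$values["B", "ppi_tissue@t1"], 1)
  expect_equal(fr$values["C", "ppi_tissue@t1"], 0)  # C not expressed in t1
  expect_equal(ncol(fr$values), 27L)  # 9 features x 3 tissues
})

test_that("tissue-specific interactors use the inclusive 20% boundary", {
  # 10 tissues; pair A-B co-expressed in exactly 2 (20%, counts) and pair
  # A-C in 3 (30%, does not).
  tissues <- paste0("t", 1:10)
  expressed <- matrix(FALSE, 3, 10, dimnames = list(c("A", "B", "C"),
                                                    tissues))
  expressed["A", ] <- TRUE
  expressed["B", c("t1", "t2")] <- TRUE
  expressed["C", c("t1", "t2", "t3")] <- TRUE
  edges <- tibble::tibble(gene_a = c("A", "A"), gene_b = c("B", "C"))
  fr <- ppi_count_features(edges, expressed, expressed & FALSE)
  expect_equal(fr$values["A", "ppi_specific@t1"], 1)  # only A-B qualifies
})

test_that("PPI count features equal the nested-loop oracle on random graphs", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    genes <- sprintf("g%02d", 1:30)
    pairs <- t(utils::combn(genes, 2))
    sel <- runif(nrow(pairs)) < 0.1
    edges <- tibble::tibble(gene_a = pairs[sel, 1], gene_b = pairs[sel, 2])
    expressed <- matrix(runif(30 * 6) < 0.5, 30, 6,
                        dimnames = list(genes, paste0("t", 1:6)))
    preferential <- matrix(runif(30 * 6) < 0.2, 30, 6,
                           dimnames = list(genes, paste0("t", 1:6)))
    fr <- ppi_count_features(edges, expressed, preferential)
    o <- ppi_oracle(edges, expressed, preferential)
    expect_equal(fr$values[, paste0("ppi_tissue@", colnames(expressed))],
                 o$tissue, ignore_attr = TRUE)
    expect_equal(fr$values[, paste0("ppi_pref@", colnames(expressed))],
                 o$pref, ignore_attr = TRUE)
    expect_equal(fr$values[, paste0("ppi_specific@", colnames(expressed))],
                 o$specific, ignore_attr = TRUE)
    # deviation features recompute from the primaries
    prim <- fr$values[, paste0("ppi_tissue@", colnames(expressed))]
    expect_equal(fr$values[, "ppi_tissue_dmean@t1"],
                 prim[, 1] - rowMeans(prim), ignore_attr = TRUE)
  }
})

test_that("differential PPI features summarize incident edge scores", {
  med <- tiny_med()
  diff <- differential_edge_scores(
    med, tibble::tibble(gene_a = "g1", gene_b = "g2"))
  fr <- differential_ppi_features(diff, rownames(med))
  # single edge: all four statistics equal the edge score
  for (s in c("min", "max", "median", "mean")) {
    expect_equal(unname(fr$values["g1", paste0("dppi_", s, "@ta")]),
                 unname(diff$scores[1, "ta"]))
  }
  expect_true(all(is.na(fr$values["g3", ])))  # isolated gene
})

test_that("differential edge score follows the scarcer-partner formula", {
  med <- tiny_med()
  diff <- differential_edge_scores(
    med, tibble::tibble(gene_a = "g1", gene_b = "g3"), eps = 1)
  lvl <- pmin(med["g1", ], med["g3", ])        # 1, 2, 2
  expect_equal(unname(diff$scores[1, "ta"]),
               log2((lvl["ta"] + 1) / (median(lvl[c("tb", "tc")]) + 1)),
               ignore_attr = TRUE)
})

test_that("four-number summaries match hand arithmetic", {
  scores <- matrix(c(-1, 0, 3), 3, 1, dimnames = list(NULL, "ta"))
  diff <- list(scores = cbind(ta = c(-1, 0, 3)),
               edges = tibble::tibble(gene_a = rep("g1", 3),
                                      gene_b = c("x", "y", "z")))
  fr <- differential_ppi_features(diff, c("g1", "x", "y", "z"))
  expect_equal(fr$values["g1", "dppi_min@ta"], -1)
  expect_equal(fr$values["g1", "dppi_max@ta"], 3)
  expect_equal(fr$values["g1", "dppi_median@ta"], 0)
  expect_equal(fr$values["g1", "dppi_mean@ta"], 2 / 3)
})

test_that("paralog ratios follow the best-partner and pseudocount rules", {
  cpm <- rbind(g = c(4, 6), p1 = c(2, 2), p2 = c(0, 0))
  colnames(cpm) <- c("s1", "s2")
  norm <- structure(list(cpm = cpm), class = "tt_norm")
  samples <- tibble::tibble(sample = c("s1", "s2"), tissue = "t1")
  paralogs <- tibble::tibble(gene = c("g", "g"), paralog = c("p1", "p2"),
                             identity = c(55, 80))
  expressed_any <- c(g = TRUE, p1 = TRUE, p2 = FALSE)
  fr <- paralog_features(norm, samples, paralogs, expressed_any)
  # best partner is p1 (p2 higher identity but not expressed anywhere);
  # ratios 4/2 and 6/2 -> median 2.5
  expect_equal(fr$values["g", "paralog_best@t1"], 2.5)
  # summed-paralog ratio: denominators 2+0 -> 4/2, 6/2
  expect_equal(fr$values["g", "paralog_sum@t1"], 2.5)
  # p1's own best partner is g
  expect_equal(fr$values["p1", "paralog_best@t1"],
               median(c(2 / 4, 2 / 6)))
  # silent paralog as denominator is floored at eps = 1
  paralogs2 <- tibble::tibble(gene = "g", paralog = "p2", identity = 80)
  ea2 <- c(g = TRUE, p1 = TRUE, p2 = TRUE)
  fr2 <- paralog_features(norm, samples, paralogs2, ea2)
  expect_equal(fr2$values["g", "paralog_best@t1"], median(c(4 / 1, 6 / 1)))
  # genes without a qualifying (>= 40%) partner stay missing
  paralogs3 <- tibble::tibble(gene = "g", paralog = "p1", identity = 39.9)
  fr3 <- paralog_features(norm, samples, paralogs3, expressed_any)
  expect_true(all(is.na(fr3$values["g", ])))
})

test_that("process terms honor the inclusive 3-100 size filter", {
  set.seed(8)
  genes <- sprintf("g%03d", 1:150)
  med <- matrix(rexp(150 * 4, 1 / 10), 150, 4,
                dimnames = list(genes, paste0("t", 1:4)))
  go <- dplyr::bind_rows(
    tibble::tibble(term = "too_small", gene = genes[1:2]),
    tibble::tibble(term = "at_min", gene = genes[1:3]),
    tibble::tibble(term = "at_max", gene = genes[1:100]),
    tibble::tibble(term = "too_big", gene = genes[1:101])
  )
  pa <- process_activity_scores(med, go)
  expect_setequal(rownames(pa$activity), c("at_min", "at_max"))
})

test_that("process activity equals the loop oracle and hand cases", {
  set.seed(9)
  genes <- sprintf("g%03d", 1:40)
  med <- matrix(rexp(40 * 5, 1 / 12), 40, 5,
                dimnames = list(genes, paste0("t", 1:5)))
  go <- tibble::tibble(
    term = rep(sprintf("T%02d", 1:10), each = 4),
    gene = sample(genes, 40, replace = TRUE)
  )
  go <- dplyr::distinct(go)
  go <- go[go$term %in% names(which(table(go$term) >= 3)), ]
  pa <- process_activity_scores(med, go)
  o <- process_oracle(med, go)
  expect_equal(pa$activity[rownames(o), ], o, tolerance = 1e-9)

  fr <- process_activity_features(pa, genes)
  g <- pa$gene_terms$gene[1]
  tms <- pa$gene_terms$term[pa$gene_terms$gene == g]
  expect_equal(fr$values[g, "process_min@t1"],
               min(pa$activity[tms, "t1"]))
  unann <- setdiff(genes, pa$gene_terms$gene)[1]
  expect_true(all(is.na(fr$values[unann, ])))
})

test_that("gene-level process features cover single and mixed term sets", {
  pa <- structure(list(
    activity = matrix(c(-1, 1, 2.1), 3, 1,
                      dimnames = list(c("T1", "T2", "T3"), "ta")),
    gene_terms = tibble::tibble(gene = c("g1", "g1", "g2"),
                                term = c("T1", "T2", "T3"))
  ), class = "tt_process")
  fr <- process_activity_features(pa, c("g1", "g2"))
  expect_equal(unname(fr$values["g1", ]), c(-1, 1, 0, 0))
  expect_equal(unname(fr$values["g2", ]), rep(2.1, 4))
})

test_that("assembly enforces gene sets, uniqueness, and the count formula", {
  expect_equal(expected_feature_count(8, 8, 7, 5, 7), 794)
  a <- random_table(20, 3, seed = 1)
  b <- random_table(20, 3, seed = 2)
  colnames(b$values) <- b$meta$feature <- paste0("x", 1:3)
  tab <- assemble_feature_table(list(a, b))
  expect_equal(ncol(tab$values), 6L)
  expect_error(assemble_feature_table(list(a, a)), "duplicate feature")
  c_tab <- random_table(19, 3, seed = 3)
  expect_error(assemble_feature_table(list(a, c_tab)), "mismatched gene set")
})

test_that("metadata queries return exactly the matching columns", {
  fx <- small_features()
  sel <- filter_features(fx$table, family = "process_activity",
                         tissue = "heart")
  expect_equal(ncol(sel$values), 4L)
  expect_true(all(startsWith(sel$meta$feature, "process_")))
  expect_false(any(is.na(fx$table$meta$family)))
})
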
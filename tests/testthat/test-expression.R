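test_that("TMM factors are exact for identity and pure-depth libraries", {
  set.seed(4)
  base <- matrix(rpois(400, 60), 200, 2,
                 dimnames = list(sprintf("g%03d", 1:200), c("s1", "s2")))
  base[, 2] <- base[, 1]
  norm <- tmm_normalize(base)
  expect_equal(norm$factors$norm_factor, c(1, 1))
  expect_equal(norm$cpm[, 1], norm$cpm[, 2])

  doubled <- cbind(A = base[, 1], B = 2L * base[, 1])
  norm2 <- tmm_normalize(doubled)
  expect_equal(unname(norm2$cpm[, "A"]), unname(norm2$cpm[, "B"]))
})

test_that("TMM factors match the straight-from-the-formula estimator", {
  set.seed(7)
  m <- matrix(rnbinom(200 * 6, mu = 80, size = 3), 200, 6,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:6)))
  m[1:10, 1] <- m[1:10, 1] * 8L  # break symmetry so trimming matters
  norm <- tmm_normalize(m, min_max_count = 0)
  expect_equal(unname(norm$factors$norm_factor), tmm_oracle(m),
               tolerance = 1e-8)
})

test_that("low-count and degenerate inputs are handled", {
  m <- matrix(c(5L, 3L, 2L, 8L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(tmm_normalize(m), "low-count filter")
  m2 <- matrix(c(50L, 30L, 0L, 0L), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(tmm_normalize(m2), "s2")
  # genes at <= 10 raw counts everywhere are dropped before estimation
  m3 <- rbind(matrix(rpois(200, 50), 10, 20), matrix(3L, 2, 20))
  dimnames(m3) <- list(sprintf("g%02d", 1:12), sprintf("s%02d", 1:20))
  expect_setequal(tmm_normalize(m3)$retained_genes, sprintf("g%02d", 1:10))
})

test_that("expressed calls use an inclusive half-of-samples rule", {
  cpm <- rbind(boundary = c(7, 7, 0, 0), below = c(7, 6.9, 0, 0),
               zero = c(0, 0, 0, 0))
  colnames(cpm) <- paste0("s", 1:4)
  norm <- structure(list(cpm = cpm), class = "tt_norm")
  samples <- tibble::tibble(sample = colnames(cpm), tissue = "t1")
  e <- call_expressed(norm, samples)
  expect_true(e["boundary", "t1"])   # 2 of 4 = half, ties inclusive
  expect_false(e["below", "t1"])
  expect_false(e["zero", "t1"])
  expect_equal(unname(attr(e, "expressed_any")), c(TRUE, FALSE, FALSE))
})

test_that("expressed calls equal the brute-force oracle on random data", {
  set.seed(11)
  cpm <- matrix(rexp(100 * 15, rate = 1 / 8), 100, 15,
                dimnames = list(sprintf("g%03d", 1:100),
                                sprintf("s%02d", 1:15)))
  tissue_of <- setNames(rep(c("a", "b", "c"), each = 5), colnames(cpm))
  norm <- structure(list(cpm = cpm), class = "tt_norm")
  samples <- tibble::tibble(sample = names(tissue_of), tissue = tissue_of)
  e <- call_expressed(norm, samples)
  o <- expressed_oracle(cpm, tissue_of)
  expect_identical(unclass(e)[, colnames(o)], o)
})

test_that("preferential expression matches hand and loop oracles", {
  med <- rbind(flat = rep(2, 5), lin = c(1, 2, 3, 4, 5))
  colnames(med) <- paste0("t", 1:5)
  pref <- suppressWarnings(preferential_expression(med))
  expect_equal(unname(pref$pref["flat", ]), rep(0, 5))
  # (5 - 3) / (4 - 2) with type-7 linear interpolation percentiles
  expect_equal(unname(pref$pref["lin", "t5"]), 1.0)

  set.seed(21)
  med2 <- matrix(rexp(50 * 6, 1 / 10), 50, 6,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("t", 1:6)))
  pref2 <- preferential_expression(med2)
  expect_equal(pref2$pref, pref_oracle(med2), tolerance = 1e-9)
})

test_that("preferential expression is location and scale standardized", {
  set.seed(22)
  med <- matrix(rexp(30 * 6, 1 / 10), 30, 6,
                dimnames = list(sprintf("g%02d", 1:30), paste0("t", 1:6)))
  p0 <- preferential_expression(med)$pref
  expect_equal(preferential_expression(med + 3)$pref, p0, tolerance = 1e-12)
  expect_equal(preferential_expression(med * 7)$pref, p0, tolerance = 1e-12)
  # the tissue attaining the maximal median attains the maximal pref
  expect_identical(apply(med, 1L, which.max), apply(p0, 1L, which.max))
})

test_that("developmental summaries follow the declared conventions", {
  dev <- tidyr::expand_grid(organ = "liver",
                            timepoint = c("tp1", "tp2"),
                            sample = "r1",
                            gene = c("const", "var", "zero"))
  dev$value <- dplyr::case_when(
    dev$gene == "const" ~ 4.0,
    dev$gene == "zero" ~ 0.0,
    dev$timepoint == "tp1" ~ 2.0,
    TRUE ~ 4.0
  )
  s <- developmental_summaries(dev)
  expect_equal(s$cv["const", "liver"], 0)
  expect_equal(s$cv["var", "liver"], sd(c(2, 4)) / 3)  # sample sd (n-1)
  expect_true(is.na(s$cv["zero", "liver"]))
  suppressMessages(expect_message(
    developmental_summaries(dev[dev$timepoint == "tp1", ]),
    "<2 timepoints"))
})
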
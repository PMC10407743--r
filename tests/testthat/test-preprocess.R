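test_that("a complete table passes through imputation unchanged", {
  tab <- random_table(40, 6, seed = 2)
  out <- impute_features(tab)
  expect_identical(out$table$values, tab$values)
})

test_that("chained imputation recovers a planted linear relation", {
  set.seed(3)
  n <- 400
  A <- rnorm(n)
  B <- 2 * A + rnorm(n, sd = 0.01)
  noise <- matrix(rnorm(n * 6), n, 6)
  m <- cbind(A = A, B = B, noise)
  colnames(m) <- c("A", "B", sprintf("n%02d", 1:6))
  rownames(m) <- sprintf("g%03d", seq_len(n))
  truth <- m
  mask <- sample(n, n / 10)
  m[mask, "B"] <- NA
  tab <- feature_table(m, tibble::tibble(feature = colnames(m),
                                         family = "expression",
                                         tissue = "general"))
  out <- impute_features(tab, iterations = 10, neighbors = 5)
  rmse <- sqrt(mean((out$table$values[mask, "B"] - truth[mask, "B"])^2))
  median_rmse <- sqrt(mean((median(m[-mask, "B"]) - truth[mask, "B"])^2))
  expect_lt(rmse, 0.1)
  expect_gt(median_rmse, 0.5)
  # observed cells never change
  expect_identical(out$table$values[-mask, "B"], truth[-mask, "B"])
})

test_that("degenerate features are dropped or skipped, not crashed on", {
  tab <- random_table(30, 4, seed = 5)
  tab$values[, 2] <- NA
  expect_warning(out <- impute_features(tab), "no observed values")
  expect_false("f002" %in% colnames(out$table$values))
  expect_false(anyNA(out$table$values))
})

test_that("imputation converges: late sweeps move cells less than early ones", {
  set.seed(6)
  m <- matrix(rnorm(200 * 8), 200, 8,
              dimnames = list(sprintf("g%03d", 1:200), paste0("f", 1:8)))
  m[, 2] <- 1.5 * m[, 1] + rnorm(200, sd = 0.3)
  m[, 3] <- -m[, 1] + 0.5 * m[, 2] + rnorm(200, sd = 0.3)
  mask <- is.na(m)
  for (j in 2:4) m[sample(200, 30), j] <- NA
  mask <- is.na(m)
  tab <- feature_table(m, tibble::tibble(feature = colnames(m),
                                         family = "expression",
                                         tissue = "general"))
  vals <- lapply(c(1, 2, 9, 10), function(it) {
    impute_features(tab, iterations = it, neighbors = 5)$table$values[mask]
  })
  d_early <- mean(abs(vals[[2]] - vals[[1]]))
  d_late <- mean(abs(vals[[4]] - vals[[3]]))
  expect_lt(d_late, d_early)
})

test_that("Yeo-Johnson fit recovers lambda = 1 for normal data", {
  set.seed(1)
  x <- rnorm(2000)
  lam <- tissuetrace:::fit_yeo_johnson(x)
  expect_lt(abs(lam - 1), 0.1)
})

test_that("Yeo-Johnson reduces skew and preserves ranks", {
  set.seed(2)
  x <- rexp(2000)
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  m <- cbind(e = x)
  rownames(m) <- sprintf("g%04d", seq_along(x))
  tab <- feature_table(m, tibble::tibble(feature = "e",
                                         family = "expression",
                                         tissue = "general"))
  out <- transform_features(tab)
  expect_lt(abs(skew(out$table$values[, "e"])), abs(skew(x)))
  expect_identical(unname(rank(out$table$values[, "e"])), rank(x))
  # non-listed families untouched
  tab2 <- feature_table(m, tibble::tibble(feature = "e", family = "eqtl",
                                          tissue = "general"))
  expect_identical(transform_features(tab2)$table$values, m)
})

test_that("fitted lambda agrees with the established power-transform fit", {
  skip_if_not_installed("car")
  set.seed(3)
  x <- rexp(1500) + 0.2
  lam <- tissuetrace:::fit_yeo_johnson(x)
  oracle <- car::powerTransform(x, family = "yjPower")$lambda
  expect_equal(unname(lam), unname(oracle), tolerance = 0.02)
})

test_that("scaling maps onto [-1, 1] affinely with the declared conventions", {
  m <- cbind(a = c(0, 5, 10), b = c(3, 3, 3), c = c(2, 1, 7))
  rownames(m) <- c("g1", "g2", "g3")
  tab <- feature_table(m, tibble::tibble(feature = colnames(m),
                                         family = "expression",
                                         tissue = "general"))
  out <- scale_features(tab)
  expect_equal(unname(out$table$values[, "a"]), c(-1, 0, 1))
  expect_equal(unname(out$table$values[, "b"]), c(0, 0, 0))
  expect_equal(cor(out$table$values[, "c"], m[, "c"], method = "spearman"), 1)
})

test_that("full preprocessing pipeline satisfies its contract", {
  prep <- small_prep()
  raw <- small_features()$table
  expect_false(anyNA(prep$table$values))
  expect_true(all(prep$table$values >= -1 & prep$table$values <= 1))
  expect_identical(rownames(prep$table$values), rownames(raw$values))
  # per-column rank preservation through transform + scale for observed
  # cells of a transformed family
  f <- prep$table$meta$feature[prep$table$meta$family == "expression"][1]
  obs <- !is.na(raw$values[, f])
  expect_identical(rank(prep$table$values[obs, f]),
                   rank(raw$values[obs, f]))
})

test_that("frozen state reproduces training-time preprocessing on new rows", {
  fx <- small_features()
  genes <- rownames(fx$table$values)
  tr <- genes[seq_len(length(genes) - 40L)]
  te <- setdiff(genes, tr)
  tab_tr <- feature_table(fx$table$values[tr, ], fx$table$meta)
  tab_te <- feature_table(fx$table$values[te, ], fx$table$meta)
  prep <- suppressWarnings(preprocess_features(tab_tr))
  out_te <- apply_preprocess(prep$state, tab_te)
  expect_false(anyNA(out_te$values))
  expect_identical(colnames(out_te$values), colnames(prep$table$values))
  # state application is deterministic
  expect_identical(out_te$values, apply_preprocess(prep$state, tab_te)$values)
})
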
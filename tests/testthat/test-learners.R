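sep_data <- function(n = 500, seed = 1, prevalence = 0.3) {
  set.seed(seed)
  y <- rbinom(n, 1, prevalence)
  X <- cbind(f1 = rnorm(n, mean = 3 * y), f2 = rnorm(n, mean = -2 * y),
             matrix(rnorm(n * 4), n, 4,
                    dimnames = list(NULL, paste0("n", 1:4))))
  rownames(X) <- sprintf("g%04d", seq_len(n))
  # make classes linearly separable on f1
  X[, "f1"] <- ifelse(y == 1, abs(X[, "f1"]) + 1.5, -abs(X[, "f1"]) - 0.5)
  list(X = X, y = y)
}

test_that("L1 selection finds an informative feature among pure noise", {
  set.seed(2)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  X <- matrix(rnorm(n * 100), n, 100,
              dimnames = list(NULL, sprintf("f%03d", 1:100)))
  X[, "f001"] <- X[, "f001"] + 3 * y  # 3-sigma mean shift
  sel <- select_features_l1(X, y, C = 0.1)
  expect_true("f001" %in% sel)
  expect_true(!anyDuplicated(sel) && all(sel %in% colnames(X)))
  expect_error(select_features_l1(X, rep(1, n)), "both classes")
})

test_that("the selection cap keeps the largest coefficients only", {
  set.seed(3)
  n <- 300
  X <- matrix(rnorm(n * 120), n, 120,
              dimnames = list(NULL, sprintf("f%03d", 1:120)))
  beta <- c(seq(2, 0.2, length.out = 60), rep(0, 60))
  y <- as.integer(plogis(X %*% beta) > runif(n))
  sel_all <- select_features_l1(X, y, C = 2)
  skip_if(length(sel_all) <= 20, "selection too sparse to exercise the cap")
  sel_cap <- select_features_l1(X, y, C = 2, cap = 20)
  expect_length(sel_cap, 20L)
  expect_identical(sel_cap, sel_all[seq_len(20)])
})

test_that("every base learner separates linearly separable data in-sample", {
  d <- sep_data()
  cfg <- trace_config(seed = 5)
  fits <- fit_base_learners(d$X, d$y, cfg, selected = colnames(d$X))
  probs <- predict_base_learners(fits, d$X)
  expect_true(all(probs >= 0 & probs <= 1))
  for (l in c("rf", "lr", "lrgb", "mlp")) {
    expect_equal(tissuetrace:::rank_auc(probs[, l], d$y), 1.0,
                 tolerance = 1e-8, label = paste("AUC of", l))
  }
  # the boosted learner carries the 0.01 positive weight, which leaves a
  # handful of near-ties on its deep trees
  expect_gte(tissuetrace:::rank_auc(probs[, "xgb"], d$y), 0.999)
})

test_that("refits with a fixed seed are identical", {
  d <- sep_data(n = 200, seed = 8)
  cfg <- trace_config(seed = 9)
  f1 <- fit_base_learners(d$X, d$y, cfg, colnames(d$X), seed = 42)
  f2 <- fit_base_learners(d$X, d$y, cfg, colnames(d$X), seed = 42)
  expect_identical(predict_base_learners(f1, d$X),
                   predict_base_learners(f2, d$X))
})

test_that("score scaling is the declared affine map with its conventions", {
  expect_equal(scale_scores(c(0.1, 0.5, 0.9)), c(0, 5, 10))
  expect_equal(scale_scores(rep(0.3, 4)), rep(5, 4))
  set.seed(1)
  v <- runif(50)
  expect_identical(rank(scale_scores(v)), rank(v))
})

test_that("the meta-learner recovers a single informative base learner", {
  set.seed(4)
  n <- 2000
  y <- rbinom(n, 1, 0.1)
  informative <- scale_scores(y + rnorm(n, sd = 0.4))
  base <- cbind(b1 = informative,
                b2 = scale_scores(runif(n)), b3 = scale_scores(runif(n)),
                b4 = scale_scores(runif(n)), b5 = scale_scores(runif(n)))
  tr <- seq_len(n) %% 2 == 0
  cfg <- trace_config(seed = 6)
  meta <- fit_meta_learner(base[tr, ], y[tr], cfg)
  p <- tissuetrace:::predict_mlp(meta, base[!tr, ])
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(tissuetrace:::rank_auc(p, y[!tr]), 0.95)
  # row equivariance: permuting genes permutes outputs identically
  perm <- sample(sum(!tr))
  expect_equal(tissuetrace:::predict_mlp(meta, base[!tr, ][perm, ]),
               p[perm], tolerance = 1e-12)
  expect_error(fit_meta_learner(base, rep(0L, n), cfg), "both classes")
})

test_that("cross-validation is stratified, disjoint, and leak-free", {
  prep <- small_prep()
  labs <- small_labels("heart")
  cv <- trace_cv(prep$table, labs, trace_config(seed = 7))
  s <- cv$scores
  expect_setequal(s$gene, rownames(prep$table$values))
  expect_equal(sort(unique(s$fold)), 1:10)
  # stratification: fold positive counts within one gene of each other
  pos_per_fold <- table(s$fold[s$label == 1])
  expect_lte(diff(range(pos_per_fold)), 1)
  expect_true(all(s$trace_score >= 0 & s$trace_score <= 10))
  base_cols <- c("xgb", "rf", "lr", "lrgb", "mlp")
  expect_true(all(as.matrix(s[base_cols]) >= 0 &
                    as.matrix(s[base_cols]) <= 10))
  expect_error(trace_cv(prep$table,
                        dplyr::mutate(labs, label = 0L),
                        trace_config()),
               "fewer folds")
})

test_that("swapping the labels reverses the ranking direction", {
  prep <- small_prep()
  labs <- small_labels("heart")
  cfg <- trace_config(seed = 19)
  cv_fwd <- trace_cv(prep$table, labs, cfg)
  flipped <- dplyr::mutate(labs, label = 1L - label)
  cv_rev <- trace_cv(prep$table, flipped, cfg)
  # scores from flipped training rank the ORIGINAL labels in reverse
  y <- labs$label[match(cv_rev$scores$gene, labs$gene)]
  a1 <- tissuetrace:::rank_auc(cv_fwd$scores$trace_score,
                               labs$label[match(cv_fwd$scores$gene,
                                                labs$gene)])
  a2 <- tissuetrace:::rank_auc(cv_rev$scores$trace_score, y)
  expect_lt(abs(a2 - (1 - a1)), 0.05)
})

test_that("evaluation metrics match their definitions and oracles", {
  perfect <- tibble::tibble(gene = letters[1:6],
                            score = 6:1,
                            label = c(1L, 1L, 0L, 0L, 0L, 0L))
  ev <- evaluate_scores(perfect)
  expect_equal(ev$auc, 1)
  expect_equal(ev$auprc, 1)

  set.seed(5)
  n <- 10000
  rnd <- tibble::tibble(gene = as.character(seq_len(n)),
                        score = runif(n),
                        label = rbinom(n, 1, 0.04))
  ev2 <- evaluate_scores(rnd)
  expect_lt(abs(ev2$auprc - 0.04), 0.01)
  expect_equal(ev2$expected_auprc, mean(rnd$label))

  # rank-based AUC agrees with an established ROC implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(
      tissuetrace:::rank_auc(rnd$score, rnd$label),
      as.numeric(suppressMessages(pROC::auc(rnd$label, rnd$score))),
      tolerance = 1e-12)
  }

  # Mann-Whitney p equals exact enumeration on a tiny example
  g <- tibble::tibble(gene = as.character(1:6),
                      score = c(4, 5, 6, 1, 2, 3),
                      label = c(1L, 1L, 1L, 0L, 0L, 0L),
                      group = rep(c("tissue_associated", "non_disease"),
                                  each = 3))
  ev3 <- evaluate_scores(g)
  p_exact <- mw_exact_oracle(c(4, 5, 6), c(1, 2, 3))
  expect_equal(
    ev3$mw$p_value[ev3$mw$comparison == "tissue_associated_vs_non_disease"],
    p_exact)
  expect_error(evaluate_scores(dplyr::mutate(perfect, label = 0L)),
               "single class")
})
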
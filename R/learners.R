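#' Configuration of the two-layer stacked learner
#'
#' All hyperparameters of the five base learners and the neural
#' meta-learner, fixed to the published values; no hyperparameter search is
#' performed. The positive:negative class weight of 0.01 is applied when
#' training the gradient-boosted forest, the random forest, the logistic
#' regression, and the logistic part of the logistic-initiated boosting —
#' but not the neural learners.
#'
#' @param folds Stratified cross-validation folds (default 10).
#' @param class_weight_pos Weight of positives relative to negatives
#'   (default 0.01).
#' @param selection_C Regularization C of the sparse linear selector used
#'   before the boosted, logistic and logistic-initiated learners
#'   (default 0.1).
#' @param interpret_C,interpret_cap Selector C and feature cap for
#'   interpretability models (defaults 2 and 50).
#' @param seed Integer seed funneling all randomness.
#' @return List of class `trace_config`.
#' @export
trace_config <- function(folds = 10, class_weight_pos = 0.01,
                         selection_C = 0.1, interpret_C = 2,
                         interpret_cap = 50, seed = 1) {
  structure(list(
    folds = as.integer(folds), class_weight_pos = class_weight_pos,
    selection_C = selection_C, interpret_C = interpret_C,
    interpret_cap = as.integer(interpret_cap),
    xgb = list(nrounds = 150, max_depth = 9, gamma = 0, eta = 0.1),
    rf = list(num_trees = 1000),
    lr = list(C = 1, maxit = 100000),
    lrgb = list(nrounds = 80, max_depth = 3, eta = 0.1),
    mlp = list(hidden = c(10, 10), alpha = 0.5, batch_size = 200),
    meta = list(hidden = c(10, 10), alpha = 0.1, lr_init = 0.01),
    seed = as.integer(seed)
  ), class = "trace_config")
}

#' Sparse linear feature selection
#'
#' Selects the features with nonzero coefficients of an L1-regularized
#' linear classifier (lambda = 1 / (n C)); with `cap` given and exceeded,
#' the cap largest-|coefficient| features are kept (ties broken by feature
#' id). Fitted on the supplied training rows only.
#'
#' @param X Numeric matrix (rows = genes).
#' @param y 0/1 labels.
#' @param C Regularization parameter; larger C keeps more features.
#' @param cap Optional upper bound on the number of selected features.
#' @return Character vector of selected feature names.
#' @export
select_features_l1 <- function(X, y, C = 0.1, cap = NULL) {
  if (length(unique(y)) < 2L) {
    stop("feature selection needs both classes present", call. = FALSE)
  }
  # Warm-started path down to the target lambda; a cold single-lambda fit
  # of the coordinate-descent solver often fails to converge.
  lam <- 1 / (nrow(X) * C)
  path <- lam * 2^seq(10, 0, length.out = 25)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = path, standardize = FALSE)
  beta <- as.matrix(fit$beta)[, ncol(fit$beta)]
  nz <- beta[beta != 0]
  if (length(nz) == 0L) {
    warning("L1 selection kept no features; falling back to all features",
            call. = FALSE)
    return(colnames(X))
  }
  ord <- order(-abs(nz), names(nz))
  sel <- names(nz)[ord]
  if (!is.null(cap) && length(sel) > cap) sel <- sel[seq_len(cap)]
  sel
}

learner_names <- c("xgb", "rf", "lr", "lrgb", "mlp")

# base_score pinned at 0.5: the historical default the published
# hyperparameters were tuned under (newer xgboost auto-estimates it from
# the weighted label mean, which degenerates under the 0.01 class weight).
xgb_params <- function(cfg, weight_pos, extra = list()) {
  c(list(objective = "binary:logistic", nthread = 1,
         max_depth = cfg$max_depth, eta = cfg$eta,
         gamma = cfg$gamma %||% 0, base_score = 0.5,
         scale_pos_weight = weight_pos), extra)
}

#' Fit the five base learners
#'
#' Gradient-boosted decision forest (150 trees, depth 9, eta 0.1, gamma 0),
#' random forest (1000 trees), ridge-penalized logistic regression,
#' gradient boosting initiated from the fitted logistic model (80 trees),
#' and a two-hidden-layer (10, 10) ReLU perceptron. Feature selection is
#' applied beforehand to the boosted, logistic and logistic-initiated
#' learners but not to the random forest or the perceptron, which handle
#' noncontributing features inherently.
#'
#' @param X Preprocessed feature matrix (no missing values, scaled).
#' @param y 0/1 labels.
#' @param config A [trace_config()].
#' @param selected Feature names from [select_features_l1()].
#' @param seed Integer seed for this fit.
#' @return List of class `tt_base_fits`.
#' @export
fit_base_learners <- function(X, y, config, selected, seed = config$seed) {
  if (length(unique(y)) < 2L) {
    stop("degenerate training set: a single class", call. = FALSE)
  }
  w <- ifelse(y == 1L, config$class_weight_pos, 1)
  Xs <- X[, selected, drop = FALSE]

  dtr <- xgboost::xgb.DMatrix(Xs, label = y, nthread = 1)
  xgb <- xgboost::xgb.train(
    params = xgb_params(config$xgb, config$class_weight_pos,
                        list(seed = seed)),
    data = dtr, nrounds = config$xgb$nrounds, verbose = 0)

  rf <- ranger::ranger(
    y = factor(y, levels = c(0L, 1L)), x = as.data.frame(X),
    num.trees = config$rf$num_trees, probability = TRUE,
    class.weights = c("0" = 1, "1" = config$class_weight_pos),
    num.threads = 1, seed = seed)

  # glmnet needs >= 2 columns; pad single-feature selections with a zero
  # dummy whose coefficient is inert.
  pad <- ncol(Xs) < 2L
  Xlr <- if (pad) cbind(Xs, `.dummy` = 0) else Xs
  lr <- glmnet::glmnet(Xlr, y, family = "binomial", alpha = 0,
                       lambda = 1 / (nrow(Xlr) * config$lr$C),
                       weights = w, standardize = FALSE,
                       maxit = config$lr$maxit)

  lr_margin <- qlogis(pmin(pmax(
    predict(lr, Xlr, type = "response")[, 1L], 1e-8), 1 - 1e-8))
  dtr2 <- xgboost::xgb.DMatrix(Xs, label = y, base_margin = lr_margin,
                               nthread = 1)
  lrgb <- xgboost::xgb.train(
    params = xgb_params(config$lrgb, 1, list(seed = seed + 1L)),
    data = dtr2, nrounds = config$lrgb$nrounds, verbose = 0)

  mlp <- fit_mlp(X, y, hidden = config$mlp$hidden,
                 alpha = config$mlp$alpha,
                 batch_size = config$mlp$batch_size,
                 solver = "adam", seed = seed + 2L)

  structure(list(xgb = xgb, rf = rf, lr = lr, lrgb = lrgb, mlp = mlp,
                 selected = selected, lr_pad = pad,
                 features = colnames(X)),
            class = "tt_base_fits")
}

#' Predict base-learner probabilities for new genes
#' @param fits A `tt_base_fits`.
#' @param X Feature matrix with the training-time columns.
#' @return Matrix genes x 5 of probabilities in `[0, 1]`.
#' @export
predict_base_learners <- function(fits, X) {
  Xs <- X[, fits$selected, drop = FALSE]
  dte <- xgboost::xgb.DMatrix(Xs, nthread = 1)
  Xlr <- if (isTRUE(fits$lr_pad)) cbind(Xs, `.dummy` = 0) else Xs
  p_lr <- predict(fits$lr, Xlr, type = "response")[, 1L]
  dte2 <- xgboost::xgb.DMatrix(
    Xs, base_margin = qlogis(pmin(pmax(p_lr, 1e-8), 1 - 1e-8)),
    nthread = 1)
  out <- cbind(
    xgb = predict(fits$xgb, dte),
    rf = predict(fits$rf, data = as.data.frame(X),
                 num.threads = 1)$predictions[, "1"],
    lr = p_lr,
    lrgb = predict(fits$lrgb, dte2),
    mlp = predict_mlp(fits$mlp, X)
  )
  rownames(out) <- rownames(X)
  out
}

#' Scale a score vector onto [0, 10]
#'
#' Affine (rank-preserving) map of the vector onto 0 (not tissue
#' associated) to 10 (tissue-associated disease gene); a constant vector
#' maps to 5 everywhere.
#'
#' @param raw Numeric vector of finite scores.
#' @return Numeric vector in `[0, 10]`.
#' @export
scale_scores <- function(raw) {
  stopifnot(all(is.finite(raw)))
  scale_minmax(raw, 0, 10)
}

#' Fit the neural meta-learner on base-learner scores
#'
#' A two-hidden-layer (10, 10) ReLU perceptron with L2 penalty 0.1 and an
#' adaptive learning rate initiated at 0.01, trained on the (out-of-fold)
#' scaled scores of the five base learners.
#'
#' @param base_scores Matrix genes x 5 of scaled base scores.
#' @param y 0/1 labels.
#' @param config A [trace_config()].
#' @param seed Integer seed.
#' @return A fitted `tt_mlp`.
#' @export
fit_meta_learner <- function(base_scores, y, config, seed = config$seed) {
  if (length(unique(y)) < 2L) {
    stop("meta-learner needs both classes present", call. = FALSE)
  }
  fit_mlp(base_scores, y, hidden = config$meta$hidden,
          alpha = config$meta$alpha, batch_size = config$mlp$batch_size,
          solver = "sgd", learning_rate_init = config$meta$lr_init,
          adaptive = TRUE, seed = seed)
}

# Out-of-fold base-learner probabilities under stratified k-fold CV.
cv_base_scores <- function(X, y, config) {
  k <- config$folds
  if (sum(y == 1L) < k) {
    stop(sprintf(
      "only %d positives for %d folds; use fewer folds", sum(y == 1L), k),
      call. = FALSE)
  }
  set.seed(child_seed(config$seed, "folds"))
  fold <- stratified_folds(y, k)
  oof <- matrix(NA_real_, nrow(X), length(learner_names),
                dimnames = list(rownames(X), learner_names))
  selected <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    sel <- select_features_l1(X[tr, , drop = FALSE], y[tr],
                              C = config$selection_C)
    fits <- fit_base_learners(X[tr, , drop = FALSE], y[tr], config, sel,
                              seed = child_seed(config$seed, "learner") + f)
    oof[!tr, ] <- predict_base_learners(fits, X[!tr, , drop = FALSE])
    selected[[f]] <- sel
  }
  list(oof = oof, fold = fold, selected = selected)
}

#' Stratified cross-validated stacked scores for one tissue
#'
#' Genes are partitioned into `folds` stratified folds. Per fold, feature
#' selection and the five base learners are fitted on the other folds and
#' the held-out fold is scored, so every gene's base scores come from
#' models that never saw it. Per-learner out-of-fold scores are scaled to
#' `[0, 10]`; the meta-learner is then trained, per fold, on the scaled
#' scores of the other folds and applied to the held-out fold. Final scores
#' are scaled to `[0, 10]`.
#'
#' @param table A preprocessed `feature_table` (or numeric matrix).
#' @param labels Data frame `gene`, `label` (and optionally `group`)
#'   aligned with the table's genes, e.g. from
#'   [label_genes_for_tissue()].
#' @param config A [trace_config()].
#' @return Object of class `trace_cv`: `scores` tibble (gene, label, fold,
#'   one column per base learner, `trace_score`), `metrics` (see
#'   [glance.trace_cv()]), `selected` features per fold.
#' @export
trace_cv <- function(table, labels, config = trace_config()) {
  X <- if (inherits(table, "feature_table")) table$values else table
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("gene", "label") %in% names(labels)))
  labels <- labels[match(rownames(X), labels$gene), ]
  y <- labels$label
  cvb <- cv_base_scores(X, y, config)
  base_scaled <- apply(cvb$oof, 2L, scale_scores)
  rownames(base_scaled) <- rownames(X)

  meta_prob <- rep(NA_real_, nrow(X))
  for (f in seq_len(config$folds)) {
    tr <- cvb$fold != f
    meta <- fit_meta_learner(base_scaled[tr, , drop = FALSE], y[tr], config,
                             seed = child_seed(config$seed, "meta") + f)
    meta_prob[!tr] <- predict_mlp(meta, base_scaled[!tr, , drop = FALSE])
  }
  trace_score <- scale_scores(meta_prob)

  scores <- tibble::tibble(gene = rownames(X), label = y,
                           fold = cvb$fold) |>
    dplyr::bind_cols(tibble::as_tibble(base_scaled)) |>
    dplyr::mutate(trace_score = trace_score, meta_prob = meta_prob)
  if ("group" %in% names(labels)) scores$group <- labels$group

  per_learner <- purrr::map_dfr(learner_names, function(l) {
    fold_auc <- vapply(seq_len(config$folds), function(f) {
      idx <- cvb$fold == f
      rank_auc(cvb$oof[idx, l], y[idx])
    }, numeric(1))
    tibble::tibble(
      learner = l,
      auc = rank_auc(cvb$oof[, l], y),
      auprc = average_precision(cvb$oof[, l], y),
      auc_fold_mean = mean(fold_auc), auc_fold_sd = sd(fold_auc),
      fpr_at_half = mean(cvb$oof[y == 0L, l] >= 0.5),
      fnr_at_half = mean(cvb$oof[y == 1L, l] < 0.5)
    )
  })
  meta_fold_auc <- vapply(seq_len(config$folds), function(f) {
    idx <- cvb$fold == f
    rank_auc(meta_prob[idx], y[idx])
  }, numeric(1))
  metrics <- dplyr::bind_rows(per_learner, tibble::tibble(
    learner = "meta",
    auc = rank_auc(meta_prob, y),
    auprc = average_precision(meta_prob, y),
    auc_fold_mean = mean(meta_fold_auc), auc_fold_sd = sd(meta_fold_auc),
    fpr_at_half = mean(meta_prob[y == 0L] >= 0.5),
    fnr_at_half = mean(meta_prob[y == 1L] < 0.5)
  ))

  structure(list(scores = scores, metrics = metrics,
                 selected = cvb$selected, config = config),
            class = "trace_cv")
}

#' @export
print.trace_cv <- function(x, ...) {
  m <- x$metrics[x$metrics$learner == "meta", ]
  cat(sprintf("stacked CV scores: %d genes (%d positives), meta AUC %.3f, %s\n",
              nrow(x$scores), sum(x$scores$label),
              m$auc, sprintf("auPRC %.3f", m$auprc)))
  invisible(x)
}

#' Tidy cross-validated scores
#' @param x A `trace_cv`.
#' @param ... Unused.
#' @return The per-gene score tibble.
#' @method tidy trace_cv
#' @export
tidy.trace_cv <- function(x, ...) x$scores

#' One-row-per-learner performance summary
#' @param x A `trace_cv`.
#' @param ... Unused.
#' @return Tibble with AUC, auPRC (with the prevalence baseline), and the
#'   error rates at the 0.5-probability operating point.
#' @method glance trace_cv
#' @export
glance.trace_cv <- function(x, ...) {
  dplyr::mutate(x$metrics,
                expected_auprc = mean(x$scores$label), .after = "auprc")
}

#' Evaluate a score vector against labels and gene groups
#'
#' AUC, auPRC with its prevalence baseline, and Mann-Whitney comparisons of
#' the tissue-associated genes' scores against the non-disease and the
#' other-disease genes (Benjamini-Hochberg adjustment across tissues is
#' applied by the caller when several tissues are evaluated).
#'
#' @param scores Data frame `gene`, `score`, `label`, and optionally
#'   `group`.
#' @return List with `auc`, `auprc`, `expected_auprc`, and `mw` (tibble of
#'   group comparisons, NULL without groups).
#' @export
evaluate_scores <- function(scores) {
  scores <- tibble::as_tibble(scores)
  out <- list(auc = rank_auc(scores$score, scores$label),
              auprc = average_precision(scores$score, scores$label),
              expected_auprc = mean(scores$label))
  if ("group" %in% names(scores)) {
    ta <- scores$score[scores$group == "tissue_associated"]
    out$mw <- purrr::map_dfr(c("non_disease", "other_disease"), function(g) {
      other <- scores$score[scores$group == g]
      p <- if (length(other) == 0L) NA_real_ else
        suppressWarnings(wilcox.test(ta, other,
                                     alternative = "greater")$p.value)
      tibble::tibble(comparison = paste0("tissue_associated_vs_", g),
                     p_value = p)
    })
  }
  out
}
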
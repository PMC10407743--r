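# Model explanation: Shapley additive attributions on the gradient-boosted
# interpretability model, importance normalization, and aggregation by
# feature family and tissue of origin.

# Interpretability models carry no class weighting: the 0.01
# positive:negative weight is specified for the prediction framework's
# learners, and a weighted boosted model degenerates to a stump at desk
# scale, which would make its attributions vacuous.
fit_interpret_xgb <- function(X, y, config, seed = config$seed) {
  sel <- select_features_l1(X, y, C = config$interpret_C,
                            cap = config$interpret_cap)
  dtr <- xgboost::xgb.DMatrix(X[, sel, drop = FALSE], label = y,
                              nthread = 1)
  bst <- xgboost::xgb.train(
    params = xgb_params(config$xgb, 1, list(seed = seed)),
    data = dtr, nrounds = config$xgb$nrounds, verbose = 0)
  list(model = bst, selected = sel)
}

# Shapley attributions (tree algorithm) for rows of X on the fitted model;
# returns list(contrib matrix with BIAS column, margin vector).
shap_contrib <- function(fit, X) {
  dte <- xgboost::xgb.DMatrix(X[, fit$selected, drop = FALSE], nthread = 1)
  contrib <- predict(fit$model, dte, predcontrib = TRUE)
  margin <- predict(fit$model, dte, outputmargin = TRUE)
  list(contrib = contrib, margin = margin)
}

#' Explain a single gene's tissue association
#'
#' Trains a gradient-boosted model on every gene except the query
#' (leave-one-out), with sparse linear feature selection capped at
#' `interpret_cap` features, labels taken from the query's affected
#' tissue. The query gene's prediction is then decomposed into additive
#' Shapley attributions (tree algorithm), whose sum plus the expected
#' model output equals the query's margin score.
#'
#' @param table A preprocessed `feature_table`.
#' @param labels Data frame `gene`, `label` for the affected tissue.
#' @param query_gene Gene id to explain.
#' @param config A [trace_config()].
#' @return List of class `tt_gene_explanation`: `attributions` tibble
#'   (feature, attribution, family, tissue), `base_value`, `margin`,
#'   `top_feature`, `model`.
#' @export
explain_gene <- function(table, labels, query_gene,
                         config = trace_config()) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values
  if (!query_gene %in% rownames(X)) {
    stop(sprintf("query gene '%s' is not in the feature table", query_gene),
         call. = FALSE)
  }
  labels <- tibble::as_tibble(labels)
  labels <- labels[match(rownames(X), labels$gene), ]
  train <- rownames(X) != query_gene
  fit <- fit_interpret_xgb(X[train, , drop = FALSE], labels$label[train],
                           config)
  sh <- shap_contrib(fit, X[!train, , drop = FALSE])
  k <- ncol(sh$contrib)
  attr_tbl <- tibble::tibble(
    feature = colnames(sh$contrib)[-k],
    attribution = sh$contrib[1L, -k]
  ) |>
    dplyr::left_join(table$meta, by = "feature") |>
    dplyr::arrange(dplyr::desc(abs(.data$attribution)))
  structure(list(
    attributions = attr_tbl,
    base_value = sh$contrib[1L, k],
    margin = sh$margin[1L],
    top_feature = attr_tbl$feature[1L],
    train_genes = rownames(X)[train],
    model = fit
  ), class = "tt_gene_explanation")
}

#' Per-feature Shapley importance of a tissue model
#'
#' Fits the interpretability gradient-boosted model on all genes with the
#' tissue's labels, computes Shapley attributions for every gene, and
#' summarizes per-feature importance as the mean absolute attribution,
#' normalized by the sum over features so importances sum to one. Features
#' never selected have importance exactly zero.
#'
#' @param table A preprocessed `feature_table`.
#' @param labels Data frame `gene`, `label` for the tissue.
#' @param config A [trace_config()].
#' @return Object of class `tt_importance`: tibble `importance` (feature,
#'   importance, normalized_importance, family, tissue), plus the fitted
#'   model and per-gene attribution matrix.
#' @export
tissue_importances <- function(table, labels, config = trace_config()) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values
  labels <- tibble::as_tibble(labels)
  labels <- labels[match(rownames(X), labels$gene), ]
  fit <- fit_interpret_xgb(X, labels$label, config)
  sh <- shap_contrib(fit, X)
  k <- ncol(sh$contrib)
  raw <- colMeans(abs(sh$contrib[, -k, drop = FALSE]))
  imp <- setNames(rep(0, ncol(X)), colnames(X))
  imp[names(raw)] <- raw
  total <- sum(imp)
  norm <- if (total > 0) imp / total else imp
  tbl <- tibble::tibble(feature = names(imp), importance = unname(imp),
                        normalized_importance = unname(norm)) |>
    dplyr::left_join(table$meta, by = "feature")
  structure(list(importance = tbl, model = fit,
                 contrib = sh$contrib, margin = sh$margin,
                 genes = rownames(X)),
            class = "tt_importance")
}

#' @export
print.tt_importance <- function(x, ...) {
  top <- dplyr::slice_max(x$importance, .data$normalized_importance, n = 5L)
  cat("tissue model importances (top 5):\n")
  print(top[, c("feature", "normalized_importance", "family", "tissue")])
  invisible(x)
}

#' Aggregate normalized importances by family or tissue of origin
#'
#' Sums the normalized Shapley importances of features sharing the
#' aggregation key. Because the groups partition the features, the group
#' values sum to one. With `modeled_tissues` given, tissues of origin
#' outside that set collapse into `"Other"`.
#'
#' @param report A `tt_importance` (or its `importance` tibble).
#' @param key `"family"` or `"tissue"`.
#' @param modeled_tissues Optional tissues kept as named groups when
#'   aggregating by tissue; `"general"` is always kept.
#' @return Tibble `group`, `value`, sorted descending; groups with no
#'   features are absent rather than zero rows.
#' @export
aggregate_importances <- function(report, key = c("family", "tissue"),
                                  modeled_tissues = NULL) {
  key <- match.arg(key)
  tbl <- if (inherits(report, "tt_importance")) report$importance else
    tibble::as_tibble(report)
  if (anyNA(tbl[[key]])) {
    stop("feature(s) without metadata cannot be aggregated", call. = FALSE)
  }
  g <- tbl[[key]]
  if (key == "tissue" && !is.null(modeled_tissues)) {
    keep <- g %in% c(modeled_tissues, "general")
    g[!keep] <- "Other"
  }
  out <- tibble::tibble(group = g, v = tbl$normalized_importance) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(value = sum(.data$v), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$value))
  out
}
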
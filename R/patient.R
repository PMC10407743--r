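# Patient-tailored prioritization: the patient's candidate genes are
# entirely withheld from every fitted statistic (imputation, transforms,
# scaling, feature selection, learners), then scored by a stacked model
# trained on the remaining genes and ranked.

#' Score and rank a patient's candidate genes (leave-candidates-out)
#'
#' Preprocessing is refit on the non-candidate genes only; candidates are
#' transformed with the frozen training-time state. The base learners score
#' the non-candidates out-of-fold through stratified cross-validation, are
#' refit on all non-candidates to score the candidates, and the
#' meta-learner — trained once on the non-candidates' out-of-fold base
#' scores — produces the final 0-10 scores. Candidates are ranked by
#' descending score, ties broken lexicographically by gene id (competition
#' ranking, recorded in the output metadata).
#'
#' @param raw_table The unpreprocessed `feature_table` over all genes
#'   (candidates included).
#' @param associations Disease-gene-tissue association table.
#' @param case One-row case: list or tibble row with `patient`, `tissue`
#'   (the affected tissue to model), `candidates` (character vector or
#'   list-column), optional `verified_gene`.
#' @param config A [trace_config()].
#' @param impute_iterations,impute_neighbors Preprocessing parameters.
#' @return Object of class `tt_rank`: `ranking` tibble (patient, tissue,
#'   gene, score, rank, quantile flags), `unscored` (candidates absent from
#'   the table), `verified_rank`, `n_candidates`, and `train_genes` for
#'   leakage audits.
#' @export
score_candidates <- function(raw_table, associations, case,
                             config = trace_config(),
                             impute_iterations = 10,
                             impute_neighbors = 100) {
  stopifnot(inherits(raw_table, "feature_table"))
  candidates <- unlist(case$candidates, use.names = FALSE)
  tissue <- case$tissue[[1L]]
  genes <- rownames(raw_table$values)
  unscored <- setdiff(candidates, genes)
  candidates <- intersect(candidates, genes)
  train_genes <- setdiff(genes, candidates)

  train_tab <- feature_table(
    raw_table$values[train_genes, , drop = FALSE], raw_table$meta)
  cand_tab <- feature_table(
    raw_table$values[candidates, , drop = FALSE], raw_table$meta)
  prep <- preprocess_features(train_tab, iterations = impute_iterations,
                              neighbors = impute_neighbors)
  cand_prep <- apply_preprocess(prep$state, cand_tab)

  # Associations referencing withheld candidates are expected here; the
  # unknown-gene warning is only meaningful for catalog labeling.
  labels <- suppressWarnings(
    label_genes_for_tissue(associations, train_genes, tissue))
  y <- labels$label[match(train_genes, labels$gene)]
  X <- prep$table$values
  cvb <- cv_base_scores(X, y, config)

  # Per-learner affine maps fitted on the out-of-fold training scores and
  # reused for the candidates (clipped into [0, 10]).
  rngs <- apply(cvb$oof, 2L, range)
  scale_with <- function(v, l) {
    lo <- rngs[1L, l]; hi <- rngs[2L, l]
    if (hi == lo) return(rep(5, length(v)))
    pmin(pmax((v - lo) / (hi - lo) * 10, 0), 10)
  }
  base_scaled <- sapply(learner_names,
                        function(l) scale_with(cvb$oof[, l], l))
  rownames(base_scaled) <- train_genes

  sel_full <- select_features_l1(X, y, C = config$selection_C)
  fits <- fit_base_learners(X, y, config, sel_full,
                            seed = child_seed(config$seed, "learner"))
  cand_prob <- predict_base_learners(fits, cand_prep$values)
  cand_scaled <- sapply(learner_names,
                        function(l) scale_with(cand_prob[, l], l))
  if (length(candidates) == 1L) {
    cand_scaled <- matrix(cand_scaled, nrow = 1L,
                          dimnames = list(candidates, learner_names))
  } else {
    rownames(cand_scaled) <- candidates
  }

  meta <- fit_meta_learner(base_scaled, y, config,
                           seed = child_seed(config$seed, "meta"))
  train_meta_prob <- predict_mlp(meta, base_scaled)
  cand_meta_prob <- predict_mlp(meta, cand_scaled)
  mrng <- range(train_meta_prob)
  cand_score <- if (mrng[2] == mrng[1]) rep(5, length(cand_meta_prob)) else
    pmin(pmax((cand_meta_prob - mrng[1]) / (mrng[2] - mrng[1]) * 10, 0), 10)

  build_rank_result(case, tissue, candidates, cand_score,
                    unscored = unscored, train_genes = train_genes)
}

build_rank_result <- function(case, tissue, candidates, score,
                              unscored = character(),
                              train_genes = character()) {
  n <- length(candidates)
  r <- rank_descending(score, candidates)
  ranking <- tibble::tibble(
    patient = case$patient[[1L]] %||% "case",
    tissue = tissue, gene = candidates, score = score, rank = r,
    above_median = r <= ceiling(n / 2),
    top_quartile = r <= ceiling(0.25 * n),
    top_decile = r <= ceiling(0.10 * n)
  ) |>
    dplyr::arrange(.data$rank)
  verified <- case$verified_gene[[1L]] %||% NA_character_
  structure(list(
    ranking = ranking, unscored = unscored, n_candidates = n,
    verified_gene = verified,
    verified_rank = if (!is.na(verified) && verified %in% candidates)
      r[match(verified, candidates)] else NA_integer_,
    train_genes = train_genes,
    tie_rule = "competition ranking, ties broken lexicographically by gene id"
  ), class = "tt_rank")
}

#' @export
print.tt_rank <- function(x, ...) {
  cat(sprintf("candidate ranking (%d candidates%s)\n", x$n_candidates,
              if (!is.na(x$verified_rank))
                sprintf(", verified gene rank %d", x$verified_rank) else ""))
  print(head(x$ranking, 5L))
  invisible(x)
}

#' Rank candidates by tissue expression level
#'
#' The baseline prioritization: candidates ranked by descending median cpm
#' in the modeled tissue (same tie rule as the model ranking). Candidates
#' absent from the expression summary rank as 0 cpm.
#'
#' @param case Case row (see [score_candidates()]).
#' @param med Matrix genes x tissues of median cpm.
#' @param tissue Affected tissue.
#' @return A `tt_rank`.
#' @export
expression_baseline <- function(case, med, tissue) {
  candidates <- unlist(case$candidates, use.names = FALSE)
  expr <- rep(0, length(candidates))
  hit <- candidates %in% rownames(med)
  expr[hit] <- med[candidates[hit], tissue]
  build_rank_result(case, tissue, candidates, expr)
}

#' Compare two candidate rankings across patients
#'
#' One-sided Wilcoxon signed-rank test of the paired verified-gene ranks
#' under the alternative "method A ranks the verified gene better (lower)
#' than method B", plus per-method median verified rank and the fractions
#' of cases with the verified gene above the candidate median, in the top
#' quartile, and in the top decile.
#'
#' @param results_a,results_b Lists of `tt_rank` over the same cases, or
#'   data frames with columns `verified_rank` and `n_candidates`.
#' @return List of class `tt_rank_comparison`.
#' @export
compare_rankings <- function(results_a, results_b) {
  as_df <- function(r) {
    if (is.data.frame(r)) return(tibble::as_tibble(r))
    purrr::map_dfr(r, function(x) tibble::tibble(
      verified_rank = x$verified_rank, n_candidates = x$n_candidates))
  }
  a <- as_df(results_a)
  b <- as_df(results_b)
  stopifnot(nrow(a) == nrow(b))
  if (nrow(a) < 6L) {
    warning("fewer than 6 pairs: exact signed-rank test", call. = FALSE)
  }
  d <- a$verified_rank - b$verified_rank
  p <- if (all(d == 0)) 1 else
    suppressWarnings(wilcox.test(a$verified_rank, b$verified_rank,
                                 paired = TRUE,
                                 alternative = "less")$p.value)
  quant <- function(df) {
    n <- df$n_candidates
    r <- df$verified_rank
    c(above_median = mean(r <= ceiling(n / 2)),
      top_quartile = mean(r <= ceiling(0.25 * n)),
      top_decile = mean(r <= ceiling(0.10 * n)))
  }
  structure(list(
    p_value = p,
    median_rank_a = median(a$verified_rank),
    median_rank_b = median(b$verified_rank),
    quantiles_a = quant(a), quantiles_b = quant(b),
    n_pairs = nrow(a)
  ), class = "tt_rank_comparison")
}

#' @export
print.tt_rank_comparison <- function(x, ...) {
  cat(sprintf(
    "paired ranking comparison over %d cases: median rank %.1f vs %.1f, %s\n",
    x$n_pairs, x$median_rank_a, x$median_rank_b,
    sprintf("one-sided signed-rank p = %.3g", x$p_value)))
  invisible(x)
}

#' Benchmark leave-candidates-out prioritization on synthetic patients
#'
#' Runs [score_candidates()] and the expression baseline for every case and
#' summarizes verified-gene ranks, quantile fractions, the leakage audit,
#' and the paired comparison against the baseline.
#'
#' @param raw_table Unpreprocessed `feature_table` over all genes.
#' @param associations Disease-gene-tissue associations.
#' @param cases Case tibble from [generate_patient_cases()] or
#'   [read_patient_cases()].
#' @param med Matrix of median cpm for the expression baseline.
#' @param config A [trace_config()].
#' @param impute_iterations,impute_neighbors Preprocessing parameters.
#' @return Object of class `tt_benchmark`: `summary` tibble (one row per
#'   case), `comparison` (`tt_rank_comparison` vs the expression
#'   baseline), `leakage_ok`.
#' @export
benchmark_patients <- function(raw_table, associations, cases, med,
                               config = trace_config(),
                               impute_iterations = 10,
                               impute_neighbors = 100) {
  rows <- vector("list", nrow(cases))
  model_res <- vector("list", nrow(cases))
  base_res <- vector("list", nrow(cases))
  leakage_ok <- TRUE
  for (i in seq_len(nrow(cases))) {
    case <- cases[i, ]
    res <- score_candidates(raw_table, associations, case, config,
                            impute_iterations, impute_neighbors)
    bl <- expression_baseline(case, med, case$tissue[[1L]])
    leakage_ok <- leakage_ok &&
      length(intersect(res$train_genes,
                       unlist(case$candidates))) == 0L
    model_res[[i]] <- res
    base_res[[i]] <- bl
    rows[[i]] <- tibble::tibble(
      patient = case$patient[[1L]], tissue = case$tissue[[1L]],
      n_candidates = res$n_candidates,
      verified_rank = res$verified_rank,
      baseline_rank = bl$verified_rank,
      above_median = res$verified_rank <= ceiling(res$n_candidates / 2),
      top_quartile = res$verified_rank <= ceiling(0.25 * res$n_candidates),
      top_decile = res$verified_rank <= ceiling(0.10 * res$n_candidates)
    )
  }
  structure(list(
    summary = dplyr::bind_rows(rows),
    comparison = compare_rankings(model_res, base_res),
    leakage_ok = leakage_ok
  ), class = "tt_benchmark")
}

#' @export
print.tt_benchmark <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "patient benchmark: %d cases, median verified rank %.1f,\n",
    "  above median %.0f%%, top quartile %.0f%%, top decile %.0f%%, %s\n"),
    nrow(s), median(s$verified_rank), 100 * mean(s$above_median),
    100 * mean(s$top_quartile), 100 * mean(s$top_decile),
    sprintf("vs expression baseline p = %.3g", x$comparison$p_value)))
  invisible(x)
}
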
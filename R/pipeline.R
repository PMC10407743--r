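#' Build the full tissue-based gene feature table for a cohort
#'
#' Runs the expression core (TMM normalization, expressed-gene calls,
#' tissue medians, preferential expression, developmental summaries) and
#' every feature family, restricted to genes expressed in at least one
#' tissue, and assembles the annotated gene x feature table.
#'
#' @param bundle A `trace_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param embedding_dims,walks_per_node,walk_len Embedding parameters
#'   (defaults 64, 20, 10).
#' @param variability Optional precomputed adult expression-variability
#'   table (`gene`, `tissue`, `score`).
#' @param seed Seed for the embedding walks (default: the cohort seed).
#' @return Object of class `tt_features`: `table` (raw `feature_table`,
#'   missing values still present), plus the intermediates `norm`,
#'   `expressed`, `med`, `pref`, `dev`.
#' @export
build_features <- function(bundle, embedding_dims = 64, walks_per_node = 20,
                           walk_len = 10, variability = NULL,
                           seed = NULL) {
  stopifnot(inherits(bundle, "trace_cohort"))
  seed <- seed %||% bundle$config$seed
  norm <- tmm_normalize(bundle$counts)
  expressed <- call_expressed(norm, bundle$samples)
  any_expr <- attr(expressed, "expressed_any")
  keep <- rownames(norm$cpm)[any_expr]
  norm$cpm <- norm$cpm[keep, , drop = FALSE]
  expressed <- expressed[keep, , drop = FALSE]

  med <- tissue_medians(norm, bundle$samples)
  pref <- suppressWarnings(preferential_expression(med))
  dev <- developmental_summaries(bundle$dev_expression)

  diff <- differential_edge_scores(med, bundle$ppi_edges)
  expressed_any <- setNames(rep(TRUE, length(keep)), keep)
  frags <- list(
    expression_features(med, expressed, pref, dev),
    eqtl_features(bundle$eqtl_q, keep),
    suppressWarnings(
      ppi_count_features(bundle$ppi_edges, expressed, pref$preferential)),
    differential_ppi_features(diff, keep),
    embedding_features(bundle$ppi_edges, expressed, dims = embedding_dims,
                       walks_per_node = walks_per_node,
                       walk_len = walk_len, seed = seed),
    paralog_features(norm, bundle$samples, bundle$paralogs, expressed_any),
    process_activity_features(
      process_activity_scores(med, bundle$go_annotations), keep)
  )
  if (!is.null(variability)) {
    frags <- c(frags, list(adult_variability_features(variability, keep)))
  }
  structure(list(table = assemble_feature_table(frags), norm = norm,
                 expressed = expressed, med = med, pref = pref, dev = dev),
            class = "tt_features")
}

#' @export
print.tt_features <- function(x, ...) {
  cat(sprintf("cohort features: %d genes x %d features\n",
              nrow(x$table$values), ncol(x$table$values)))
  invisible(x)
}

#' Expected feature-table width
#'
#' Closed form for the assembled column count:
#' `|T| * (2 expression + 9 PPI + 4 differential-PPI + 2 paralog +
#' 4 process) + |T_eqtl| + dims * (|T| + 1) + organs x timepoints +
#' CV organs + optional adult-variability columns`.
#'
#' @param n_tissues,n_eqtl_tissues,n_organs,n_timepoints,n_cv_organs Grid
#'   sizes.
#' @param dims Embedding dimension (default 64).
#' @param n_variability_tissues Optional adult-variability columns
#'   (default 0).
#' @return Integer column count.
#' @export
expected_feature_count <- function(n_tissues, n_eqtl_tissues = n_tissues,
                                   n_organs = 7, n_timepoints = 5,
                                   n_cv_organs = n_organs, dims = 64,
                                   n_variability_tissues = 0) {
  n_tissues * (2 + 9 + 4 + 2 + 4) + n_eqtl_tissues +
    dims * (n_tissues + 1) + n_organs * n_timepoints + n_cv_organs +
    n_variability_tissues
}
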
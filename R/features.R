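# Tissue-based gene feature families. Each builder returns a feature_table
# fragment over the retained genes; structurally undefined cells (no
# paralog, no edges, no annotation) stay missing for later imputation, only
# "not expressed" cases explicitly defined as zero are zero-filled.

#' Transcriptomic features: expression, preferential expression, development
#'
#' Per tissue, one expression feature (median cpm, 0 where the gene is not
#' called expressed in the tissue) and one preferential-expression feature;
#' per developmental (organ, timepoint) one expression feature and per organ
#' one developmental-variability (CV) feature.
#'
#' @param med Matrix genes x tissues of median cpm.
#' @param expressed Logical matrix from [call_expressed()].
#' @param pref A `tt_pref` from [preferential_expression()].
#' @param dev A `tt_dev` from [developmental_summaries()], or NULL to skip
#'   developmental features.
#' @return A `feature_table` fragment.
#' @export
expression_features <- function(med, expressed, pref, dev = NULL) {
  genes <- rownames(med)
  tissues <- colnames(med)
  expr <- med * expressed[genes, tissues]
  colnames(expr) <- paste0("expr@", tissues)
  pr <- pref$pref[genes, tissues, drop = FALSE]
  colnames(pr) <- paste0("pref@", tissues)
  frags <- list(
    feature_table(expr, tibble::tibble(feature = colnames(expr),
                                       family = "expression",
                                       tissue = tissues)),
    feature_table(pr, tibble::tibble(feature = colnames(pr),
                                     family = "preferential_expression",
                                     tissue = tissues))
  )
  if (!is.null(dev)) {
    dm <- matrix(NA_real_, length(genes), ncol(dev$med),
                 dimnames = list(genes, paste0("dev@", colnames(dev$med))))
    common <- intersect(genes, rownames(dev$med))
    dm[common, ] <- dev$med[common, ]
    frags <- c(frags, list(feature_table(dm, tibble::tibble(
      feature = colnames(dm), family = "developmental_expression",
      tissue = sub("@.*$", "", colnames(dev$med))))))
    cvm <- matrix(NA_real_, length(genes), ncol(dev$cv),
                  dimnames = list(genes, paste0("devcv@", colnames(dev$cv))))
    cvm[common, ] <- dev$cv[common, ]
    frags <- c(frags, list(feature_table(cvm, tibble::tibble(
      feature = colnames(cvm), family = "dev_variability",
      tissue = colnames(dev$cv)))))
  }
  assemble_feature_table(frags)
}

#' eQTL features
#'
#' One feature per tissue holding the gene's eGene q-value in that tissue.
#' Genes absent from the eQTL table stay missing (imputed later), never 1.
#'
#' @param eqtl Data frame with columns `gene`, `tissue`, `q`.
#' @param genes Gene universe (row order of the feature table).
#' @return A `feature_table` fragment with one column per tissue having
#'   eQTL data.
#' @export
eqtl_features <- function(eqtl, genes) {
  eqtl <- tibble::as_tibble(eqtl)
  stopifnot(all(c("gene", "tissue", "q") %in% names(eqtl)))
  if (any(eqtl$q < 0 | eqtl$q > 1, na.rm = TRUE)) {
    stop("eQTL q-values must lie in [0, 1]", call. = FALSE)
  }
  eqtl <- eqtl[eqtl$gene %in% genes, ]
  tissues <- sort(unique(eqtl$tissue))
  m <- matrix(NA_real_, length(genes), length(tissues),
              dimnames = list(genes, paste0("eqtl@", tissues)))
  m[cbind(match(eqtl$gene, genes), match(eqtl$tissue, tissues))] <- eqtl$q
  feature_table(m, tibble::tibble(feature = colnames(m), family = "eqtl",
                                  tissue = tissues))
}

#' PPI count features
#'
#' Per tissue, three primary features: (i) tissue interactors — the number
#' of a gene's interactors expressed in the tissue (0 when the gene itself
#' is not expressed there); (ii) preferential tissue interactors — same,
#' counting preferentially expressed interactors; (iii) tissue-specific
#' interactors — for genes with (i) > 0, the number of tissue interactors
#' whose pair is co-expressed in at most `specific_max` of the tissues
#' (inclusive boundary). Each primary feature gets two deviation features:
#' the primary value minus its mean, and minus its median, across tissues.
#'
#' @param edges Undirected edge list (columns `gene_a`, `gene_b`).
#' @param expressed Logical genes x tissues matrix.
#' @param preferential Logical genes x tissues matrix (pref >= threshold).
#' @param specific_max Fraction of tissues for the tissue-specific rule
#'   (default 0.2).
#' @return A `feature_table` fragment with 9 features per tissue.
#' @export
ppi_count_features <- function(edges, expressed, preferential,
                               specific_max = 0.2) {
  genes <- rownames(expressed)
  tissues <- colnames(expressed)
  edges <- tibble::as_tibble(edges)
  known <- edges$gene_a %in% genes & edges$gene_b %in% genes
  if (any(!known)) {
    warning(sprintf("%d PPI edge(s) reference genes absent from the %s",
                    sum(!known), "expression data; ignored"), call. = FALSE)
    edges <- edges[known, ]
  }
  ia <- match(edges$gene_a, genes)
  ib <- match(edges$gene_b, genes)
  n <- length(genes)
  A <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia), x = 1,
                            dims = c(n, n))
  E <- expressed * 1
  P <- preferential[genes, tissues, drop = FALSE] * 1
  co_expressed <- rowSums(E[ia, , drop = FALSE] * E[ib, , drop = FALSE])
  specific_edge <- co_expressed <= specific_max * length(tissues)
  sel <- which(specific_edge)
  A_spec <- Matrix::sparseMatrix(i = c(ia[sel], ib[sel]),
                                 j = c(ib[sel], ia[sel]), x = 1,
                                 dims = c(n, n))
  cnt1 <- as.matrix(A %*% E) * E
  cnt2 <- as.matrix(A %*% P) * E
  cnt3 <- as.matrix(A_spec %*% E) * E
  cnt3[cnt1 == 0] <- NA_real_

  deviation_pair <- function(m, name) {
    mu <- rowMeans(m, na.rm = TRUE)
    md <- apply(m, 1L, median, na.rm = TRUE)
    d1 <- m - mu
    d2 <- m - md
    colnames(d1) <- paste0(name, "_dmean@", tissues)
    colnames(d2) <- paste0(name, "_dmedian@", tissues)
    list(d1, d2)
  }
  prim <- list(ppi_tissue = cnt1, ppi_pref = cnt2, ppi_specific = cnt3)
  mats <- list()
  for (nm in names(prim)) {
    m <- prim[[nm]]
    colnames(m) <- paste0(nm, "@", tissues)
    mats <- c(mats, list(m), deviation_pair(prim[[nm]], nm))
  }
  values <- do.call(cbind, mats)
  rownames(values) <- genes
  feature_table(values, tibble::tibble(
    feature = colnames(values), family = "ppi",
    tissue = rep(tissues, times = length(mats))
  ))
}

#' Tissue-differential PPI edge scores
#'
#' Scores how available an interaction is in each tissue relative to the
#' others: an interaction is as available as its scarcer partner, so the
#' edge level in tissue t is the minimum of the two endpoint median cpms,
#' and the score is its log2 ratio to the median of the edge levels in the
#' other tissues (pseudocount `eps` cpm on both sides).
#'
#' @param med Matrix genes x tissues of median cpm.
#' @param edges Undirected edge list with endpoints present in `med`.
#' @param eps Pseudocount in cpm (default 1).
#' @return List with `scores` (edges x tissues matrix) and `edges` (the
#'   tibble actually scored).
#' @export
differential_edge_scores <- function(med, edges, eps = 1) {
  edges <- tibble::as_tibble(edges)
  keep <- edges$gene_a %in% rownames(med) & edges$gene_b %in% rownames(med)
  edges <- edges[keep, ]
  lvl <- pmin(med[edges$gene_a, , drop = FALSE],
              med[edges$gene_b, , drop = FALSE])
  tissues <- colnames(med)
  scores <- matrix(NA_real_, nrow(edges), length(tissues),
                   dimnames = list(NULL, tissues))
  for (k in seq_along(tissues)) {
    ref <- apply(lvl[, -k, drop = FALSE], 1L, median)
    scores[, k] <- log2((lvl[, k] + eps) / (ref + eps))
  }
  list(scores = scores, edges = edges)
}

#' Tissue-differential PPI gene features
#'
#' Per gene and tissue: the minimum, maximum, median, and mean of the
#' differential interaction scores of the gene's incident edges. Genes with
#' no edges get four missing cells per tissue.
#'
#' @param diff Result of [differential_edge_scores()].
#' @param genes Gene universe (row order).
#' @return A `feature_table` fragment with 4 features per tissue.
#' @export
differential_ppi_features <- function(diff, genes) {
  tissues <- colnames(diff$scores)
  edge_idx <- c(seq_len(nrow(diff$edges)), seq_len(nrow(diff$edges)))
  gene_of <- c(diff$edges$gene_a, diff$edges$gene_b)
  incident <- split(edge_idx, factor(gene_of, levels = genes))
  stats <- c(min = min, max = max, median = median, mean = mean)
  mats <- lapply(stats, function(f) {
    m <- matrix(NA_real_, length(genes), length(tissues),
                dimnames = list(genes, tissues))
    m
  })
  for (g in seq_along(genes)) {
    idx <- incident[[g]]
    if (length(idx) == 0L) next
    sub <- diff$scores[idx, , drop = FALSE]
    mats$min[g, ] <- apply(sub, 2L, min)
    mats$max[g, ] <- apply(sub, 2L, max)
    mats$median[g, ] <- apply(sub, 2L, median)
    mats$mean[g, ] <- colMeans(sub)
  }
  for (nm in names(mats)) {
    colnames(mats[[nm]]) <- paste0("dppi_", nm, "@", tissues)
  }
  values <- do.call(cbind, mats)
  feature_table(values, tibble::tibble(
    feature = colnames(values), family = "differential_ppi",
    tissue = rep(tissues, times = 4L)
  ))
}

#' Paralog dosage features
#'
#' Paralogs qualify at reciprocal sequence identity >= `min_identity`
#' percent. Per tissue: (1) the median, over the tissue's samples, of the
#' cpm ratio between the gene and its best-matching paralog (the qualifying
#' partner with the highest identity that is expressed in at least one
#' tissue); (2) the median ratio between the gene and the summed cpm of all
#' its qualifying paralogs. Ratio denominators are floored at `eps` cpm so
#' silent paralogs keep the ratio finite. Genes without qualifying paralogs
#' stay missing.
#'
#' @param norm A `tt_norm`.
#' @param samples Sample-to-tissue map.
#' @param paralogs Data frame `gene`, `paralog`, `identity` (percent,
#'   symmetric pairs listed once).
#' @param expressed_any Named logical: gene expressed in >= 1 tissue.
#' @param min_identity Inclusion threshold in percent (default 40).
#' @param eps Denominator floor in cpm (default 1).
#' @return A `feature_table` fragment with 2 features per tissue.
#' @export
paralog_features <- function(norm, samples, paralogs, expressed_any,
                             min_identity = 40, eps = 1) {
  stopifnot(inherits(norm, "tt_norm"))
  if (any(paralogs$identity < 0 | paralogs$identity > 100)) {
    stop("paralog identity must be in [0, 100]", call. = FALSE)
  }
  genes <- rownames(norm$cpm)
  # Symmetrize and keep qualifying, in-universe pairs.
  pairs <- dplyr::bind_rows(
    paralogs[, c("gene", "paralog", "identity")],
    tibble::tibble(gene = paralogs$paralog, paralog = paralogs$gene,
                   identity = paralogs$identity)
  )
  pairs <- pairs[pairs$identity >= min_identity &
                   pairs$gene %in% genes & pairs$paralog %in% genes, ]
  pairs$partner_expressed <- expressed_any[pairs$paralog]
  best <- pairs[pairs$partner_expressed, ] |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_max(.data$identity, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()

  tissues <- unique(samples$tissue)
  tissue_of <- setNames(samples$tissue, samples$sample)
  f1 <- matrix(NA_real_, length(genes), length(tissues),
               dimnames = list(genes, paste0("paralog_best@", tissues)))
  f2 <- matrix(NA_real_, length(genes), length(tissues),
               dimnames = list(genes, paste0("paralog_sum@", tissues)))
  if (nrow(best) > 0L) {
    num <- norm$cpm[best$gene, , drop = FALSE]
    den <- pmax(norm$cpm[best$paralog, , drop = FALSE], eps)
    ratio <- num / den
    for (t in tissues) {
      cols <- intersect(names(tissue_of)[tissue_of == t], colnames(ratio))
      f1[best$gene, paste0("paralog_best@", t)] <-
        apply(ratio[, cols, drop = FALSE], 1L, median)
    }
  }
  with_any <- unique(pairs$gene)
  if (length(with_any) > 0L) {
    summed <- rowsum(norm$cpm[pairs$paralog, , drop = FALSE],
                     group = pairs$gene)
    summed <- summed[with_any, , drop = FALSE]
    ratio2 <- norm$cpm[with_any, , drop = FALSE] / pmax(summed, eps)
    for (t in tissues) {
      cols <- intersect(names(tissue_of)[tissue_of == t], colnames(ratio2))
      f2[with_any, paste0("paralog_sum@", t)] <-
        apply(ratio2[, cols, drop = FALSE], 1L, median)
    }
  }
  values <- cbind(f1, f2)
  feature_table(values, tibble::tibble(
    feature = colnames(values), family = "paralog",
    tissue = rep(tissues, times = 2L)
  ))
}

#' Differential Gene Ontology process activity scores
#'
#' Terms are filtered to 3-100 annotated member genes (inclusive, counted
#' over genes present in the expression data). The activity of a term in a
#' tissue is the mean log2 fold-change of its member genes, where a gene's
#' log2 fold-change in tissue t is
#' `log2((med[g, t] + eps) / (median of med[g, t'] over t' != t + eps))`.
#'
#' @param med Matrix genes x tissues of median cpm.
#' @param go Data frame `term`, `gene`.
#' @param size_range Inclusive term-size bounds (default `c(3, 100)`).
#' @param eps Pseudocount in cpm (default 1).
#' @return List of class `tt_process`: `activity` (terms x tissues),
#'   `gene_terms` (tibble `gene`, `term` restricted to eligible terms).
#' @export
process_activity_scores <- function(med, go, size_range = c(3, 100),
                                    eps = 1) {
  go <- tibble::as_tibble(go)
  go <- go[go$gene %in% rownames(med), ]
  go <- dplyr::distinct(go)
  sizes <- table(go$term)
  eligible <- names(sizes)[sizes >= size_range[1] & sizes <= size_range[2]]
  go <- go[go$term %in% eligible, ]
  tissues <- colnames(med)
  lfc <- matrix(NA_real_, nrow(med), length(tissues),
                dimnames = dimnames(med))
  for (k in seq_along(tissues)) {
    ref <- apply(med[, -k, drop = FALSE], 1L, median)
    lfc[, k] <- log2((med[, k] + eps) / (ref + eps))
  }
  sums <- rowsum(lfc[go$gene, , drop = FALSE], group = go$term)
  activity <- sums / as.vector(table(go$term)[rownames(sums)])
  structure(list(activity = activity, gene_terms = go),
            class = "tt_process")
}

#' Differential process activity gene features
#'
#' Per gene and tissue: the minimum, maximum, median and mean differential
#' activity score over the GO terms the gene is annotated to. Unannotated
#' genes stay missing.
#'
#' @param pa A `tt_process` from [process_activity_scores()].
#' @param genes Gene universe (row order).
#' @return A `feature_table` fragment with 4 features per tissue.
#' @export
process_activity_features <- function(pa, genes) {
  tissues <- colnames(pa$activity)
  terms_of <- split(pa$gene_terms$term, factor(pa$gene_terms$gene,
                                               levels = genes))
  mats <- lapply(c("min", "max", "median", "mean"), function(nm) {
    matrix(NA_real_, length(genes), length(tissues),
           dimnames = list(genes, paste0("process_", nm, "@", tissues)))
  })
  names(mats) <- c("min", "max", "median", "mean")
  for (g in seq_along(genes)) {
    tm <- terms_of[[g]]
    if (length(tm) == 0L) next
    sub <- pa$activity[tm, , drop = FALSE]
    mats$min[g, ] <- apply(sub, 2L, min)
    mats$max[g, ] <- apply(sub, 2L, max)
    mats$median[g, ] <- apply(sub, 2L, median)
    mats$mean[g, ] <- colMeans(sub)
  }
  values <- do.call(cbind, mats)
  feature_table(values, tibble::tibble(
    feature = colnames(values), family = "process_activity",
    tissue = rep(tissues, times = 4L)
  ))
}

#' Optional precomputed adult expression-variability features
#'
#' Accepts a per-gene-per-tissue table of adult expression-variability
#' scores computed elsewhere; no algorithm is claimed for them here.
#'
#' @param variability Data frame `gene`, `tissue`, `score`.
#' @param genes Gene universe (row order).
#' @return A `feature_table` fragment (family `variability`).
#' @export
adult_variability_features <- function(variability, genes) {
  variability <- tibble::as_tibble(variability)
  stopifnot(all(c("gene", "tissue", "score") %in% names(variability)))
  variability <- variability[variability$gene %in% genes, ]
  tissues <- sort(unique(variability$tissue))
  m <- matrix(NA_real_, length(genes), length(tissues),
              dimnames = list(genes, paste0("adultvar@", tissues)))
  m[cbind(match(variability$gene, genes),
          match(variability$tissue, tissues))] <- variability$score
  feature_table(m, tibble::tibble(feature = colnames(m),
                                  family = "variability", tissue = tissues))
}
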
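#' Normalize a raw count matrix with trimmed mean of M-values (TMM)
#'
#' Removes genes with at most `min_max_count` raw counts in every sample
#' (typically regarded as noise), estimates per-sample TMM scaling factors
#' with edgeR, and converts counts to linear-scale counts per million (cpm)
#' using the effective library sizes. No pseudocount is added: downstream
#' expressed-gene calls threshold linear cpm directly.
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames are
#'   gene ids), samples in columns (colnames are sample ids).
#' @param min_max_count Genes whose maximum raw count across all samples is
#'   at most this value are dropped before factor estimation (default 10).
#' @return An object of class `tt_norm`: a list with `cpm` (matrix over
#'   retained genes), `factors` (tibble with `sample`, `lib_size`,
#'   `norm_factor`), and `retained_genes`.
#' @examples
#' m <- matrix(rpois(200, 40), 20, 10,
#'             dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
#' norm <- tmm_normalize(m)
#' head(norm$cpm)
#' @export
tmm_normalize <- function(counts, min_max_count = 10) {
  check_gene_matrix(counts, "counts")
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  zero_lib <- colSums(counts) == 0
  if (any(zero_lib)) {
    stop(sprintf("sample(s) with zero library size: %s",
                 paste(colnames(counts)[zero_lib], collapse = ", ")),
         call. = FALSE)
  }
  keep <- apply(counts, 1L, max) > min_max_count
  if (!any(keep)) {
    stop("all genes removed by the low-count filter; matrix is empty",
         call. = FALSE)
  }
  filtered <- counts[keep, , drop = FALSE]
  nf <- edgeR::calcNormFactors(filtered, method = "TMM")
  lib <- colSums(filtered)
  cpm <- sweep(filtered, 2L, lib * nf, "/") * 1e6
  structure(
    list(
      cpm = cpm,
      factors = tibble::tibble(sample = colnames(counts),
                               lib_size = lib,
                               norm_factor = unname(nf)),
      retained_genes = rownames(filtered)
    ),
    class = "tt_norm"
  )
}

#' @export
print.tt_norm <- function(x, ...) {
  cat(sprintf("TMM-normalized expression: %d genes x %d samples\n",
              nrow(x$cpm), ncol(x$cpm)))
  invisible(x)
}

#' Call expressed genes per tissue
#'
#' A gene is expressed in a tissue when its cpm is at least `cpm_threshold`
#' in at least half of that tissue's samples (count >= n_t / 2, ties
#' inclusive, so 2 of 4 qualifies). Genes expressed in no tissue are flagged
#' for exclusion from downstream features.
#'
#' @param norm A `tt_norm` object from [tmm_normalize()].
#' @param samples Data frame with columns `sample` and `tissue` mapping every
#'   column of the cpm matrix to exactly one tissue.
#' @param cpm_threshold Linear-cpm threshold (default 7).
#' @return Logical matrix genes x tissues with attribute `expressed_any`
#'   (logical vector per gene).
#' @export
call_expressed <- function(norm, samples, cpm_threshold = 7) {
  stopifnot(inherits(norm, "tt_norm"))
  samples <- tibble::as_tibble(samples)
  if (!all(colnames(norm$cpm) %in% samples$sample)) {
    stop("every cpm sample must be mapped to a tissue", call. = FALSE)
  }
  tissue_of <- setNames(as.character(samples$tissue), samples$sample)
  tissues <- unique(unname(tissue_of[colnames(norm$cpm)]))
  hit <- norm$cpm >= cpm_threshold
  out <- vapply(tissues, function(t) {
    cols <- names(tissue_of)[tissue_of == t]
    cols <- intersect(cols, colnames(norm$cpm))
    n_t <- length(cols)
    rowSums(hit[, cols, drop = FALSE]) >= n_t / 2
  }, logical(nrow(norm$cpm)))
  dimnames(out) <- list(rownames(norm$cpm), tissues)
  attr(out, "expressed_any") <- rowSums(out) > 0
  out
}

#' Per-tissue median expression
#'
#' Median cpm of each gene over each tissue's samples; the quantity the
#' preferential-expression score is built from.
#'
#' @inheritParams call_expressed
#' @return Numeric matrix genes x tissues of median cpm.
#' @export
tissue_medians <- function(norm, samples) {
  stopifnot(inherits(norm, "tt_norm"))
  samples <- tibble::as_tibble(samples)
  tissue_of <- setNames(as.character(samples$tissue), samples$sample)
  tissues <- unique(unname(tissue_of[colnames(norm$cpm)]))
  med <- vapply(tissues, function(t) {
    cols <- intersect(names(tissue_of)[tissue_of == t], colnames(norm$cpm))
    apply(norm$cpm[, cols, drop = FALSE], 1L, median)
  }, numeric(nrow(norm$cpm)))
  dimnames(med) <- list(rownames(norm$cpm), tissues)
  med
}

#' Preferential expression per gene and tissue
#'
#' Standardizes each gene's tissue medians by their across-tissue median and
#' interquartile range:
#' `pref[g, t] = (med[g, t] - median_t'(med[g, t'])) / IQR_t'(med[g, t'])`.
#' Positive values reflect overexpression in the tissue, negative values
#' underexpression. Percentiles use linear interpolation (type 7). Genes
#' whose medians are identical across tissues (IQR 0) carry no tissue
#' preference and get pref 0 in every tissue (a warning reports how many).
#'
#' @param med Matrix genes x tissues of median cpm (from [tissue_medians()]).
#' @param pref_threshold Genes with pref at or above this value in a tissue
#'   are flagged preferentially expressed there (default 2).
#' @return A list of class `tt_pref`: `pref` (matrix genes x tissues),
#'   `iqr_of_medians` (named vector), `preferential` (logical matrix,
#'   `pref >= pref_threshold`).
#' @export
preferential_expression <- function(med, pref_threshold = 2) {
  check_gene_matrix(med, "median matrix")
  if (ncol(med) < 3L) {
    stop("preferential expression needs at least 3 tissues", call. = FALSE)
  }
  center <- apply(med, 1L, median)
  iqr <- apply(med, 1L, iqr7)
  pref <- (med - center) / ifelse(iqr == 0, 1, iqr)
  flat <- iqr == 0
  if (any(flat)) {
    pref[flat, ] <- 0
    warning(sprintf(
      "%d gene(s) with zero IQR across tissue medians: pref set to 0",
      sum(flat)), call. = FALSE)
  }
  structure(
    list(pref = pref, iqr_of_medians = iqr,
         preferential = pref >= pref_threshold),
    class = "tt_pref"
  )
}

#' Developmental expression summaries
#'
#' Per organ and timepoint, each gene's expression is its median normalized
#' count over that cell's samples. Developmental variability per organ is
#' the coefficient of variation (sample sd over mean, n - 1 convention)
#' computed over the gene's timepoint medians within the organ; undefined
#' (missing) where the timepoint medians are all zero or an organ has fewer
#' than two timepoints.
#'
#' @param dev Data frame with columns `organ`, `timepoint`, `sample`,
#'   `gene`, `value` (normalized counts). A `sample` column is optional;
#'   without it each row is taken as the cell value directly.
#' @return A list of class `tt_dev`: `med` (matrix genes x organ@timepoint)
#'   and `cv` (matrix genes x organs, NA where undefined).
#' @export
developmental_summaries <- function(dev) {
  dev <- tibble::as_tibble(dev)
  stopifnot(all(c("organ", "timepoint", "gene", "value") %in% names(dev)))
  med_tbl <- dev |>
    dplyr::group_by(.data$organ, .data$timepoint, .data$gene) |>
    dplyr::summarise(med = median(.data$value), .groups = "drop")
  med_tbl$cell <- paste0(med_tbl$organ, "@", med_tbl$timepoint)
  genes <- sort(unique(med_tbl$gene))
  cells <- unique(med_tbl$cell[order(med_tbl$organ, med_tbl$timepoint)])
  med <- matrix(NA_real_, length(genes), length(cells),
                dimnames = list(genes, cells))
  med[cbind(match(med_tbl$gene, genes), match(med_tbl$cell, cells))] <-
    med_tbl$med

  organs <- unique(med_tbl$organ)
  cv <- matrix(NA_real_, length(genes), length(organs),
               dimnames = list(genes, organs))
  for (o in organs) {
    cols <- which(startsWith(cells, paste0(o, "@")))
    if (length(cols) < 2L) {
      message(sprintf("organ '%s' has <2 timepoints: cv left missing", o))
      next
    }
    m <- med[, cols, drop = FALSE]
    mu <- rowMeans(m)
    s <- apply(m, 1L, sd)
    cv[, o] <- ifelse(mu == 0, NA_real_, s / mu)
  }
  structure(list(med = med, cv = cv), class = "tt_dev")
}
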
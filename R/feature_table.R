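#' Construct a feature table
#'
#' A feature table couples a genes x features numeric matrix (missing values
#' allowed before imputation) with per-feature metadata: the feature family
#' and the tissue of origin. The metadata drives attribution aggregation.
#'
#' @param values Numeric matrix, gene rownames, feature colnames.
#' @param meta Data frame with columns `feature`, `family`, `tissue`
#'   aligned with `colnames(values)`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, meta) {
  check_gene_matrix(values, "feature values")
  meta <- tibble::as_tibble(meta)
  stopifnot(all(c("feature", "family", "tissue") %in% names(meta)))
  if (!identical(meta$feature, colnames(values))) {
    stop("meta$feature must match colnames(values) in order", call. = FALSE)
  }
  structure(list(values = values, meta = meta), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  fam <- table(x$meta$family)
  cat(sprintf("feature table: %d genes x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(fam), fam), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Tidy a feature table into a long tibble
#' @param x A `feature_table`.
#' @param ... Unused.
#' @return Tibble with columns `gene`, `feature`, `family`, `tissue`,
#'   `value`.
#' @method tidy feature_table
#' @export
tidy.feature_table <- function(x, ...) {
  long <- tibble::as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "feature", values_to = "value")
  dplyr::left_join(long, x$meta, by = "feature")
}

#' Select feature columns by metadata
#' @param x A `feature_table`.
#' @param family,tissue Optional filters.
#' @return A `feature_table` restricted to matching columns.
#' @export
filter_features <- function(x, family = NULL, tissue = NULL) {
  stopifnot(inherits(x, "feature_table"))
  keep <- rep(TRUE, nrow(x$meta))
  if (!is.null(family)) keep <- keep & x$meta$family %in% family
  if (!is.null(tissue)) keep <- keep & x$meta$tissue %in% tissue
  feature_table(x$values[, keep, drop = FALSE], x$meta[keep, ])
}

#' Column-concatenate feature-table fragments
#'
#' All fragments must cover the same gene set (same order); feature ids
#' must be globally unique.
#'
#' @param fragments List of `feature_table` fragments.
#' @return A single `feature_table`.
#' @export
assemble_feature_table <- function(fragments) {
  stopifnot(length(fragments) >= 1L)
  genes <- rownames(fragments[[1L]]$values)
  for (i in seq_along(fragments)) {
    if (!identical(rownames(fragments[[i]]$values), genes)) {
      stop(sprintf("fragment %d (%s...) has a mismatched gene set",
                   i, fragments[[i]]$meta$family[1L]), call. = FALSE)
    }
  }
  values <- do.call(cbind, lapply(fragments, function(f) f$values))
  meta <- dplyr::bind_rows(lapply(fragments, function(f) f$meta))
  if (anyDuplicated(meta$feature)) {
    stop(sprintf("duplicate feature id(s): %s",
                 paste(unique(meta$feature[duplicated(meta$feature)]),
                       collapse = ", ")), call. = FALSE)
  }
  feature_table(values, meta)
}

#' Write a feature table as TSV with a metadata sidecar
#' @param x A `feature_table`.
#' @param path Values TSV path; metadata goes to `<path>.meta.tsv`.
#' @export
write_feature_table <- function(x, path) {
  write_matrix_tsv(x$values, path)
  readr::write_tsv(x$meta, paste0(path, ".meta.tsv"))
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path Values TSV path.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  meta <- tibble::as_tibble(utils::read.delim(paste0(path, ".meta.tsv"),
                                              check.names = FALSE))
  feature_table(m, meta)
}
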
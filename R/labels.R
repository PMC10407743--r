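#' Label genes for one tissue from disease-gene-tissue associations
#'
#' A gene is positive for a tissue when at least one of its associated
#' diseases manifests in that tissue; every other gene is negative. Group
#' tags for evaluation: `tissue_associated` (positives), `other_disease`
#' (disease genes with no association to the tissue), `non_disease`
#' (everything else). The three groups partition the gene universe.
#'
#' @param associations Data frame `disease`, `gene`, `tissue`.
#' @param genes Gene universe.
#' @param tissue Tissue id.
#' @return Tibble `gene`, `label` (1/0), `group`.
#' @export
label_genes_for_tissue <- function(associations, genes, tissue) {
  associations <- tibble::as_tibble(associations)
  unknown <- !associations$gene %in% genes
  if (any(unknown)) {
    warning(sprintf("%d association(s) to unknown genes skipped",
                    sum(unknown)), call. = FALSE)
    associations <- associations[!unknown, ]
  }
  disease_genes <- unique(associations$gene)
  pos <- unique(associations$gene[associations$tissue == tissue])
  tibble::tibble(
    gene = genes,
    label = as.integer(genes %in% pos),
    group = dplyr::case_when(
      genes %in% pos ~ "tissue_associated",
      genes %in% disease_genes ~ "other_disease",
      TRUE ~ "non_disease"
    )
  )
}

#' Label genes for all tissues
#' @inheritParams label_genes_for_tissue
#' @param tissues Tissues to label (default: all tissues in the table other
#'   than non-modeled placeholders).
#' @return Long tibble `tissue`, `gene`, `label`, `group`.
#' @export
label_all_tissues <- function(associations, genes, tissues = NULL) {
  tissues <- tissues %||% setdiff(unique(associations$tissue), "other")
  purrr::map_dfr(tissues, function(t) {
    dplyr::mutate(label_genes_for_tissue(associations, genes, t),
                  tissue = t, .before = 1L)
  })
}

#' Label genes for a brain region with curation confidence
#'
#' Positive when the gene's disease is associated with the region at a
#' confidence level of 2 or above; confidence-1 associations (and
#' associations to other regions only) are negative.
#'
#' @param brain_assoc Data frame `disease`, `gene`, `region`, `confidence`
#'   with confidence in {1, 2, 3}.
#' @param genes Gene universe.
#' @param region Brain region id.
#' @return Tibble `gene`, `label`.
#' @export
label_brain_regions <- function(brain_assoc, genes, region) {
  brain_assoc <- tibble::as_tibble(brain_assoc)
  if (!all(brain_assoc$confidence %in% 1:3)) {
    stop("brain association confidence must be 1, 2 or 3", call. = FALSE)
  }
  pos <- unique(brain_assoc$gene[brain_assoc$region == region &
                                   brain_assoc$confidence >= 2L])
  tibble::tibble(gene = genes, label = as.integer(genes %in% pos))
}

#' Tissues with enough positives to support a model
#'
#' Robust per-tissue models need strictly more than `min_positives`
#' associated disease genes.
#'
#' @param labels Long label tibble from [label_all_tissues()].
#' @param min_positives Strict lower bound (default 60).
#' @return Character vector of eligible tissues.
#' @export
eligible_tissues <- function(labels, min_positives = 60) {
  if (nrow(labels) == 0L) return(character())
  counts <- labels |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(n_pos = sum(.data$label), .groups = "drop")
  sort(counts$tissue[counts$n_pos > min_positives])
}
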
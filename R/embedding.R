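#' Network-embedding features for the general and tissue interactomes
#'
#' The tissue interactome of tissue t contains the PPI edges whose two
#' endpoints are both expressed in t. The general interactome and every
#' tissue interactome are embedded independently with uniform second-order
#' random walks (return and in-out parameters both 1, so walks reduce to
#' first-order uniform walks), 20 walks of length 10 per node, and a
#' skip-gram objective with negative sampling producing 64-dimensional
#' vectors. Genes absent from (or isolated in) an interactome get missing
#' cells for that interactome's 64 columns.
#'
#' @param edges Undirected edge list (`gene_a`, `gene_b`).
#' @param expressed Logical genes x tissues matrix from [call_expressed()].
#' @param dims Embedding dimension (default 64).
#' @param walks_per_node Walks started per node (default 20).
#' @param walk_len Walk length in nodes (default 10).
#' @param window Skip-gram window (default 5).
#' @param negatives Negative samples per positive pair (default 5).
#' @param seed Integer seed; fixed seed and single worker give identical
#'   vectors across runs.
#' @return A `feature_table` fragment with `dims` columns per interactome
#'   (general first), family `embedding`.
#' @export
embedding_features <- function(edges, expressed, dims = 64,
                               walks_per_node = 20, walk_len = 10,
                               window = 5, negatives = 5, seed = 1) {
  genes <- rownames(expressed)
  tissues <- colnames(expressed)
  edges <- tibble::as_tibble(edges)
  edges <- edges[edges$gene_a %in% genes & edges$gene_b %in% genes, ]
  interactomes <- c(list(general = edges),
                    lapply(setNames(tissues, tissues), function(t) {
                      on_t <- genes[expressed[, t]]
                      edges[edges$gene_a %in% on_t & edges$gene_b %in% on_t, ]
                    }))
  frags <- vector("list", length(interactomes))
  base_seed <- child_seed(seed, "walks")
  for (i in seq_along(interactomes)) {
    nm <- names(interactomes)[i]
    e <- interactomes[[i]]
    if (nrow(e) == 0L) {
      stop(sprintf("interactome '%s' has no edges; cannot embed", nm),
           call. = FALSE)
    }
    nodes <- sort(unique(c(e$gene_a, e$gene_b)))
    idx_a <- match(e$gene_a, nodes) - 1L
    idx_b <- match(e$gene_b, nodes) - 1L
    nb <- split(c(idx_b, idx_a), c(idx_a, idx_b))
    adj_list <- vector("list", length(nodes))
    adj_list[as.integer(names(nb)) + 1L] <- nb
    lens <- lengths(adj_list)
    offsets <- c(0L, cumsum(lens))
    adj <- unlist(adj_list, use.names = FALSE) %||% integer()
    emb <- node2vec_embed(as.integer(offsets), as.integer(adj),
                          as.integer(dims), as.integer(walks_per_node),
                          as.integer(walk_len), as.integer(window),
                          as.integer(negatives), 0.025,
                          as.integer((base_seed + i * 131L) %% 2147483647L))
    m <- matrix(NA_real_, length(genes), dims,
                dimnames = list(genes,
                                sprintf("emb_%s@d%02d", nm, seq_len(dims))))
    m[nodes, ] <- emb
    frags[[i]] <- feature_table(m, tibble::tibble(
      feature = colnames(m), family = "embedding", tissue = nm))
  }
  assemble_feature_table(frags)
}
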
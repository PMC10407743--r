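# Readers and writers for the on-disk formats: TSV as the lingua franca,
# GCT 1.2 accepted for expression matrices.

#' Canonicalize an undirected edge list
#'
#' Orders each pair lexicographically, drops self-loops (with a warning) and
#' duplicate edges (A-B and B-A collapse to one undirected edge).
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`.
#' @param quiet Suppress the self-loop warning.
#' @return Tibble of unique undirected edges, `gene_a < gene_b`.
#' @export
canonical_edges <- function(edges, quiet = FALSE) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("gene_a", "gene_b") %in% names(edges)))
  loops <- edges$gene_a == edges$gene_b
  if (any(loops) && !quiet) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)), call. = FALSE)
  }
  edges <- edges[!loops, ]
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  out <- tibble::tibble(gene_a = a, gene_b = b)
  out <- dplyr::distinct(out)
  dplyr::arrange(out, .data$gene_a, .data$gene_b)
}

#' Read a gene x sample count matrix (TSV or GCT 1.2)
#'
#' TSV layout: first column gene ids, header row of sample ids. GCT 1.2
#' layout: `#1.2` line, dimension line, then Name/Description + samples.
#'
#' @param path File path; format picked by extension (`.gct` vs anything
#'   else) unless `format` is given.
#' @param format `"tsv"`, `"gct"`, or `NULL` to infer.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv")
  if (format == "gct") {
    header <- readLines(path, n = 2L)
    if (length(header) < 2L || !startsWith(header[1L], "#1.2")) {
      stop(sprintf("%s: not a GCT 1.2 file (line 1)", path), call. = FALSE)
    }
    dims <- suppressWarnings(as.integer(strsplit(header[2L], "\t")[[1L]]))
    if (length(dims) < 2L || anyNA(dims)) {
      stop(sprintf("%s: malformed GCT dimension line (line 2)", path),
           call. = FALSE)
    }
    df <- utils::read.delim(path, skip = 2L, check.names = FALSE)
    if (nrow(df) != dims[1L] || ncol(df) - 2L != dims[2L]) {
      stop(sprintf(
        "%s: GCT header declares %d x %d but body is %d x %d (line 2)",
        path, dims[1L], dims[2L], nrow(df), ncol(df) - 2L), call. = FALSE)
    }
    m <- as.matrix(df[, -(1:2), drop = FALSE])
    rownames(m) <- df[[1L]]
  } else {
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
  }
  storage.mode(m) <- "integer"
  check_gene_matrix(m, "count matrix")
  m
}

#' Write a gene x sample matrix as TSV
#' @param m Matrix with rownames and colnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_two_col <- function(path, names) {
  df <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
  if (!all(names %in% colnames(df))) {
    stop(sprintf("%s: expected columns %s", path,
                 paste(names, collapse = ", ")), call. = FALSE)
  }
  df[names]
}

#' Write a synthetic cohort bundle to a directory of plain-text files
#'
#' Emits the same formats the readers consume, so the pipeline can be
#' exercised end-to-end from files: counts TSV, sample map TSV, development
#' TSV, PPI edge TSV, GO annotation TSV, paralog TSV, eQTL TSV, association
#' TSV, truth TSV and a config JSON.
#'
#' @param bundle A `trace_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "trace_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_matrix_tsv(bundle$counts, p("counts.tsv"))
  readr::write_tsv(bundle$samples, p("samples.tsv"))
  readr::write_tsv(bundle$dev_expression, p("dev_expression.tsv"))
  readr::write_tsv(bundle$ppi_edges, p("ppi_edges.tsv"))
  readr::write_tsv(bundle$go_annotations, p("go_annotations.tsv"))
  readr::write_tsv(bundle$paralogs, p("paralogs.tsv"))
  readr::write_tsv(bundle$eqtl_q, p("eqtl_q.tsv"))
  readr::write_tsv(bundle$associations, p("associations.tsv"))
  readr::write_tsv(bundle$truth, p("truth.tsv"))
  jsonlite::write_json(unclass(bundle$config), p("config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#' @param dir Directory containing the bundle files.
#' @return A `trace_cohort`.
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  cfg_raw <- jsonlite::read_json(p("config.json"), simplifyVector = TRUE)
  cfg <- do.call(cohort_config, cfg_raw[setdiff(names(cfg_raw), character())])
  structure(
    list(
      counts = read_counts(p("counts.tsv")),
      samples = read_two_col(p("samples.tsv"), c("sample", "tissue")),
      dev_expression = tibble::as_tibble(
        utils::read.delim(p("dev_expression.tsv"))),
      ppi_edges = canonical_edges(
        read_two_col(p("ppi_edges.tsv"), c("gene_a", "gene_b"))),
      go_annotations = read_two_col(p("go_annotations.tsv"),
                                    c("term", "gene")),
      paralogs = read_two_col(p("paralogs.tsv"),
                              c("gene", "paralog", "identity")),
      eqtl_q = read_two_col(p("eqtl_q.tsv"), c("gene", "tissue", "q")),
      associations = read_two_col(p("associations.tsv"),
                                  c("disease", "gene", "tissue")),
      truth = tibble::as_tibble(utils::read.delim(p("truth.tsv"))),
      config = cfg
    ),
    class = "trace_cohort"
  )
}

#' Read patient cases from TSV
#'
#' Layout: one row per candidate gene with columns `patient`, `tissue`,
#' `gene`, and optional `verified` (0/1 flag marking the verified disease
#' gene of the case).
#'
#' @param path TSV path.
#' @return Tibble with one row per (patient, tissue): `patient`, `tissue`,
#'   `verified_gene` (NA when unflagged), `candidates` list-column.
#' @export
read_patient_cases <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
  stopifnot(all(c("patient", "tissue", "gene") %in% names(df)))
  if (!"verified" %in% names(df)) df$verified <- 0L
  df |>
    dplyr::group_by(.data$patient, .data$tissue) |>
    dplyr::summarise(
      verified_gene = if (any(.data$verified == 1L))
        .data$gene[.data$verified == 1L][1L] else NA_character_,
      candidates = list(.data$gene),
      .groups = "drop"
    )
}
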
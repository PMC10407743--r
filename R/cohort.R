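#' Configuration for the synthetic multi-omics cohort
#'
#' Bundles every knob of the synthetic cohort generator with its default.
#' Defaults emulate, at desk scale, the statistical structure of an adult
#' multi-tissue RNA-seq compendium with tissue-preferential gene blocks, a
#' scale-free-ish protein interaction network with co-expression-structured
#' edges, Gene Ontology terms of 3-100 members with planted
#' tissue-preferential modules, paralog pairs with dosage relationships, and
#' per-tissue disease-gene labels planted to depend on tissue features.
#'
#' @param n_genes Number of genes (default 3000; see the methods vignette
#'   for how problem sizes were chosen).
#' @param tissues Character vector of tissue ids (default the eight tissues
#'   with enough associated disease genes to support per-tissue models).
#' @param samples_per_tissue Samples drawn per tissue (default 30).
#' @param n_dev_organs,n_dev_timepoints Developmental grid (default 7 x 5).
#' @param frac_disease_genes Fraction of genes in the Mendelian disease pool
#'   (default 0.2, matching the roughly one-in-five rate among
#'   protein-coding genes).
#' @param positives_per_tissue Planted tissue-associated disease genes per
#'   tissue (default 70).
#' @param effect_sizes Named list: `pref_expr_shift` (log2 expression shift
#'   of positives in their tissue), `process_shift` (log2 shift applied
#'   jointly to planted GO-module members), `ppi_density_boost` (extra
#'   tissue-expressed interactors per positive as a fraction of the mean
#'   degree).
#' @param ppi_mean_degree Mean degree of the global interactome (default 8).
#' @param n_go_terms Number of random GO terms (default 250), in addition to
#'   the planted modules.
#' @param go_term_size_range Allowed term sizes, must lie within `[3, 100]`.
#' @param paralog_frac Fraction of genes given at least one paralog.
#' @param eqtl_missing Fraction of (gene, tissue) eQTL cells left missing.
#' @param seed Integer seed; a fixed seed gives a bit-identical bundle.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 3000,
                          tissues = c("blood", "brain", "heart", "liver",
                                      "muscle", "nerve", "skin", "testis"),
                          samples_per_tissue = 30,
                          n_dev_organs = 7,
                          n_dev_timepoints = 5,
                          frac_disease_genes = 0.2,
                          positives_per_tissue = 70,
                          effect_sizes = list(pref_expr_shift = 2,
                                              process_shift = 1.5,
                                              ppi_density_boost = 0.3),
                          ppi_mean_degree = 8,
                          n_go_terms = 250,
                          go_term_size_range = c(3, 100),
                          paralog_frac = 0.3,
                          eqtl_missing = 0.3,
                          seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes), tissues = as.character(tissues),
              samples_per_tissue = as.integer(samples_per_tissue),
              n_dev_organs = as.integer(n_dev_organs),
              n_dev_timepoints = as.integer(n_dev_timepoints),
              frac_disease_genes = frac_disease_genes,
              positives_per_tissue = as.integer(positives_per_tissue),
              effect_sizes = effect_sizes,
              ppi_mean_degree = ppi_mean_degree,
              n_go_terms = as.integer(n_go_terms),
              go_term_size_range = as.integer(go_term_size_range),
              paralog_frac = paralog_frac, eqtl_missing = eqtl_missing,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  frac_fields <- c("frac_disease_genes", "paralog_frac", "eqtl_missing")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) abort_config(f, "must be in [0, 1]")
  }
  es <- cfg$effect_sizes
  needed <- c("pref_expr_shift", "process_shift", "ppi_density_boost")
  if (!all(needed %in% names(es))) {
    abort_config("effect_sizes",
                 sprintf("must name %s", paste(needed, collapse = ", ")))
  }
  if (es$ppi_density_boost < 0 || es$ppi_density_boost > 1) {
    abort_config("effect_sizes$ppi_density_boost", "must be in [0, 1]")
  }
  if (cfg$go_term_size_range[1] < 3 || cfg$go_term_size_range[2] > 100 ||
      cfg$go_term_size_range[1] > cfg$go_term_size_range[2]) {
    abort_config("go_term_size_range", "must be within [3, 100]")
  }
  n_disease <- round(cfg$n_genes * cfg$frac_disease_genes)
  if (cfg$positives_per_tissue * length(cfg$tissues) > cfg$n_genes *
      cfg$frac_disease_genes) {
    abort_config("positives_per_tissue",
                 "x |tissues| exceeds n_genes x frac_disease_genes")
  }
  if (cfg$samples_per_tissue < 2L) {
    abort_config("samples_per_tissue", "must be >= 2")
  }
  invisible(cfg)
}

#' Generate a synthetic multi-omics cohort with planted tissue signal
#'
#' Draws a complete mock cohort: raw counts (log-normal gene baselines with
#' per-tissue multiplicative shifts, then Poisson sampling), developmental
#' organ x timepoint expression, an undirected PPI edge list, GO term
#' annotations, paralog pairs, per-tissue eQTL q-values with missingness,
#' disease-gene-tissue associations, and a `truth` record of the planted
#' positives and their mechanisms. For each tissue, planted positives
#' receive a mean log2 expression shift in that tissue, membership in a GO
#' module whose members are jointly shifted there, an elevated edge
#' probability towards tissue-expressed genes, and smaller eQTL q-values.
#'
#' @param config A [cohort_config()].
#' @return A list of class `trace_cohort` with elements `counts`, `samples`,
#'   `dev_expression`, `ppi_edges`, `go_annotations`, `paralogs`, `eqtl_q`,
#'   `associations`, `truth`, and `config`.
#' @examples
#' cfg <- cohort_config(n_genes = 300, tissues = c("a", "b", "c", "d"),
#'                      samples_per_tissue = 6, positives_per_tissue = 10,
#'                      n_go_terms = 30, seed = 7)
#' bundle <- generate_cohort(cfg)
#' dim(bundle$counts)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  cfg <- config
  set.seed(child_seed(cfg$seed, "cohort"))

  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  tissues <- cfg$tissues
  n_t <- length(tissues)
  es <- cfg$effect_sizes

  # Disease pool and planted positives (overlap across tissues allowed, as
  # diseases can manifest in more than one tissue).
  # log2 expression model: bimodal baseline (a silent-ish class and an
  # expressed class) + mild per-tissue deviation + tissue-preferential
  # blocks, drawn before any planting.
  silent <- runif(cfg$n_genes) < 0.3
  mu <- ifelse(silent, rnorm(cfg$n_genes, -4, 2), rnorm(cfg$n_genes, 2, 2))
  log2_lambda <- matrix(mu, cfg$n_genes, n_t,
                        dimnames = list(genes, tissues))
  log2_lambda <- log2_lambda + matrix(rnorm(cfg$n_genes * n_t, 0, 0.3),
                                      cfg$n_genes, n_t)
  block_gene <- runif(cfg$n_genes) < 0.1
  block_tissue <- sample(tissues, cfg$n_genes, replace = TRUE)
  for (t in tissues) {
    sel <- block_gene & block_tissue == t
    log2_lambda[sel, t] <- log2_lambda[sel, t] + 2.5
  }

  # Disease pool: drawn from genes whose baseline expected cpm clears the
  # expressed threshold somewhere, mirroring how the labeled universe only
  # ever contains retained genes. Sampling from the same distribution the
  # retained negatives come from keeps a fully null cohort (all effect
  # sizes zero) free of planted signal.
  base_cpm <- sweep(2^log2_lambda, 2L, colSums(2^log2_lambda), "/") * 1e6
  eligible_pool <- genes[rowSums(base_cpm >= 7) > 0]
  n_disease <- round(cfg$n_genes * cfg$frac_disease_genes)
  if (length(eligible_pool) < n_disease) eligible_pool <- genes
  disease_pool <- sort(sample(eligible_pool, n_disease))
  positives <- lapply(tissues, function(t) {
    sort(sample(disease_pool, cfg$positives_per_tissue))
  })
  names(positives) <- tissues
  any_effect <- es$pref_expr_shift != 0 || es$process_shift != 0 ||
    es$ppi_density_boost != 0
  for (t in tissues) {
    log2_lambda[positives[[t]], t] <-
      log2_lambda[positives[[t]], t] + es$pref_expr_shift
  }

  # GO terms: planted tissue modules (chunks of ~25 positives per tissue,
  # jointly shifted by process_shift; not planted at all when the process
  # effect is zero) + random terms with log-normal sizes.
  go <- list()
  truth_terms <- list()
  if (es$process_shift != 0) {
    for (t in tissues) {
      pos <- positives[[t]]
      n_chunk <- max(1L, ceiling(length(pos) / 25))
      chunks <- split(pos, rep_len(seq_len(n_chunk), length(pos)))
      for (i in seq_along(chunks)) {
        term <- sprintf("GO:P_%s_%d", t, i)
        members <- chunks[[i]]
        go[[term]] <- members
        truth_terms[[t]] <- c(truth_terms[[t]] %||% character(),
                              setNames(rep(term, length(members)), members))
        log2_lambda[members, t] <- log2_lambda[members, t] +
          es$process_shift
      }
    }
  }
  lo <- cfg$go_term_size_range[1]; hi <- cfg$go_term_size_range[2]
  sizes <- pmin(hi, pmax(lo, round(exp(rnorm(cfg$n_go_terms, log(12), 0.9)))))
  for (i in seq_len(cfg$n_go_terms)) {
    go[[sprintf("GO:R_%04d", i)]] <- sort(sample(genes, sizes[i]))
  }
  go_annotations <- tibble::tibble(
    term = rep(names(go), lengths(go)),
    gene = unlist(go, use.names = FALSE)
  )

  # Counts: Poisson around lambda * per-sample depth.
  lambda <- 2^log2_lambda
  n_s <- cfg$samples_per_tissue
  sample_ids <- paste0("s", sprintf("%04d", seq_len(n_t * n_s)))
  sample_tissue <- rep(tissues, each = n_s)
  depth <- exp(rnorm(n_t * n_s, log(3), 0.2))
  counts <- matrix(0L, cfg$n_genes, n_t * n_s,
                   dimnames = list(genes, sample_ids))
  for (j in seq_len(n_t * n_s)) {
    counts[, j] <- rpois(cfg$n_genes, lambda[, sample_tissue[j]] * depth[j])
  }
  samples <- tibble::tibble(sample = sample_ids, tissue = sample_tissue)

  # Approximate expressed calls from the expected cpm, used to structure the
  # PPI boost before normalization exists.
  exp_cpm <- sweep(lambda, 2L, colSums(lambda), "/") * 1e6
  expressed_approx <- exp_cpm >= 7

  # PPI: Chung-Lu with truncated power-law weights, plus within-block edges
  # (co-expression structure) and the planted tissue-density boost.
  w <- pmin((1 - runif(cfg$n_genes))^(-1 / 1.5), 60)
  m_edges <- round(cfg$n_genes * cfg$ppi_mean_degree / 2)
  a <- sample(genes, m_edges, replace = TRUE, prob = w)
  b <- sample(genes, m_edges, replace = TRUE, prob = w)
  for (t in tissues) {
    blk <- genes[block_gene & block_tissue == t]
    if (length(blk) >= 2L) {
      extra <- round(length(blk) * 1.5)
      a <- c(a, sample(blk, extra, replace = TRUE))
      b <- c(b, sample(blk, extra, replace = TRUE))
    }
  }
  boost_n <- round(es$ppi_density_boost * cfg$ppi_mean_degree)
  if (boost_n > 0) {
    for (t in tissues) {
      partners <- genes[expressed_approx[, t]]
      for (g in positives[[t]]) {
        a <- c(a, rep(g, boost_n))
        b <- c(b, sample(partners, boost_n))
      }
    }
  }
  ppi_edges <- canonical_edges(tibble::tibble(gene_a = a, gene_b = b),
                               quiet = TRUE)

  # Paralogs: partners matched on baseline expression so ratio features have
  # dosage structure; identity spans the 40% inclusion threshold.
  n_par <- round(cfg$n_genes * cfg$paralog_frac / 2)
  members <- sample(cfg$n_genes, 2 * n_par)
  members <- members[order(mu[members])]
  cand <- matrix(members, ncol = 2, byrow = TRUE)
  paralogs <- tibble::tibble(
    gene = genes[cand[, 1]],
    paralog = genes[cand[, 2]],
    identity = round(runif(n_par, 20, 95), 1)
  )

  # eQTL q-values: positives in their tissue get small q, planted only
  # alongside the other mechanisms (a fully null cohort plants nothing).
  eqtl <- tidyr::expand_grid(gene = genes, tissue = tissues)
  eqtl$q <- runif(nrow(eqtl))
  if (any_effect) {
    for (t in tissues) {
      hit <- eqtl$tissue == t & eqtl$gene %in% positives[[t]]
      eqtl$q[hit] <- rbeta(sum(hit), 1, 30)
    }
  }
  eqtl <- eqtl[runif(nrow(eqtl)) >= cfg$eqtl_missing, ]

  # Disease-gene-tissue associations: one disease per disease-pool gene,
  # associated with all tissues the gene was planted for; pool genes planted
  # nowhere get a disease of a non-modeled tissue ("other").
  pos_tissues <- lapply(setNames(disease_pool, disease_pool), function(g) {
    tissues[vapply(tissues, function(t) g %in% positives[[t]], logical(1))]
  })
  assoc <- purrr::map2_dfr(disease_pool, pos_tissues, function(g, ts) {
    if (length(ts) == 0L) ts <- "other"
    tibble::tibble(disease = paste0("D_", g), gene = g, tissue = ts)
  })

  truth <- purrr::map_dfr(tissues, function(t) {
    tibble::tibble(
      tissue = t, gene = positives[[t]],
      mech_expression = es$pref_expr_shift != 0,
      mech_process = es$process_shift != 0,
      mech_ppi = boost_n > 0,
      planted_term = if (is.null(truth_terms[[t]])) NA_character_ else
        unname(truth_terms[[t]][positives[[t]]])
    )
  })

  structure(
    list(counts = counts, samples = samples,
         dev_expression = simulate_dev_expression(cfg, genes, mu),
         ppi_edges = ppi_edges, go_annotations = go_annotations,
         paralogs = paralogs, eqtl_q = tibble::as_tibble(eqtl),
         associations = assoc, truth = truth, config = cfg),
    class = "trace_cohort"
  )
}

simulate_dev_expression <- function(cfg, genes, mu) {
  organs <- c("cerebrum", "cerebellum", "heart", "kidney", "liver", "ovary",
              "testis")[seq_len(cfg$n_dev_organs)]
  if (cfg$n_dev_organs > 7L) {
    organs <- c(organs, sprintf("organ%02d", seq_len(cfg$n_dev_organs - 7L)))
  }
  tps <- sprintf("tp%02d", seq_len(cfg$n_dev_timepoints))
  grid <- tidyr::expand_grid(organ = organs, timepoint = tps,
                             sample = c("r1", "r2"), gene = genes)
  organ_dev <- matrix(rnorm(length(genes) * length(organs), 0, 0.5),
                      length(genes), length(organs),
                      dimnames = list(genes, organs))
  tp_dev <- matrix(rnorm(length(genes) * length(tps), 0, 0.4),
                   length(genes), length(tps),
                   dimnames = list(genes, tps))
  base <- mu[match(grid$gene, genes)] +
    organ_dev[cbind(grid$gene, grid$organ)] +
    tp_dev[cbind(grid$gene, grid$timepoint)]
  grid$value <- 2^(base + rnorm(nrow(grid), 0, 0.2))
  grid
}

#' @export
print.trace_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic cohort: %d genes, %d tissues x %d samples, %d PPI edges,\n",
    "  %d GO terms, %d paralog pairs, %d planted positives\n"),
    nrow(x$counts), length(x$config$tissues), x$config$samples_per_tissue,
    nrow(x$ppi_edges), dplyr::n_distinct(x$go_annotations$term),
    nrow(x$paralogs), nrow(x$truth)))
  invisible(x)
}

#' Simulate patient cases from a synthetic cohort
#'
#' Each case has one affected tissue, one verified gene drawn from that
#' tissue's planted positives, and `candidates_per_patient - 1` decoys drawn
#' from genes not positive for that tissue. The verified gene is always in
#' the candidate list, emulating a filtered exome candidate list.
#'
#' @param bundle A `trace_cohort` from [generate_cohort()].
#' @param n_patients Number of cases.
#' @param candidates_per_patient Candidate list size (>= 2; the scale of a
#'   median filtered exome is around 186 candidates).
#' @param seed Integer seed.
#' @param gene_universe Genes candidates may be drawn from (default: all
#'   cohort genes; pass the feature-table genes so every candidate is
#'   scoreable).
#' @return Tibble with one row per case: `patient`, `tissue`,
#'   `verified_gene`, and a `candidates` list-column.
#' @export
generate_patient_cases <- function(bundle, n_patients,
                                   candidates_per_patient = 186, seed = 1,
                                   gene_universe = NULL) {
  stopifnot(inherits(bundle, "trace_cohort"))
  if (candidates_per_patient < 2L) {
    stop("candidates_per_patient must be >= 2 (no decoys possible)",
         call. = FALSE)
  }
  if (nrow(bundle$truth) == 0L) {
    stop("cohort has no planted positives; cannot generate cases",
         call. = FALSE)
  }
  set.seed(child_seed(seed, "patients"))
  genes <- gene_universe %||% rownames(bundle$counts)
  purrr::map_dfr(seq_len(n_patients), function(i) {
    tissue <- sample(unique(bundle$truth$tissue), 1L)
    pos_t <- intersect(bundle$truth$gene[bundle$truth$tissue == tissue],
                       genes)
    if (length(pos_t) == 0L) {
      stop(sprintf("tissue '%s' has no planted positives in the universe",
                   tissue), call. = FALSE)
    }
    verified <- sample(pos_t, 1L)
    decoy_pool <- setdiff(genes, pos_t)
    decoys <- sample(decoy_pool, candidates_per_patient - 1L)
    tibble::tibble(patient = sprintf("p%03d", i), tissue = tissue,
                   verified_gene = verified,
                   candidates = list(sample(c(verified, decoys))))
  })
}
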
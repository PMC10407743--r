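# Independent oracles, implemented straight from the published formulas and
# kept free of any package internals.

# Robinson-Oshlack TMM scaling factors: reference sample = upper-quartile
# rate closest to the mean; 30% two-sided trim on M, 5% on A; weighted mean
# of M with inverse asymptotic variances; factors normalized to geometric
# mean 1.
tmm_oracle <- function(counts) {
  lib <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)), function(j) {
    quantile(counts[, j], 0.75, names = FALSE) / lib[j]
  }, numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  xr <- counts[, ref]
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    x <- counts[, j]
    ok <- x > 0 & xr > 0
    M <- log2((x[ok] / lib[j]) / (xr[ok] / lib[ref]))
    A <- 0.5 * log2((x[ok] / lib[j]) * (xr[ok] / lib[ref]))
    w <- (lib[j] - x[ok]) / (lib[j] * x[ok]) +
      (lib[ref] - xr[ok]) / (lib[ref] * xr[ok])
    fin <- is.finite(M) & is.finite(A) & A > -1e10
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (max(abs(M)) < 1e-6) {
      f[j] <- 1
      next
    }
    n <- length(M)
    loM <- floor(n * 0.3) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1
    hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    f[j] <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f / exp(mean(log(f)))
}

# Direct per-gene preferential-expression loop.
pref_oracle <- function(med) {
  out <- med * NA_real_
  for (g in seq_len(nrow(med))) {
    v <- med[g, ]
    iqr <- unname(diff(quantile(v, c(0.25, 0.75), type = 7)))
    out[g, ] <- if (iqr == 0) 0 else (v - median(v)) / iqr
  }
  out
}

# Brute-force expressed call.
expressed_oracle <- function(cpm, tissue_of, threshold = 7) {
  tissues <- unique(tissue_of)
  out <- matrix(FALSE, nrow(cpm), length(tissues),
                dimnames = list(rownames(cpm), tissues))
  for (g in seq_len(nrow(cpm))) {
    for (t in tissues) {
      cols <- names(tissue_of)[tissue_of == t]
      n_t <- length(cols)
      out[g, t] <- sum(cpm[g, cols] >= threshold) >= n_t / 2
    }
  }
  out
}

# Nested-loop PPI count oracle: returns list of 3 primary matrices.
ppi_oracle <- function(edges, expressed, preferential, specific_max = 0.2) {
  genes <- rownames(expressed)
  tissues <- colnames(expressed)
  nbrs <- lapply(setNames(genes, genes), function(g) {
    c(edges$gene_b[edges$gene_a == g], edges$gene_a[edges$gene_b == g])
  })
  t1 <- t2 <- t3 <- matrix(0, length(genes), length(tissues),
                           dimnames = list(genes, tissues))
  for (g in genes) {
    for (t in tissues) {
      if (!expressed[g, t]) {
        t3[g, t] <- NA_real_
        next
      }
      nb <- nbrs[[g]]
      tissue_int <- nb[expressed[nb, t]]
      t1[g, t] <- length(tissue_int)
      t2[g, t] <- sum(preferential[nb, t])
      if (length(tissue_int) == 0L) {
        t3[g, t] <- NA_real_
        next
      }
      cnt <- 0L
      for (p in tissue_int) {
        co <- sum(expressed[g, ] & expressed[p, ])
        if (co <= specific_max * length(tissues)) cnt <- cnt + 1L
      }
      t3[g, t] <- cnt
    }
  }
  list(tissue = t1, pref = t2, specific = t3)
}

# Direct process-activity loop.
process_oracle <- function(med, go, eps = 1, size_range = c(3, 100)) {
  go <- go[go$gene %in% rownames(med), ]
  go <- unique(go)
  keep <- names(which(table(go$term) >= size_range[1] &
                        table(go$term) <= size_range[2]))
  go <- go[go$term %in% keep, ]
  tissues <- colnames(med)
  terms <- sort(unique(go$term))
  out <- matrix(NA_real_, length(terms), length(tissues),
                dimnames = list(terms, tissues))
  for (tm in terms) {
    members <- go$gene[go$term == tm]
    for (t in tissues) {
      lfc <- vapply(members, function(g) {
        ref <- median(med[g, setdiff(tissues, t)])
        log2((med[g, t] + eps) / (ref + eps))
      }, numeric(1))
      out[tm, t] <- mean(lfc)
    }
  }
  out
}

# Exact one-sided Mann-Whitney p by enumeration of group assignments.
mw_exact_oracle <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v)
  k <- length(x)
  u_obs <- sum(rank(all_v)[seq_len(k)]) - k * (k + 1) / 2
  combs <- utils::combn(n, k)
  u_all <- apply(combs, 2L, function(idx) {
    sum(rank(all_v)[idx]) - k * (k + 1) / 2
  })
  mean(u_all >= u_obs)
}
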
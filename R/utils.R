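# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

# IQR with linear-interpolation (type 7) percentiles; convention recorded in
# run metadata by callers.
iqr7 <- function(x) {
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  q[2L] - q[1L]
}

# Affine map of a vector onto [lo, hi]; constant input maps to the midpoint.
scale_minmax <- function(x, lo = -1, hi = 1) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(rep((lo + hi) / 2, length(x)))
  }
  lo + (hi - lo) * (x - rng[1]) / (rng[2] - rng[1])
}

# Rank-based AUC (Mann-Whitney statistic); labels are 0/1.
rank_auc <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: labels contain a single class", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the precision-recall curve as average precision:
# sum over thresholds of (recall_i - recall_{i-1}) * precision_i.
average_precision <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos)
  if (n1 == 0L) stop("auPRC undefined: no positives", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y <- as.integer(pos[ord])
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / n1
  d_recall <- diff(c(0, recall))
  sum(precision * d_recall)
}

# Stratified fold assignment: positives and negatives shuffled separately and
# dealt round-robin so fold positive counts differ by at most one gene.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Deterministic ranking: descending score, ties broken lexicographically by id.
# Returns a permutation of 1..n.
rank_descending <- function(score, id) {
  ord <- order(-score, id)
  r <- integer(length(score))
  r[ord] <- seq_along(score)
  r
}

# Derive a bounded child seed from a parent seed and a stream label.
child_seed <- function(seed, stream) {
  offsets <- c(cohort = 11L, patients = 23L, walks = 37L, impute = 53L,
               folds = 71L, learner = 89L, meta = 101L)
  off <- offsets[[stream]] %||% 7L
  (as.integer(seed) * 7919L + off * 104729L) %% 2147483587L
}

check_gene_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("%s must be a matrix with gene rownames and colnames", what),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate column ids", call. = FALSE)
  invisible(x)
}
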
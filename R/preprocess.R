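# Preprocessing: chained imputation, Yeo-Johnson symmetrization of the
# expression families, and per-feature min-max scaling onto [-1, 1]. The
# fitted state is kept so withheld genes (patient candidates) can be
# transformed with training-time parameters only.

#' Iteratively impute missing feature values
#'
#' Missing cells are initialized to the feature median, then each feature
#' with missingness is re-predicted by a Bayesian ridge regression on its
#' `neighbors` most correlated features (largest absolute Pearson
#' correlation on the current complete values), sweeping features in
#' ascending-missingness order (ties by feature id) for `iterations`
#' rounds. Observed cells never change. Features that are entirely missing
#' are dropped with a warning; features constant on their observed cells
#' keep the median fill and are skipped as regression targets.
#'
#' @param table A `feature_table` (missing values allowed).
#' @param iterations Sweep count (default 10).
#' @param neighbors Neighbor features per target (default 100).
#' @return List with `table` (no missing cells) and `state` (reusable via
#'   [apply_preprocess()]).
#' @export
impute_features <- function(table, iterations = 10, neighbors = 100) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values
  all_missing <- colSums(!is.na(X)) == 0L
  if (any(all_missing)) {
    warning(sprintf("dropped %d feature(s) with no observed values: %s",
                    sum(all_missing),
                    paste(head(colnames(X)[all_missing], 5L),
                          collapse = ", ")), call. = FALSE)
    X <- X[, !all_missing, drop = FALSE]
    table <- feature_table(X, table$meta[!all_missing, ])
  }
  miss <- is.na(X)
  medians <- apply(X, 2L, median, na.rm = TRUE)
  X_init <- X
  for (j in which(colSums(miss) > 0L)) X_init[miss[, j], j] <- medians[j]

  frac <- colMeans(miss)
  obs_sd <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[!miss[, j], j]
    if (length(v) < 2L) 0 else sd(v)
  }, numeric(1))
  target_cols <- which(frac > 0 & obs_sd > 0)
  target_cols <- target_cols[order(frac[target_cols],
                                   colnames(X)[target_cols])]

  if (length(target_cols) > 0L) {
    cm <- suppressWarnings(cor(X_init))
    cm[!is.finite(cm)] <- 0
    nb <- lapply(target_cols, function(j) {
      r <- abs(cm[, j])
      r[j] <- -1  # never select the target itself
      k <- min(neighbors, ncol(X) - 1L)
      ord <- order(-r, colnames(X))
      as.integer(ord[seq_len(k)] - 1L)
    })
    X_done <- impute_chain_cpp(X_init, miss * 1L,
                               as.integer(target_cols - 1L), nb,
                               as.integer(iterations))
    coefs <- impute_final_models_cpp(X_done, miss * 1L,
                                     as.integer(target_cols - 1L), nb)
  } else {
    X_done <- X_init
    nb <- list()
    coefs <- list()
  }
  dimnames(X_done) <- dimnames(X)
  state <- list(features = colnames(X), medians = medians,
                targets = colnames(X)[target_cols],
                neighbors = lapply(nb, function(i) colnames(X)[i + 1L]),
                coefs = coefs, iterations = iterations)
  list(table = feature_table(X_done, table$meta), state = state)
}

# Yeo-Johnson transform for a fixed lambda; strictly monotone in x.
yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) > 1e-10) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  l2 <- 2 - lambda
  if (abs(l2) > 1e-10) {
    out[!pos] <- -((-x[!pos] + 1)^l2 - 1) / l2
  } else {
    out[!pos] <- -log1p(-x[!pos])
  }
  out
}

# Maximum-likelihood lambda for the Yeo-Johnson transform (profile
# log-likelihood, normal model), searched on [-5, 5].
fit_yeo_johnson <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || sd(x) == 0) return(NA_real_)
  ll <- function(lambda) {
    y <- yeo_johnson(x, lambda)
    s2 <- mean((y - mean(y))^2)
    if (!is.finite(s2) || s2 <= 0) return(-Inf)
    -0.5 * length(x) * log(s2) +
      (lambda - 1) * sum(sign(x) * log1p(abs(x)))
  }
  opt <- tryCatch(optimize(ll, c(-5, 5), maximum = TRUE),
                  error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$objective)) return(NA_real_)
  opt$maximum
}

#' Symmetrize skewed feature families with the Yeo-Johnson transform
#'
#' Each feature in the named families is replaced by its Yeo-Johnson
#' transform with lambda fitted per feature by maximum likelihood. The
#' transform is strictly monotone, so within-column ranks are preserved.
#' Features whose lambda fit fails are left untransformed with a warning.
#'
#' @param table A `feature_table` with no missing cells.
#' @param families Families to transform (default the expression and
#'   preferential-expression features, whose distributions are the
#'   nonsymmetrical ones).
#' @param lambdas Optional named vector of frozen lambdas (training-time
#'   parameters applied to new genes).
#' @return List with `table` and `lambdas` (named vector, NA = skipped).
#' @export
transform_features <- function(table,
                               families = c("expression",
                                            "preferential_expression"),
                               lambdas = NULL) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values
  cols <- table$meta$feature[table$meta$family %in% families]
  if (is.null(lambdas)) {
    lambdas <- vapply(cols, function(f) fit_yeo_johnson(X[, f]), numeric(1))
    if (anyNA(lambdas)) {
      warning(sprintf("Yeo-Johnson fit failed for %d feature(s); left %s",
                      sum(is.na(lambdas)), "untransformed"), call. = FALSE)
    }
  }
  for (f in intersect(cols, names(lambdas))) {
    if (!is.na(lambdas[[f]])) X[, f] <- yeo_johnson(X[, f], lambdas[[f]])
  }
  list(table = feature_table(X, table$meta), lambdas = lambdas)
}

#' Scale every feature onto [-1, 1]
#'
#' Affine per-feature map `x -> 2 (x - min) / (max - min) - 1`; affine maps
#' are the shape-preserving maps onto the interval. Constant features map
#' to 0 everywhere.
#'
#' @param table A `feature_table` with no missing cells.
#' @param ranges Optional tibble (`feature`, `min`, `max`) of frozen
#'   training-time ranges; new genes may then fall outside [-1, 1].
#' @return List with `table` and `ranges`.
#' @export
scale_features <- function(table, ranges = NULL) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$values
  if (anyNA(X)) stop("scale_features requires a complete table", call. = FALSE)
  if (is.null(ranges)) {
    ranges <- tibble::tibble(feature = colnames(X),
                             min = apply(X, 2L, min),
                             max = apply(X, 2L, max))
  }
  rmin <- setNames(ranges$min, ranges$feature)[colnames(X)]
  rmax <- setNames(ranges$max, ranges$feature)[colnames(X)]
  span <- rmax - rmin
  const <- span == 0
  span[const] <- 1
  X <- sweep(sweep(X, 2L, rmin, "-"), 2L, span / 2, "/") - 1
  X[, const] <- 0
  list(table = feature_table(X, table$meta), ranges = ranges)
}

#' Full preprocessing pipeline with reusable state
#'
#' Imputation, then Yeo-Johnson symmetrization of the expression families,
#' then per-feature scaling onto [-1, 1]. The returned state freezes every
#' fitted statistic so withheld genes are transformed without touching
#' training-time parameters.
#'
#' @inheritParams impute_features
#' @inheritParams transform_features
#' @return List with `table` (complete, scaled) and `state` (class
#'   `tt_preprocess_state`).
#' @export
preprocess_features <- function(table, iterations = 10, neighbors = 100,
                                families = c("expression",
                                             "preferential_expression")) {
  imp <- impute_features(table, iterations, neighbors)
  tr <- transform_features(imp$table, families)
  sc <- scale_features(tr$table)
  state <- structure(
    list(impute = imp$state, lambdas = tr$lambdas, ranges = sc$ranges,
         families = families,
         metadata = list(percentile_convention = "type7",
                         sd_convention = "sample (n-1)",
                         scaling = "per-feature min-max")),
    class = "tt_preprocess_state"
  )
  list(table = sc$table, state = state)
}

#' Apply a frozen preprocessing state to new genes
#'
#' @param state A `tt_preprocess_state` from [preprocess_features()].
#' @param table A `feature_table` over new genes with the training-time
#'   feature columns.
#' @return A `feature_table`, complete and scaled with training parameters.
#' @export
apply_preprocess <- function(state, table) {
  stopifnot(inherits(state, "tt_preprocess_state"),
            inherits(table, "feature_table"))
  keep <- table$meta$feature %in% state$impute$features
  table <- feature_table(table$values[, keep, drop = FALSE],
                         table$meta[keep, ])
  X <- table$values[, state$impute$features, drop = FALSE]
  meta <- table$meta[match(state$impute$features, table$meta$feature), ]
  miss <- is.na(X)
  for (j in seq_len(ncol(X))) {
    X[miss[, j], j] <- state$impute$medians[[j]]
  }
  tcols <- match(state$impute$targets, colnames(X))
  if (length(tcols) > 0L) {
    nb <- lapply(state$impute$neighbors,
                 function(f) as.integer(match(f, colnames(X)) - 1L))
    usable <- vapply(state$impute$coefs, length, integer(1)) > 0L
    X <- impute_apply_cpp(X, miss * 1L, as.integer(tcols[usable] - 1L),
                          nb[usable], state$impute$coefs[usable],
                          as.integer(state$impute$iterations))
    dimnames(X) <- list(rownames(table$values), state$impute$features)
  }
  tab <- feature_table(X, meta)
  tab <- transform_features(tab, state$families, lambdas = state$lambdas)$table
  scale_features(tab, ranges = state$ranges)$table
}
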
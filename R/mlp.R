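# Small multilayer perceptron for binary classification, mirroring the
# scikit-learn MLPClassifier semantics the stacking framework expects: ReLU
# hidden layers, logistic output, L2 penalty `alpha` (scaled per batch),
# minibatch training with Adam, or SGD with momentum and an adaptive
# learning rate (divided by 5 after `n_iter_no_change` stagnant epochs).
# The training loop lives in C++ (src/mlp.cpp) and is bit-reproducible
# under a fixed seed on a single thread.

fit_mlp <- function(X, y, hidden = c(10, 10), alpha = 0.5,
                    batch_size = 200, solver = c("adam", "sgd"),
                    learning_rate_init = NULL, adaptive = FALSE,
                    max_iter = 200, tol = 1e-4, n_iter_no_change = 10,
                    seed = 1) {
  solver <- match.arg(solver)
  lr <- learning_rate_init %||% if (solver == "adam") 1e-3 else 0.01
  fit <- mlp_train_cpp(X, as.numeric(y), as.integer(hidden), alpha,
                       as.integer(batch_size),
                       ifelse(solver == "adam", 0L, 1L), lr,
                       isTRUE(adaptive), as.integer(max_iter), tol,
                       as.integer(n_iter_no_change), as.integer(seed))
  structure(list(par = list(W = fit$W,
                            b = lapply(fit$b, as.vector)),
                 hidden = hidden, alpha = alpha, solver = solver,
                 epochs = fit$epochs),
            class = "tt_mlp")
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  act <- vector("list", L + 1L)
  act[[1L]] <- X
  for (l in seq_len(L)) {
    z <- act[[l]] %*% par$W[[l]]
    z <- sweep(z, 2L, par$b[[l]], "+")
    act[[l + 1L]] <- if (l < L) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  act
}

predict_mlp <- function(fit, X) {
  act <- mlp_forward(fit$par, X)
  as.vector(act[[length(act)]])
}
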
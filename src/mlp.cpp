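// Minibatch training loop for the in-package multilayer perceptron (ReLU
// hidden layers, logistic output, per-batch L2 penalty), with Adam or SGD
// plus momentum and an optional adaptive learning rate (divide by 5 after
// `n_iter_no_change` stagnant epochs). Seeded mt19937 shuffling keeps runs
// bit-identical on a single thread.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List mlp_train_cpp(const arma::mat& X, const arma::vec& y,
                         const arma::ivec& hidden, double alpha,
                         int batch_size, int solver, double lr_init,
                         bool adaptive, int max_iter, double tol,
                         int n_iter_no_change, int seed) {
  const uword n = X.n_rows, p = X.n_cols;
  const uword L = hidden.n_elem + 1;
  std::mt19937 rng(static_cast<uint32_t>(seed));

  std::vector<uword> sizes;
  sizes.push_back(p);
  for (uword l = 0; l < hidden.n_elem; ++l) {
    sizes.push_back(static_cast<uword>(hidden[l]));
  }
  sizes.push_back(1);

  std::vector<mat> W(L), mW(L), vW(L), velW(L);
  std::vector<rowvec> b(L), mb(L), vb(L), velb(L);
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  for (uword l = 0; l < L; ++l) {
    double lim = std::sqrt(6.0 / (sizes[l] + sizes[l + 1]));
    W[l].set_size(sizes[l], sizes[l + 1]);
    for (uword j = 0; j < W[l].n_cols; ++j) {      // column-major fill so
      for (uword i = 0; i < W[l].n_rows; ++i) {    // draws are ordered
        W[l](i, j) = lim * unif(rng);
      }
    }
    b[l].zeros(sizes[l + 1]);
    mW[l].zeros(size(W[l])); vW[l].zeros(size(W[l]));
    velW[l].zeros(size(W[l]));
    mb[l].zeros(sizes[l + 1]); vb[l].zeros(sizes[l + 1]);
    velb[l].zeros(sizes[l + 1]);
  }

  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double lr = lr_init;
  long step = 0;
  double best_loss = datum::inf;
  int stagnant = 0;
  int bsz = std::min<int>(batch_size, n);
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;

  std::vector<mat> act(L + 1), gWl(L);
  std::vector<rowvec> gbl(L);
  int epoch = 0;
  for (epoch = 1; epoch <= max_iter; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double epoch_loss = 0.0;
    for (uword s = 0; s < n; s += bsz) {
      uword e = std::min<uword>(s + bsz, n);
      uvec rows(e - s);
      for (uword i = s; i < e; ++i) rows[i - s] = idx[i];
      const double m = static_cast<double>(rows.n_elem);
      act[0] = X.rows(rows);
      for (uword l = 0; l < L; ++l) {
        act[l + 1] = act[l] * W[l];
        act[l + 1].each_row() += b[l];
        if (l + 1 < L) {
          act[l + 1].transform([](double v) { return v > 0 ? v : 0.0; });
        } else {
          act[l + 1].transform([](double v) {
            return 1.0 / (1.0 + std::exp(-v));
          });
        }
      }
      vec prob = act[L].col(0);
      vec yb = y.elem(rows);
      vec pc = clamp(prob, 1e-10, 1.0 - 1e-10);
      double pen = 0.0;
      for (uword l = 0; l < L; ++l) pen += accu(square(W[l]));
      epoch_loss += -accu(yb % log(pc) + (1.0 - yb) % log(1.0 - pc)) +
        0.5 * alpha * pen * m / n;

      mat delta = (prob - yb) / m;
      for (uword l = L; l-- > 0;) {
        gWl[l] = act[l].t() * delta + (alpha / n) * W[l];
        gbl[l] = sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta %= conv_to<mat>::from(act[l] > 0);
        }
      }
      if (solver == 0) {  // adam
        ++step;
        double corr = std::sqrt(1.0 - std::pow(b2, step)) /
          (1.0 - std::pow(b1, step));
        for (uword l = 0; l < L; ++l) {
          mW[l] = b1 * mW[l] + (1 - b1) * gWl[l];
          vW[l] = b2 * vW[l] + (1 - b2) * square(gWl[l]);
          W[l] -= lr * corr * mW[l] / (sqrt(vW[l]) + eps);
          mb[l] = b1 * mb[l] + (1 - b1) * gbl[l];
          vb[l] = b2 * vb[l] + (1 - b2) * square(gbl[l]);
          b[l] -= lr * corr * mb[l] / (sqrt(vb[l]) + eps);
        }
      } else {  // sgd + momentum
        for (uword l = 0; l < L; ++l) {
          velW[l] = 0.9 * velW[l] - lr * gWl[l];
          velb[l] = 0.9 * velb[l] - lr * gbl[l];
          W[l] += velW[l];
          b[l] += velb[l];
        }
      }
    }
    epoch_loss /= n;
    if (epoch_loss > best_loss - tol) ++stagnant; else stagnant = 0;
    if (epoch_loss < best_loss) best_loss = epoch_loss;
    if (stagnant >= n_iter_no_change) {
      if (adaptive && solver == 1) {
        lr /= 5.0;
        stagnant = 0;
        if (lr < 1e-6) break;
      } else {
        break;
      }
    }
  }

  Rcpp::List Wout(L), bout(L);
  for (uword l = 0; l < L; ++l) {
    Wout[l] = Rcpp::wrap(W[l]);
    bout[l] = Rcpp::wrap(mat(b[l]));
  }
  return Rcpp::List::create(Rcpp::Named("W") = Wout,
                            Rcpp::Named("b") = bout,
                            Rcpp::Named("epochs") = epoch);
}
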
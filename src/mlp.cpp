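// Mini-batch Adam trainer for a small dense feed-forward network
// (tanh hidden layers, linear scalar output). All randomness — weight
// initialization and per-epoch shuffling — is drawn on the R side and
// passed in, so training is bit-reproducible for a fixed R seed.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::vec forward(const arma::mat& X,
                         const std::vector<arma::mat>& W,
                         const std::vector<arma::vec>& b,
                         std::vector<arma::mat>* acts) {
  // X: m x p (rows = observations); layer l maps a_{l-1} (m x n_{l-1})
  // to a_l = f(a_{l-1} W_l + 1 b_l')
  arma::mat a = X;
  if (acts) acts->push_back(a);
  const size_t L = W.size();
  for (size_t l = 0; l < L; ++l) {
    arma::mat z = a * W[l];
    z.each_row() += b[l].t();
    a = (l + 1 < L) ? arma::tanh(z) : z;
    if (acts) acts->push_back(a);
  }
  return a.col(0);
}

static double mse(const arma::vec& pred, const arma::vec& y) {
  arma::vec d = pred - y;
  return arma::dot(d, d) / d.n_elem;
}

// [[Rcpp::export(name = ".mlp_train_cpp")]]
List mlp_train_cpp(const arma::mat& Xtr, const arma::vec& ytr,
                   const arma::mat& Xval, const arma::vec& yval,
                   List W0, List b0, const arma::imat& perms,
                   double lr, double beta1, double beta2, double eps,
                   int batch_size) {
  const size_t L = W0.size();
  std::vector<arma::mat> W(L), mW(L), vW(L);
  std::vector<arma::vec> b(L), mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(W0[l]);
    b[l] = as<arma::vec>(b0[l]);
    mW[l].zeros(W[l].n_rows, W[l].n_cols);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mb[l].zeros(b[l].n_elem);
    vb[l].zeros(b[l].n_elem);
  }
  const int epochs = perms.n_rows;
  const int ntr = Xtr.n_rows;
  arma::vec train_mse(epochs), val_mse(epochs);
  long t = 0;  // Adam timestep
  // checkpoint of the best-validation epoch
  std::vector<arma::mat> bW = W;
  std::vector<arma::vec> bb = b;
  double best_score = 0;
  int best_epoch = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int start = 0; start < ntr; start += batch_size) {
      const int stop = std::min(start + batch_size, ntr) - 1;
      const int m = stop - start + 1;
      arma::uvec idx(m);
      for (int k = 0; k < m; ++k) idx[k] = perms(ep, start + k) - 1;
      arma::mat Xb = Xtr.rows(idx);
      arma::vec yb = ytr.elem(idx);

      std::vector<arma::mat> acts;
      arma::vec pred = forward(Xb, W, b, &acts);
      if (!pred.is_finite())
        Rcpp::stop("training diverged (non-finite loss); lower the learning rate");

      // backward: delta at output = dL/dz_L, MSE loss
      arma::mat delta = acts[L];
      delta.col(0) -= yb;
      delta *= 2.0 / m;
      ++t;
      const double c1 = 1.0 - std::pow(beta1, (double)t);
      const double c2 = 1.0 - std::pow(beta2, (double)t);
      for (int l = (int)L - 1; l >= 0; --l) {
        arma::mat gW = acts[l].t() * delta;
        arma::vec gb = arma::sum(delta, 0).t();
        if (l > 0) {
          arma::mat da = delta * W[l].t();
          delta = da % (1.0 - arma::square(acts[l]));  // tanh'
        }
        mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1 - beta2) * arma::square(gW);
        W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
        mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1 - beta2) * arma::square(gb);
        b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
      }
    }
    train_mse[ep] = mse(forward(Xtr, W, b, nullptr), ytr);
    val_mse[ep] = Xval.n_rows ? mse(forward(Xval, W, b, nullptr), yval)
                              : NA_REAL;
    if (!std::isfinite(train_mse[ep]))
      Rcpp::stop("training diverged (non-finite loss); lower the learning rate");
    const double score = Xval.n_rows ? val_mse[ep] : train_mse[ep];
    if (ep == 0 || score < best_score) {
      best_score = score;
      best_epoch = ep;
      bW = W;
      bb = b;
    }
  }

  List Wout(L), bout(L), WbestOut(L), bbestOut(L);
  for (size_t l = 0; l < L; ++l) {
    Wout[l] = W[l];
    bout[l] = b[l];
    WbestOut[l] = bW[l];
    bbestOut[l] = bb[l];
  }
  arma::vec fitted = forward(Xtr, W, b, nullptr);
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["W_best"] = WbestOut, _["b_best"] = bbestOut,
                      _["best_epoch"] = best_epoch + 1,
                      _["train_mse"] = train_mse, _["val_mse"] = val_mse,
                      _["fitted"] = fitted);
}

// [[Rcpp::export(name = ".mlp_forward_cpp")]]
arma::vec mlp_forward_cpp(const arma::mat& X, List Wl, List bl) {
  const size_t L = Wl.size();
  std::vector<arma::mat> W(L);
  std::vector<arma::vec> b(L);
  for (size_t l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(Wl[l]);
    b[l] = as<arma::vec>(bl[l]);
  }
  return forward(X, W, b, nullptr);
}
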
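// Minimal feed-forward network used for the deep-learning summary
// statistics: four ReLU hidden layers with a softmax (classification) or
// linear (regression) head, trained by Adam on minibatches with early
// stopping on a validation split. R's RNG drives initialization and
// shuffling so training is reproducible via set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::vec;

namespace {

mat he_init(int rows, int cols) {
  mat W(rows, cols);
  double s = std::sqrt(2.0 / rows);
  for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = norm_rand() * s;
  return W;
}

// forward pass; returns activations per layer (a[0] = X)
void forward(const std::vector<mat>& W, const std::vector<arma::rowvec>& b,
             const mat& X, int task, std::vector<mat>& a) {
  const int nl = W.size();
  a.assign(nl + 1, mat());
  a[0] = X;
  for (int l = 0; l < nl; ++l) {
    mat z = a[l] * W[l];
    z.each_row() += b[l];
    if (l < nl - 1) {
      a[l + 1] = arma::clamp(z, 0.0, arma::datum::inf);  // ReLU
    } else if (task == 0) {
      z.each_col() -= arma::max(z, 1);  // stable softmax
      mat e = arma::exp(z);
      e.each_col() /= arma::sum(e, 1);
      a[l + 1] = e;
    } else {
      a[l + 1] = z;
    }
  }
}

double loss_of(const mat& out, const mat& Y, int task) {
  if (task == 0) {
    return -arma::accu(Y % arma::log(out + 1e-12)) / out.n_rows;
  }
  return 0.5 * arma::accu(arma::square(out - Y)) / out.n_rows;
}

}  // namespace

// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& X, const arma::mat& Y,
                   IntegerVector hidden, int task,
                   double lr, int batch, int max_epochs, int patience,
                   double val_frac) {
  const int n = X.n_rows, d = X.n_cols, k = Y.n_cols;
  std::vector<int> sizes;
  sizes.push_back(d);
  for (int h : hidden) sizes.push_back(h);
  sizes.push_back(k);
  const int nl = sizes.size() - 1;

  std::vector<mat> W(nl);
  std::vector<arma::rowvec> b(nl);
  for (int l = 0; l < nl; ++l) {
    W[l] = he_init(sizes[l], sizes[l + 1]);
    b[l] = arma::rowvec(sizes[l + 1], arma::fill::zeros);
  }

  // random split into train/validation
  arma::uvec perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1)); if (j > i) j = i;
    std::swap(perm[i], perm[j]);
  }
  int nval = (int)std::floor(val_frac * n);
  if (nval >= n) nval = n - 1;
  const int ntr = n - nval;
  arma::uvec tr_idx = perm.head(ntr);
  arma::uvec va_idx = nval > 0 ? perm.tail(nval) : arma::uvec();
  mat Xtr = X.rows(tr_idx), Ytr = Y.rows(tr_idx);
  mat Xva, Yva;
  if (nval > 0) { Xva = X.rows(va_idx); Yva = Y.rows(va_idx); }

  std::vector<mat> mW(nl), vW(nl);
  std::vector<arma::rowvec> mb(nl), vb(nl);
  for (int l = 0; l < nl; ++l) {
    mW[l].zeros(sizes[l], sizes[l + 1]); vW[l].zeros(sizes[l], sizes[l + 1]);
    mb[l].zeros(sizes[l + 1]); vb[l].zeros(sizes[l + 1]);
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  std::vector<mat> bestW = W;
  std::vector<arma::rowvec> bestb = b;
  double best_val = R_PosInf;
  int bad = 0, epochs_run = 0;
  std::vector<mat> act;
  NumericVector val_trace;

  for (int ep = 0; ep < max_epochs; ++ep) {
    // shuffle training rows
    arma::uvec ord(ntr);
    for (int i = 0; i < ntr; ++i) ord[i] = i;
    for (int i = ntr - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1)); if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    for (int s0 = 0; s0 < ntr; s0 += batch) {
      int s1 = std::min(s0 + batch, ntr) - 1;
      arma::uvec ids = ord.subvec(s0, s1);
      mat Xb = Xtr.rows(ids), Yb = Ytr.rows(ids);
      forward(W, b, Xb, task, act);
      // output delta: both softmax-CE and linear-MSE give (out - Y)/m
      mat delta = (act[nl] - Yb) / Xb.n_rows;
      ++step;
      for (int l = nl - 1; l >= 0; --l) {
        mat gW = act[l].t() * delta;
        arma::rowvec gb = arma::sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta %= arma::conv_to<mat>::from(act[l] > 0.0);
        }
        mW[l] = b1 * mW[l] + (1 - b1) * gW;
        vW[l] = b2 * vW[l] + (1 - b2) * arma::square(gW);
        mb[l] = b1 * mb[l] + (1 - b1) * gb;
        vb[l] = b2 * vb[l] + (1 - b2) * arma::square(gb);
        double c1 = 1 - std::pow(b1, (double)step);
        double c2 = 1 - std::pow(b2, (double)step);
        W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
        b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
      }
    }
    epochs_run = ep + 1;
    if (nval > 0) {
      forward(W, b, Xva, task, act);
      double vl = loss_of(act[nl], Yva, task);
      val_trace.push_back(vl);
      if (vl < best_val - 1e-9) {
        best_val = vl; bestW = W; bestb = b; bad = 0;
      } else if (++bad >= patience) break;
    }
  }
  if (nval > 0) { W = bestW; b = bestb; }

  List lw(nl), lb(nl);
  for (int l = 0; l < nl; ++l) { lw[l] = W[l]; lb[l] = b[l]; }
  return List::create(_["W"] = lw, _["b"] = lb,
                      _["val_loss"] = best_val,
                      _["val_trace"] = val_trace,
                      _["epochs"] = epochs_run);
}

// [[Rcpp::export]]
arma::mat mlp_predict_cpp(List net, const arma::mat& X, int task) {
  List lw = net["W"], lb = net["b"];
  const int nl = lw.size();
  std::vector<mat> W(nl);
  std::vector<arma::rowvec> b(nl);
  for (int l = 0; l < nl; ++l) {
    W[l] = as<mat>(lw[l]);
    b[l] = as<arma::rowvec>(lb[l]);
  }
  std::vector<mat> act;
  forward(W, b, X, task, act);
  return act[nl];
}
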
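// Dense feed-forward ReLU regression networks: f(x) = W_{L+1} s(W_L s(... W_1 x))
// with s(x) = max(x, 0), one linear output unit, biases in every layer.
// Trained by plain mini-batch SGD on mean squared error, with inverted
// dropout after every hidden activation (training only).
//
// All randomness (initialization, per-epoch shuffles, dropout masks) comes
// from a std::mt19937 engine seeded explicitly, so a fitted network is a
// pure function of (X, y, widths, hyperparameters, seed).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Fan-in-scaled uniform init on (-1/sqrt(fan_in), 1/sqrt(fan_in)).
void init_layer(arma::mat &W, arma::vec &b, std::mt19937 &eng,
                double init_scale) {
  const double bound = init_scale / std::sqrt(static_cast<double>(W.n_cols));
  std::uniform_real_distribution<double> unif(-bound, bound);
  for (arma::uword j = 0; j < W.n_cols; ++j)
    for (arma::uword i = 0; i < W.n_rows; ++i) W(i, j) = unif(eng);
  for (arma::uword i = 0; i < b.n_elem; ++i) b(i) = unif(eng);
}

// Forward pass without dropout; X is d x n (samples in columns).
arma::rowvec forward_eval(const std::vector<arma::mat> &W,
                          const std::vector<arma::vec> &b,
                          const arma::mat &X) {
  arma::mat H = X;
  const size_t L = W.size() - 1;  // hidden layers
  for (size_t l = 0; l < L; ++l) {
    H = W[l] * H;
    H.each_col() += b[l];
    H.transform([](double v) { return v > 0.0 ? v : 0.0; });
  }
  arma::mat out = W[L] * H;
  out.each_col() += b[L];
  return arma::conv_to<arma::rowvec>::from(out.row(0));
}

// fused in-place Adam update for one parameter block
inline void adam_update(double *w, const double *g, double *m, double *v,
                        arma::uword n, double lr, double beta1, double beta2,
                        double bc1, double bc2, double eps) {
  for (arma::uword i = 0; i < n; ++i) {
    m[i] = beta1 * m[i] + (1.0 - beta1) * g[i];
    v[i] = beta2 * v[i] + (1.0 - beta2) * g[i] * g[i];
    w[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
  }
}

}  // namespace

// Train a ReLU network. X: n x d (R convention), y: length n.
// widths: hidden-layer sizes. Returns weights/biases and the average
// per-epoch minibatch loss trace.
// [[Rcpp::export]]
List cpp_relu_train(const arma::mat &X, const arma::vec &y,
                    const arma::uvec &widths, int epochs, int num_batches,
                    double learning_rate, double dropout, double momentum,
                    int use_adam, double init_scale, unsigned int seed) {
  const arma::uword n = X.n_rows, d = X.n_cols;
  const size_t L = widths.n_elem;
  std::mt19937 eng(seed);

  std::vector<arma::mat> W(L + 1);
  std::vector<arma::vec> b(L + 1);
  arma::uword fan_in = d;
  for (size_t l = 0; l < L; ++l) {
    W[l].set_size(widths[l], fan_in);
    b[l].set_size(widths[l]);
    // init_scale widens only the first hidden layer (breakpoint spread)
    init_layer(W[l], b[l], eng, l == 0 ? init_scale : 1.0);
    fan_in = widths[l];
  }
  W[L].set_size(1, fan_in);
  b[L].set_size(1);
  init_layer(W[L], b[L], eng, 1.0);

  const arma::mat Xt = X.t();  // d x n, samples in columns
  const int batch = static_cast<int>(std::ceil(static_cast<double>(n) /
                                               num_batches));
  std::vector<arma::uword> order(n);
  for (arma::uword i = 0; i < n; ++i) order[i] = i;

  const double keep = 1.0 - dropout;
  std::uniform_real_distribution<double> u01(0.0, 1.0);
  arma::vec epoch_loss(epochs, arma::fill::zeros);

  std::vector<arma::mat> A(L + 1);      // post-activation (post-dropout) outputs
  std::vector<arma::mat> mask(L);       // dropout masks
  std::vector<arma::mat> delta(L + 1);  // backprop errors

  // optimizer state: heavy-ball velocity (sgd) or first/second moments (adam)
  std::vector<arma::mat> VW(L + 1), MW(L + 1);
  std::vector<arma::vec> Vb(L + 1), Mb(L + 1);
  for (size_t l = 0; l <= L; ++l) {
    VW[l].zeros(W[l].n_rows, W[l].n_cols);
    Vb[l].zeros(b[l].n_elem);
    MW[l].zeros(W[l].n_rows, W[l].n_cols);
    Mb[l].zeros(b[l].n_elem);
  }
  const double beta1 = 0.9, beta2 = 0.999, eps_adam = 1e-8;
  long step = 0;

  arma::mat Xb, gW;
  arma::rowvec yb, err;
  arma::vec gb;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), eng);
    double loss_sum = 0.0;
    int nb = 0;
    for (arma::uword start = 0; start < n; start += batch, ++nb) {
      const arma::uword stop = std::min<arma::uword>(start + batch, n) - 1;
      const arma::uword bs = stop - start + 1;
      Xb.set_size(d, bs);
      yb.set_size(bs);
      for (arma::uword k = 0; k < bs; ++k) {
        const arma::uword i = order[start + k];
        Xb.col(k) = Xt.unsafe_col(i);
        yb(k) = y(i);
      }

      // forward with inverted dropout
      const arma::mat *Hprev = &Xb;
      for (size_t l = 0; l < L; ++l) {
        arma::mat &H = A[l];
        H = W[l] * (*Hprev);
        H.each_col() += b[l];
        if (dropout > 0.0) {
          // inverted dropout; dropped positions found by geometric skips
          // (only a `dropout` fraction of units drop, so per-element draws
          // are wasteful)
          mask[l].set_size(H.n_rows, H.n_cols);
          const double inv_keep = 1.0 / keep;
          double *h = H.memptr(), *mk = mask[l].memptr();
          const arma::uword ne = H.n_elem;
          for (arma::uword i = 0; i < ne; ++i) {
            h[i] = h[i] > 0.0 ? h[i] * inv_keep : 0.0;
            mk[i] = inv_keep;
          }
          const double log_keep = std::log(keep);
          arma::uword pos = 0;
          while (true) {
            const double u = u01(eng);
            pos += static_cast<arma::uword>(std::log1p(-u) / log_keep);
            if (pos >= ne) break;
            h[pos] = 0.0;
            mk[pos] = 0.0;
            ++pos;
          }
        } else {
          double *h = H.memptr();
          const arma::uword ne = H.n_elem;
          for (arma::uword i = 0; i < ne; ++i)
            if (h[i] < 0.0) h[i] = 0.0;
        }
        Hprev = &A[l];
      }
      err = W[L] * (*Hprev);  // 1 x bs output row
      err += b[L](0);
      err -= yb;
      loss_sum += arma::dot(err, err) / bs;

      // backprop of the batch-mean squared error
      delta[L] = (2.0 / bs) * err;  // 1 x bs
      for (size_t l = L; l-- > 0;) {
        arma::mat &up = delta[l];
        up = (l + 1 == L) ? W[L].t() * delta[L] : W[l + 1].t() * delta[l + 1];
        // ReLU derivative via post-activation sign; with dropout the kept
        // activations are positive iff pre-activation was, and the mask
        // scaling 1/keep must be reapplied to the gradient
        const double *a = A[l].memptr();
        double *u = up.memptr();
        const arma::uword ne = up.n_elem;
        if (dropout > 0.0) {
          const double *mk = mask[l].memptr();
          for (arma::uword i = 0; i < ne; ++i)
            u[i] = a[i] > 0.0 ? u[i] * mk[i] : 0.0;
        } else {
          for (arma::uword i = 0; i < ne; ++i)
            if (a[i] <= 0.0) u[i] = 0.0;
        }
      }

      // gradient step
      ++step;
      const double bc1 = 1.0 - std::pow(beta1, static_cast<double>(step));
      const double bc2 = 1.0 - std::pow(beta2, static_cast<double>(step));
      for (size_t l = 0; l <= L; ++l) {
        const arma::mat &Hin = (l > 0) ? A[l - 1] : Xb;
        gW = delta[l] * Hin.t();
        gb = arma::sum(delta[l], 1);
        const arma::uword nw = gW.n_elem, nbv = gb.n_elem;
        if (use_adam) {
          adam_update(W[l].memptr(), gW.memptr(), MW[l].memptr(),
                      VW[l].memptr(), nw, learning_rate, beta1, beta2,
                      bc1, bc2, eps_adam);
          adam_update(b[l].memptr(), gb.memptr(), Mb[l].memptr(),
                      Vb[l].memptr(), nbv, learning_rate, beta1, beta2,
                      bc1, bc2, eps_adam);
        } else {  // heavy-ball momentum; plain SGD when momentum = 0
          double *w = W[l].memptr(), *vw = VW[l].memptr();
          const double *g = gW.memptr();
          for (arma::uword i = 0; i < nw; ++i) {
            vw[i] = momentum * vw[i] + g[i];
            w[i] -= learning_rate * vw[i];
          }
          double *bp = b[l].memptr(), *vb = Vb[l].memptr();
          const double *gbp = gb.memptr();
          for (arma::uword i = 0; i < nbv; ++i) {
            vb[i] = momentum * vb[i] + gbp[i];
            bp[i] -= learning_rate * vb[i];
          }
        }
      }
    }
    epoch_loss(ep) = loss_sum / nb;
  }

  List Wl(L + 1), bl(L + 1);
  for (size_t l = 0; l <= L; ++l) {
    Wl[l] = W[l];
    bl[l] = b[l];
  }
  return List::create(_["weights"] = Wl, _["biases"] = bl,
                      _["epoch_loss"] = epoch_loss);
}

// Evaluation-mode forward map (dropout disabled). X: n x d.
// [[Rcpp::export]]
arma::vec cpp_relu_predict(const List &weights, const List &biases,
                           const arma::mat &X) {
  const size_t nl = weights.size();
  std::vector<arma::mat> W(nl);
  std::vector<arma::vec> b(nl);
  for (size_t l = 0; l < nl; ++l) {
    W[l] = as<arma::mat>(weights[l]);
    b[l] = as<arma::vec>(biases[l]);
  }
  return arma::conv_to<arma::vec>::from(forward_eval(W, b, X.t()));
}
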
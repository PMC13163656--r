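// Online backpropagation with momentum for a full-synapse three-layer
// sigmoid network.  All randomness (weight init, per-epoch shuffling) comes
// from a std::mt19937 seeded explicitly, so a given seed reproduces the
// trained weights bit-for-bit on one platform.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// 53-bit uniform in [0, 1), deterministic given the engine state.
static inline double unif53(std::mt19937 &gen) {
  const double a = static_cast<double>(gen() >> 5);  // 27 bits
  const double b = static_cast<double>(gen() >> 6);  // 26 bits
  return (a * 67108864.0 + b) / 9007199254740992.0;
}

// Weight matrices are stored with one row per unit; the last column is the
// bias.  W1: n_hidden x (n_in + 1), W2: n_out x (n_hidden + 1).
// [[Rcpp::export]]
List cpp_mlp_init(int n_in, int n_hidden, int n_out, int seed) {
  std::mt19937 gen(static_cast<uint32_t>(seed));
  NumericMatrix W1(n_hidden, n_in + 1), W2(n_out, n_hidden + 1);
  // fill row-major so the draw order follows units, matching the update order
  for (int i = 0; i < n_hidden; ++i)
    for (int j = 0; j <= n_in; ++j) W1(i, j) = unif53(gen) - 0.5;
  for (int i = 0; i < n_out; ++i)
    for (int j = 0; j <= n_hidden; ++j) W2(i, j) = unif53(gen) - 0.5;
  return List::create(_["W1"] = W1, _["W2"] = W2);
}

static void forward_one(const NumericMatrix &W1, const NumericMatrix &W2,
                        const double *x, std::vector<double> &h,
                        std::vector<double> &y) {
  const int n_hidden = W1.nrow(), n_in = W1.ncol() - 1;
  const int n_out = W2.nrow();
  for (int i = 0; i < n_hidden; ++i) {
    double s = W1(i, n_in);  // bias
    for (int j = 0; j < n_in; ++j) s += W1(i, j) * x[j];
    h[i] = sigmoid(s);
  }
  for (int k = 0; k < n_out; ++k) {
    double s = W2(k, n_hidden);
    for (int i = 0; i < n_hidden; ++i) s += W2(k, i) * h[i];
    y[k] = sigmoid(s);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_mlp_forward(NumericMatrix W1, NumericMatrix W2,
                              NumericMatrix X) {
  const int n_in = W1.ncol() - 1, n_hidden = W1.nrow(), n_out = W2.nrow();
  if (X.ncol() != n_in) stop("input length %d does not match n_inputs %d",
                             X.ncol(), n_in);
  NumericMatrix Y(X.nrow(), n_out);
  std::vector<double> h(n_hidden), y(n_out), x(n_in);
  for (int s = 0; s < X.nrow(); ++s) {
    for (int j = 0; j < n_in; ++j) x[j] = X(s, j);
    forward_one(W1, W2, x.data(), h, y);
    for (int k = 0; k < n_out; ++k) Y(s, k) = y[k];
  }
  return Y;
}

// Gradient of the per-sample loss 0.5 * sum_k (y_k - t_k)^2; used by the
// finite-difference check in the test suite.
// [[Rcpp::export]]
List cpp_mlp_grad(NumericMatrix W1, NumericMatrix W2, NumericVector x,
                  NumericVector t) {
  const int n_in = W1.ncol() - 1, n_hidden = W1.nrow(), n_out = W2.nrow();
  if (x.size() != n_in) stop("input length mismatch");
  if (t.size() != n_out) stop("target length mismatch");
  std::vector<double> h(n_hidden), y(n_out);
  forward_one(W1, W2, &x[0], h, y);
  NumericMatrix G1(n_hidden, n_in + 1), G2(n_out, n_hidden + 1);
  std::vector<double> delta_out(n_out), delta_hid(n_hidden, 0.0);
  for (int k = 0; k < n_out; ++k)
    delta_out[k] = (y[k] - t[k]) * y[k] * (1.0 - y[k]);
  for (int k = 0; k < n_out; ++k) {
    for (int i = 0; i < n_hidden; ++i) {
      G2(k, i) = delta_out[k] * h[i];
      delta_hid[i] += delta_out[k] * W2(k, i);
    }
    G2(k, n_hidden) = delta_out[k];
  }
  for (int i = 0; i < n_hidden; ++i) {
    const double d = delta_hid[i] * h[i] * (1.0 - h[i]);
    for (int j = 0; j < n_in; ++j) G1(i, j) = d * x[j];
    G1(i, n_in) = d;
  }
  return List::create(_["G1"] = G1, _["G2"] = G2);
}

// Online training: one weight update per sample, update
//   dw <- -lr * grad + momentum * dw_prev,  w <- w + dw.
// RMSE over all samples and outputs is evaluated at each epoch end and
// training stops once it reaches target_rmse.  Weights are copied into
// flat row-major buffers so the per-sample loops touch memory
// sequentially.
// [[Rcpp::export]]
List cpp_mlp_train(NumericMatrix W1_, NumericMatrix W2_, NumericMatrix X,
                   NumericMatrix T, double lr, double momentum,
                   double target_rmse, int max_epochs, int seed,
                   bool shuffle) {
  const int n_in = W1_.ncol() - 1, n_hidden = W1_.nrow(), n_out = W2_.nrow();
  const int n_samp = X.nrow();
  if (X.ncol() != n_in) stop("sample length does not match n_inputs");
  if (T.nrow() != n_samp || T.ncol() != n_out) stop("target shape mismatch");

  const int c1 = n_in + 1, c2 = n_hidden + 1;
  std::vector<double> w1(static_cast<size_t>(n_hidden) * c1);
  std::vector<double> w2(static_cast<size_t>(n_out) * c2);
  for (int i = 0; i < n_hidden; ++i)
    for (int j = 0; j < c1; ++j) w1[static_cast<size_t>(i) * c1 + j] = W1_(i, j);
  for (int k = 0; k < n_out; ++k)
    for (int j = 0; j < c2; ++j) w2[static_cast<size_t>(k) * c2 + j] = W2_(k, j);

  // samples row-major, with targets alongside
  std::vector<double> Xr(static_cast<size_t>(n_samp) * n_in);
  std::vector<double> Tr(static_cast<size_t>(n_samp) * n_out);
  for (int s = 0; s < n_samp; ++s) {
    for (int j = 0; j < n_in; ++j) Xr[static_cast<size_t>(s) * n_in + j] = X(s, j);
    for (int k = 0; k < n_out; ++k) Tr[static_cast<size_t>(s) * n_out + k] = T(s, k);
  }

  // previous updates, for the momentum (heavy-ball) term
  std::vector<double> dW1(w1.size(), 0.0), dW2(w2.size(), 0.0);
  std::vector<double> h(n_hidden), y(n_out);
  std::vector<double> delta_out(n_out), delta_hid(n_hidden);
  std::vector<int> order(n_samp);
  for (int s = 0; s < n_samp; ++s) order[s] = s;

  // distinct stream from the init draw: offset the seed
  std::mt19937 gen(static_cast<uint32_t>(seed) + 0x9e3779b9u);
  std::vector<double> log_rmse;
  log_rmse.reserve(256);
  bool converged = false;
  int epoch = 0;

  for (epoch = 0; epoch < max_epochs; ++epoch) {
    if (shuffle && n_samp > 1) {
      for (int i = n_samp - 1; i > 0; --i) {
        const int j = static_cast<int>(gen() % static_cast<uint32_t>(i + 1));
        std::swap(order[i], order[j]);
      }
    }
    for (int si = 0; si < n_samp; ++si) {
      const int s = order[si];
      const double *x = &Xr[static_cast<size_t>(s) * n_in];
      const double *t = &Tr[static_cast<size_t>(s) * n_out];
      // forward
      for (int i = 0; i < n_hidden; ++i) {
        const double *w = &w1[static_cast<size_t>(i) * c1];
        double acc = w[n_in];
        for (int j = 0; j < n_in; ++j) acc += w[j] * x[j];
        h[i] = sigmoid(acc);
      }
      for (int k = 0; k < n_out; ++k) {
        const double *w = &w2[static_cast<size_t>(k) * c2];
        double acc = w[n_hidden];
        for (int i = 0; i < n_hidden; ++i) acc += w[i] * h[i];
        y[k] = sigmoid(acc);
        delta_out[k] = (y[k] - t[k]) * y[k] * (1.0 - y[k]);
      }
      std::fill(delta_hid.begin(), delta_hid.end(), 0.0);
      // output layer
      for (int k = 0; k < n_out; ++k) {
        const double dk = delta_out[k];
        double *w = &w2[static_cast<size_t>(k) * c2];
        double *dw = &dW2[static_cast<size_t>(k) * c2];
        for (int i = 0; i < n_hidden; ++i) {
          delta_hid[i] += dk * w[i];
          dw[i] = -lr * dk * h[i] + momentum * dw[i];
          w[i] += dw[i];
        }
        dw[n_hidden] = -lr * dk + momentum * dw[n_hidden];
        w[n_hidden] += dw[n_hidden];
      }
      // hidden layer
      for (int i = 0; i < n_hidden; ++i) {
        const double d = delta_hid[i] * h[i] * (1.0 - h[i]);
        const double step = -lr * d;
        double *w = &w1[static_cast<size_t>(i) * c1];
        double *dw = &dW1[static_cast<size_t>(i) * c1];
        for (int j = 0; j < n_in; ++j) {
          dw[j] = step * x[j] + momentum * dw[j];
          w[j] += dw[j];
        }
        dw[n_in] = step + momentum * dw[n_in];
        w[n_in] += dw[n_in];
      }
    }
    // epoch-end RMSE over all samples and outputs
    double ss = 0.0;
    for (int s = 0; s < n_samp; ++s) {
      const double *x = &Xr[static_cast<size_t>(s) * n_in];
      const double *t = &Tr[static_cast<size_t>(s) * n_out];
      for (int i = 0; i < n_hidden; ++i) {
        const double *w = &w1[static_cast<size_t>(i) * c1];
        double acc = w[n_in];
        for (int j = 0; j < n_in; ++j) acc += w[j] * x[j];
        h[i] = sigmoid(acc);
      }
      for (int k = 0; k < n_out; ++k) {
        const double *w = &w2[static_cast<size_t>(k) * c2];
        double acc = w[n_hidden];
        for (int i = 0; i < n_hidden; ++i) acc += w[i] * h[i];
        const double e = sigmoid(acc) - t[k];
        ss += e * e;
      }
    }
    const double r = std::sqrt(ss / (static_cast<double>(n_samp) * n_out));
    log_rmse.push_back(r);
    if (r <= target_rmse) {
      converged = true;
      ++epoch;
      break;
    }
    if (epoch % 512 == 511) Rcpp::checkUserInterrupt();
  }

  NumericMatrix W1(n_hidden, c1), W2(n_out, c2);
  for (int i = 0; i < n_hidden; ++i)
    for (int j = 0; j < c1; ++j) W1(i, j) = w1[static_cast<size_t>(i) * c1 + j];
  for (int k = 0; k < n_out; ++k)
    for (int j = 0; j < c2; ++j) W2(k, j) = w2[static_cast<size_t>(k) * c2 + j];
  return List::create(_["W1"] = W1, _["W2"] = W2,
                      _["rmse_log"] = NumericVector(log_rmse.begin(),
                                                    log_rmse.end()),
                      _["converged"] = converged, _["epochs"] = epoch);
}
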
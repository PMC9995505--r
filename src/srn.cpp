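// Inner loops of the Elman clock network. Kept in C++ because the parameter
// sweep trains hundreds of networks sample-by-sample (stochastic updates in
// temporal order, no shuffling), which is prohibitively slow in pure R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::vec sigmoid(const arma::vec& a) {
  return 1.0 / (1.0 + arma::exp(-a));
}

static inline arma::vec out_activation(const arma::vec& a, bool softmax) {
  if (!softmax) return sigmoid(a);
  arma::vec e = arma::exp(a - a.max());
  return e / arma::accu(e);
}

// Trains the SRN in place. `states` holds the oscillator state at rows
// t = 0..horizon (so horizon training pairs). Context h_{t-1} resets to the
// sigmoid resting state 0.5 at each epoch start; momentum buffers persist.
// Gradients are truncated at the context copy (no backprop through time).
// The Fahlman offset `c` is added wherever a sigmoid derivative y*(1-y)
// scales an error term (hidden layer always; output layer only when the
// output activation is the per-unit sigmoid).
// [[Rcpp::export]]
List srn_train_cpp(arma::mat A, arma::mat R, arma::mat U,
                   arma::vec bh, arma::vec bo,
                   const arma::mat& states,
                   int epochs, double lr, double momentum,
                   double offset, bool softmax) {
  const int horizon = states.n_rows - 1;
  const int H = A.n_rows;
  const int n_in = A.n_cols;   // 12 oscillators
  const int n_out = U.n_rows;  // 12 predictions

  arma::mat dA(H, n_in, arma::fill::zeros);
  arma::mat dR(H, H, arma::fill::zeros);
  arma::mat dU(n_out, H, arma::fill::zeros);
  arma::vec dbh(H, arma::fill::zeros);
  arma::vec dbo(n_out, arma::fill::zeros);

  // states transposed once so each sample is a contiguous, copy-free column
  const arma::mat S = states.t();

  arma::vec epoch_mse(epochs, arma::fill::zeros);
  arma::vec h_prev(H), h(H), y(n_out), err(n_out), delta_o(n_out), delta_h(H);

  for (int e = 0; e < epochs; ++e) {
    h_prev.fill(0.5);
    double sse = 0.0;
    for (int t = 0; t < horizon; ++t) {
      const arma::vec x(const_cast<double*>(S.colptr(t)), n_in, false, true);
      const arma::vec target(const_cast<double*>(S.colptr(t + 1)), n_in,
                             false, true);

      h = A * x;
      h += R * h_prev;
      h += bh;
      h = 1.0 / (1.0 + arma::exp(-h));
      y = U * h;
      y += bo;
      if (softmax) {
        y -= y.max();
        y = arma::exp(y);
        y /= arma::accu(y);
      } else {
        y = 1.0 / (1.0 + arma::exp(-y));
      }
      err = y - target;
      sse += arma::dot(err, err);

      // Loss is the squared error averaged over the 12 output units, so the
      // error term is scaled by 1/n_out before the derivative.
      if (softmax) {
        // Jacobian of softmax applied to the squared-error gradient.
        delta_o = (y % (err - arma::dot(err, y))) / n_out;
      } else {
        delta_o = (err / n_out) % (y % (1.0 - y) + offset);
      }
      delta_h = (U.t() * delta_o) % (h % (1.0 - h) + offset);

      dU *= momentum; dU -= lr * (delta_o * h.t());
      dbo *= momentum; dbo -= lr * delta_o;
      dA *= momentum; dA -= lr * (delta_h * x.t());
      dR *= momentum; dR -= lr * (delta_h * h_prev.t());
      dbh *= momentum; dbh -= lr * delta_h;

      U += dU; bo += dbo; A += dA; R += dR; bh += dbh;
      h_prev = h;
    }
    epoch_mse(e) = sse / (static_cast<double>(horizon) * n_out);
  }

  return List::create(_["A"] = A, _["R"] = R, _["U"] = U,
                      _["hidden_bias"] = bh, _["output_bias"] = bo,
                      _["epoch_mse"] = epoch_mse);
}

// Teacher-driven evaluation: the input at every step is the true oscillator
// state (rows of `states`, t = 0..duration-1); the context layer carries the
// network's own hidden history. Returns predictions for t = 1..duration.
// [[Rcpp::export]]
arma::mat srn_driven_run_cpp(const arma::mat& A, const arma::mat& R,
                             const arma::mat& U,
                             const arma::vec& bh, const arma::vec& bo,
                             const arma::mat& states, int duration,
                             bool softmax) {
  const int H = A.n_rows;
  const int n_out = U.n_rows;
  arma::mat out(duration, n_out);
  arma::vec h_prev(H); h_prev.fill(0.5);
  arma::vec h(H);
  for (int t = 0; t < duration; ++t) {
    h = sigmoid(A * states.row(t).t() + R * h_prev + bh);
    out.row(t) = out_activation(U * h + bo, softmax).t();
    h_prev = h;
  }
  return out;
}

// Closed-loop duration estimation: the first input is the all-0.5 initial
// oscillator state; every later input is the previous prediction. Returns
// one predicted state vector per millisecond, rows t = 1..duration.
// [[Rcpp::export]]
arma::mat srn_free_run_cpp(const arma::mat& A, const arma::mat& R,
                           const arma::mat& U,
                           const arma::vec& bh, const arma::vec& bo,
                           const arma::vec& x0, int duration, bool softmax) {
  const int H = A.n_rows;
  const int n_out = U.n_rows;
  arma::mat out(duration, n_out);
  arma::vec h_prev(H); h_prev.fill(0.5);
  arma::vec x = x0, h(H), y(n_out);
  for (int t = 0; t < duration; ++t) {
    h = sigmoid(A * x + R * h_prev + bh);
    y = out_activation(U * h + bo, softmax);
    out.row(t) = y.t();
    h_prev = h;
    x = y;
  }
  return out;
}
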
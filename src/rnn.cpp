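// Hierarchical recurrent network: 101 STFT inputs -> four ReLU recurrent
// layers of 64 units -> one linear recurrent output unit. Forward pass,
// truncated-nowhere BPTT gradients and Adam updates live here; everything
// is driven (and seeded) from R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Net {
  std::vector<arma::mat> W;  // input weights per layer (units x n_in)
  std::vector<arma::mat> U;  // recurrent weights per layer (units x units)
  std::vector<arma::vec> b;  // biases per layer
};

Net unpack(const List& params) {
  Net net;
  List W = params["W"], U = params["U"], b = params["b"];
  for (int l = 0; l < W.size(); ++l) {
    net.W.push_back(as<arma::mat>(W[l]));
    net.U.push_back(as<arma::mat>(U[l]));
    net.b.push_back(as<arma::vec>(b[l]));
  }
  return net;
}

List pack(const Net& net) {
  List W(net.W.size()), U(net.U.size()), b(net.b.size());
  for (size_t l = 0; l < net.W.size(); ++l) {
    W[l] = wrap(net.W[l]);
    U[l] = wrap(net.U[l]);
    b[l] = wrap(net.b[l]);
  }
  return List::create(_["W"] = W, _["U"] = U, _["b"] = b);
}

// Forward pass for a batch of C input sequences (cols of each time slice).
// Xc: n_features x T x C cube. Fills H[l] (units x C x T) for the hidden
// layers and Y (C x T) for the output unit.
void forward_batch(const Net& net, const arma::cube& Xc,
                   std::vector<arma::cube>& H, arma::mat& Y) {
  const int T = Xc.n_cols, C = Xc.n_slices;
  const int L = net.W.size() - 1;        // hidden layers
  H.assign(L, arma::cube());
  for (int l = 0; l < L; ++l)
    H[l] = arma::cube(net.W[l].n_rows, C, T, arma::fill::zeros);
  Y.zeros(C, T);
  std::vector<arma::mat> hprev(L);
  for (int l = 0; l < L; ++l)
    hprev[l] = arma::mat(net.W[l].n_rows, C, arma::fill::zeros);
  arma::rowvec yprev(C, arma::fill::zeros);
  arma::mat x(Xc.n_rows, C);
  for (int t = 0; t < T; ++t) {
    for (int c = 0; c < C; ++c) x.col(c) = Xc.slice(c).col(t);
    arma::mat cur = x;
    for (int l = 0; l < L; ++l) {
      arma::mat a = net.W[l] * cur + net.U[l] * hprev[l];
      a.each_col() += net.b[l];
      a.transform([](double v) { return v > 0.0 ? v : 0.0; });
      H[l].slice(t) = a;
      hprev[l] = a;
      cur = a;
    }
    arma::rowvec a5 = net.W[L] * cur + net.U[L](0, 0) * yprev +
                      net.b[L](0);
    Y.col(t) = a5.t();
    yprev = a5;
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_rnn_forward(List params, arma::mat X) {
  Net net = unpack(params);
  arma::cube Xc(X.n_rows, X.n_cols, 1);
  Xc.slice(0) = X;
  std::vector<arma::cube> H;
  arma::mat Y;
  forward_batch(net, Xc, H, Y);
  const int L = H.size(), T = X.n_cols;
  List Hout(L);
  for (int l = 0; l < L; ++l) {
    arma::mat Hl(H[l].n_rows, T);
    for (int t = 0; t < T; ++t) Hl.col(t) = H[l].slice(t).col(0);
    Hout[l] = wrap(Hl);
  }
  return List::create(_["activations"] = Hout,
                      _["output"] = wrap(arma::vec(Y.row(0).t())));
}

// [[Rcpp::export]]
List cpp_rnn_train(List params, List inputs, arma::mat targets,
                   IntegerVector cond, IntegerMatrix order, int batch_size,
                   double lr, double beta1, double beta2, double eps) {
  Net net = unpack(params);
  const int L = net.W.size() - 1;             // hidden layers
  const int C = inputs.size();
  const arma::mat first = as<arma::mat>(inputs[0]);
  const int T = first.n_cols;
  arma::cube Xc(first.n_rows, T, C);
  for (int c = 0; c < C; ++c) Xc.slice(c) = as<arma::mat>(inputs[c]);
  const int n_trials = targets.n_rows;
  const int epochs = order.nrow();

  // Adam state
  Net gm, gv;
  for (int l = 0; l <= L; ++l) {
    gm.W.push_back(arma::zeros<arma::mat>(net.W[l].n_rows, net.W[l].n_cols));
    gm.U.push_back(arma::zeros<arma::mat>(net.U[l].n_rows, net.U[l].n_cols));
    gm.b.push_back(arma::zeros<arma::vec>(net.b[l].n_elem));
    gv.W.push_back(arma::zeros<arma::mat>(net.W[l].n_rows, net.W[l].n_cols));
    gv.U.push_back(arma::zeros<arma::mat>(net.U[l].n_rows, net.U[l].n_cols));
    gv.b.push_back(arma::zeros<arma::vec>(net.b[l].n_elem));
  }
  long step = 0;
  arma::vec history(epochs, arma::fill::zeros);

  std::vector<arma::cube> H;
  arma::mat Y;

  for (int e = 0; e < epochs; ++e) {
    double epoch_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < n_trials; start += batch_size) {
      const int end = std::min(start + batch_size, n_trials) - 1;
      const int B = end - start + 1;
      // per-condition counts and mean targets within the batch
      arma::vec w(C, arma::fill::zeros);
      arma::mat tbar(C, T, arma::fill::zeros);
      for (int k = start; k <= end; ++k) {
        const int i = order(e, k) - 1;
        const int c = cond[i] - 1;
        w(c) += 1.0;
        tbar.row(c) += targets.row(i);
      }
      for (int c = 0; c < C; ++c) if (w(c) > 0) tbar.row(c) /= w(c);

      forward_batch(net, Xc, H, Y);

      // exact batch MSE: weighted distance to condition means plus the
      // within-condition spread of the targets themselves
      double loss = 0.0;
      for (int c = 0; c < C; ++c)
        if (w(c) > 0)
          loss += w(c) * arma::accu(arma::square(Y.row(c) - tbar.row(c)));
      for (int k = start; k <= end; ++k) {
        const int i = order(e, k) - 1;
        const int c = cond[i] - 1;
        loss += arma::accu(arma::square(targets.row(i) - tbar.row(c)));
      }
      loss /= (double)B * T;
      if (!std::isfinite(loss))
        stop("training diverged: non-finite loss at epoch %d", e + 1);
      epoch_loss += loss;
      ++n_batches;

      // output-unit error, weighted by per-condition counts
      arma::mat dY(C, T, arma::fill::zeros);
      for (int c = 0; c < C; ++c)
        if (w(c) > 0)
          dY.row(c) = 2.0 * w(c) / ((double)B * T) *
                      (Y.row(c) - tbar.row(c));

      // gradients
      Net g;
      for (int l = 0; l <= L; ++l) {
        g.W.push_back(arma::zeros<arma::mat>(net.W[l].n_rows, net.W[l].n_cols));
        g.U.push_back(arma::zeros<arma::mat>(net.U[l].n_rows, net.U[l].n_cols));
        g.b.push_back(arma::zeros<arma::vec>(net.b[l].n_elem));
      }
      // backward through time: output layer first, errors pushed down
      {
        const int nu = net.W[L].n_cols;     // units feeding the output
        std::vector<arma::mat> edown_t(T, arma::mat(nu, C));
        arma::rowvec d_next(C, arma::fill::zeros);
        for (int t = T - 1; t >= 0; --t) {
          arma::rowvec delta = dY.col(t).t() + net.U[L](0, 0) * d_next;
          const arma::mat& h_in = H[L - 1].slice(t);   // nu x C
          g.W[L] += delta * h_in.t();
          if (t > 0) g.U[L](0, 0) += arma::dot(delta, Y.col(t - 1).t());
          g.b[L](0) += arma::accu(delta);
          edown_t[t] = net.W[L].t() * delta;
          d_next = delta;
        }
        // hidden layers, top down
        std::vector<arma::mat> err_t = edown_t;
        for (int l = L - 1; l >= 0; --l) {
          arma::mat d_nexth(net.W[l].n_rows, C, arma::fill::zeros);
          std::vector<arma::mat> next_err;
          if (l > 0) next_err.assign(T, arma::mat(net.W[l - 1].n_rows, C));
          for (int t = T - 1; t >= 0; --t) {
            arma::mat delta = err_t[t] + net.U[l].t() * d_nexth;
            delta %= arma::conv_to<arma::mat>::from(H[l].slice(t) > 0);
            arma::mat x_in;
            if (l == 0) {
              x_in.set_size(Xc.n_rows, C);
              for (int c = 0; c < C; ++c) x_in.col(c) = Xc.slice(c).col(t);
            } else {
              x_in = H[l - 1].slice(t);
            }
            g.W[l] += delta * x_in.t();
            if (t > 0) g.U[l] += delta * H[l].slice(t - 1).t();
            g.b[l] += arma::sum(delta, 1);
            if (l > 0) next_err[t] = net.W[l].t() * delta;
            d_nexth = delta;
          }
          if (l > 0) err_t = next_err;
        }
      }

      // Adam update
      ++step;
      const double bc1 = 1.0 - std::pow(beta1, (double)step);
      const double bc2 = 1.0 - std::pow(beta2, (double)step);
      for (int l = 0; l <= L; ++l) {
        gm.W[l] = beta1 * gm.W[l] + (1 - beta1) * g.W[l];
        gv.W[l] = beta2 * gv.W[l] + (1 - beta2) * arma::square(g.W[l]);
        net.W[l] -= lr * (gm.W[l] / bc1) / (arma::sqrt(gv.W[l] / bc2) + eps);
        gm.U[l] = beta1 * gm.U[l] + (1 - beta1) * g.U[l];
        gv.U[l] = beta2 * gv.U[l] + (1 - beta2) * arma::square(g.U[l]);
        net.U[l] -= lr * (gm.U[l] / bc1) / (arma::sqrt(gv.U[l] / bc2) + eps);
        gm.b[l] = beta1 * gm.b[l] + (1 - beta1) * g.b[l];
        gv.b[l] = beta2 * gv.b[l] + (1 - beta2) * arma::square(g.b[l]);
        net.b[l] -= lr * (gm.b[l] / bc1) / (arma::sqrt(gv.b[l] / bc2) + eps);
      }
    }
    history(e) = epoch_loss / n_batches;
  }
  return List::create(_["params"] = pack(net),
                      _["history"] = wrap(history));
}
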
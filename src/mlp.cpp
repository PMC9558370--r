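// Multilayer-perceptron regressor trained with per-example-weighted L1
// loss, SGD with momentum, an exponentially decaying learning rate and
// early stopping on held-fold loss. Single-threaded and seeded with its
// own mt19937 so training is bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

struct Net {
  std::vector<mat> W;  // layer l: (out x in)
  std::vector<vec> b;
};

static Net init_net(int n_in, const std::vector<int>& widths,
                    std::mt19937& rng) {
  Net net;
  std::vector<int> sizes;
  sizes.push_back(n_in);
  for (int w : widths) sizes.push_back(w);
  sizes.push_back(1);
  for (size_t l = 0; l + 1 < sizes.size(); ++l) {
    double sd = std::sqrt(2.0 / sizes[l]);
    std::normal_distribution<double> nd(0.0, sd);
    mat W(sizes[l + 1], sizes[l]);
    for (arma::uword j = 0; j < W.n_cols; ++j)
      for (arma::uword i = 0; i < W.n_rows; ++i) W(i, j) = nd(rng);
    net.W.push_back(W);
    net.b.push_back(vec(sizes[l + 1], arma::fill::zeros));
  }
  return net;
}

// forward pass on a (p x n) batch; keeps activations for backprop
static vec forward(const Net& net, const mat& X,
                   std::vector<mat>* acts = nullptr) {
  mat a = X;
  if (acts) acts->push_back(a);
  size_t L = net.W.size();
  for (size_t l = 0; l < L; ++l) {
    mat z = net.W[l] * a;
    z.each_col() += net.b[l];
    if (l + 1 < L) {
      a = z;
      a.elem(arma::find(z < 0.0)).zeros();  // ReLU
      if (acts) acts->push_back(a);
    } else {
      a = z;
    }
  }
  return a.row(0).t();
}

static double l1_loss(const Net& net, const mat& X, const vec& y,
                      const vec& w) {
  vec pred = forward(net, X);
  return arma::dot(w, arma::abs(pred - y)) / arma::accu(w);
}

static Rcpp::List net_to_list(const Net& net) {
  List W(net.W.size()), b(net.b.size());
  for (size_t l = 0; l < net.W.size(); ++l) {
    W[l] = wrap(net.W[l]);
    b[l] = wrap(net.b[l]);
  }
  return List::create(Named("W") = W, Named("b") = b);
}

static Net net_from_list(const List& model) {
  Net net;
  List W = model["W"], b = model["b"];
  for (int l = 0; l < W.size(); ++l) {
    net.W.push_back(as<mat>(W[l]));
    net.b.push_back(as<vec>(b[l]));
  }
  return net;
}

// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& X, const arma::vec& y,
                   const arma::vec& sample_weights,
                   const arma::mat& X_val, const arma::vec& y_val,
                   const std::vector<int>& hidden_widths,
                   int epochs, double lr0, double lr_decay_per,
                   double momentum, int batch_cap, int patience,
                   int eval_every, int seed) {
  // X: n x p (row-major samples); transpose once for column-wise batches
  const mat Xt = X.t();
  const mat Xvt = X_val.t();
  const int n = Xt.n_cols;
  const bool has_val = Xvt.n_cols > 0;
  std::mt19937 rng(static_cast<uint32_t>(seed));
  Net net = init_net(Xt.n_rows, hidden_widths, rng);
  std::vector<mat> vW(net.W.size());
  std::vector<vec> vb(net.b.size());
  for (size_t l = 0; l < net.W.size(); ++l) {
    vW[l] = mat(net.W[l].n_rows, net.W[l].n_cols, arma::fill::zeros);
    vb[l] = vec(net.b[l].n_elem, arma::fill::zeros);
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  const int bsz = std::min(batch_cap, n);
  double best_val = arma::datum::inf;
  Net best = net;
  int best_epoch = 0, stopped_epoch = epochs;
  const vec w_val = vec(y_val.n_elem, arma::fill::ones);
  const size_t L = net.W.size();

  for (int epoch = 0; epoch < epochs; ++epoch) {
    const double lr = lr0 * std::pow(0.1, epoch / lr_decay_per);
    std::shuffle(order.begin(), order.end(), rng);
    for (int start = 0; start < n; start += bsz) {
      const int stop = std::min(start + bsz, n);
      uvec idx(stop - start);
      for (int i = start; i < stop; ++i) idx[i - start] = order[i];
      mat Xb = Xt.cols(idx);
      vec yb = y.elem(idx);
      vec wb = sample_weights.elem(idx);
      std::vector<mat> acts;
      vec pred = forward(net, Xb, &acts);
      // d(weighted mean L1)/d pred
      vec delta_out = wb % arma::sign(pred - yb) / arma::accu(wb);
      mat delta = delta_out.t();  // (1 x nb)
      for (int l = static_cast<int>(L) - 1; l >= 0; --l) {
        mat gW = delta * acts[l].t();
        vec gb = arma::sum(delta, 1);
        if (l > 0) {
          mat da = net.W[l].t() * delta;
          delta = da % arma::conv_to<mat>::from(acts[l] > 0.0);
        }
        vW[l] = momentum * vW[l] - lr * gW;
        vb[l] = momentum * vb[l] - lr * gb;
        net.W[l] += vW[l];
        net.b[l] += vb[l];
      }
    }
    if (!net.W[0].is_finite()) {
      return List::create(Named("ok") = false,
                          Named("error") = "non-finite weights",
                          Named("epoch") = epoch);
    }
    if (has_val && ((epoch + 1) % eval_every == 0 || epoch + 1 == epochs)) {
      double vl = l1_loss(net, Xvt, y_val, w_val);
      if (vl < best_val) {
        best_val = vl;
        best = net;
        best_epoch = epoch;
      } else if (epoch - best_epoch > patience) {
        stopped_epoch = epoch + 1;
        break;
      }
    }
  }
  if (!has_val) {
    best = net;
    best_val = NA_REAL;
    best_epoch = stopped_epoch = epochs;
  }
  List out = net_to_list(best);
  out["val_loss"] = best_val;
  out["best_epoch"] = best_epoch;
  out["stopped_epoch"] = stopped_epoch;
  out["ok"] = true;
  return out;
}

// [[Rcpp::export]]
arma::vec mlp_predict_cpp(const List& model, const arma::mat& X) {
  Net net = net_from_list(model);
  return forward(net, X.t());
}

// Gradient of the scalar output with respect to each input, per sample.
// [[Rcpp::export]]
arma::mat mlp_input_grad_cpp(const List& model, const arma::mat& X) {
  Net net = net_from_list(model);
  const mat Xt = X.t();
  std::vector<mat> acts;
  forward(net, Xt, &acts);
  const size_t L = net.W.size();
  mat delta(1, Xt.n_cols, arma::fill::ones);
  for (int l = static_cast<int>(L) - 1; l >= 0; --l) {
    mat da = net.W[l].t() * delta;
    if (l > 0) {
      delta = da % arma::conv_to<mat>::from(acts[l] > 0.0);
    } else {
      delta = da;
    }
  }
  return delta.t();  // n x p
}
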
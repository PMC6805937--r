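// Stacked-LSTM forward pass and backpropagation-through-time.
//
// Parameter vector layout (flat, in order), for layers l = 0..L-1 with
// input dims F_0 = n_features, F_l = units (l > 0):
//   W_l : F_l x 4U   (input weights, column blocks [i | f | o | g])
//   U_l : U   x 4U   (recurrent weights, same block order)
//   b_l : 4U         (biases)
// followed by the output head: w_out (U), b_out (1).
//
// Per-hour probability: sigmoid(w_out . h_t(top layer) + b_out).
// Gates follow the standard LSTM update:
//   i,f,o = sigmoid(W x + U h_prev + b); g = tanh(...);
//   c = f*c_prev + i*g; h = o * tanh(c).
// Dropout (training only) multiplies each layer's input by a per-sequence
// binary mask scaled by 1/(1-p) (inverted dropout on the non-recurrent
// connections); masks are drawn from R's RNG so runs are reproducible
// under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Dims {
  int n_features, n_layers, units;
  int layer_in(int l) const { return l == 0 ? n_features : units; }
  int layer_size(int l) const {
    return layer_in(l) * 4 * units + units * 4 * units + 4 * units;
  }
  int total() const {
    int s = 0;
    for (int l = 0; l < n_layers; ++l) s += layer_size(l);
    return s + units + 1;
  }
};

struct LayerW {
  arma::mat W, U;   // F_l x 4U, U x 4U
  arma::rowvec b;   // 4U
};

struct Params {
  std::vector<LayerW> layers;
  arma::vec w_out;
  double b_out;
};

Params unpack(const arma::vec& p, const Dims& d) {
  Params out;
  int off = 0;
  for (int l = 0; l < d.n_layers; ++l) {
    LayerW lw;
    int fin = d.layer_in(l), g4 = 4 * d.units;
    lw.W = arma::reshape(p.subvec(off, off + fin * g4 - 1), fin, g4);
    off += fin * g4;
    lw.U = arma::reshape(p.subvec(off, off + d.units * g4 - 1), d.units, g4);
    off += d.units * g4;
    lw.b = p.subvec(off, off + g4 - 1).t();
    off += g4;
    out.layers.push_back(lw);
  }
  out.w_out = p.subvec(off, off + d.units - 1);
  off += d.units;
  out.b_out = p(off);
  return out;
}

inline arma::mat sigmoid(const arma::mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// log(1 + exp(z)), stable
inline double softplus(double z) {
  if (z > 35.0) return z;
  if (z < -35.0) return std::exp(z);
  return std::log1p(std::exp(z));
}

struct LayerCache {
  arma::mat X;                 // T x F_l, input after dropout
  arma::rowvec mask;           // dropout mask applied to the layer input
  arma::mat Gi, Gf, Go, Gg;    // T x U, post-activation gates
  arma::mat C, H, TC;          // cell state, hidden state, tanh(c)
};

// Forward through the stack for one sequence; fills caches when training.
arma::vec forward_seq(const arma::mat& x, const Params& P, const Dims& d,
                      double dropout_p, bool training,
                      std::vector<LayerCache>* caches) {
  int T = x.n_rows, U = d.units;
  arma::mat in = x;
  for (int l = 0; l < d.n_layers; ++l) {
    arma::rowvec mask(in.n_cols, arma::fill::ones);
    if (training && dropout_p > 0.0) {
      for (arma::uword j = 0; j < in.n_cols; ++j) {
        mask(j) = (R::unif_rand() < dropout_p) ? 0.0 : 1.0 / (1.0 - dropout_p);
      }
      in.each_row() %= mask;
    }
    const LayerW& lw = P.layers[l];
    arma::mat Gi(T, U), Gf(T, U), Go(T, U), Gg(T, U), C(T, U), H(T, U), TC(T, U);
    arma::rowvec h_prev(U, arma::fill::zeros), c_prev(U, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      arma::rowvec z = in.row(t) * lw.W + h_prev * lw.U + lw.b;
      arma::rowvec i = 1.0 / (1.0 + arma::exp(-z.subvec(0, U - 1)));
      arma::rowvec f = 1.0 / (1.0 + arma::exp(-z.subvec(U, 2 * U - 1)));
      arma::rowvec o = 1.0 / (1.0 + arma::exp(-z.subvec(2 * U, 3 * U - 1)));
      arma::rowvec g = arma::tanh(z.subvec(3 * U, 4 * U - 1));
      arma::rowvec c = f % c_prev + i % g;
      arma::rowvec tc = arma::tanh(c);
      arma::rowvec h = o % tc;
      Gi.row(t) = i; Gf.row(t) = f; Go.row(t) = o; Gg.row(t) = g;
      C.row(t) = c; H.row(t) = h; TC.row(t) = tc;
      h_prev = h; c_prev = c;
    }
    if (caches) {
      LayerCache lc;
      lc.X = in; lc.mask = mask; lc.Gi = Gi; lc.Gf = Gf; lc.Go = Go;
      lc.Gg = Gg; lc.C = C; lc.H = H; lc.TC = TC;
      (*caches)[l] = lc;
    }
    in = H;
  }
  // logits from the top layer's hidden states
  arma::vec logit = in * P.w_out + P.b_out;
  return logit;
}

} // namespace

// [[Rcpp::export]]
List cpp_lstm_forward(List seqs, arma::vec params, int n_features,
                      int n_layers, int units) {
  Dims d{n_features, n_layers, units};
  if ((int)params.n_elem != d.total())
    stop("parameter vector has %d entries; layout needs %d",
         (int)params.n_elem, d.total());
  Params P = unpack(params, d);
  int n = seqs.size();
  List out(n);
  for (int s = 0; s < n; ++s) {
    arma::mat x = as<arma::mat>(seqs[s]);
    if ((int)x.n_cols != n_features)
      stop("sequence %d has %d features; model expects %d", s + 1,
           (int)x.n_cols, n_features);
    if (!x.is_finite()) stop("sequence %d contains non-finite values", s + 1);
    arma::vec logit = forward_seq(x, P, d, 0.0, false, nullptr);
    out[s] = NumericVector(wrap(arma::vec(1.0 / (1.0 + arma::exp(-logit)))));
  }
  return out;
}

// Weighted binary cross-entropy loss and full gradient for a mini-batch of
// sequences. targets/weights are per-sequence vectors of per-hour labels
// (0/1) and loss weights. Loss = sum(w * bce) / sum(w).
// [[Rcpp::export]]
List cpp_lstm_loss_grad(List seqs, List targets, List weights,
                        arma::vec params, int n_features, int n_layers,
                        int units, double dropout_p) {
  Dims d{n_features, n_layers, units};
  if ((int)params.n_elem != d.total())
    stop("parameter vector has %d entries; layout needs %d",
         (int)params.n_elem, d.total());
  Params P = unpack(params, d);
  int U = units, n = seqs.size();

  // total weight for normalization
  double wsum = 0.0;
  for (int s = 0; s < n; ++s) wsum += arma::accu(as<arma::vec>(weights[s]));
  if (wsum <= 0.0) stop("total loss weight is zero");

  arma::vec grad(d.total(), arma::fill::zeros);
  std::vector<arma::mat> dW(d.n_layers), dU(d.n_layers);
  std::vector<arma::rowvec> db(d.n_layers);
  for (int l = 0; l < d.n_layers; ++l) {
    dW[l].zeros(d.layer_in(l), 4 * U);
    dU[l].zeros(U, 4 * U);
    db[l].zeros(4 * U);
  }
  arma::vec dw_out(U, arma::fill::zeros);
  double db_out = 0.0, loss = 0.0;

  for (int s = 0; s < n; ++s) {
    arma::mat x = as<arma::mat>(seqs[s]);
    arma::vec y = as<arma::vec>(targets[s]);
    arma::vec w = as<arma::vec>(weights[s]);
    int T = x.n_rows;
    if ((int)y.n_elem != T || (int)w.n_elem != T)
      stop("sequence %d: target/weight length mismatch", s + 1);
    std::vector<LayerCache> caches(d.n_layers);
    arma::vec logit = forward_seq(x, P, d, dropout_p, true, &caches);
    arma::vec prob = 1.0 / (1.0 + arma::exp(-logit));
    for (int t = 0; t < T; ++t) {
      loss += w(t) * (softplus(logit(t)) - y(t) * logit(t));
    }
    arma::vec dlogit = w % (prob - y) / wsum;   // T
    // head grads; dH into top layer
    const arma::mat& Htop = caches[d.n_layers - 1].H;
    dw_out += Htop.t() * dlogit;
    db_out += arma::accu(dlogit);
    arma::mat dH_in = dlogit * P.w_out.t();     // T x U

    for (int l = d.n_layers - 1; l >= 0; --l) {
      const LayerCache& lc = caches[l];
      const LayerW& lw = P.layers[l];
      arma::mat dX(T, lc.X.n_cols, arma::fill::zeros);
      arma::rowvec dh_next(U, arma::fill::zeros), dc_next(U, arma::fill::zeros);
      for (int t = T - 1; t >= 0; --t) {
        arma::rowvec dh = dH_in.row(t) + dh_next;
        arma::rowvec tc = lc.TC.row(t);
        arma::rowvec o = lc.Go.row(t), i = lc.Gi.row(t), f = lc.Gf.row(t),
                     g = lc.Gg.row(t);
        arma::rowvec do_ = dh % tc;
        arma::rowvec dc = dc_next + dh % o % (1.0 - tc % tc);
        arma::rowvec cprev = (t > 0) ? arma::rowvec(lc.C.row(t - 1))
                                     : arma::rowvec(U, arma::fill::zeros);
        arma::rowvec dzi = (dc % g) % i % (1.0 - i);
        arma::rowvec dzf = (dc % cprev) % f % (1.0 - f);
        arma::rowvec dzo = do_ % o % (1.0 - o);
        arma::rowvec dzg = (dc % i) % (1.0 - g % g);
        dc_next = dc % f;
        arma::rowvec dz = arma::join_rows(arma::join_rows(dzi, dzf),
                                          arma::join_rows(dzo, dzg));
        dW[l] += lc.X.row(t).t() * dz;
        if (t > 0) dU[l] += lc.H.row(t - 1).t() * dz;
        db[l] += dz;
        dh_next = dz * lw.U.t();
        dX.row(t) = dz * lw.W.t();
      }
      // lc.X already includes the dropout mask; the chain rule back to the
      // layer below multiplies by the same mask.
      if (l > 0) {
        dX.each_row() %= lc.mask;
        dH_in = dX;
      }
    }
  }
  loss /= wsum;
  // pack grads
  int off = 0;
  for (int l = 0; l < d.n_layers; ++l) {
    int fin = d.layer_in(l), g4 = 4 * U;
    grad.subvec(off, off + fin * g4 - 1) = arma::vectorise(dW[l]);
    off += fin * g4;
    grad.subvec(off, off + U * g4 - 1) = arma::vectorise(dU[l]);
    off += U * g4;
    grad.subvec(off, off + g4 - 1) = db[l].t();
    off += g4;
  }
  grad.subvec(off, off + U - 1) = dw_out;
  grad(off + U) = db_out;
  return List::create(_["loss"] = loss, _["grad"] = grad);
}
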
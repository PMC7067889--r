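// Neural-network core: 1-D CNN stack + bidirectional LSTM + dense sigmoid
// head (the per-encoding advanced-feature extractor), and a small ReLU MLP
// (the final classifier). Implemented with im2col+GEMM convolutions and full
// backpropagation-through-time; Adam optimizer; own mt19937 RNG so training
// is deterministic for a fixed seed and independent of R's RNG state.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct CbiArch {
  ivec nb_filter;      // output channels per conv layer
  ivec filter_len;     // kernel length per conv layer
  int pool = 2;
  int lstm = 32;       // hidden units per direction
  int dense = 16;
  int in_len = 0;
  int n_conv() const { return (int)nb_filter.n_elem; }
};

// Parameter order: conv (W,b) x n_conv, LSTM fwd (Wx,Wh,b), LSTM bwd
// (Wx,Wh,b), dense1 (W,b), dense2 (W,b).
typedef std::vector<mat> Params;

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

int conv_out_len(int in, int k) { return in - k + 1; }

// Minimal input length that leaves >= 1 timestep after the whole stack.
int min_input_len(const CbiArch& a) {
  int need = 1;
  for (int i = a.n_conv() - 1; i >= 0; --i) {
    need = need * a.pool;                 // before pooling
    need = need + (int)a.filter_len[i] - 1;  // before convolution
  }
  return need;
}

// Timestep counts after each conv+pool block.
std::vector<int> layer_lengths(const CbiArch& a) {
  std::vector<int> len;
  int cur = a.in_len;
  for (int i = 0; i < a.n_conv(); ++i) {
    cur = conv_out_len(cur, (int)a.filter_len[i]) / a.pool;
    len.push_back(cur);
  }
  return len;
}

void check_arch(const CbiArch& a) {
  if (a.nb_filter.n_elem != a.filter_len.n_elem)
    Rcpp::stop("nb_filter and filter_length must have equal length");
  int m = min_input_len(a);
  if (a.in_len < m)
    Rcpp::stop("input length %d too short for the conv stack; minimum is %d",
               a.in_len, m);
}

double glorot_limit(int fan_in, int fan_out) {
  return std::sqrt(6.0 / (double)(fan_in + fan_out));
}

mat init_mat(int r, int c, double lim, std::mt19937& rng) {
  std::uniform_real_distribution<double> u(-lim, lim);
  mat W(r, c);
  for (uword j = 0; j < W.n_cols; ++j)
    for (uword i = 0; i < W.n_rows; ++i) W(i, j) = u(rng);
  return W;
}

Params init_params(const CbiArch& a, std::mt19937& rng) {
  Params P;
  int ci = 1;
  for (int l = 0; l < a.n_conv(); ++l) {
    int k = (int)a.filter_len[l], co = (int)a.nb_filter[l];
    P.push_back(init_mat(k * ci, co, glorot_limit(k * ci, co), rng));
    P.push_back(zeros<mat>(1, co));
    ci = co;
  }
  std::vector<int> len = layer_lengths(a);
  int T = len.back(), H = a.lstm;
  for (int d = 0; d < 2; ++d) {
    P.push_back(init_mat(ci, 4 * H, glorot_limit(ci, H), rng));
    P.push_back(init_mat(H, 4 * H, glorot_limit(H, H), rng));
    mat b = zeros<mat>(1, 4 * H);
    b.cols(H, 2 * H - 1).fill(1.0);   // forget-gate bias init
    P.push_back(b);
  }
  int flat = 2 * H * T;
  P.push_back(init_mat(flat, a.dense, glorot_limit(flat, a.dense), rng));
  P.push_back(zeros<mat>(1, a.dense));
  P.push_back(init_mat(a.dense, 1, glorot_limit(a.dense, 1), rng));
  P.push_back(zeros<mat>(1, 1));
  return P;
}

// Gather index helpers (sample-major activation layout: row = b*T + t).
uvec conv_base_idx(int B, int Ti, int To) {
  uvec idx(B * (uword)To);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < To; ++t) idx[b * (uword)To + t] = b * (uword)Ti + t;
  return idx;
}

uvec time_idx(int B, int T, int t) {
  uvec idx(B);
  for (int b = 0; b < B; ++b) idx[b] = b * (uword)T + t;
  return idx;
}

struct ConvCache {
  mat Mcol;        // im2col matrix
  umat pool_arg;   // argmax offset within each pool window
  mat pre_relu_mask;
  int Ti, To, Tp, Ci, Co, K;
};

struct LstmCache {
  cube i, f, g, o, c, tc, h_prev, c_prev, x;  // B x H (or C) x T slices
};

struct FwdCache {
  std::vector<ConvCache> conv;
  LstmCache fw, bw;
  mat A_lstm_in;    // activations entering the LSTM (B*T x C)
  mat H_out;        // B*T x 2H
  mat F;            // flattened B x 2H*T
  mat drop_mask;    // dropout mask on F (empty when not training)
  mat D1, D1_mask;  // dense1 activations / relu mask
  vec p;            // output probabilities
  int T = 0, C = 0;
};

void lstm_forward(const mat& A, int B, int T, int C, int H,
                  const mat& Wx, const mat& Wh, const mat& b,
                  bool reverse, mat& H_out, int col_off, LstmCache& cache) {
  cache.i.set_size(B, H, T); cache.f.set_size(B, H, T);
  cache.g.set_size(B, H, T); cache.o.set_size(B, H, T);
  cache.c.set_size(B, H, T); cache.tc.set_size(B, H, T);
  cache.h_prev.set_size(B, H, T); cache.c_prev.set_size(B, H, T);
  cache.x.set_size(B, C, T);
  mat h = zeros<mat>(B, H), c = zeros<mat>(B, H);
  for (int s = 0; s < T; ++s) {
    int t = reverse ? T - 1 - s : s;
    mat xt = A.rows(time_idx(B, T, t));
    mat Z = xt * Wx + h * Wh;
    Z.each_row() += b.row(0);
    mat gi = sigmoid(Z.cols(0, H - 1));
    mat gf = sigmoid(Z.cols(H, 2 * H - 1));
    mat gg = tanh(Z.cols(2 * H, 3 * H - 1));
    mat go = sigmoid(Z.cols(3 * H, 4 * H - 1));
    cache.h_prev.slice(s) = h; cache.c_prev.slice(s) = c; cache.x.slice(s) = xt;
    c = gf % c + gi % gg;
    mat tc = tanh(c);
    h = go % tc;
    cache.i.slice(s) = gi; cache.f.slice(s) = gf; cache.g.slice(s) = gg;
    cache.o.slice(s) = go; cache.c.slice(s) = c; cache.tc.slice(s) = tc;
    H_out.submat(time_idx(B, T, t), regspace<uvec>(col_off, col_off + H - 1)) = h;
  }
}

// Backward through one LSTM direction; accumulates weight grads and returns
// gradient wrt the input activations A (B*T x C).
void lstm_backward(const LstmCache& cache, int B, int T, int C, int H,
                   const mat& Wx, const mat& Wh, bool reverse,
                   const mat& dH_out, int col_off,
                   mat& dA, mat& gWx, mat& gWh, mat& gb) {
  mat dh_carry = zeros<mat>(B, H), dc_carry = zeros<mat>(B, H);
  for (int s = T - 1; s >= 0; --s) {
    int t = reverse ? T - 1 - s : s;
    mat dh = dH_out.submat(time_idx(B, T, t),
                           regspace<uvec>(col_off, col_off + H - 1)) + dh_carry;
    const mat &gi = cache.i.slice(s), &gf = cache.f.slice(s),
              &gg = cache.g.slice(s), &go = cache.o.slice(s),
              &tc = cache.tc.slice(s);
    mat dc = dh % go % (1.0 - tc % tc) + dc_carry;
    mat da_o = dh % tc % go % (1.0 - go);
    mat da_i = dc % gg % gi % (1.0 - gi);
    mat da_f = dc % cache.c_prev.slice(s) % gf % (1.0 - gf);
    mat da_g = dc % gi % (1.0 - gg % gg);
    mat dZ = join_rows(join_rows(da_i, da_f), join_rows(da_g, da_o));
    gWx += cache.x.slice(s).t() * dZ;
    gWh += cache.h_prev.slice(s).t() * dZ;
    gb += sum(dZ, 0);
    dA.rows(time_idx(B, T, t)) += dZ * Wx.t();
    dh_carry = dZ * Wh.t();
    dc_carry = dc % gf;
  }
}

// Full forward pass; dropout applied only when rng != nullptr.
void cbi_forward(const mat& X, const Params& P, const CbiArch& a,
                 double dropout, std::mt19937* rng, FwdCache& cc) {
  int B = (int)X.n_rows;
  // input as (B*L) x 1
  mat A(B * (uword)a.in_len, 1);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < a.in_len; ++t) A(b * (uword)a.in_len + t, 0) = X(b, t);
  int Ti = a.in_len, Ci = 1;
  cc.conv.assign(a.n_conv(), ConvCache());
  for (int l = 0; l < a.n_conv(); ++l) {
    ConvCache& c = cc.conv[l];
    c.K = (int)a.filter_len[l]; c.Co = (int)a.nb_filter[l];
    c.Ti = Ti; c.Ci = Ci;
    c.To = conv_out_len(Ti, c.K);
    c.Tp = c.To / a.pool;
    uvec base = conv_base_idx(B, Ti, c.To);
    c.Mcol.set_size(B * (uword)c.To, (uword)(c.K * Ci));
    for (int k = 0; k < c.K; ++k)
      c.Mcol.cols(k * Ci, (k + 1) * Ci - 1) = A.rows(base + k);
    mat Z = c.Mcol * P[2 * l];
    Z.each_row() += P[2 * l + 1].row(0);
    c.pre_relu_mask = conv_to<mat>::from(Z > 0.0);
    Z = Z % c.pre_relu_mask;
    // max pool (stride = size = a.pool)
    mat Ap(B * (uword)c.Tp, c.Co);
    c.pool_arg.set_size(B * (uword)c.Tp, c.Co);
    for (int b = 0; b < B; ++b) {
      for (int t = 0; t < c.Tp; ++t) {
        uword orow = b * (uword)c.Tp + t;
        uword irow0 = b * (uword)c.To + t * a.pool;
        for (int ch = 0; ch < c.Co; ++ch) {
          double best = Z(irow0, ch); uword arg = 0;
          for (int j = 1; j < a.pool; ++j) {
            double v = Z(irow0 + j, ch);
            if (v > best) { best = v; arg = j; }
          }
          Ap(orow, ch) = best; c.pool_arg(orow, ch) = arg;
        }
      }
    }
    A = Ap; Ti = c.Tp; Ci = c.Co;
  }
  cc.T = Ti; cc.C = Ci;
  cc.A_lstm_in = A;
  int H = a.lstm, T = Ti;
  int base_lstm = 2 * a.n_conv();
  cc.H_out.set_size(B * (uword)T, 2 * H);
  lstm_forward(A, B, T, Ci, H, P[base_lstm], P[base_lstm + 1], P[base_lstm + 2],
               false, cc.H_out, 0, cc.fw);
  lstm_forward(A, B, T, Ci, H, P[base_lstm + 3], P[base_lstm + 4], P[base_lstm + 5],
               true, cc.H_out, H, cc.bw);
  // flatten (time-major per sample: [t0 fw|bw, t1 fw|bw, ...])
  cc.F.set_size(B, 2 * H * T);
  for (int t = 0; t < T; ++t)
    cc.F.cols(t * 2 * H, (t + 1) * 2 * H - 1) = cc.H_out.rows(time_idx(B, T, t));
  if (rng && dropout > 0.0) {
    std::uniform_real_distribution<double> u(0.0, 1.0);
    cc.drop_mask.set_size(cc.F.n_rows, cc.F.n_cols);
    for (uword j = 0; j < cc.F.n_cols; ++j)
      for (uword i = 0; i < cc.F.n_rows; ++i)
        cc.drop_mask(i, j) = (u(*rng) < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
    cc.F = cc.F % cc.drop_mask;
  } else {
    cc.drop_mask.reset();
  }
  int bd = base_lstm + 6;
  mat Z1 = cc.F * P[bd];
  Z1.each_row() += P[bd + 1].row(0);
  cc.D1_mask = conv_to<mat>::from(Z1 > 0.0);
  cc.D1 = Z1 % cc.D1_mask;
  mat logits = cc.D1 * P[bd + 2];
  logits.each_row() += P[bd + 3].row(0);
  cc.p = sigmoid(logits).col(0);
}

double bce_loss(const vec& p, const vec& y) {
  vec pc = clamp(p, 1e-7, 1.0 - 1e-7);
  return -mean(y % log(pc) + (1.0 - y) % log(1.0 - pc));
}

// Backward pass; fills `G` (same shapes as P) and returns the batch loss.
double cbi_backprop(const mat& X, const vec& y, const Params& P,
                    const CbiArch& a, double dropout, std::mt19937* rng,
                    Params& G) {
  FwdCache cc;
  cbi_forward(X, P, a, dropout, rng, cc);
  int B = (int)X.n_rows, H = a.lstm, T = cc.T;
  double loss = bce_loss(cc.p, y);
  G.assign(P.size(), mat());
  for (size_t i = 0; i < P.size(); ++i) G[i] = zeros<mat>(P[i].n_rows, P[i].n_cols);
  int bd = 2 * a.n_conv() + 6;
  mat dlogit = (cc.p - y) / (double)B;            // B x 1
  G[bd + 2] = cc.D1.t() * dlogit;
  G[bd + 3] = sum(dlogit, 0);
  mat dD1 = (dlogit * P[bd + 2].t()) % cc.D1_mask;
  G[bd] = cc.F.t() * dD1;
  G[bd + 1] = sum(dD1, 0);
  mat dF = dD1 * P[bd].t();
  if (!cc.drop_mask.is_empty()) dF = dF % cc.drop_mask;
  mat dH_out(B * (uword)T, 2 * H);
  for (int t = 0; t < T; ++t)
    dH_out.rows(time_idx(B, T, t)) = dF.cols(t * 2 * H, (t + 1) * 2 * H - 1);
  int bl = 2 * a.n_conv();
  mat dA = zeros<mat>(size(cc.A_lstm_in));
  lstm_backward(cc.fw, B, T, cc.C, H, P[bl], P[bl + 1], false, dH_out, 0,
                dA, G[bl], G[bl + 1], G[bl + 2]);
  lstm_backward(cc.bw, B, T, cc.C, H, P[bl + 3], P[bl + 4], true, dH_out, H,
                dA, G[bl + 3], G[bl + 4], G[bl + 5]);
  // conv stack backward
  for (int l = a.n_conv() - 1; l >= 0; --l) {
    const ConvCache& c = cc.conv[l];
    // un-pool
    mat dZ = zeros<mat>(B * (uword)c.To, c.Co);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < c.Tp; ++t) {
        uword orow = b * (uword)c.Tp + t;
        uword irow0 = b * (uword)c.To + t * a.pool;
        for (int ch = 0; ch < c.Co; ++ch)
          dZ(irow0 + c.pool_arg(orow, ch), ch) = dA(orow, ch);
      }
    dZ = dZ % c.pre_relu_mask;
    G[2 * l] = c.Mcol.t() * dZ;
    G[2 * l + 1] = sum(dZ, 0);
    if (l > 0 || true) {
      mat dMcol = dZ * P[2 * l].t();
      mat dAin = zeros<mat>(B * (uword)c.Ti, c.Ci);
      uvec base = conv_base_idx(B, c.Ti, c.To);
      for (int k = 0; k < c.K; ++k)
        dAin.rows(base + k) += dMcol.cols(k * c.Ci, (k + 1) * c.Ci - 1);
      dA = dAin;
    }
  }
  return loss;
}

struct Adam {
  std::vector<mat> m, v;
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  Adam(const Params& P, double lr_) : lr(lr_) {
    for (const mat& W : P) { m.push_back(zeros<mat>(size(W))); v.push_back(zeros<mat>(size(W))); }
  }
  void step(Params& P, const Params& G) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t), c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < P.size(); ++i) {
      m[i] = b1 * m[i] + (1.0 - b1) * G[i];
      v[i] = b2 * v[i] + (1.0 - b2) * (G[i] % G[i]);
      P[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
  }
};

CbiArch arch_from_list(const Rcpp::List& cfg, int in_len) {
  CbiArch a;
  a.nb_filter = Rcpp::as<ivec>(cfg["nb_filter"]);
  a.filter_len = Rcpp::as<ivec>(cfg["filter_length"]);
  a.pool = Rcpp::as<int>(cfg["pool_size"]);
  a.lstm = Rcpp::as<int>(cfg["lstm_units"]);
  a.dense = Rcpp::as<int>(cfg["dense_units"]);
  a.in_len = in_len;
  check_arch(a);
  return a;
}

Params params_from_list(const Rcpp::List& W) {
  Params P;
  for (int i = 0; i < W.size(); ++i) P.push_back(Rcpp::as<mat>(W[i]));
  return P;
}

Rcpp::List params_to_list(const Params& P) {
  Rcpp::List out(P.size());
  for (size_t i = 0; i < P.size(); ++i) out[i] = P[i];
  return out;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cbi_min_input")]]
int cbi_min_input(Rcpp::List config) {
  CbiArch a;
  a.nb_filter = Rcpp::as<ivec>(config["nb_filter"]);
  a.filter_len = Rcpp::as<ivec>(config["filter_length"]);
  a.pool = Rcpp::as<int>(config["pool_size"]);
  a.lstm = Rcpp::as<int>(config["lstm_units"]);
  a.dense = Rcpp::as<int>(config["dense_units"]);
  return min_input_len(a);
}

//' @noRd
// [[Rcpp::export(name = ".cbi_shapes")]]
Rcpp::IntegerVector cbi_shapes(Rcpp::List config, int in_len) {
  CbiArch a = arch_from_list(config, in_len);
  std::vector<int> len = layer_lengths(a);
  return Rcpp::wrap(len);
}

//' @noRd
// [[Rcpp::export(name = ".cbi_init")]]
Rcpp::List cbi_init(Rcpp::List config, int in_len, int seed) {
  CbiArch a = arch_from_list(config, in_len);
  std::mt19937 rng((unsigned)seed);
  return params_to_list(init_params(a, rng));
}

//' @noRd
// [[Rcpp::export(name = ".cbi_train")]]
Rcpp::List cbi_train(arma::mat X, arma::vec y, Rcpp::List config, int seed) {
  CbiArch a = arch_from_list(config, (int)X.n_cols);
  double dropout = Rcpp::as<double>(config["dropout"]);
  double lr = Rcpp::as<double>(config["learning_rate"]);
  int batch = Rcpp::as<int>(config["batch_size"]);
  int epochs = Rcpp::as<int>(config["epochs"]);
  std::mt19937 rng((unsigned)seed);
  Params P = init_params(a, rng);
  Adam opt(P, lr);
  int n = (int)X.n_rows;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  vec history(epochs);
  Params G;
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double total = 0.0; int nb = 0;
    for (int start = 0; start < n; start += batch) {
      int end = std::min(n, start + batch);
      uvec rows(end - start);
      for (int i = start; i < end; ++i) rows[i - start] = idx[i];
      double loss = cbi_backprop(X.rows(rows), y.elem(rows), P, a, dropout,
                                 &rng, G);
      opt.step(P, G);
      total += loss * (end - start); nb += end - start;
      Rcpp::checkUserInterrupt();
    }
    history[e] = total / nb;
  }
  return Rcpp::List::create(Rcpp::Named("weights") = params_to_list(P),
                            Rcpp::Named("history") = history,
                            Rcpp::Named("in_len") = (int)X.n_cols);
}

//' @noRd
// [[Rcpp::export(name = ".cbi_predict")]]
arma::vec cbi_predict(Rcpp::List weights, arma::mat X, Rcpp::List config) {
  CbiArch a = arch_from_list(config, (int)X.n_cols);
  Params P = params_from_list(weights);
  int n = (int)X.n_rows;
  vec out(n);
  int chunk = 512;
  for (int start = 0; start < n; start += chunk) {
    int end = std::min(n, start + chunk);
    FwdCache cc;
    cbi_forward(X.rows(start, end - 1), P, a, 0.0, nullptr, cc);
    out.subvec(start, end - 1) = cc.p;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cbi_loss")]]
double cbi_loss(Rcpp::List weights, arma::mat X, arma::vec y, Rcpp::List config) {
  CbiArch a = arch_from_list(config, (int)X.n_cols);
  Params P = params_from_list(weights);
  FwdCache cc;
  cbi_forward(X, P, a, 0.0, nullptr, cc);
  return bce_loss(cc.p, y);
}

//' @noRd
// [[Rcpp::export(name = ".cbi_grad")]]
Rcpp::List cbi_grad(Rcpp::List weights, arma::mat X, arma::vec y, Rcpp::List config) {
  CbiArch a = arch_from_list(config, (int)X.n_cols);
  Params P = params_from_list(weights);
  Params G;
  cbi_backprop(X, y, P, a, 0.0, nullptr, G);
  return params_to_list(G);
}

// ---------------- small dense MLP (final classifier) ----------------

namespace {

struct MlpCache { std::vector<mat> A, mask; vec p; };

void mlp_forward(const mat& X, const Params& P, MlpCache& cc) {
  int nl = (int)P.size() / 2;
  cc.A.assign(nl, mat()); cc.mask.assign(nl, mat());
  mat A = X;
  for (int l = 0; l < nl; ++l) {
    mat Z = A * P[2 * l];
    Z.each_row() += P[2 * l + 1].row(0);
    if (l < nl - 1) {
      cc.mask[l] = conv_to<mat>::from(Z > 0.0);
      A = Z % cc.mask[l];
      cc.A[l] = A;
    } else {
      cc.p = sigmoid(Z).col(0);
    }
  }
}

double mlp_backprop(const mat& X, const vec& y, const Params& P, Params& G) {
  MlpCache cc;
  mlp_forward(X, P, cc);
  int nl = (int)P.size() / 2, B = (int)X.n_rows;
  double loss = bce_loss(cc.p, y);
  G.assign(P.size(), mat());
  mat delta = mat(cc.p - y) / (double)B;
  for (int l = nl - 1; l >= 0; --l) {
    const mat& Ain = (l == 0) ? X : cc.A[l - 1];
    G[2 * l] = Ain.t() * delta;
    G[2 * l + 1] = sum(delta, 0);
    if (l > 0) delta = (delta * P[2 * l].t()) % cc.mask[l - 1];
  }
  return loss;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".mlp_train")]]
Rcpp::List mlp_train(arma::mat X, arma::vec y, arma::ivec hidden, double lr,
                     int batch, int epochs, double val_fraction, int patience,
                     int seed) {
  std::mt19937 rng((unsigned)seed);
  int n = (int)X.n_rows, din = (int)X.n_cols;
  // layer sizes: din -> hidden... -> 1
  Params P;
  int prev = din;
  for (uword l = 0; l < hidden.n_elem; ++l) {
    int h = (int)hidden[l];
    P.push_back(init_mat(prev, h, glorot_limit(prev, h), rng));
    P.push_back(zeros<mat>(1, h));
    prev = h;
  }
  P.push_back(init_mat(prev, 1, glorot_limit(prev, 1), rng));
  P.push_back(zeros<mat>(1, 1));
  // validation split for early stopping
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::shuffle(idx.begin(), idx.end(), rng);
  int nval = (patience > 0) ? (int)std::floor(val_fraction * n) : 0;
  if (nval > 0 && n - nval < 2) nval = 0;
  uvec vrows(std::max(nval, 0)), trows(n - nval);
  for (int i = 0; i < nval; ++i) vrows[i] = idx[i];
  for (int i = nval; i < n; ++i) trows[i - nval] = idx[i];
  mat Xt = X.rows(trows); vec yt = y.elem(trows);
  Adam opt(P, lr);
  int ntr = (int)Xt.n_rows;
  std::vector<int> order(ntr);
  for (int i = 0; i < ntr; ++i) order[i] = i;
  std::vector<double> tr_hist, val_hist;
  Params best = P; double best_val = datum::inf; int bad = 0;
  Params G;
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(order.begin(), order.end(), rng);
    double total = 0.0;
    for (int start = 0; start < ntr; start += batch) {
      int end = std::min(ntr, start + batch);
      uvec rows(end - start);
      for (int i = start; i < end; ++i) rows[i - start] = order[i];
      double loss = mlp_backprop(Xt.rows(rows), yt.elem(rows), P, G);
      opt.step(P, G);
      total += loss * (end - start);
    }
    tr_hist.push_back(total / ntr);
    if (nval > 0) {
      MlpCache cc;
      mlp_forward(X.rows(vrows), P, cc);
      double vl = bce_loss(cc.p, y.elem(vrows));
      val_hist.push_back(vl);
      if (vl < best_val - 1e-6) { best_val = vl; best = P; bad = 0; }
      else if (++bad >= patience) break;
    }
  }
  if (nval > 0) P = best;
  return Rcpp::List::create(Rcpp::Named("weights") = params_to_list(P),
                            Rcpp::Named("history") = Rcpp::wrap(tr_hist),
                            Rcpp::Named("val_history") = Rcpp::wrap(val_hist),
                            Rcpp::Named("in_len") = din);
}

//' @noRd
// [[Rcpp::export(name = ".mlp_predict")]]
arma::vec mlp_predict(Rcpp::List weights, arma::mat X) {
  Params P = params_from_list(weights);
  MlpCache cc;
  mlp_forward(X, P, cc);
  return cc.p;
}
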
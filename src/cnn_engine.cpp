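// Numerical engine for the length-flexible convolutional host classifier.
//
// Batch layout: N reads sharing a truncation length L travel as a single
// 4 x (L*N) matrix, read n occupying columns [n*L, (n+1)*L).  Convolutions
// are 'same'-padded with stride 1; average pooling uses non-overlapping
// windows of `pool` positions with a final partial window averaged over its
// true size, so any input length >= 1 survives every stage.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Net {
  std::vector<arma::mat> W;  // layer i: F_i x (C_i * k), row f = filter f
  std::vector<arma::vec> b;  // F_i
  arma::vec fw;              // final linear layer weights (F_last)
  double fb;                 // final bias
  int k, pool, nlayers;
};

static Net unpack(const List& convW, const List& convB,
                  const arma::vec& fcW, double fcB, int kernel, int pool) {
  Net net;
  net.k = kernel;
  net.pool = pool;
  net.nlayers = convW.size();
  for (int i = 0; i < net.nlayers; ++i) {
    net.W.push_back(as<arma::mat>(convW[i]));
    net.b.push_back(as<arma::vec>(convB[i]));
  }
  net.fw = fcW;
  net.fb = fcB;
  return net;
}

// Unfold A (C x L) into the (C*k) x L patch matrix; out-of-range positions
// stay zero (same padding).  Row block kk holds input offset kk - k/2.
static arma::mat im2col(const arma::mat& A, int k) {
  const int C = A.n_rows, L = A.n_cols, pad = k / 2;
  arma::mat out(C * k, L, arma::fill::zeros);
  for (int kk = 0; kk < k; ++kk) {
    const int off = kk - pad;
    const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
    if (t1 > t0)
      out.submat(kk * C, t0, kk * C + C - 1, t1 - 1) =
          A.cols(t0 + off, t1 - 1 + off);
  }
  return out;
}

// Adjoint of im2col: scatter-add patch-space gradients back to positions.
static arma::mat col2im(const arma::mat& G, int C, int k) {
  const int L = G.n_cols, pad = k / 2;
  arma::mat out(C, L, arma::fill::zeros);
  for (int kk = 0; kk < k; ++kk) {
    const int off = kk - pad;
    const int t0 = std::max(0, -off), t1 = std::min(L, L - off);
    if (t1 > t0)
      out.cols(t0 + off, t1 - 1 + off) +=
          G.submat(kk * C, t0, kk * C + C - 1, t1 - 1);
  }
  return out;
}

static arma::mat pool_fwd(const arma::mat& A, int p) {
  const int L = A.n_cols, Lp = (L + p - 1) / p;
  arma::mat P(A.n_rows, Lp);
  for (int j = 0; j < Lp; ++j) {
    const int a = j * p, b = std::min(L, a + p);
    P.col(j) = arma::mean(A.cols(a, b - 1), 1);
  }
  return P;
}

static arma::mat pool_bwd(const arma::mat& dP, int L, int p) {
  const int Lp = dP.n_cols;
  arma::mat dA(dP.n_rows, L);
  for (int j = 0; j < Lp; ++j) {
    const int a = j * p, b = std::min(L, a + p);
    const double w = b - a;
    for (int t = a; t < b; ++t) dA.col(t) = dP.col(j) / w;
  }
  return dA;
}

struct Cache {
  std::vector<arma::mat> in;    // conv input per layer
  std::vector<arma::mat> mask;  // ReLU mask per layer (0/1)
  arma::mat last;               // post-pool output of the last layer
  double logit;
};

static double fwd_read(const Net& net, const arma::mat& x, Cache* cc) {
  arma::mat A = x;
  if (cc) {
    cc->in.clear();
    cc->mask.clear();
  }
  for (int i = 0; i < net.nlayers; ++i) {
    if (cc) cc->in.push_back(A);
    arma::mat Z = net.W[i] * im2col(A, net.k);
    Z.each_col() += net.b[i];
    arma::mat m = arma::conv_to<arma::mat>::from(Z > 0.0);
    if (cc) cc->mask.push_back(m);
    A = pool_fwd(Z % m, net.pool);
  }
  const double logit = arma::dot(net.fw, arma::mean(A, 1)) + net.fb;
  if (cc) {
    cc->last = A;
    cc->logit = logit;
  }
  return logit;
}

struct Grads {
  std::vector<arma::mat> dW;
  std::vector<arma::vec> db;
  arma::vec dfw;
  double dfb;
  arma::mat dx;
};

// Reverse pass with seed d(logit) = 1: unit parameter gradients dz/dtheta
// and, when requested, the input gradient dz/dx.
static void bwd_read(const Net& net, const Cache& cc, Grads& g, bool want_dx) {
  const int nl = net.nlayers;
  const int Lp = cc.last.n_cols;
  g.dfw = arma::mean(cc.last, 1);
  g.dfb = 1.0;
  arma::mat dA = arma::repmat(net.fw / Lp, 1, Lp);
  for (int i = nl - 1; i >= 0; --i) {
    const int Li = cc.in[i].n_cols;
    arma::mat dZ = pool_bwd(dA, Li, net.pool) % cc.mask[i];
    g.db[i] = arma::sum(dZ, 1);
    g.dW[i] = dZ * im2col(cc.in[i], net.k).t();
    if (i > 0 || want_dx)
      dA = col2im(net.W[i].t() * dZ, cc.in[i].n_rows, net.k);
  }
  if (want_dx) g.dx = dA;
}

// Forward-over-reverse pass for the input-gradient (double-backprop)
// penalty.  With v = dz/dx held fixed, the directional derivative
// z_t = (dz/dx) . v is evaluated by a tangent forward pass (ReLU masks
// frozen at their primal values), then differentiated w.r.t. the weights by
// an ordinary reverse pass through that tangent computation.  Conv and
// output biases never enter the tangent path, so they receive no penalty
// gradient.  Returns z_t (= ||dz/dx||^2 when v is the input gradient).
static double tangent_pass(const Net& net, const Cache& cc, const arma::mat& v,
                           Grads& tg) {
  std::vector<arma::mat> tin(net.nlayers);
  arma::mat t = v;
  for (int i = 0; i < net.nlayers; ++i) {
    tin[i] = t;
    arma::mat U = net.W[i] * im2col(t, net.k);
    U %= cc.mask[i];
    t = pool_fwd(U, net.pool);
  }
  const int Lp = t.n_cols;
  const double zt = arma::dot(net.fw, arma::mean(t, 1));
  tg.dfw = arma::mean(t, 1);
  tg.dfb = 0.0;
  arma::mat dA = arma::repmat(net.fw / Lp, 1, Lp);
  for (int i = net.nlayers - 1; i >= 0; --i) {
    const int Li = tin[i].n_cols;
    arma::mat dU = pool_bwd(dA, Li, net.pool) % cc.mask[i];
    tg.dW[i] = dU * im2col(tin[i], net.k).t();
    if (i > 0) dA = col2im(net.W[i].t() * dU, tin[i].n_rows, net.k);
  }
  return zt;
}

static double bce_stable(double z, double y) {
  return std::max(z, 0.0) - z * y + std::log1p(std::exp(-std::fabs(z)));
}

// [[Rcpp::export]]
arma::vec cnn_forward_cpp(List convW, List convB, arma::vec fcW, double fcB,
                          int kernel, int pool, const arma::mat& X, int L) {
  const Net net = unpack(convW, convB, fcW, fcB, kernel, pool);
  const int N = X.n_cols / L;
  arma::vec logits(N);
  for (int n = 0; n < N; ++n)
    logits(n) = fwd_read(net, X.cols((size_t)n * L, (size_t)n * L + L - 1),
                         nullptr);
  return logits;
}

// [[Rcpp::export]]
arma::mat cnn_input_grad_cpp(List convW, List convB, arma::vec fcW, double fcB,
                             int kernel, int pool, const arma::mat& X, int L) {
  const Net net = unpack(convW, convB, fcW, fcB, kernel, pool);
  const int N = X.n_cols / L;
  arma::mat out(X.n_rows, X.n_cols);
  Cache cc;
  Grads g;
  g.dW.resize(net.nlayers);
  g.db.resize(net.nlayers);
  for (int n = 0; n < N; ++n) {
    fwd_read(net, X.cols((size_t)n * L, (size_t)n * L + L - 1), &cc);
    bwd_read(net, cc, g, true);
    out.cols((size_t)n * L, (size_t)n * L + L - 1) = g.dx;
  }
  return out;
}

// Mean binary cross-entropy plus (optionally) the mean squared input-
// gradient penalty, with their exact parameter gradients, averaged over the
// batch.  L2 and the lambda factors are applied by the caller.
// [[Rcpp::export]]
List cnn_grad_cpp(List convW, List convB, arma::vec fcW, double fcB,
                  int kernel, int pool, const arma::mat& X, int L,
                  arma::vec y, bool weight_grads, bool grad_penalty) {
  const Net net = unpack(convW, convB, fcW, fcB, kernel, pool);
  const int N = X.n_cols / L;
  const int nl = net.nlayers;

  std::vector<arma::mat> aW(nl), pW(nl);
  std::vector<arma::vec> ab(nl);
  for (int i = 0; i < nl; ++i) {
    aW[i] = arma::mat(arma::size(net.W[i]), arma::fill::zeros);
    pW[i] = arma::mat(arma::size(net.W[i]), arma::fill::zeros);
    ab[i] = arma::vec(net.b[i].n_elem, arma::fill::zeros);
  }
  arma::vec afw(net.fw.n_elem, arma::fill::zeros);
  arma::vec pfw(net.fw.n_elem, arma::fill::zeros);
  double afb = 0.0, bce = 0.0, gp = 0.0;
  arma::vec logits(N);

  Cache cc;
  Grads g, tg;
  g.dW.resize(nl);
  g.db.resize(nl);
  tg.dW.resize(nl);
  tg.db.resize(nl);

  for (int n = 0; n < N; ++n) {
    const arma::mat x = X.cols((size_t)n * L, (size_t)n * L + L - 1);
    fwd_read(net, x, &cc);
    const double z = cc.logit;
    logits(n) = z;
    bce += bce_stable(z, y(n)) / N;
    const bool need_bwd = weight_grads || grad_penalty;
    if (need_bwd) bwd_read(net, cc, g, grad_penalty);
    if (weight_grads) {
      const double coef = (1.0 / (1.0 + std::exp(-z)) - y(n)) / N;
      for (int i = 0; i < nl; ++i) {
        aW[i] += coef * g.dW[i];
        ab[i] += coef * g.db[i];
      }
      afw += coef * g.dfw;
      afb += coef;
    }
    if (grad_penalty) {
      gp += arma::accu(g.dx % g.dx) / N;
      if (weight_grads) {
        tangent_pass(net, cc, g.dx, tg);
        for (int i = 0; i < nl; ++i) pW[i] += (2.0 / N) * tg.dW[i];
        pfw += (2.0 / N) * tg.dfw;
      }
    }
  }

  List gW(nl), gb(nl), gpW(nl);
  for (int i = 0; i < nl; ++i) {
    gW[i] = aW[i];
    gb[i] = ab[i];
    gpW[i] = pW[i];
  }
  return List::create(_["bce"] = bce, _["grad_penalty"] = gp,
                      _["logits"] = logits, _["gW"] = gW, _["gb"] = gb,
                      _["gfw"] = afw, _["gfb"] = afb, _["gpW"] = gpW,
                      _["gpfw"] = pfw);
}

// Forward pass that records pre-activation values at every ReLU.
static double fwd_store_pre(const Net& net, const arma::mat& x,
                            std::vector<arma::mat>& Zs) {
  arma::mat A = x;
  Zs.clear();
  for (int i = 0; i < net.nlayers; ++i) {
    arma::mat Z = net.W[i] * im2col(A, net.k);
    Z.each_col() += net.b[i];
    Zs.push_back(Z);
    A = pool_fwd(Z % arma::conv_to<arma::mat>::from(Z > 0.0), net.pool);
  }
  return arma::dot(net.fw, arma::mean(A, 1)) + net.fb;
}

// DeepLift rescale-rule attributions of the logit against a set of
// reference inputs.  Every layer except ReLU is affine, so propagating the
// activation difference with the exact rescale multiplier
// (ReLU(z_x) - ReLU(z_r)) / (z_x - z_r) makes the per-position scores sum
// to logit(x) - logit(r) exactly; where z_x == z_r the gradient (primal
// mask) is used and the position contributes nothing.
// [[Rcpp::export]]
List deeplift_cpp(List convW, List convB, arma::vec fcW, double fcB,
                  int kernel, int pool, const arma::mat& x,
                  const arma::mat& refs, int L) {
  const Net net = unpack(convW, convB, fcW, fcB, kernel, pool);
  const int R = refs.n_cols / L;
  const double eps = 1e-12;

  std::vector<arma::mat> Zx, Zr;
  const double zx = fwd_store_pre(net, x, Zx);
  arma::mat scores(x.n_rows, L, arma::fill::zeros);
  arma::vec ref_logits(R);

  for (int r = 0; r < R; ++r) {
    const arma::mat ref = refs.cols((size_t)r * L, (size_t)r * L + L - 1);
    ref_logits(r) = fwd_store_pre(net, ref, Zr);
    // rescale multipliers per layer
    std::vector<arma::mat> mult(net.nlayers);
    for (int i = 0; i < net.nlayers; ++i) {
      arma::mat d = Zx[i] - Zr[i];
      arma::mat m = (arma::clamp(Zx[i], 0.0, arma::datum::inf) -
                     arma::clamp(Zr[i], 0.0, arma::datum::inf));
      arma::umat tiny = arma::abs(d) < eps;
      d.elem(arma::find(tiny)).ones();
      m /= d;
      arma::mat grad_mask = arma::conv_to<arma::mat>::from(Zx[i] > 0.0);
      m.elem(arma::find(tiny)) = grad_mask.elem(arma::find(tiny));
      mult[i] = m;
    }
    // reverse pass with the multipliers in place of the ReLU derivative
    const int LpLast = Zx[net.nlayers - 1].n_cols == 0
                           ? 0
                           : (int)((Zx[net.nlayers - 1].n_cols + pool - 1) /
                                   pool);
    arma::mat dA = arma::repmat(net.fw / LpLast, 1, LpLast);
    for (int i = net.nlayers - 1; i >= 0; --i) {
      const int Li = Zx[i].n_cols;
      arma::mat dZ = pool_bwd(dA, Li, net.pool) % mult[i];
      const int Cin = (i == 0) ? (int)x.n_rows : (int)net.W[i - 1].n_rows;
      dA = col2im(net.W[i].t() * dZ, Cin, net.k);
    }
    scores += ((x - ref) % dA) / R;
  }
  return List::create(_["scores"] = scores, _["input_logit"] = zx,
                      _["ref_logits"] = ref_logits);
}

// [[Rcpp::export]]
arma::mat encode_seqs_cpp(CharacterVector seqs, int L) {
  const int N = seqs.size();
  arma::mat X(4, (size_t)L * N, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    const char* s = CHAR(STRING_ELT(seqs, n));
    const size_t base = (size_t)n * L;
    for (int t = 0; t < L; ++t) {
      switch (s[t]) {
        case 'A': case 'a': X(0, base + t) = 1.0; break;
        case 'C': case 'c': X(1, base + t) = 1.0; break;
        case 'G': case 'g': X(2, base + t) = 1.0; break;
        case 'T': case 't': X(3, base + t) = 1.0; break;
        default: break;  // ambiguity codes stay all-zero
      }
    }
  }
  return X;
}

static int pick(const arma::rowvec& cum, double u) {
  for (arma::uword i = 0; i < cum.n_elem; ++i)
    if (u <= cum(i)) return i;
  return cum.n_elem - 1;
}

// First-order Markov-chain sampler over A/C/G/T, driven by R's RNG so that
// set.seed() governs reproducibility.
// [[Rcpp::export]]
CharacterVector markov_seqs_cpp(IntegerVector lengths, arma::mat trans,
                                arma::vec init) {
  static const char* alphabet = "ACGT";
  arma::rowvec cinit = arma::cumsum(init.t());
  arma::mat ctrans = arma::cumsum(trans, 1);
  const int N = lengths.size();
  CharacterVector out(N);
  for (int n = 0; n < N; ++n) {
    const int len = lengths[n];
    std::string s(len, 'A');
    int cur = pick(cinit, unif_rand());
    s[0] = alphabet[cur];
    for (int t = 1; t < len; ++t) {
      cur = pick(ctrans.row(cur), unif_rand());
      s[t] = alphabet[cur];
    }
    out[n] = s;
  }
  return out;
}
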
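// Training kernel for the neural-network ODE right-hand side.
//
// Forward: classic RK4 over a (possibly non-uniform) day-of-year grid with
// driver values precomputed at the grid nodes and step midpoints. The scalar
// trajectory loss (length/angle form) is evaluated at observation days via
// linear interpolation between the two bracketing grid nodes.
//
// Backward: discrete adjoint of the exact forward computation. Observation
// adjoints are scattered onto the bracketing nodes, then propagated step by
// step through the four RK4 stages; each stage evaluation is re-run to
// rebuild its layer cache before the vector-Jacobian product.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double SQRT2 = 1.4142135623730951;
static const double INV_SQRT_2PI = 0.3989422804014327;

static inline vec gelu(const vec& x) {
  return x % (0.5 * (1.0 + erf(x / SQRT2)));
}
static inline vec gelu_grad(const vec& x) {
  vec Phi = 0.5 * (1.0 + erf(x / SQRT2));
  vec phi = INV_SQRT_2PI * exp(-0.5 * square(x));
  return Phi + x % phi;
}

struct MLP {
  std::vector<mat> W;
  std::vector<vec> b;
  size_t L;
  double out_scale;  // fixed time-scale factor on the network output
};

// Forward pass caching pre-activations z and activations a per layer.
struct Cache {
  std::vector<vec> a;  // a[0] = input, a[l+1] = activation after layer l
  std::vector<vec> z;  // pre-activations
};

static vec mlp_forward(const MLP& net, const vec& u, Cache* cache) {
  vec a = u;
  if (cache) { cache->a.clear(); cache->z.clear(); cache->a.push_back(a); }
  for (size_t l = 0; l < net.L; ++l) {
    vec z = net.W[l] * a + net.b[l];
    if (cache) cache->z.push_back(z);
    a = (l + 1 < net.L) ? gelu(z) : z;  // linear output layer
    if (cache) cache->a.push_back(a);
  }
  return net.out_scale * a;
}

// Vector-Jacobian product: given g = dL/d(output), accumulate parameter
// gradients and return dL/d(input).
static vec mlp_vjp(const MLP& net, const Cache& cache, vec g,
                   std::vector<mat>& gW, std::vector<vec>& gb) {
  g *= net.out_scale;
  for (size_t li = net.L; li-- > 0;) {
    if (li + 1 < net.L) g = g % gelu_grad(cache.z[li]);  // undo activation (hidden layers stored post-W below)
    gW[li] += g * cache.a[li].t();
    gb[li] += g;
    g = net.W[li].t() * g;
  }
  return g;
}

static MLP unpack(const Rcpp::List& Wl, const Rcpp::List& bl,
                  double out_scale) {
  MLP net;
  net.out_scale = out_scale;
  net.L = Wl.size();
  for (size_t l = 0; l < net.L; ++l) {
    net.W.push_back(Rcpp::as<mat>(Wl[l]));
    net.b.push_back(Rcpp::as<vec>(bl[l]));
  }
  return net;
}

// RHS evaluation: network applied to (state, drivers).
static vec rhs(const MLP& net, const vec& x, const rowvec& d, Cache* cache) {
  vec u(x.n_elem + d.n_elem);
  u.subvec(0, x.n_elem - 1) = x;
  u.subvec(x.n_elem, u.n_elem - 1) = d.t();
  return mlp_forward(net, u, cache);
}

// [[Rcpp::export]]
Rcpp::List cpp_ude_loss_grad(Rcpp::List W, Rcpp::List b,
                             arma::vec x0, arma::vec h,
                             arma::mat Dnode, arma::mat Dmid,
                             arma::ivec obs_i, arma::vec obs_w,
                             arma::mat obs,
                             double w_length, double w_angle,
                             bool want_grad, double out_scale) {
  MLP net = unpack(W, b, out_scale);
  const size_t N = h.n_elem;           // number of steps
  const size_t ns = x0.n_elem;         // state dimension
  const double eps = 1e-12;

  mat X(N + 1, ns);
  X.row(0) = x0.t();
  mat K1(N, ns), K2(N, ns), K3(N, ns);

  // ---- forward integration ----
  for (size_t n = 0; n < N; ++n) {
    vec xn = X.row(n).t();
    double hn = h(n);
    vec k1 = rhs(net, xn, Dnode.row(n), nullptr);
    vec k2 = rhs(net, xn + 0.5 * hn * k1, Dmid.row(n), nullptr);
    vec k3 = rhs(net, xn + 0.5 * hn * k2, Dmid.row(n), nullptr);
    vec k4 = rhs(net, xn + hn * k3, Dnode.row(n + 1), nullptr);
    vec xn1 = xn + (hn / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!xn1.is_finite() || norm(xn1, "inf") > 1e6) {
      return Rcpp::List::create(Rcpp::Named("loss") = R_PosInf,
                                Rcpp::Named("traj") = X,
                                Rcpp::Named("ok") = false);
    }
    K1.row(n) = k1.t(); K2.row(n) = k2.t(); K3.row(n) = k3.t();
    X.row(n + 1) = xn1.t();
  }

  // ---- loss at observations (linear interpolation between nodes) ----
  const size_t M = obs_i.n_elem;
  double loss_len = 0.0, loss_ang = 0.0;
  mat A(N + 1, ns, fill::zeros);  // node adjoints
  for (size_t j = 0; j < M; ++j) {
    size_t i = (size_t)obs_i(j);
    double w = obs_w(j);
    vec m = ((1.0 - w) * X.row(i) + w * X.row(i + 1)).t();
    vec x = obs.row(j).t();
    double lm = norm(m), lx = norm(x);
    double dl = lm - lx;
    loss_len += dl * dl;
    vec gm(ns, fill::zeros);
    if (lm > eps) gm += w_length * (2.0 * dl / lm) * m;
    if (lm > eps && lx > eps) {
      double dp = dot(m, x);
      loss_ang += 1.0 - dp / (lm * lx);
      gm += w_angle * (-(x / (lm * lx)) + (dp / (lm * lm * lm * lx)) * m);
    }
    if (want_grad) {
      gm /= (double)M;
      A.row(i) += (1.0 - w) * gm.t();
      A.row(i + 1) += w * gm.t();
    }
  }
  double loss = M ? (w_length * loss_len + w_angle * loss_ang) / (double)M : 0.0;

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("loss") = loss,
                                      Rcpp::Named("traj") = X,
                                      Rcpp::Named("ok") = true);
  if (!want_grad) return out;

  // ---- discrete adjoint ----
  std::vector<mat> gW; std::vector<vec> gb;
  for (size_t l = 0; l < net.L; ++l) {
    gW.push_back(mat(size(net.W[l]), fill::zeros));
    gb.push_back(vec(size(net.b[l]), fill::zeros));
  }
  vec adj = A.row(N).t();
  for (size_t n = N; n-- > 0;) {
    vec xn = X.row(n).t();
    double hn = h(n);
    vec k1 = K1.row(n).t(), k2 = K2.row(n).t(), k3 = K3.row(n).t();

    // rebuild stage caches (inputs reconstructed from stored stage slopes)
    Cache c1, c2, c3, c4;
    rhs(net, xn, Dnode.row(n), &c1);
    rhs(net, xn + 0.5 * hn * k1, Dmid.row(n), &c2);
    rhs(net, xn + 0.5 * hn * k2, Dmid.row(n), &c3);
    rhs(net, xn + hn * k3, Dnode.row(n + 1), &c4);

    vec g4 = (hn / 6.0) * adj;
    vec d4 = mlp_vjp(net, c4, g4, gW, gb).subvec(0, ns - 1);
    vec g3 = (2.0 * hn / 6.0) * adj + hn * d4;
    vec d3 = mlp_vjp(net, c3, g3, gW, gb).subvec(0, ns - 1);
    vec g2 = (2.0 * hn / 6.0) * adj + 0.5 * hn * d3;
    vec d2 = mlp_vjp(net, c2, g2, gW, gb).subvec(0, ns - 1);
    vec g1 = (hn / 6.0) * adj + 0.5 * hn * d2;
    vec d1 = mlp_vjp(net, c1, g1, gW, gb).subvec(0, ns - 1);

    adj = adj + d1 + d2 + d3 + d4 + A.row(n).t();
  }

  Rcpp::List gWl(net.L), gbl(net.L);
  for (size_t l = 0; l < net.L; ++l) { gWl[l] = gW[l]; gbl[l] = gb[l]; }
  out["gradW"] = gWl;
  out["gradb"] = gbl;
  out["grad_x0"] = adj;
  return out;
}

// Batched network evaluation (rows of U are (state, driver) inputs).
// [[Rcpp::export]]
arma::mat cpp_mlp_eval(Rcpp::List W, Rcpp::List b, arma::mat U,
                       double out_scale) {
  MLP net = unpack(W, b, out_scale);
  mat A = U.t();  // columns = samples
  for (size_t l = 0; l < net.L; ++l) {
    mat Z = net.W[l] * A;
    Z.each_col() += net.b[l];
    if (l + 1 < net.L) {
      Z = Z % (0.5 * (1.0 + erf(Z / SQRT2)));
    }
    A = Z;
  }
  return net.out_scale * A.t();
}
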
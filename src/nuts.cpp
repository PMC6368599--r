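// No-U-Turn sampler (Hoffman & Gelman 2014, Alg. 6) with dual-averaging
// step-size adaptation and Stan-style windowed diagonal-metric adaptation,
// specialised to the grouped hierarchical Poisson family:
//
//   y[u,n]    ~ Poisson(exp(eta[u,n])),  eta = B X' + log(offset)
//   B[u,j]    ~ Normal(0, sigma_{g(j)})          (j = 1..K coefficients)
//   sigma_g   ~ HalfNormal(0, c_g)               (g = 1..G scale groups)
//
// Unconstrained parameterisation: theta = (vec(B), tau), tau_g = log sigma_g.
// Masked cells (mask == 0) contribute nothing to the likelihood.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Prior groups: a "regular" group gives each member column an iid
// N(0, sigma_g) prior with one log-scale parameter tau.  A "compound"
// group gives the member columns of each unit a joint
// MVN(0, sw^2 I + sb^2 J) prior (compound symmetry) with two log-scale
// parameters (tau_w, tau_b); this is the exact marginalisation of a
// shared random intercept over a full set of level indicators, and keeps
// the likelihood full-rank.
struct Model {
  mat Y;        // U x N counts
  mat logoff;   // U x N log offsets
  mat mask;     // U x N {0,1}
  mat X;        // N x K design (shared across units)
  uvec gidx;    // K, 0-based scale-group index per coefficient
  uvec gtype;   // G, 0 = regular, 1 = compound
  vec cscale;   // hyperprior scale(s): regular 1, compound 2 (within, between)
  uvec tau_off; // G, offset of each group's tau parameter(s)
  uword U, N, K, G, P, T;  // T = total number of tau parameters
  std::vector<uvec> gcols;  // columns per group
  mutable mat eta_s, mu_s;  // scratch

  void init_dims() {
    U = Y.n_rows; N = Y.n_cols; K = X.n_cols; G = gtype.n_elem;
    tau_off.set_size(G);
    uword t = 0;
    for (uword g = 0; g < G; ++g) {
      tau_off(g) = t;
      t += (gtype(g) == 1) ? 2 : 1;
      gcols.push_back(find(gidx == g));
    }
    T = t;
    P = U * K + T;
    eta_s.set_size(U, N);
    mu_s.set_size(U, N);
  }

  // log posterior and gradient over the coefficients, at fixed tau;
  // returns -inf on numerical failure.  Scale parameters are updated
  // outside the Hamiltonian by exact conditional slice-Gibbs moves, which
  // removes the hierarchical funnel from the NUTS geometry.
  double logp_grad(const vec& theta_b, const vec& tau, vec& grad) const {
    const mat B(const_cast<double*>(theta_b.memptr()), U, K, false, true);
    grad.set_size(U * K);
    grad.zeros();
    mat Gb(grad.memptr(), U, K, false, true);

    mat& eta = eta_s;
    mat& mu = mu_s;
    eta = B * X.t() + logoff;
    if (!eta.is_finite()) return -datum::inf;
    double lp = 0.0;
    for (uword n = 0; n < N; ++n) {
      for (uword u = 0; u < U; ++u) {
        double m = mask(u, n);
        if (m == 0.0) { mu(u, n) = 0.0; continue; }
        double e = eta(u, n);
        if (e > 600.0) return -datum::inf;
        double ex = std::exp(e);
        mu(u, n) = ex;
        lp += Y(u, n) * e - ex;
      }
    }
    if (!std::isfinite(lp)) return -datum::inf;

    // dB likelihood part
    Gb = ((Y - mu) % mask) * X;

    for (uword g = 0; g < G; ++g) {
      const uvec& cols = gcols[g];
      uword k = cols.n_elem;
      uword to = tau_off(g);
      if (gtype(g) == 0) {
        double tg = tau(to);
        double inv_s2 = std::exp(-2.0 * tg);
        double ss = 0.0;
        for (uword c = 0; c < k; ++c) {
          uword j = cols(c);
          ss += dot(B.col(j), B.col(j));
          Gb.col(j) -= B.col(j) * inv_s2;
        }
        lp += -0.5 * ss * inv_s2 - (double)(U * k) * tg;
      } else {
        // compound symmetry: per unit alpha ~ MVN(0, A I + Bq J)
        double tw = tau(to), tb = tau(to + 1);
        double A = std::exp(2.0 * tw), Bq = std::exp(2.0 * tb);
        double D = A + (double)k * Bq;
        for (uword u = 0; u < U; ++u) {
          double S = 0.0, Q = 0.0;
          for (uword c = 0; c < k; ++c) {
            double a = B(u, cols(c));
            S += a; Q += a * a;
          }
          lp += -0.5 * (Q / A - Bq * S * S / (A * D));
          // gradient wrt alpha_j: -Sigma^{-1} alpha
          double corr = Bq * S / (A * D);
          for (uword c = 0; c < k; ++c)
            Gb(u, cols(c)) += -B(u, cols(c)) / A + corr;
        }
        lp += -0.5 * (double)U *
              (((double)k - 1.0) * std::log(A) + std::log(D));
      }
    }
    if (!std::isfinite(lp) || !grad.is_finite()) return -datum::inf;
    return lp;
  }

  // log conditional density of the tau parameters given the coefficients
  // (tau hyperpriors + the tau-dependent part of the coefficient priors)
  double logp_tau(const mat& B, const vec& tau) const {
    double lp = 0.0;
    for (uword g = 0; g < G; ++g) {
      const uvec& cols = gcols[g];
      uword k = cols.n_elem;
      uword to = tau_off(g);
      if (gtype(g) == 0) {
        double tg = tau(to);
        double inv_s2 = std::exp(-2.0 * tg);
        double ss = 0.0;
        for (uword c = 0; c < k; ++c) ss += dot(B.col(cols(c)), B.col(cols(c)));
        lp += -0.5 * ss * inv_s2 - (double)(U * k) * tg;
        double c0 = cscale(to), s2 = std::exp(2.0 * tg);
        lp += -0.5 * s2 / (c0 * c0) + tg;
      } else {
        double tw = tau(to), tb = tau(to + 1);
        double A = std::exp(2.0 * tw), Bq = std::exp(2.0 * tb);
        double D = A + (double)k * Bq;
        for (uword u = 0; u < U; ++u) {
          double S = 0.0, Q = 0.0;
          for (uword c = 0; c < k; ++c) {
            double a = B(u, cols(c));
            S += a; Q += a * a;
          }
          lp += -0.5 * (Q / A - Bq * S * S / (A * D));
        }
        lp += -0.5 * (double)U *
              (((double)k - 1.0) * std::log(A) + std::log(D));
        double cw = cscale(to), cb = cscale(to + 1);
        lp += -0.5 * A / (cw * cw) + tw - 0.5 * Bq / (cb * cb) + tb;
      }
    }
    return lp;
  }
};

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() {
    return std::generate_canonical<double, 53>(gen);
  }
  double normal() {
    // Box-Muller (deterministic across stdlib implementations)
    double u1 = unif(), u2 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  double expo() { return -std::log(std::max(unif(), 1e-300)); }
};

struct State {
  vec theta, r, grad;
  double logp;
};

struct Sampler {
  const Model& mdl;
  Rng rng;
  vec minv;          // diagonal inverse metric (variances), coefficients only
  vec tau;           // current scale parameters (Gibbs-updated)
  double eps;
  double max_dH;     // divergence threshold
  int max_depth;
  bool divergent_this_iter;

  Sampler(const Model& m, uint64_t seed)
      : mdl(m), rng(seed), minv(m.U * m.K, fill::ones),
        tau(m.T, fill::zeros),
        eps(0.1), max_dH(1000.0), max_depth(10),
        divergent_this_iter(false) {}

  double kinetic(const vec& r) const { return 0.5 * dot(r % minv, r); }

  // one leapfrog step; returns false if logp is -inf
  bool leapfrog(State& s, double direction) {
    double e = direction * eps;
    s.r += 0.5 * e * s.grad;
    s.theta += e * (minv % s.r);
    s.logp = mdl.logp_grad(s.theta, tau, s.grad);
    if (!std::isfinite(s.logp)) return false;
    s.r += 0.5 * e * s.grad;
    return true;
  }

  // Diagonal metric from the Poisson Fisher information (sum_n X^2 mu at
  // a reference point, plus the prior precision at the current tau).  For
  // this model family the conditional posterior of each coefficient is
  // close to Gaussian with exactly this precision, so empirical variance
  // estimation during warmup is unnecessary.  The reference point for the
  // likelihood part is refreshed only during warmup; afterwards only the
  // tau-dependent prior part is recombined, which keeps the NUTS kernel
  // valid (the metric may depend on tau, which is fixed during the
  // coefficient update, but not on the coefficients being updated).
  vec info_lik;  // U*K likelihood information at the reference point

  void fisher_reference(const vec& theta_b) {
    const mat B(const_cast<double*>(theta_b.memptr()), mdl.U, mdl.K,
                false, true);
    mat eta0 = B * mdl.X.t() + mdl.logoff;
    mat mu0 = exp(clamp(eta0, -700.0, 30.0)) % mdl.mask;
    info_lik.set_size(mdl.U * mdl.K);
    for (uword j = 0; j < mdl.K; ++j)
      for (uword u = 0; u < mdl.U; ++u) {
        double info = 0.0;
        for (uword n = 0; n < mdl.N; ++n)
          info += mdl.X(n, j) * mdl.X(n, j) * mu0(u, n);
        info_lik(u + j * mdl.U) = info;
      }
  }

  void fisher_metric(const vec& theta_b) {
    fisher_reference(theta_b);
    recombine_metric();
  }

  void recombine_metric() {
    for (uword j = 0; j < mdl.K; ++j) {
      uword g = mdl.gidx(j);
      double prior_prec = std::exp(-2.0 * tau(mdl.tau_off(g)));
      for (uword u = 0; u < mdl.U; ++u)
        minv(u + j * mdl.U) =
            1.0 / (info_lik(u + j * mdl.U) + prior_prec);
    }
  }

  // generic stepping-out + shrinkage slice sampler (Neal 2003)
  template <class F>
  double slice1d(const F& logf, double x0, double w = 1.0) {
    double f0 = logf(x0);
    if (!std::isfinite(f0)) return x0;
    double ly = f0 - rng.expo();
    double L = x0 - w * rng.unif();
    double R = L + w;
    for (int i = 0; i < 100 && logf(L) > ly; ++i) L -= w;
    for (int i = 0; i < 100 && logf(R) > ly; ++i) R += w;
    for (int i = 0; i < 200; ++i) {
      double x1 = L + rng.unif() * (R - L);
      if (logf(x1) > ly) return x1;
      if (x1 < x0) L = x1; else R = x1;
      if (R - L < 1e-12) break;
    }
    return x0;
  }

  // centered conditional update of each tau coordinate given B
  void gibbs_tau(const vec& theta_b) {
    const mat B(const_cast<double*>(theta_b.memptr()), mdl.U, mdl.K,
                false, true);
    vec tt = tau;
    for (uword t = 0; t < mdl.T; ++t) {
      tau(t) = slice1d([&](double x) {
        tt = tau; tt(t) = x;
        return mdl.logp_tau(B, tt);
      }, tau(t));
    }
  }

  // interweaved (non-centered) re-update of the regular-group scales:
  // holding z = B/sigma fixed, tau is slice-sampled against the
  // likelihood (plus its half-normal hyperprior), then B is rescaled.
  // This breaks the funnel that the centered Gibbs move alone cannot
  // traverse when many member coefficients are weakly identified.
  void asis_tau(vec& theta_b) {
    mat B(theta_b.memptr(), mdl.U, mdl.K, false, true);
    mat eta_full = B * mdl.X.t() + mdl.logoff;
    for (uword g = 0; g < mdl.G; ++g) {
      if (mdl.gtype(g) != 0) continue;
      const uvec& cols = mdl.gcols[g];
      uword to = mdl.tau_off(g);
      mat eta_g(mdl.U, mdl.N, fill::zeros);
      for (uword c = 0; c < cols.n_elem; ++c)
        eta_g += B.col(cols(c)) * mdl.X.col(cols(c)).t();
      mat eta_other = eta_full - eta_g;
      double t0 = tau(to), c0 = mdl.cscale(to);
      auto logf = [&](double t) -> double {
        double s = std::exp(t - t0);
        double lp = 0.0;
        for (uword n = 0; n < mdl.N; ++n)
          for (uword u = 0; u < mdl.U; ++u) {
            if (mdl.mask(u, n) == 0.0) continue;
            double e = eta_other(u, n) + s * eta_g(u, n);
            if (e > 600.0) return -datum::inf;
            lp += mdl.Y(u, n) * e - std::exp(e);
          }
        return lp - 0.5 * std::exp(2.0 * t) / (c0 * c0) + t;
      };
      double t1 = slice1d(logf, t0, 0.5);
      if (t1 != t0) {
        double s = std::exp(t1 - t0);
        for (uword c = 0; c < cols.n_elem; ++c) B.col(cols(c)) *= s;
        tau(to) = t1;
        eta_full = eta_other + s * eta_g;
      }
    }
  }

  struct Tree {
    State minus, plus, prop;
    double n_valid;     // number of slice-valid states
    bool ok;            // no u-turn / divergence inside
    double alpha_sum;   // for dual averaging
    double n_alpha;
  };

  bool no_uturn(const State& minus, const State& plus) const {
    vec d = plus.theta - minus.theta;
    return dot(d, minv % minus.r) >= 0.0 && dot(d, minv % plus.r) >= 0.0;
  }

  void build_tree(Tree& out, const State& s, double logu, double dir,
                  int depth, double H0) {
    if (depth == 0) {
      State s1 = s;
      bool finite_ok = leapfrog(s1, dir);
      double H = finite_ok ? (s1.logp - kinetic(s1.r)) : -datum::inf;
      out.minus = s1; out.plus = s1; out.prop = s1;
      out.n_valid = (logu <= H) ? 1.0 : 0.0;
      bool div = !finite_ok || (H0 - H > max_dH) || !std::isfinite(H);
      if (div) divergent_this_iter = true;
      out.ok = !div;
      out.alpha_sum = std::min(1.0, std::exp(std::min(0.0, H - H0)));
      out.n_alpha = 1.0;
      return;
    }
    Tree first;
    build_tree(first, s, logu, dir, depth - 1, H0);
    out = first;
    if (!first.ok) return;
    Tree second;
    if (dir < 0) {
      build_tree(second, first.minus, logu, dir, depth - 1, H0);
      out.minus = second.minus;
    } else {
      build_tree(second, first.plus, logu, dir, depth - 1, H0);
      out.plus = second.plus;
    }
    double ntot = first.n_valid + second.n_valid;
    if (second.n_valid > 0 && rng.unif() < second.n_valid / std::max(ntot, 1.0))
      out.prop = second.prop;
    out.n_valid = ntot;
    out.alpha_sum = first.alpha_sum + second.alpha_sum;
    out.n_alpha = first.n_alpha + second.n_alpha;
    out.ok = second.ok && no_uturn(out.minus, out.plus);
  }

  // one NUTS transition; updates cur; returns (depth, accept_stat)
  void transition(State& cur, int& depth_out, double& accept_stat) {
    divergent_this_iter = false;
    for (uword i = 0; i < mdl.U * mdl.K; ++i)
      cur.r(i) = rng.normal() / std::sqrt(minv(i));
    double H0 = cur.logp - kinetic(cur.r);
    double logu = H0 - rng.expo();  // log of u ~ U(0, exp(H0))

    State minus = cur, plus = cur, prop = cur;
    double n_valid = 1.0;
    bool ok = true;
    int depth = 0;
    double alpha_sum = 0.0, n_alpha = 0.0;
    while (ok && depth < max_depth) {
      double dir = rng.unif() < 0.5 ? -1.0 : 1.0;
      Tree t;
      if (dir < 0) {
        build_tree(t, minus, logu, dir, depth, H0);
        if (t.ok) minus = t.minus;
      } else {
        build_tree(t, plus, logu, dir, depth, H0);
        if (t.ok) plus = t.plus;
      }
      alpha_sum = t.alpha_sum; n_alpha = t.n_alpha;
      if (t.ok && t.n_valid > 0 &&
          rng.unif() < std::min(1.0, t.n_valid / n_valid))
        prop = t.prop;
      n_valid += t.n_valid;
      ok = t.ok && no_uturn(minus, plus);
      ++depth;
    }
    cur = prop;
    depth_out = depth;
    accept_stat = n_alpha > 0 ? alpha_sum / n_alpha : 0.0;
  }

  double find_initial_eps(State& cur) {
    eps = 1.0;
    State s = cur;
    for (uword i = 0; i < mdl.U * mdl.K; ++i)
      s.r(i) = rng.normal() / std::sqrt(minv(i));
    double H0 = s.logp - kinetic(s.r);
    State s1 = s;
    bool okl = leapfrog(s1, 1.0);
    double H1 = okl ? s1.logp - kinetic(s1.r) : -datum::inf;
    double a = (H1 - H0) > std::log(0.5) ? 1.0 : -1.0;
    for (int it = 0; it < 50; ++it) {
      eps *= std::pow(2.0, a);
      s1 = s;
      okl = leapfrog(s1, 1.0);
      H1 = okl ? s1.logp - kinetic(s1.r) : -datum::inf;
      double dH = H1 - H0;
      if (a > 0 && dH <= std::log(0.5)) break;
      if (a < 0 && dH >= std::log(0.5)) break;
      if (eps < 1e-10 || eps > 1e7) break;
    }
    return eps;
  }
};

}  // namespace

namespace {
Model make_model(Rcpp::NumericMatrix Y_, Rcpp::NumericMatrix logoff_,
                 Rcpp::NumericMatrix mask_, Rcpp::NumericMatrix X_,
                 Rcpp::IntegerVector gidx_, Rcpp::IntegerVector gtype_,
                 Rcpp::NumericVector cscale_) {
  Model mdl;
  mdl.Y = mat(Y_.begin(), Y_.nrow(), Y_.ncol());
  mdl.logoff = mat(logoff_.begin(), logoff_.nrow(), logoff_.ncol());
  mdl.mask = mat(mask_.begin(), mask_.nrow(), mask_.ncol());
  mdl.X = mat(X_.begin(), X_.nrow(), X_.ncol());
  mdl.gidx = conv_to<uvec>::from(vec(Rcpp::as<std::vector<double>>(gidx_)));
  mdl.gtype = conv_to<uvec>::from(vec(Rcpp::as<std::vector<double>>(gtype_)));
  mdl.cscale = vec(cscale_.begin(), cscale_.size());
  mdl.init_dims();
  return mdl;
}
}  // namespace

// exposed for gradient validation in the test suite
// [[Rcpp::export(name = ".hb_logp_grad")]]
Rcpp::List hb_logp_grad(Rcpp::NumericMatrix Y_, Rcpp::NumericMatrix logoff_,
                        Rcpp::NumericMatrix mask_, Rcpp::NumericMatrix X_,
                        Rcpp::IntegerVector gidx_, Rcpp::IntegerVector gtype_,
                        Rcpp::NumericVector cscale_,
                        Rcpp::NumericVector theta_) {
  Model mdl = make_model(Y_, logoff_, mask_, X_, gidx_, gtype_, cscale_);
  vec theta(theta_.begin(), theta_.size());
  vec theta_b = theta.subvec(0, mdl.U * mdl.K - 1);
  vec tau = theta.subvec(mdl.U * mdl.K, mdl.P - 1);
  vec grad;
  double lp = mdl.logp_grad(theta_b, tau, grad);
  const mat B(theta_b.memptr(), mdl.U, mdl.K);
  double lpt = mdl.logp_tau(B, tau);
  return Rcpp::List::create(Rcpp::Named("logp_coef") = lp,
                            Rcpp::Named("grad_coef") = Rcpp::wrap(grad),
                            Rcpp::Named("logp_tau") = lpt);
}

// [[Rcpp::export(name = ".nuts_chain")]]
Rcpp::List nuts_chain(Rcpp::NumericMatrix Y_, Rcpp::NumericMatrix logoff_,
                      Rcpp::NumericMatrix mask_, Rcpp::NumericMatrix X_,
                      Rcpp::IntegerVector gidx_, Rcpp::IntegerVector gtype_,
                      Rcpp::NumericVector cscale_,
                      Rcpp::NumericVector theta0_, int n_warmup, int n_draws,
                      int max_depth, double seed) {
  Model mdl = make_model(Y_, logoff_, mask_, X_, gidx_, gtype_, cscale_);

  Sampler smp(mdl, (uint64_t)seed);
  smp.max_depth = max_depth;

  vec theta0(theta0_.begin(), theta0_.size());
  State cur;
  cur.theta = theta0.subvec(0, mdl.U * mdl.K - 1);
  smp.tau = theta0.subvec(mdl.U * mdl.K, mdl.P - 1);
  cur.r.set_size(mdl.U * mdl.K);
  cur.logp = mdl.logp_grad(cur.theta, smp.tau, cur.grad);
  if (!std::isfinite(cur.logp))
    Rcpp::stop("initial parameter values have non-finite log posterior");

  // posterior scales here span many orders of magnitude, so a unit
  // metric would make early warmup prohibitively stiff
  smp.fisher_metric(cur.theta);

  // dual averaging state
  smp.find_initial_eps(cur);
  double mu = std::log(10.0 * smp.eps);
  double log_eps_bar = 0.0, h_bar = 0.0;
  const double delta = 0.8, gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;

  // adaptation windows (Stan-like, scaled for short warmups)
  int init_buf = std::max(15, (int)std::floor(0.15 * n_warmup));
  int term_buf = std::max(10, (int)std::floor(0.10 * n_warmup));
  int win = 25;
  if (init_buf + term_buf + win > n_warmup) {
    init_buf = (int)std::floor(0.15 * n_warmup);
    term_buf = (int)std::floor(0.10 * n_warmup);
    win = n_warmup - init_buf - term_buf;
  }
  int win_start = init_buf, win_end = std::min(win_start + win, n_warmup - term_buf);

  mat draws(n_draws, mdl.P);
  Rcpp::IntegerVector depth_out(n_draws);
  Rcpp::LogicalVector div_out(n_draws);
  int warmup_div = 0;

  int depth; double astat;
  for (int it = 0; it < n_warmup + n_draws; ++it) {
    smp.transition(cur, depth, astat);
    smp.gibbs_tau(cur.theta);
    smp.asis_tau(cur.theta);
    smp.recombine_metric();
    cur.logp = mdl.logp_grad(cur.theta, smp.tau, cur.grad);
    if (it < n_warmup) {
      if (smp.divergent_this_iter) ++warmup_div;
      // dual averaging update
      ++da_count;
      double eta_h = 1.0 / (da_count + t0);
      h_bar = (1.0 - eta_h) * h_bar + eta_h * (delta - astat);
      double log_eps = mu - std::sqrt((double)da_count) / gamma * h_bar;
      double eta_x = std::pow((double)da_count, -kappa);
      log_eps_bar = eta_x * log_eps + (1.0 - eta_x) * log_eps_bar;
      smp.eps = std::exp(log_eps);
      // refresh the Fisher metric at window boundaries (position- and
      // tau-dependent) and restart step-size adaptation around the
      // current averaged eps
      if (it == win_end - 1 && win_end < n_warmup) {
        smp.fisher_metric(cur.theta);
        mu = std::log(10.0 * std::exp(log_eps_bar));
        h_bar = 0.0; da_count = 0;
        int next_win = std::min(2 * (win_end - win_start),
                                n_warmup - term_buf - win_end);
        win_start = win_end;
        win_end = win_start + std::max(next_win, 0);
      }
      if (it == n_warmup - 1) smp.eps = std::exp(log_eps_bar);
    } else {
      int k = it - n_warmup;
      draws.row(k) = join_cols(cur.theta, smp.tau).t();
      depth_out[k] = depth;
      div_out[k] = smp.divergent_this_iter;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("draws") = Rcpp::wrap(draws),
      Rcpp::Named("treedepth") = depth_out,
      Rcpp::Named("divergent") = div_out,
      Rcpp::Named("warmup_divergences") = warmup_div,
      Rcpp::Named("stepsize") = smp.eps,
      Rcpp::Named("inv_metric") = Rcpp::wrap(smp.minv));
}
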
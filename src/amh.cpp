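// Core numerics for the AMH-Weibull bivariate survival model.
//
// Weibull margins are rate-type: S_j(t) = exp(-beta_j * t^alpha_j), so the
// censored-data likelihood factors into two univariate Weibull pieces times
// per-subject copula factors Psi_i whose form depends on the censoring
// pattern (delta_i1, delta_i2).  Everything is computed in log space; any
// nonpositive Psi numerator (possible only through underflow at phi near
// the boundary) yields a -Inf kernel value, which an MH step rejects.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// generic slice sampling step (stepping-out with fixed increment lambda,
// then either uniform-on-bracket ("paper" mode) or reject-and-shrink until
// the draw lies inside the slice ("shrink" mode, the default for exactness).
// The kernel's support is (0, Inf): stepping stops at the origin.
// ---------------------------------------------------------------------------
template <typename F>
static double slice_step_generic(F logk, double cur, double lambda, bool shrink) {
  double lk_cur = logk(cur);
  if (!R_finite(lk_cur))
    stop("slice sampler: kernel is not finite at the current point");
  double logu = lk_cur + std::log(unif_rand());
  // lo/hi: outermost accepted points (the A-tilde bracket, always containing
  // the current point); lo_out/hi_out: first points found outside the slice,
  // which bracket it entirely and are the valid shrinkage endpoints.
  double lo = cur, hi = cur, lo_out = cur, hi_out = cur;
  const long max_steps = 1000000L;
  long m;
  for (m = 1; m <= max_steps; ++m) {
    double x = cur - m * lambda;
    if (x <= 0.0) { lo_out = 0.0; break; }
    if (logk(x) > logu) lo = x; else { lo_out = x; break; }
  }
  if (m > max_steps) stop("slice sampler: stepping out exceeded 1e6 increments (unbounded slice?)");
  for (m = 1; m <= max_steps; ++m) {
    double x = cur + m * lambda;
    if (logk(x) > logu) hi = x; else { hi_out = x; break; }
  }
  if (m > max_steps) stop("slice sampler: stepping out exceeded 1e6 increments (unbounded slice?)");
  if (!shrink) return R::runif(lo, hi);
  for (int k = 0; k < 10000; ++k) {
    double x = R::runif(lo_out, hi_out);
    if (logk(x) > logu) return x;
    if (x < cur) lo_out = x; else hi_out = x;
  }
  return cur;  // degenerate slice narrower than machine resolution
}

// half-open interval index of phi on the grid -1, -0.9, ..., 1 (a = 1..20)
static inline int phi_interval(double phi) {
  int a = (int)std::floor((phi + 1.0) / 0.1) + 1;
  if (a < 1) a = 1;
  if (a > 20) a = 20;
  return a;
}

// propose phi* from the 2- or 3-interval uniform mixture centred on the
// current interval; logP receives the log Hastings factor q(phi|phi*)/q(phi*|phi)
static double propose_phi(double phi, double& logP) {
  int a = phi_interval(phi);
  int arity_from = (a == 1 || a == 20) ? 2 : 3;
  int target;
  double u = unif_rand();
  if (a == 1)       target = (u <= 0.5) ? 1 : 2;
  else if (a == 20) target = (u <= 0.5) ? 20 : 19;
  else              target = (u <= 1.0 / 3.0) ? (a - 1) : ((u <= 2.0 / 3.0) ? a : (a + 1));
  double lo = -1.0 + 0.1 * (target - 1);
  double prop = R::runif(lo, lo + 0.1);
  int as = phi_interval(prop);
  int arity_to = (as == 1 || as == 20) ? 2 : 3;
  logP = std::log((double)arity_from) - std::log((double)arity_to);
  return prop;
}

// ---------------------------------------------------------------------------
// model state with per-margin caches (t^alpha and F = 1 - exp(-beta t^alpha))
// ---------------------------------------------------------------------------
struct Model {
  int n;
  std::vector<double> t1, t2, logt1, logt2;
  std::vector<int> d1, d2;
  double r1, r2, sdl1, sdl2;                  // r_j, sum_i delta_ij log t_ij
  double a11, a12, a21, a22, b11, b12, b21, b22;
  double al1, be1, al2, be2, phi;
  std::vector<double> ta1, ta2, F1, F2;
  double sum_ta1, sum_ta2;

  void init(const NumericVector& t1_, const IntegerVector& d1_,
            const NumericVector& t2_, const IntegerVector& d2_,
            const NumericVector& hyper, const NumericVector& par) {
    n = t1_.size();
    t1.assign(t1_.begin(), t1_.end());
    t2.assign(t2_.begin(), t2_.end());
    d1.assign(d1_.begin(), d1_.end());
    d2.assign(d2_.begin(), d2_.end());
    logt1.resize(n); logt2.resize(n);
    r1 = r2 = sdl1 = sdl2 = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!(t1[i] > 0.0) || !(t2[i] > 0.0)) stop("times must be strictly positive");
      logt1[i] = std::log(t1[i]);
      logt2[i] = std::log(t2[i]);
      r1 += d1[i]; sdl1 += d1[i] * logt1[i];
      r2 += d2[i]; sdl2 += d2[i] * logt2[i];
    }
    a11 = hyper[0]; a12 = hyper[1]; a21 = hyper[2]; a22 = hyper[3];
    b11 = hyper[4]; b12 = hyper[5]; b21 = hyper[6]; b22 = hyper[7];
    al1 = par[0]; be1 = par[1]; al2 = par[2]; be2 = par[3]; phi = par[4];
    ta1.resize(n); ta2.resize(n); F1.resize(n); F2.resize(n);
    recompute_margin(1);
    recompute_margin(2);
  }

  void recompute_margin(int margin) {
    if (margin == 1) {
      sum_ta1 = 0.0;
      for (int i = 0; i < n; ++i) {
        ta1[i] = std::exp(al1 * logt1[i]);
        sum_ta1 += ta1[i];
        F1[i] = 1.0 - std::exp(-be1 * ta1[i]);
      }
    } else {
      sum_ta2 = 0.0;
      for (int i = 0; i < n; ++i) {
        ta2[i] = std::exp(al2 * logt2[i]);
        sum_ta2 += ta2[i];
        F2[i] = 1.0 - std::exp(-be2 * ta2[i]);
      }
    }
  }

  // sum_i log Psi_i at given marginal CDF values and phi
  double psi_log(const std::vector<double>& G1, const std::vector<double>& G2,
                 double ph) const {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      double ff = G1[i] * G2[i];
      double D = 1.0 - ph * ff;
      if (!(D > 0.0)) return NEG_INF;
      int powD;
      if (d1[i] && d2[i]) {
        double N = (1.0 + ph) * (1.0 + ph * ff) - 2.0 * ph * (G1[i] + G2[i]);
        if (!(N > 0.0)) return NEG_INF;
        s += std::log(N);
        powD = 3;
      } else if (d1[i]) {
        double N = 1.0 - ph * G2[i];
        if (!(N > 0.0)) return NEG_INF;
        s += std::log(N);
        powD = 2;
      } else if (d2[i]) {
        double N = 1.0 - ph * G1[i];
        if (!(N > 0.0)) return NEG_INF;
        s += std::log(N);
        powD = 2;
      } else {
        powD = 1;
      }
      s -= powD * std::log(D);
    }
    return s;
  }

  double margin_term(int margin) const {
    if (margin == 1)
      return r1 * (std::log(al1) + std::log(be1)) + (al1 - 1.0) * sdl1 - be1 * sum_ta1;
    return r2 * (std::log(al2) + std::log(be2)) + (al2 - 1.0) * sdl2 - be2 * sum_ta2;
  }

  double loglik() const {
    double ps = psi_log(F1, F2, phi);
    if (ps == NEG_INF) return NEG_INF;
    return margin_term(1) + margin_term(2) + ps;
  }

  // alpha-dependent part of the log-likelihood for one margin (trial value a):
  // r log a + (a-1) sdl - beta sum t^a + sum log Psi(F_trial)
  double lik_kernel_alpha(int margin, double a) const {
    if (!(a > 0.0)) return NEG_INF;
    const std::vector<double>& lt = (margin == 1) ? logt1 : logt2;
    double be  = (margin == 1) ? be1  : be2;
    double r   = (margin == 1) ? r1   : r2;
    double sdl = (margin == 1) ? sdl1 : sdl2;
    std::vector<double> Ft(n);
    double ssum = 0.0;
    for (int i = 0; i < n; ++i) {
      double ta = std::exp(a * lt[i]);
      ssum += ta;
      Ft[i] = 1.0 - std::exp(-be * ta);
    }
    double ps = (margin == 1) ? psi_log(Ft, F2, phi) : psi_log(F1, Ft, phi);
    if (ps == NEG_INF) return NEG_INF;
    return r * std::log(a) + (a - 1.0) * sdl - be * ssum + ps;
  }

  // log kappa(alpha): likelihood kernel plus the Gamma prior kernel
  double log_kappa(int margin, double a) const {
    if (!(a > 0.0)) return NEG_INF;
    double sh = (margin == 1) ? a11 : a21;
    double rt = (margin == 1) ? a12 : a22;
    double lk = lik_kernel_alpha(margin, a);
    if (lk == NEG_INF) return NEG_INF;
    return lk + (sh - 1.0) * std::log(a) - rt * a;
  }

  void set_alpha(int margin, double a) {
    if (margin == 1) al1 = a; else al2 = a;
    recompute_margin(margin);
  }

  void set_beta(int margin, double b) {
    if (margin == 1) be1 = b; else be2 = b;
    recompute_margin(margin);
  }

  // method: 0 = IMH (prior proposal), 1 = RWM, 2 = slice/shrink, 3 = slice/paper
  bool update_alpha(int margin, int method, double sigma2, double lambda) {
    double cur = (margin == 1) ? al1 : al2;
    double sh  = (margin == 1) ? a11 : a21;
    double rt  = (margin == 1) ? a12 : a22;
    if (method == 0) {
      double prop = R::rgamma(sh, 1.0 / rt);
      if (!(prop > 0.0) || !R_finite(prop)) return false;
      double la = lik_kernel_alpha(margin, prop) - lik_kernel_alpha(margin, cur);
      if (std::log(unif_rand()) <= la) { set_alpha(margin, prop); return true; }
      return false;
    }
    if (method == 1) {
      double prop = cur + norm_rand() * std::sqrt(sigma2);
      if (!(prop > 0.0)) return false;  // zero prior support
      double la = (lik_kernel_alpha(margin, prop) + R::dgamma(prop, sh, 1.0 / rt, 1)) -
                  (lik_kernel_alpha(margin, cur)  + R::dgamma(cur,  sh, 1.0 / rt, 1));
      if (std::log(unif_rand()) <= la) { set_alpha(margin, prop); return true; }
      return false;
    }
    const Model* self = this;
    double nx = slice_step_generic(
      [self, margin](double x) { return self->log_kappa(margin, x); },
      cur, lambda, method == 2);
    set_alpha(margin, nx);
    return true;  // a slice move is always a valid draw
  }

  bool update_beta(int margin) {
    double b1h = (margin == 1) ? b11 : b21;
    double b2h = (margin == 1) ? b12 : b22;
    double r   = (margin == 1) ? r1  : r2;
    double sta = (margin == 1) ? sum_ta1 : sum_ta2;
    double prop = R::rgamma(b1h + r, 1.0 / (b2h + sta));
    if (!(prop > 0.0) || !R_finite(prop)) return false;
    const std::vector<double>& ta = (margin == 1) ? ta1 : ta2;
    std::vector<double> Ft(n);
    for (int i = 0; i < n; ++i) Ft[i] = 1.0 - std::exp(-prop * ta[i]);
    double la = ((margin == 1) ? psi_log(Ft, F2, phi) : psi_log(F1, Ft, phi)) -
                psi_log(F1, F2, phi);
    if (std::log(unif_rand()) <= la) { set_beta(margin, prop); return true; }
    return false;
  }

  bool update_phi() {
    double logP;
    double prop = propose_phi(phi, logP);
    double la = psi_log(F1, F2, prop) - psi_log(F1, F2, phi) + logP;
    if (std::log(unif_rand()) <= la) { phi = prop; return true; }
    return false;
  }
};

static Model make_model(NumericVector t1, IntegerVector d1,
                        NumericVector t2, IntegerVector d2,
                        NumericVector hyper, NumericVector par) {
  if (t1.size() != d1.size() || t1.size() != t2.size() || t1.size() != d2.size())
    stop("data vectors must have equal length");
  if (hyper.size() != 8) stop("hyper must have length 8");
  if (par.size() != 5) stop("params must have length 5");
  Model M;
  M.init(t1, d1, t2, d2, hyper, par);
  return M;
}

// [[Rcpp::export]]
double amh_loglik_cpp(NumericVector t1, IntegerVector d1,
                      NumericVector t2, IntegerVector d2,
                      NumericVector params) {
  NumericVector hyper = NumericVector::create(0.01, 0.01, 0.01, 0.01,
                                              0.01, 0.01, 0.01, 0.01);
  Model M = make_model(t1, d1, t2, d2, hyper, params);
  return M.loglik();
}

// [[Rcpp::export]]
double amh_log_kappa_cpp(NumericVector t1, IntegerVector d1,
                         NumericVector t2, IntegerVector d2,
                         NumericVector hyper, NumericVector params,
                         int margin, double alpha) {
  Model M = make_model(t1, d1, t2, d2, hyper, params);
  return M.log_kappa(margin, alpha);
}

// single MCMC block updates, exported for unit testing and phi-only chains ---

// [[Rcpp::export]]
List step_alpha_cpp(NumericVector t1, IntegerVector d1,
                    NumericVector t2, IntegerVector d2,
                    NumericVector hyper, NumericVector params,
                    int margin, int method, double sigma2, double lambda) {
  Model M = make_model(t1, d1, t2, d2, hyper, params);
  bool acc = M.update_alpha(margin, method, sigma2, lambda);
  double val = (margin == 1) ? M.al1 : M.al2;
  return List::create(_["value"] = val, _["accepted"] = acc);
}

// [[Rcpp::export]]
List step_beta_cpp(NumericVector t1, IntegerVector d1,
                   NumericVector t2, IntegerVector d2,
                   NumericVector hyper, NumericVector params, int margin) {
  Model M = make_model(t1, d1, t2, d2, hyper, params);
  bool acc = M.update_beta(margin);
  double val = (margin == 1) ? M.be1 : M.be2;
  return List::create(_["value"] = val, _["accepted"] = acc);
}

// [[Rcpp::export]]
List step_phi_cpp(NumericVector t1, IntegerVector d1,
                  NumericVector t2, IntegerVector d2,
                  NumericVector params) {
  NumericVector hyper = NumericVector::create(0.01, 0.01, 0.01, 0.01,
                                              0.01, 0.01, 0.01, 0.01);
  Model M = make_model(t1, d1, t2, d2, hyper, params);
  bool acc = M.update_phi();
  return List::create(_["value"] = M.phi, _["accepted"] = acc);
}

// phi-only chain with the margins held fixed (used against a deterministic
// 1-D posterior quadrature in tests)

// [[Rcpp::export]]
NumericVector grid_phi_chain_model_cpp(int n_steps,
                                       NumericVector t1, IntegerVector d1,
                                       NumericVector t2, IntegerVector d2,
                                       NumericVector params) {
  NumericVector hyper = NumericVector::create(0.01, 0.01, 0.01, 0.01,
                                              0.01, 0.01, 0.01, 0.01);
  Model M = make_model(t1, d1, t2, d2, hyper, params);
  NumericVector out(n_steps);
  for (int l = 0; l < n_steps; ++l) {
    M.update_phi();
    out[l] = M.phi;
    if ((l + 1) % 10000 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// phi chain under a flat likelihood: stationary law must be U(-1, 1)

// [[Rcpp::export]]
NumericVector grid_phi_chain_flat_cpp(int n_steps, double phi0) {
  double phi = phi0;
  NumericVector out(n_steps);
  for (int l = 0; l < n_steps; ++l) {
    double logP;
    double prop = propose_phi(phi, logP);
    if (std::log(unif_rand()) <= logP) phi = prop;
    out[l] = phi;
  }
  return out;
}

// slice sampler on a known truncated-Gaussian kernel exp(-(x-mu)^2/(2 sd^2)),
// x > 0 -- exercises the same stepping/shrinkage code path as the model updates

// [[Rcpp::export]]
NumericVector slice_chain_gauss_cpp(int n_steps, double x0, double mu,
                                    double sd, double lambda, bool shrink) {
  double x = x0;
  NumericVector out(n_steps);
  double inv2v = 1.0 / (2.0 * sd * sd);
  auto logk = [mu, inv2v](double z) {
    return (z > 0.0) ? -(z - mu) * (z - mu) * inv2v : NEG_INF;
  };
  for (int l = 0; l < n_steps; ++l) {
    x = slice_step_generic(logk, x, lambda, shrink);
    out[l] = x;
    if ((l + 1) % 10000 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// full chain driver.  Update order per iteration: alpha1, beta1, alpha2,
// beta2, phi; each beta update consumes the same iteration's fresh alpha.
// alg: 1 = IMH shapes (A1), 2 = RWM shapes (A2), 3 = slice shapes (A3).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List run_chain_cpp(NumericVector t1, IntegerVector d1,
                   NumericVector t2, IntegerVector d2,
                   NumericVector hyper, NumericVector init,
                   int L, int B, int J, int alg,
                   double sigma2, double lambda, bool slice_shrink) {
  Model M = make_model(t1, d1, t2, d2, hyper, init);
  if (M.loglik() == NEG_INF)
    stop("log-posterior is not finite at the initial parameter values");
  if (B < 0 || B >= L || J < 1) stop("invalid chain configuration");
  int S = (L - B) / J;
  if (S < 1) stop("no draws would be kept: increase L or reduce burn-in/thinning");
  int method = (alg == 1) ? 0 : (alg == 2) ? 1 : (slice_shrink ? 2 : 3);
  NumericMatrix draws(S, 5);
  IntegerVector acc(5);
  int k = 0;
  for (int l = 1; l <= L; ++l) {
    if (M.update_alpha(1, method, sigma2, lambda)) acc[0]++;
    if (M.update_beta(1)) acc[1]++;
    if (M.update_alpha(2, method, sigma2, lambda)) acc[2]++;
    if (M.update_beta(2)) acc[3]++;
    if (M.update_phi()) acc[4]++;
    if (l > B && (l - B) % J == 0 && k < S) {
      draws(k, 0) = M.al1; draws(k, 1) = M.be1;
      draws(k, 2) = M.al2; draws(k, 3) = M.be2;
      draws(k, 4) = M.phi;
      ++k;
    }
    if (l % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["draws"] = draws, _["accept"] = acc, _["S"] = S);
}
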
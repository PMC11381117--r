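#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Structure type codes shared with R (see R/model-family.R):
//   0 = linear      f(e) = b e                theta = (b)
//   1 = affine      f(e) = a + b e            theta = (a, b)
//   2 = quadratic   f(e) = a + (b + c e) e    theta = (a, b, c)
//   3 = cubic       f(e) = a + (b + c e + d e^2) e
//   4 = kth-order   f(e_n..e_{n-k+1}) = a + b1 e_n + ... + bk e_{n-k+1}
// History shorter than k is padded by repeating the initial error e0
// (index below 0 maps to element 0).

static inline double drift_at(int type, int k, const double* th,
                              const double* e, int pos) {
  double en = e[pos];
  switch (type) {
  case 0: return th[0] * en;
  case 1: return th[0] + th[1] * en;
  case 2: return th[0] + (th[1] + th[2] * en) * en;
  case 3: return th[0] + (th[1] + th[2] * en + th[3] * en * en) * en;
  case 4: {
    double s = th[0];
    for (int j = 0; j < k; ++j) {
      int idx = pos - j;
      s += th[1 + j] * e[idx >= 0 ? idx : 0];
    }
    return s;
  }
  }
  return NA_REAL;
}

// Forward-simulate the proxy process e_{n+1} = e_n + f(history) + sigma dz.
// `noise` holds pre-drawn standard-normal deviates (length n_trials) or is
// empty for the deterministic path. Returns length n_trials + 1 (e_0 first).
// [[Rcpp::export(name = ".sim_proxy_cpp")]]
NumericVector sim_proxy_cpp(int type, int k, NumericVector theta, double e0,
                            int n_trials, double sigma, NumericVector noise) {
  NumericVector e(n_trials + 1);
  e[0] = e0;
  bool stoch = noise.size() > 0;
  const double* th = theta.begin();
  double* ep = e.begin();
  for (int n = 0; n < n_trials; ++n) {
    double f = drift_at(type, k, th, ep, n);
    ep[n + 1] = ep[n] + f + (stoch ? sigma * noise[n] : 0.0);
  }
  return e;
}

// Deterministic simulation SSE against observations at given trial indices
// (0-based into the simulated sequence). Divergent trajectories are rejected
// with +Inf so multi-start optimisation discards them.
// [[Rcpp::export(name = ".sse_proxy_cpp")]]
double sse_proxy_cpp(int type, int k, NumericVector theta, double e0,
                     int n_trials, IntegerVector obs_idx, NumericVector obs) {
  std::vector<double> e(n_trials + 1);
  e[0] = e0;
  const double* th = theta.begin();
  for (int n = 0; n < n_trials; ++n) {
    double f = drift_at(type, k, th, e.data(), n);
    e[n + 1] = e[n] + f;
    if (!std::isfinite(e[n + 1]) || std::fabs(e[n + 1]) > 1e8)
      return R_PosInf;
  }
  double sse = 0.0;
  for (int i = 0; i < obs_idx.size(); ++i) {
    double d = obs[i] - e[obs_idx[i]];
    sse += d * d;
  }
  return sse;
}

// Multi-rate model with dynamic proxy support. obs/avail have one entry per
// trial (0-based); on trials without an available observation the internal
// error estimate ehat is forward-predicted by the embedded second-order proxy
// process (theta = a, b1, b2), with history padded by its first element.
// yhat[n] = xf[n] + xs[n] is the prediction BEFORE updating with trial n.
// [[Rcpp::export(name = ".run_dpxmrml_cpp")]]
List run_dpxmrml_cpp(double Af, double As, double Bf, double Bs,
                     NumericVector theta, double sigma,
                     NumericVector obs, LogicalVector avail,
                     NumericVector noise) {
  int N = obs.size();
  NumericVector ehat(N), yhat(N), xf(N + 1), xs(N + 1);
  xf[0] = 0.0; xs[0] = 0.0;
  bool stoch = noise.size() > 0;
  for (int n = 0; n < N; ++n) {
    yhat[n] = xf[n] + xs[n];
    if (avail[n]) {
      ehat[n] = obs[n];
    } else {
      double e1 = ehat[n - 1];            // n >= 1 guaranteed by R wrapper
      double e2 = (n >= 2) ? ehat[n - 2] : e1;
      double f = theta[0] + theta[1] * e1 + theta[2] * e2;
      ehat[n] = e1 + f + (stoch ? sigma * noise[n] : 0.0);
    }
    xf[n + 1] = Af * xf[n] + Bf * ehat[n];
    xs[n + 1] = As * xs[n] + Bs * ehat[n];
  }
  return List::create(_["yhat"] = yhat, _["ehat"] = ehat,
                      _["xf"] = xf, _["xs"] = xs);
}

// SSE of dPxMRML predictions at available (no-vision) trials, deterministic.
// [[Rcpp::export(name = ".sse_dpxmrml_cpp")]]
double sse_dpxmrml_cpp(double Af, double As, double Bf, double Bs,
                       NumericVector theta, NumericVector obs,
                       LogicalVector avail) {
  int N = obs.size();
  double xf = 0.0, xs = 0.0, e1 = 0.0, e2 = 0.0, sse = 0.0;
  for (int n = 0; n < N; ++n) {
    double yhat = xf + xs;
    double eh;
    if (avail[n]) {
      eh = obs[n];
      double d = obs[n] - yhat;
      sse += d * d;
    } else {
      double ep2 = (n >= 2) ? e2 : e1;
      eh = e1 + theta[0] + theta[1] * e1 + theta[2] * ep2;
    }
    double xf1 = Af * xf + Bf * eh;
    double xs1 = As * xs + Bs * eh;
    if (!std::isfinite(xf1) || !std::isfinite(xs1) ||
        std::fabs(xf1) + std::fabs(xs1) > 1e8)
      return R_PosInf;
    xf = xf1; xs = xs1; e2 = e1; e1 = eh;
  }
  return sse;
}

static inline int draw_index(const double* cw, int n) {
  // cw: cumulative weights normalised to end at 1; inverse-CDF draw
  double u = unif_rand();
  int lo = 0, hi = n - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (u <= cw[mid]) hi = mid; else lo = mid + 1;
  }
  return lo;
}

// B weighted-bootstrap medians of x (resampling probability proportional to
// weights, given as a normalised cumulative vector). Uses R's RNG.
// [[Rcpp::export(name = ".boot_median_cpp")]]
NumericVector boot_median_cpp(NumericVector x, NumericVector cumw, int B) {
  int n = x.size();
  NumericVector out(B);
  std::vector<double> buf(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) buf[i] = x[draw_index(cumw.begin(), n)];
    int h = n / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double med = buf[h];
    if (n % 2 == 0) {
      double lo = *std::max_element(buf.begin(), buf.begin() + h);
      med = 0.5 * (med + lo);
    }
    out[b] = med;
  }
  return out;
}

// Mann-Whitney U of group A (labels 0) in a combined labelled sample, with
// average ranks for ties.
static double ranksum_U(std::vector<std::pair<double, int> >& v, int na) {
  int N = v.size();
  std::sort(v.begin(), v.end());
  double W = 0.0;
  int i = 0;
  while (i < N) {
    int j = i;
    while (j < N && v[j].first == v[i].first) ++j;
    double avg_rank = 0.5 * (i + 1 + j);   // ranks are 1-based
    for (int m = i; m < j; ++m)
      if (v[m].second == 0) W += avg_rank;
    i = j;
  }
  return W - na * (na + 1.0) / 2.0;
}

// [[Rcpp::export(name = ".ranksum_u_cpp")]]
double ranksum_u_cpp(NumericVector xa, NumericVector xb) {
  std::vector<std::pair<double, int> > v(xa.size() + xb.size());
  for (int i = 0; i < xa.size(); ++i) v[i] = std::make_pair(xa[i], 0);
  for (int i = 0; i < xb.size(); ++i)
    v[xa.size() + i] = std::make_pair(xb[i], 1);
  return ranksum_U(v, xa.size());
}

// Bootstrap null distribution of the Mann-Whitney U statistic: under the
// null both groups share one distribution, so each replicate draws both
// groups from the pooled weighted sample and computes U of the first group.
// Returns the B replicate U values; the p-value is taken in R as the
// proportion at least as far from the null mean na*nb/2 as the observed U.
// [[Rcpp::export(name = ".boot_ranksum_null_cpp")]]
NumericVector boot_ranksum_null_cpp(NumericVector pool, NumericVector cumw,
                                    int na, int nb, int B) {
  int n = pool.size();
  NumericVector out(B);
  std::vector<std::pair<double, int> > v(na + nb);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < na; ++i)
      v[i] = std::make_pair(pool[draw_index(cumw.begin(), n)], 0);
    for (int i = 0; i < nb; ++i)
      v[na + i] = std::make_pair(pool[draw_index(cumw.begin(), n)], 1);
    out[b] = ranksum_U(v, na);
  }
  return out;
}
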
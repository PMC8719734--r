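// Compiled core: discretized delay kernel, Euler-Maruyama simulation of the
// delayed chemical Langevin equation, and the augmented-state Kalman filter
// used as the likelihood inside MCMC.  Everything here is performance
// critical; the R layer owns validation and documentation.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Delay kernel discretization
// ---------------------------------------------------------------------------

// Cell masses of the truncated, renormalised gamma delay density on a uniform
// grid of step h over [0, tau_max].  Mass of cell j (j = 1..M) is
// P((j-1)h < tau <= jh) / P(tau <= tau_max), attributed to the cell midpoint.
// A kernel narrower than one grid cell (sd < h) collapses to a point mass on
// the cell containing the mean, which preserves the fixed-delay limiting case.
static std::vector<double> kernel_masses(double shape, double rate,
                                         double tau_max, double h) {
  int M = (int)std::lround(tau_max / h);
  std::vector<double> w((size_t)M, 0.0);
  double mean = shape / rate;
  double sd = std::sqrt(shape) / rate;
  double scale = 1.0 / rate;
  double Z = R::pgamma(tau_max, shape, scale, 1, 0);
  bool degenerate = (sd < h) || !(Z > 0.0) || !R_finite(Z);
  if (!degenerate) {
    double prev = 0.0, tot = 0.0;
    for (int j = 0; j < M; ++j) {
      double cur = R::pgamma((j + 1) * h, shape, scale, 1, 0);
      double wj = (cur - prev) / Z;
      if (wj < 0.0 || !R_finite(wj)) wj = 0.0;
      w[(size_t)j] = wj;
      tot += wj;
      prev = cur;
    }
    if (tot > 0.0) {
      for (int j = 0; j < M; ++j) w[(size_t)j] /= tot;
      return w;
    }
    degenerate = true;
  }
  int j = (int)std::floor(mean / h);
  if (j < 0) j = 0;
  if (j >= M) j = M - 1;
  std::fill(w.begin(), w.end(), 0.0);
  w[(size_t)j] = 1.0;
  return w;
}

// Weights applied to the lagged state vector (x(t), x(t-h), ..., x(t-Mh)) so
// that sum_k v_k x(t-kh) approximates the delayed integral: each midpoint
// value is the average of its two bracketing grid states.
static std::vector<double> state_weights(const std::vector<double>& w) {
  int M = (int)w.size();
  std::vector<double> v((size_t)M + 1, 0.0);
  v[0] = 0.5 * w[0];
  for (int k = 1; k < M; ++k) v[(size_t)k] = 0.5 * (w[(size_t)(k - 1)] + w[(size_t)k]);
  v[(size_t)M] = 0.5 * w[(size_t)(M - 1)];
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_kernel_masses(double shape, double rate, double tau_max,
                                double h) {
  std::vector<double> w = kernel_masses(shape, rate, tau_max, h);
  return NumericVector(w.begin(), w.end());
}

// [[Rcpp::export]]
NumericVector cpp_state_weights(double shape, double rate, double tau_max,
                                double h) {
  std::vector<double> v = state_weights(kernel_masses(shape, rate, tau_max, h));
  return NumericVector(v.begin(), v.end());
}

// ---------------------------------------------------------------------------
// Hill transcription function
// ---------------------------------------------------------------------------

static inline double hill(double z, double R, double K, double n) {
  if (n == 0.0) return 0.5 * R;
  if (z <= 0.0) return R;
  return R / (1.0 + std::pow(z / K, n));
}

// dH/dz evaluated at z (<= 0 guarded: the repression function is flat there)
static inline double hill_prime(double z, double R, double K, double n) {
  if (n == 0.0 || z <= 0.0) return 0.0;
  double u = std::pow(z / K, n);
  double denom = 1.0 + u;
  return -R * n * u / (z * denom * denom);
}

// d2H/dz2 (guarded as above)
static inline double hill_second(double z, double R, double K, double n) {
  if (n == 0.0 || z <= 0.0) return 0.0;
  double u = std::pow(z / K, n);
  double denom = 1.0 + u;
  // H'' = R n u [ (1-n) + (n+1) u ] / (z^2 (1+u)^3)
  return R * n * u * ((1.0 - n) + (n + 1.0) * u) /
         (z * z * denom * denom * denom);
}

// Positive equilibrium of R/(1+(x/K)^n) = mu x by bisection on [0, R/mu].
// The left side is non-increasing and the right side increasing, so the root
// is unique.
static double equilibrium_cpp(double R, double K, double n, double mu) {
  if (n == 0.0) return 0.5 * R / mu;
  double lo = 0.0, hi = R / mu;
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    double f = hill(mid, R, K, n) - mu * mid;
    if (f > 0.0) lo = mid; else hi = mid;
    if ((hi - lo) <= 1e-14 * hi) break;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
double cpp_equilibrium(double R, double K, double n, double mu) {
  return equilibrium_cpp(R, K, n, mu);
}

// ---------------------------------------------------------------------------
// Euler-Maruyama simulation of the delayed CLE
// ---------------------------------------------------------------------------

// hist:  npaths x (M+1) initial buffer, column k holding x(-k*dt).
// Rv, Kv, nv, muv: per-path parameters (length 1 recycles).
// V:     state-weight matrix, npaths x (M+1) (or 1 x (M+1) shared).
// shock: length-nsteps additive drift (molecules/hour) applied in each step.
// Returns npaths x (nsteps+1) matrix of paths, column c holding x(c*dt).
// Negative excursions are clamped at zero.  Uses the R RNG stream so that
// set.seed() in R gives bit-reproducible ensembles.
// [[Rcpp::export]]
NumericMatrix cpp_sim_paths(NumericMatrix hist, NumericVector Rv,
                            NumericVector Kv, NumericVector nv,
                            NumericVector muv, NumericMatrix V, double dt,
                            int nsteps, NumericVector shock, bool stochastic) {
  const int npaths = hist.nrow();
  const int D = hist.ncol();          // M + 1
  const int M = D - 1;
  const bool sharedV = (V.nrow() == 1);
  const bool sharedP = (Rv.size() == 1);

  // rolling buffer: columns 0..(M+nsteps), column c is time (c - M)*dt
  const int ncol = M + nsteps + 1;
  std::vector<double> B((size_t)npaths * ncol);
  for (int k = 0; k <= M; ++k) {
    // hist column k is lag k => buffer column M - k
    std::memcpy(&B[(size_t)(M - k) * npaths], &hist(0, k),
                sizeof(double) * (size_t)npaths);
  }

  std::vector<double> z((size_t)npaths);
  RNGScope scope;
  for (int t = 0; t < nsteps; ++t) {
    const int c = M + t;   // current column
    std::fill(z.begin(), z.end(), 0.0);
    for (int k = 0; k <= M; ++k) {
      const double* col = &B[(size_t)(c - k) * npaths];
      if (sharedV) {
        const double vk = V(0, k);
        if (vk == 0.0) continue;
        for (int p = 0; p < npaths; ++p) z[(size_t)p] += vk * col[p];
      } else {
        for (int p = 0; p < npaths; ++p) z[(size_t)p] += V(p, k) * col[p];
      }
    }
    const double sq = std::sqrt(dt);
    double* nw = &B[(size_t)(c + 1) * npaths];
    const double* cur = &B[(size_t)c * npaths];
    for (int p = 0; p < npaths; ++p) {
      const double Rp = sharedP ? Rv[0] : Rv[p];
      const double Kp = sharedP ? Kv[0] : Kv[p];
      const double np = sharedP ? nv[0] : nv[p];
      const double mp = sharedP ? muv[0] : muv[p];
      const double x = cur[p];
      const double hr = hill(z[(size_t)p], Rp, Kp, np);
      double xn = x + (hr - mp * x + shock[t]) * dt;
      if (stochastic) {
        double var = (hr + mp * x);
        if (var < 0.0) var = 0.0;
        xn += std::sqrt(var) * sq * norm_rand();
      }
      nw[p] = (xn > 0.0) ? xn : 0.0;
    }
  }

  NumericMatrix out(npaths, nsteps + 1);
  for (int c = 0; c <= nsteps; ++c)
    std::memcpy(&out(0, c), &B[(size_t)(M + c) * npaths],
                sizeof(double) * (size_t)npaths);
  return out;
}

// ---------------------------------------------------------------------------
// Augmented-state Kalman filter likelihood
// ---------------------------------------------------------------------------
//
// State: (x(t), x(t-h), ..., x(t-Mh)) with M h = tau_max.  Prediction uses a
// first-order linearisation of the Euler map of the delayed CLE; the process
// noise variance is evaluated at the plug-in filtered mean.  Observation at
// each frame is a trapezoid approximation of the exposure integral scaled by
// kappa, with additive Gaussian read noise.

struct FilterOut {
  double loglik;
  bool ok;
};

static FilterOut filter_core(const double* y, int T, double Rr, double K,
                             double n, double mu, double kappa, double sigeta,
                             double dmean, double dsd, double tau_max,
                             double h, int r, double diffuse,
                             double* pred_mean, double* pred_sd,
                             double* filt_mean) {
  FilterOut res; res.loglik = R_NegInf; res.ok = false;
  if (!(dmean > 0.0) || !(dsd > 0.0) || dmean >= tau_max) return res;
  double shape = (dmean * dmean) / (dsd * dsd);
  double rate = dmean / (dsd * dsd);
  std::vector<double> v = state_weights(kernel_masses(shape, rate, tau_max, h));
  // drop dead trailing lags: coordinates past the kernel's numerical
  // support never feed back and the observation touches only 0..r, so
  // truncating where the tail mass is < 1e-12 leaves the likelihood
  // unchanged to that precision while shrinking the O(D^2) recursions
  {
    double tail = 0.0;
    int jmax = (int)v.size() - 1;
    while (jmax > r + 1) {
      tail += v[(size_t)jmax];
      if (tail >= 1e-12) break;
      --jmax;
    }
    if (jmax + 1 < (int)v.size()) {
      v.resize((size_t)jmax + 1);
      double tot = 0.0;
      for (double w : v) tot += w;
      for (double& w : v) w /= tot;
    }
  }
  const int D = (int)v.size();
  if (r >= D) return res;

  const double xstar = equilibrium_cpp(Rr, K, n, mu);
  const double expo = r * h;
  double init = (T > 0 && y[0] > 0.0) ? y[0] / (kappa * expo) : xstar;
  if (!(init > 0.0) || !R_finite(init)) init = xstar;

  std::vector<double> m((size_t)D, init);
  std::vector<double> P((size_t)D * D, 0.0);
  std::vector<double> Pb((size_t)D), g((size_t)D), Pv((size_t)D);
  for (int i = 0; i < D; ++i) P[(size_t)i * D + i] = diffuse * xstar;

  const double sig2 = sigeta * sigeta;
  double ll = 0.0;

  // trapezoid observation weights on coordinates 0..r
  std::vector<double> cw((size_t)r + 1, kappa * h);
  cw[0] = 0.5 * kappa * h;
  cw[(size_t)r] = 0.5 * kappa * h;

  // The lag buffer is circular: logical lag k lives at physical index
  // (base + k) % D, so the per-substep shift is a relabelling (base
  // decrement) rather than a matrix copy.  The dropped oldest lag's slot
  // becomes the new current coordinate.
  int base = 0;
  std::vector<double> bphys((size_t)D);
  // Kalman downdate pending from the previous frame; it is materialized
  // lazily during the next prediction's covariance sweep so each frame
  // makes a single full pass over P
  bool pending = false;
  double pendS = 1.0;

  for (int t = 0; t < T; ++t) {
    for (int s = 0; s < r; ++s) {
      // prediction over one substep of length h
      double z = 0.0;
      for (int k = 0; k < D; ++k) {
        int j = base + k; if (j >= D) j -= D;
        z += v[(size_t)k] * m[(size_t)j];
      }
      if (z < 0.0) z = 0.0;
      // variance of the delayed proxy Z under the current filter state
      for (int k = 0; k < D; ++k) {
        int j = base + k; if (j >= D) j -= D;
        bphys[(size_t)j] = v[(size_t)k];     // reuse as scattered weights
      }
      double zvar = 0.0;
      if (pending) {
        for (int k = 0; k < D; ++k) {
          double* Pc = &P[(size_t)k * D];
          const double gk = g[(size_t)k] / pendS;
          double acc = 0.0;
          for (int l = 0; l < D; ++l) {
            const double val = Pc[l] - g[(size_t)l] * gk;
            Pc[l] = val;
            acc += val * bphys[(size_t)l];
          }
          Pv[(size_t)k] = acc;
          zvar += bphys[(size_t)k] * acc;
        }
        for (int k = 0; k < D; ++k) {
          double* dk = &P[(size_t)k * D + k];
          if (*dk < 0.0) *dk = 0.0;
        }
        pending = false;
      } else {
        for (int k = 0; k < D; ++k) {
          double acc = 0.0;
          const double* Pc = &P[(size_t)k * D];
          for (int l = 0; l < D; ++l) acc += Pc[l] * bphys[(size_t)l];
          Pv[(size_t)k] = acc;
          zvar += bphys[(size_t)k] * acc;
        }
      }
      if (zvar < 0.0) zvar = 0.0;
      // second-order (Gaussian) moment closure of the Hill drift:
      // E[H(Z)] and the quadratic contribution to Var(H(Z)); the
      // first-order term H'(z)^2 Var(Z) is carried by the Jacobian
      const double h2 = hill_second(z, Rr, K, n);
      double hr = hill(z, Rr, K, n) + 0.5 * h2 * zvar;
      if (hr < 0.0) hr = 0.0;
      if (hr > Rr) hr = Rr;
      const double hp = hill_prime(z, Rr, K, n);
      const double qdrift = 0.5 * h2 * h2 * zvar * zvar * h * h;
      const double m0 = m[(size_t)base];
      double q = (hr + mu * (m0 > 0.0 ? m0 : 0.0)) * h + qdrift;
      if (q < 1e-12) q = 1e-12;

      // Jacobian row is b = (1 - mu h) e_base + h H' v, so
      // P b = (1 - mu h) P[, base] + h H' (P v): no second product needed
      const double a0 = 1.0 - mu * h;
      const double a1 = h * hp;
      const double* Pbase = &P[(size_t)base * D];
      for (int k = 0; k < D; ++k)
        Pb[(size_t)k] = a0 * Pbase[k] + a1 * Pv[(size_t)k];
      const double bPb = a0 * a0 * Pbase[base] +
                         2.0 * a0 * a1 * Pv[(size_t)base] +
                         a1 * a1 * zvar;

      // relabel: new current coordinate occupies the old oldest slot
      base = (base == 0) ? D - 1 : base - 1;
      double* col0 = &P[(size_t)base * D];
      for (int k = 0; k < D; ++k) {
        col0[k] = Pb[(size_t)k];
        P[(size_t)k * D + base] = Pb[(size_t)k];
      }
      P[(size_t)base * D + base] = bPb + q;
      m[(size_t)base] = m0 + (hr - mu * m0) * h;
    }

    // observation update: c touches logical coordinates 0..r
    double cm = 0.0;
    std::fill(g.begin(), g.end(), 0.0);
    for (int k = 0; k <= r; ++k) {
      int j = base + k; if (j >= D) j -= D;
      cm += cw[(size_t)k] * m[(size_t)j];
      const double* Pc = &P[(size_t)j * D];
      const double ck = cw[(size_t)k];
      for (int l = 0; l < D; ++l) g[(size_t)l] += ck * Pc[l];
    }
    double S = sig2;
    for (int k = 0; k <= r; ++k) {
      int j = base + k; if (j >= D) j -= D;
      S += cw[(size_t)k] * g[(size_t)j];
    }
    if (!(S > 0.0) || !R_finite(S)) return res;

    const double innov = y[t] - cm;
    ll += -0.5 * (std::log(2.0 * M_PI * S) + innov * innov / S);
    if (!R_finite(ll)) return res;

    const double gain = innov / S;
    for (int k = 0; k < D; ++k) m[(size_t)k] += g[(size_t)k] * gain;
    pending = true;           // P <- P - g g^T / S, applied lazily
    pendS = S;

    if (pred_mean) pred_mean[t] = cm;
    if (pred_sd) pred_sd[t] = std::sqrt(S);
    if (filt_mean) filt_mean[t] = m[(size_t)base];
  }
  res.loglik = ll;
  res.ok = true;
  return res;
}

// [[Rcpp::export]]
List cpp_filter(NumericVector y, double Rr, double K, double n, double mu,
                double kappa, double sigeta, double dmean, double dsd,
                double tau_max, double h, int r, double diffuse) {
  const int T = y.size();
  NumericVector pm(T), ps(T), fm(T);
  FilterOut res = filter_core(&y[0], T, Rr, K, n, mu, kappa, sigeta, dmean,
                              dsd, tau_max, h, r, diffuse, &pm[0], &ps[0],
                              &fm[0]);
  return List::create(_["loglik"] = res.loglik, _["ok"] = res.ok,
                      _["pred_mean"] = pm, _["pred_sd"] = ps,
                      _["filt_mean"] = fm);
}

// Per-location log-likelihoods for a lattice.  par has one row per location:
// (R, K, n, mu, dmean, dsd, kappa, sigeta).
// [[Rcpp::export]]
NumericVector cpp_filter_multi(NumericMatrix Y, NumericMatrix par,
                               double tau_max, double h, int r,
                               double diffuse) {
  const int L = Y.nrow();
  const int T = Y.ncol();
  NumericVector out(L);
  std::vector<double> yi((size_t)T);
  for (int i = 0; i < L; ++i) {
    for (int t = 0; t < T; ++t) yi[(size_t)t] = Y(i, t);
    FilterOut res = filter_core(yi.data(), T, par(i, 0), par(i, 1), par(i, 2),
                                par(i, 3), par(i, 6), par(i, 7), par(i, 4),
                                par(i, 5), tau_max, h, r, diffuse, nullptr,
                                nullptr, nullptr);
    out[i] = res.ok ? res.loglik : R_NegInf;
  }
  return out;
}
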
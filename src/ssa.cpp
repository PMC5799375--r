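// Exact stochastic simulation core (Gillespie direct method with
// dependency-graph propensity updates and block-sum reaction selection),
// plus an approximate tau-leaping integrator.
//
// Time-varying inputs (protocol events, ensemble synchronisation points)
// enter as changepoints: the pending unit-exponential quantum xi is
// decremented by a0*dt when a boundary is crossed and carried over, so the
// jump process is exact across propensity discontinuities and a no-op
// changepoint leaves the sample path bit-identical.
//
// RNG: PCG32 (O'Neill's permuted congruential generator), one independent
// stream per cell keyed by (seed, stream); the 128-bit generator state is
// passed in/out so a path can be advanced in chunks.

#include <Rcpp.h>
#include <cstring>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Pcg32 {
  uint64_t state, inc;
  void seed(uint64_t initstate, uint64_t initseq) {
    state = 0u; inc = (initseq << 1u) | 1u;
    next(); state += initstate; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double uniform() {  // in (0,1)
    return (next() + 0.5) * (1.0 / 4294967296.0);
  }
};

static void pack_rng(const Pcg32 &r, double *out) {
  std::memcpy(out, &r.state, 8);
  std::memcpy(out + 1, &r.inc, 8);
}
static void unpack_rng(Pcg32 &r, const double *in) {
  std::memcpy(&r.state, in, 8);
  std::memcpy(&r.inc, in + 1, 8);
}

// propensity of reaction j given state x
static inline double propensity(int j, const double *x,
                                const double *rate, const int *ri, int m,
                                const int *inhv, const double *alphav) {
  double a = rate[j];
  if (a == 0.0) return 0.0;
  for (int s = 0; s < 3; ++s) {
    int k = ri[j + s * m];
    if (k > 0) a *= x[k - 1];
  }
  int ih = inhv[j];
  if (ih > 0) a /= (1.0 + alphav[j] * x[ih - 1]);
  return a;
}

// [[Rcpp::export(name = ".ssa_core")]]
List ssa_core(NumericVector x0, NumericVector rate0,
              IntegerMatrix ri_m, IntegerVector inh, NumericVector alpha,
              IntegerVector st_reac, IntegerVector st_spec,
              IntegerVector st_delta,
              NumericVector cp_times, NumericMatrix cp_dx,
              NumericMatrix cp_rates,
              NumericVector grid, double t_start, double t_end,
              NumericVector rng_state, IntegerVector seed2, double xi_in,
              double max_events) {
  const int S = x0.size();
  const int m = rate0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> rate(rate0.begin(), rate0.end());
  const int *ri = ri_m.begin();
  const int *inhv = inh.begin();
  const double *alphav = alpha.begin();
  const int nst = st_reac.size();

  // stoichiometry: CSR by reaction (st_reac is sorted, 1-based)
  std::vector<int> roff(m + 1, 0);
  for (int k = 0; k < nst; ++k) roff[st_reac[k]]++;
  for (int j = 0; j < m; ++j) roff[j + 1] += roff[j];

  // dependency graph: species -> reactions using it; reaction -> dependents
  std::vector< std::vector<int> > sp2r(S);
  for (int j = 0; j < m; ++j) {
    for (int s = 0; s < 3; ++s) {
      int k = ri[j + s * m];
      if (k > 0) sp2r[k - 1].push_back(j);
    }
    if (inhv[j] > 0) sp2r[inhv[j] - 1].push_back(j);
  }
  std::vector< std::vector<int> > dep(m);
  {
    std::vector<int> mark(m, -1);
    for (int j = 0; j < m; ++j) {
      for (int k = roff[j]; k < roff[j + 1]; ++k) {
        int sidx = st_spec[k] - 1;
        for (size_t q = 0; q < sp2r[sidx].size(); ++q) {
          int r2 = sp2r[sidx][q];
          if (mark[r2] != j) { mark[r2] = j; dep[j].push_back(r2); }
        }
      }
    }
  }

  // propensities + block sums
  const int BL = 16;
  const int nb = (m + BL - 1) / BL;
  std::vector<double> a(m), bsum(nb, 0.0);
  double a0 = 0.0;
  auto refresh = [&]() {
    a0 = 0.0;
    std::fill(bsum.begin(), bsum.end(), 0.0);
    for (int j = 0; j < m; ++j) {
      a[j] = propensity(j, x.data(), rate.data(), ri, m, inhv, alphav);
      if (a[j] < 0 || !R_finite(a[j]))
        stop("invalid propensity in reaction %d", j + 1);
      bsum[j / BL] += a[j];
      a0 += a[j];
    }
  };
  refresh();

  Pcg32 rng;
  if (rng_state.size() == 2) unpack_rng(rng, rng_state.begin());
  else rng.seed((uint64_t)(uint32_t)seed2[0] * 2654435761ULL + 1442695040888963407ULL,
                (uint64_t)(uint32_t)seed2[1]);

  const int ng = grid.size();
  NumericMatrix out(ng, S);
  int gi = 0;
  // grid points at or before t_start take the initial state
  while (gi < ng && grid[gi] <= t_start) {
    for (int s = 0; s < S; ++s) out(gi, s) = x[s];
    ++gi;
  }

  double t = t_start;
  double xi = xi_in;
  if (xi < 0) xi = -std::log(rng.uniform());
  int cpi = 0;
  const int ncp = cp_times.size();
  while (cpi < ncp && cp_times[cpi] <= t_start) ++cpi; // earlier cps handled by caller
  double n_events = 0.0;
  double since_refresh = 0.0;

  auto record_until = [&](double tb) {
    while (gi < ng && grid[gi] <= tb) {
      for (int s = 0; s < S; ++s) out(gi, s) = x[s];
      ++gi;
    }
  };

  while (t < t_end) {
    double boundary = (cpi < ncp && cp_times[cpi] < t_end) ? cp_times[cpi]
                                                           : t_end;
    bool hit_boundary;
    double t_next;
    if (a0 <= 1e-300) {
      hit_boundary = true;
      t_next = boundary;
    } else {
      double tau = xi / a0;
      t_next = t + tau;
      hit_boundary = (t_next >= boundary);
      if (hit_boundary) t_next = boundary;
    }

    if (hit_boundary) {
      if (a0 > 1e-300) xi -= a0 * (t_next - t);
      record_until(t_next);  // state just before the boundary
      t = t_next;
      if (cpi < ncp && boundary == cp_times[cpi] && t < t_end) {
        for (int s = 0; s < S; ++s) {
          double d = cp_dx(s, cpi);
          if (d != 0.0) x[s] += std::floor(d + 0.5);
        }
        for (int j = 0; j < m; ++j) rate[j] = cp_rates(j, cpi);
        ++cpi;
        refresh();
      }
      continue;
    }

    // fire a reaction at t_next
    record_until(t_next);
    t = t_next;
    double u = rng.uniform() * a0;
    int b = 0;
    while (b < nb - 1 && u > bsum[b]) { u -= bsum[b]; ++b; }
    int j = b * BL;
    int jmax = std::min(m, (b + 1) * BL) - 1;
    while (j < jmax && u > a[j]) { u -= a[j]; ++j; }
    if (a[j] <= 0.0) {  // floating-point drift: fall back to full scan
      refresh();
      double u2 = rng.uniform() * a0;
      j = 0;
      while (j < m - 1 && (u2 > a[j] || a[j] <= 0.0)) {
        if (a[j] > 0.0) u2 -= a[j];
        ++j;
      }
      if (a[j] <= 0.0) continue;
    }
    // apply stoichiometry
    for (int k = roff[j]; k < roff[j + 1]; ++k) {
      int sidx = st_spec[k] - 1;
      x[sidx] += st_delta[k];
      if (x[sidx] < 0)
        stop("negative count for species %d after reaction %d",
             sidx + 1, j + 1);
    }
    // update dependent propensities
    for (size_t q = 0; q < dep[j].size(); ++q) {
      int r2 = dep[j][q];
      double anew = propensity(r2, x.data(), rate.data(), ri, m, inhv, alphav);
      if (anew < 0 || !R_finite(anew))
        stop("invalid propensity in reaction %d", r2 + 1);
      double dlt = anew - a[r2];
      a[r2] = anew;
      bsum[r2 / BL] += dlt;
      a0 += dlt;
    }
    xi = -std::log(rng.uniform());
    n_events += 1.0;
    since_refresh += 1.0;
    if (since_refresh >= 1048576.0) { refresh(); since_refresh = 0.0; }
    if (n_events >= max_events)
      stop("event budget exceeded (%.0f events before t = %g s)",
           max_events, t);
  }
  record_until(t_end);

  NumericVector rs(2);
  pack_rng(rng, rs.begin());
  return List::create(_["counts"] = out,
                      _["state"] = NumericVector(x.begin(), x.end()),
                      _["rng_state"] = rs,
                      _["xi"] = xi,
                      _["n_events"] = n_events);
}

// [[Rcpp::export(name = ".tau_core")]]
List tau_core(NumericVector x0, NumericVector rate0,
              IntegerMatrix ri_m, IntegerVector inh, NumericVector alpha,
              IntegerVector st_reac, IntegerVector st_spec,
              IntegerVector st_delta,
              NumericVector cp_times, NumericMatrix cp_dx,
              NumericMatrix cp_rates,
              NumericVector grid, double t_start, double t_end,
              IntegerVector seed2, double eps) {
  const int S = x0.size();
  const int m = rate0.size();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> rate(rate0.begin(), rate0.end());
  const int *ri = ri_m.begin();
  const int *inhv = inh.begin();
  const double *alphav = alpha.begin();
  const int nst = st_reac.size();
  std::vector<int> roff(m + 1, 0);
  for (int k = 0; k < nst; ++k) roff[st_reac[k]]++;
  for (int j = 0; j < m; ++j) roff[j + 1] += roff[j];

  Pcg32 rng;
  rng.seed((uint64_t)(uint32_t)seed2[0] * 2654435761ULL + 1442695040888963407ULL,
           (uint64_t)(uint32_t)seed2[1]);
  // Poisson sampler (Knuth for small mean, normal approximation for large)
  auto rpois_local = [&](double lambda) -> double {
    if (lambda <= 0) return 0.0;
    if (lambda < 30.0) {
      double L = std::exp(-lambda), p = 1.0;
      int k = 0;
      do { ++k; p *= rng.uniform(); } while (p > L);
      return k - 1;
    }
    double u1 = rng.uniform(), u2 = rng.uniform();
    double z = std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
    double v = std::floor(lambda + std::sqrt(lambda) * z + 0.5);
    return v < 0 ? 0.0 : v;
  };

  std::vector<double> a(m), mu(S), sig2(S), xtry(S);
  const int ng = grid.size();
  NumericMatrix out(ng, S);
  int gi = 0;
  while (gi < ng && grid[gi] <= t_start) {
    for (int s = 0; s < S; ++s) out(gi, s) = x[s];
    ++gi;
  }
  double t = t_start;
  int cpi = 0;
  const int ncp = cp_times.size();
  while (cpi < ncp && cp_times[cpi] <= t_start) ++cpi;
  double n_steps = 0.0;

  auto record_until = [&](double tb) {
    while (gi < ng && grid[gi] <= tb) {
      for (int s = 0; s < S; ++s) out(gi, s) = x[s];
      ++gi;
    }
  };

  while (t < t_end) {
    double boundary = (cpi < ncp && cp_times[cpi] < t_end) ? cp_times[cpi]
                                                           : t_end;
    double a0 = 0.0;
    for (int j = 0; j < m; ++j) {
      a[j] = propensity(j, x.data(), rate.data(), ri, m, inhv, alphav);
      if (a[j] < 0 || !R_finite(a[j]))
        stop("invalid propensity in reaction %d", j + 1);
      a0 += a[j];
    }
    if (a0 <= 1e-300) {
      record_until(boundary);
      t = boundary;
    } else {
      std::fill(mu.begin(), mu.end(), 0.0);
      std::fill(sig2.begin(), sig2.end(), 0.0);
      for (int j = 0; j < m; ++j) {
        if (a[j] == 0) continue;
        for (int k = roff[j]; k < roff[j + 1]; ++k) {
          int sidx = st_spec[k] - 1;
          mu[sidx] += st_delta[k] * a[j];
          sig2[sidx] += (double)st_delta[k] * st_delta[k] * a[j];
        }
      }
      double tau = boundary - t;
      for (int s = 0; s < S; ++s) {
        if (sig2[s] == 0) continue;
        double bnd = eps * x[s]; if (bnd < 1.0) bnd = 1.0;
        if (mu[s] != 0) tau = std::min(tau, bnd / std::fabs(mu[s]));
        tau = std::min(tau, bnd * bnd / sig2[s]);
      }
      bool ok = false;
      while (!ok) {
        if (tau * a0 < 1.0) tau = 1.0 / a0;  // degenerate: near-exact stepping
        if (t + tau > boundary) tau = boundary - t;
        std::copy(x.begin(), x.end(), xtry.begin());
        ok = true;
        for (int j = 0; j < m && ok; ++j) {
          if (a[j] == 0) continue;
          double k = rpois_local(a[j] * tau);
          if (k == 0) continue;
          for (int q = roff[j]; q < roff[j + 1]; ++q) {
            int sidx = st_spec[q] - 1;
            xtry[sidx] += st_delta[q] * k;
            if (xtry[sidx] < 0) { ok = false; break; }
          }
        }
        if (!ok) tau *= 0.5;  // redo the leap with a smaller step
      }
      record_until(t + tau);
      std::copy(xtry.begin(), xtry.end(), x.begin());
      t += tau;
      n_steps += 1.0;
    }
    if (cpi < ncp && t >= cp_times[cpi] && t < t_end) {
      for (int s = 0; s < S; ++s) {
        double d = cp_dx(s, cpi);
        if (d != 0.0) x[s] += std::floor(d + 0.5);
      }
      for (int j = 0; j < m; ++j) rate[j] = cp_rates(j, cpi);
      ++cpi;
    }
  }
  record_until(t_end);
  return List::create(_["counts"] = out,
                      _["state"] = NumericVector(x.begin(), x.end()),
                      _["n_events"] = n_steps);
}
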
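#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Adaptive Cash-Karp RK4(5) for small fixed-dimension ODE systems.
// Used by the BiSSE branch integrator; dimension 4 (E0, E1, D0, D1).
// ---------------------------------------------------------------------------

struct BisseP {
  double la0, la1, mu0, mu1, q01, q10;
};

static inline void bisse_deriv(const double *y, double *dy, const BisseP &p) {
  const double E0 = y[0], E1 = y[1], D0 = y[2], D1 = y[3];
  dy[0] = p.mu0 - (p.la0 + p.mu0 + p.q01) * E0 + p.q01 * E1 + p.la0 * E0 * E0;
  dy[1] = p.mu1 - (p.la1 + p.mu1 + p.q10) * E1 + p.q10 * E0 + p.la1 * E1 * E1;
  dy[2] = -(p.la0 + p.mu0 + p.q01) * D0 + p.q01 * D1 + 2.0 * p.la0 * E0 * D0;
  dy[3] = -(p.la1 + p.mu1 + p.q10) * D1 + p.q10 * D0 + 2.0 * p.la1 * E1 * D1;
}

// Cash-Karp tableau
static const double CK_B[6][5] = {
  {0, 0, 0, 0, 0},
  {1.0 / 5, 0, 0, 0, 0},
  {3.0 / 40, 9.0 / 40, 0, 0, 0},
  {3.0 / 10, -9.0 / 10, 6.0 / 5, 0, 0},
  {-11.0 / 54, 5.0 / 2, -70.0 / 27, 35.0 / 27, 0},
  {1631.0 / 55296, 175.0 / 512, 575.0 / 13824, 44275.0 / 110592, 253.0 / 4096}};
static const double CK_C5[6] = {37.0 / 378, 0, 250.0 / 621, 125.0 / 594, 0, 512.0 / 1771};
static const double CK_C4[6] = {2825.0 / 27648, 0, 18575.0 / 48384, 13525.0 / 55296,
                                277.0 / 14336, 1.0 / 4};

// integrate the 4-dim BiSSE system over [0, len]; y updated in place.
// returns false on failure (step underflow).
static bool bisse_integrate(double *y, double len, const BisseP &p,
                            double rtol, double atol) {
  if (len <= 0) return true;
  double t = 0.0;
  double h = len / 10.0;
  const double hmin = len * 1e-12;
  double k[6][4], ytmp[4], y5[4], y4[4];
  int iter = 0;
  while (t < len) {
    if (++iter > 1000000) return false;
    if (h > len - t) h = len - t;
    for (int s = 0; s < 6; ++s) {
      for (int i = 0; i < 4; ++i) {
        double acc = y[i];
        for (int j = 0; j < s; ++j) acc += h * CK_B[s][j] * k[j][i];
        ytmp[i] = acc;
      }
      bisse_deriv(ytmp, k[s], p);
    }
    double errmax = 0.0;
    for (int i = 0; i < 4; ++i) {
      double d5 = 0.0, d4 = 0.0;
      for (int s = 0; s < 6; ++s) {
        d5 += CK_C5[s] * k[s][i];
        d4 += CK_C4[s] * k[s][i];
      }
      y5[i] = y[i] + h * d5;
      y4[i] = y[i] + h * d4;
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double e = std::fabs(y5[i] - y4[i]) / sc;
      if (e > errmax) errmax = e;
    }
    if (errmax <= 1.0) {
      t += h;
      for (int i = 0; i < 4; ++i) y[i] = y5[i];
      // E are probabilities
      for (int i = 0; i < 2; ++i) {
        if (y[i] < 0.0) y[i] = 0.0;
        if (y[i] > 1.0) y[i] = 1.0;
      }
      double fac = 0.9 * std::pow(std::max(errmax, 1e-10), -0.2);
      h *= std::min(5.0, fac);
    } else {
      h *= std::max(0.1, 0.9 * std::pow(errmax, -0.25));
      if (h < hmin) return false;
    }
  }
  return true;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_bisse_loglik")]]
double cpp_bisse_loglik(IntegerMatrix edge, NumericVector edge_length,
                        int n_tip, IntegerVector tip_state,
                        NumericVector pars, double f0, double f1,
                        int root_type, bool condition,
                        double rtol, double atol) {
  // edge must be in ape "postorder" order; node indices are ape-style:
  // tips 1..n_tip, root n_tip+1.
  BisseP p{pars[0], pars[1], pars[2], pars[3], pars[4], pars[5]};
  int n_node = n_tip + n_tip - 1;
  std::vector<double> E0(n_node + 1), E1(n_node + 1), D0(n_node + 1),
      D1(n_node + 1);
  std::vector<int> nseen(n_node + 1, 0);
  double loglik = 0.0;
  int root = n_tip + 1;

  // initialise tips
  for (int i = 1; i <= n_tip; ++i) {
    E0[i] = 1.0 - f0;
    E1[i] = 1.0 - f1;
    int st = tip_state[i - 1];
    D0[i] = (st == 0) ? f0 : 0.0;
    D1[i] = (st == 1) ? f1 : 0.0;
  }

  int n_edge = edge.nrow();
  for (int e = 0; e < n_edge; ++e) {
    int par = edge(e, 0), ch = edge(e, 1);
    double y[4] = {E0[ch], E1[ch], D0[ch], D1[ch]};
    if (!bisse_integrate(y, edge_length[e], p, rtol, atol))
      stop("BiSSE branch integration failed on edge %d", e + 1);
    // rescale D to avoid underflow
    double sc = std::fabs(y[2]) + std::fabs(y[3]);
    if (sc > 0 && R_finite(sc)) {
      y[2] /= sc;
      y[3] /= sc;
      loglik += std::log(sc);
    } else {
      return R_NegInf;
    }
    if (nseen[par] == 0) {
      E0[par] = y[0]; E1[par] = y[1]; D0[par] = y[2]; D1[par] = y[3];
    } else {
      // combine at node: D_i <- la_i * D_left * D_right (no la at crown root)
      double m0 = (par == root) ? 1.0 : p.la0;
      double m1 = (par == root) ? 1.0 : p.la1;
      D0[par] = m0 * D0[par] * y[2];
      D1[par] = m1 * D1[par] * y[3];
      E0[par] = 0.5 * (E0[par] + y[0]);
      E1[par] = 0.5 * (E1[par] + y[1]);
    }
    nseen[par] += 1;
  }

  double d0 = D0[root], d1 = D1[root];
  if (condition) {
    double c0 = (1.0 - E0[root]) * (1.0 - E0[root]);
    double c1 = (1.0 - E1[root]) * (1.0 - E1[root]);
    if (c0 <= 0 || c1 <= 0) return R_NegInf;
    d0 /= c0;
    d1 /= c1;
  }
  double L;
  if (root_type == 0) {           // FitzJohn weighting
    double s = d0 + d1;
    if (s <= 0) return R_NegInf;
    L = (d0 * d0 + d1 * d1) / s;
  } else if (root_type == 1) {    // equal weights
    L = 0.5 * (d0 + d1);
  } else {                        // plain sum
    L = d0 + d1;
  }
  if (L <= 0 || !R_finite(L)) return R_NegInf;
  return loglik + std::log(L);
}

// ---------------------------------------------------------------------------
// Mk pruning likelihood for a k-state continuous-time Markov chain on the
// tree (k small: 2 for single binary traits, 4 for the joint Pagel chain).
// Branch transition matrices by scaling-and-squaring matrix exponential.
// ---------------------------------------------------------------------------

static void mat_mult(const std::vector<double> &A, const std::vector<double> &B,
                     std::vector<double> &C, int k) {
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) {
      double s = 0.0;
      for (int l = 0; l < k; ++l) s += A[i * k + l] * B[l * k + j];
      C[i * k + j] = s;
    }
}

static void mat_expm(std::vector<double> A, std::vector<double> &E, int k) {
  // scale so that max |a_ij| * 2^-s < 0.25, Taylor to order 14, square back
  double amax = 0.0;
  for (int i = 0; i < k * k; ++i) amax = std::max(amax, std::fabs(A[i]));
  int s = 0;
  while (amax > 0.25 && s < 60) {
    amax *= 0.5;
    ++s;
  }
  double scale = std::pow(2.0, -s);
  for (int i = 0; i < k * k; ++i) A[i] *= scale;
  std::vector<double> term(k * k), tmp(k * k);
  // E = I + A + A^2/2! + ...
  for (int i = 0; i < k * k; ++i) {
    E[i] = (i % (k + 1) == 0) ? 1.0 : 0.0;
    term[i] = E[i];
  }
  for (int n = 1; n <= 14; ++n) {
    mat_mult(term, A, tmp, k);
    for (int i = 0; i < k * k; ++i) {
      term[i] = tmp[i] / n;
      E[i] += term[i];
    }
  }
  for (int j = 0; j < s; ++j) {
    mat_mult(E, E, tmp, k);
    E.swap(tmp);
  }
}

//' @noRd
// [[Rcpp::export(name = ".cpp_mk_loglik")]]
double cpp_mk_loglik(IntegerMatrix edge, NumericVector edge_length, int n_tip,
                     IntegerVector tip_state, NumericMatrix Q, int root_type) {
  // tip_state: 1..k, or 0 for ambiguous. root_type: 0 equal, 1 sum,
  // 2 FitzJohn-style observed weighting.
  int k = Q.nrow();
  int n_node = 2 * n_tip - 1;
  std::vector<double> L((n_node + 1) * k, 0.0);
  std::vector<int> nseen(n_node + 1, 0);
  std::vector<double> Qv(k * k), P(k * k), vin(k), vout(k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) Qv[i * k + j] = Q(i, j);
  double loglik = 0.0;
  int root = n_tip + 1;
  for (int i = 1; i <= n_tip; ++i) {
    int st = tip_state[i - 1];
    for (int j = 0; j < k; ++j)
      L[i * k + j] = (st == 0 || st == j + 1) ? 1.0 : 0.0;
  }
  int n_edge = edge.nrow();
  std::vector<double> A(k * k);
  for (int e = 0; e < n_edge; ++e) {
    int par = edge(e, 0), ch = edge(e, 1);
    for (int i = 0; i < k * k; ++i) A[i] = Qv[i] * edge_length[e];
    mat_expm(A, P, k);
    for (int i = 0; i < k; ++i) vin[i] = L[ch * k + i];
    double sc = 0.0;
    for (int i = 0; i < k; ++i) {
      double s = 0.0;
      for (int j = 0; j < k; ++j) s += P[i * k + j] * vin[j];
      vout[i] = s;
      sc += s;
    }
    if (sc <= 0 || !R_finite(sc)) return R_NegInf;
    loglik += std::log(sc);
    for (int i = 0; i < k; ++i) vout[i] /= sc;
    if (nseen[par] == 0) {
      for (int i = 0; i < k; ++i) L[par * k + i] = vout[i];
    } else {
      for (int i = 0; i < k; ++i) L[par * k + i] *= vout[i];
    }
    nseen[par] += 1;
  }
  double Ltot = 0.0, s = 0.0;
  for (int i = 0; i < k; ++i) s += L[root * k + i];
  if (root_type == 0) {
    Ltot = s / k;
  } else if (root_type == 1) {
    Ltot = s;
  } else {
    if (s <= 0) return R_NegInf;
    for (int i = 0; i < k; ++i) Ltot += L[root * k + i] * L[root * k + i] / s;
  }
  if (Ltot <= 0 || !R_finite(Ltot)) return R_NegInf;
  return loglik + std::log(Ltot);
}

// ---------------------------------------------------------------------------
// Diversity-dependent hidden-lineage master equation.
//
// State: probability vector over m = 0..M hidden (unobserved) lineages while
// k observed lineages are present; total standing diversity N = k + m.
// Linear diversity dependence: la(N) = max(0, la0 - (la0 - mu) * N / K).
// Between observed branching times, forward in time:
//   dQ_m/dt = (k+m-1) la(k+m-1) Q_{m-1} + (m+1) mu Q_{m+1}
//             - [ (k+m) la(k+m) + (m+k) mu ] Q_m
// (loss includes k*mu: an observed lineage going extinct leaves the set of
// valid reconstructed histories).
// ---------------------------------------------------------------------------

static inline double dd_rate(double n, double la0, double mu, double K) {
  double la = la0 - (la0 - mu) * n / K;
  return la > 0 ? la : 0.0;
}

static void dd_deriv(const std::vector<double> &q, std::vector<double> &dq,
                     int k, int M, double la0, double mu, double K) {
  // Non-conservative system: the birth inflow carries (2k + m - 1) -- a
  // hidden daughter born to an observed lineage counts both daughter
  // orderings -- while the loss keeps the plain total event rate. This is
  // what makes the k-lineage solution reduce to the Nee likelihood factors
  // when K -> infinity.
  for (int m = 0; m <= M; ++m) {
    double N = k + m;
    double out = N * dd_rate(N, la0, mu, K) + N * mu;
    double v = -out * q[m];
    if (m > 0) v += (2 * k + m - 1) * dd_rate(N - 1, la0, mu, K) * q[m - 1];
    if (m < M) v += (m + 1) * mu * q[m + 1];
    dq[m] = v;
  }
}

//' @noRd
// [[Rcpp::export(name = ".cpp_dd_evolve")]]
NumericVector cpp_dd_evolve(NumericVector q0, int k, double dt, double la0,
                            double mu, double K) {
  // RK4 with step size bounded by the fastest total event rate
  int M = q0.size() - 1;
  std::vector<double> q(q0.begin(), q0.end());
  double rmax = (k + M) * (la0 + mu) + 1.0;
  int nstep = (int)std::ceil(dt * rmax * 8.0);  // h * ratemax <= 0.125
  if (nstep < 4) nstep = 4;
  double h = dt / nstep;
  std::vector<double> k1(M + 1), k2(M + 1), k3(M + 1), k4(M + 1), tmp(M + 1);
  for (int s = 0; s < nstep; ++s) {
    dd_deriv(q, k1, k, M, la0, mu, K);
    for (int i = 0; i <= M; ++i) tmp[i] = q[i] + 0.5 * h * k1[i];
    dd_deriv(tmp, k2, k, M, la0, mu, K);
    for (int i = 0; i <= M; ++i) tmp[i] = q[i] + 0.5 * h * k2[i];
    dd_deriv(tmp, k3, k, M, la0, mu, K);
    for (int i = 0; i <= M; ++i) tmp[i] = q[i] + h * k3[i];
    dd_deriv(tmp, k4, k, M, la0, mu, K);
    for (int i = 0; i <= M; ++i)
      q[i] += h / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
  }
  return NumericVector(q.begin(), q.end());
}

//' @noRd
// [[Rcpp::export(name = ".cpp_dd_survival")]]
double cpp_dd_survival(double t, double la0, double mu, double K, int M) {
  // probability that a single lineage (diversity-dependent rates driven by
  // its own descendant count) has >= 1 descendant after time t
  if (mu <= 0) return 1.0;
  std::vector<double> p(M + 1, 0.0);
  p[1] = 1.0;
  double rmax = M * (la0 + mu) + 1.0;
  int nstep = (int)std::ceil(t * rmax * 8.0);
  if (nstep < 4) nstep = 4;
  double h = t / nstep;
  std::vector<double> k1(M + 1), k2(M + 1), k3(M + 1), k4(M + 1), tmp(M + 1);
  auto deriv = [&](const std::vector<double> &q, std::vector<double> &dq) {
    for (int n = 0; n <= M; ++n) {
      double out = n * (dd_rate(n, la0, mu, K) + mu);
      double v = -out * q[n];
      if (n > 0) v += (n - 1) * dd_rate(n - 1, la0, mu, K) * q[n - 1];
      if (n < M) v += (n + 1) * mu * q[n + 1];
      dq[n] = v;
    }
  };
  for (int s = 0; s < nstep; ++s) {
    deriv(p, k1);
    for (int i = 0; i <= M; ++i) tmp[i] = p[i] + 0.5 * h * k1[i];
    deriv(tmp, k2);
    for (int i = 0; i <= M; ++i) tmp[i] = p[i] + 0.5 * h * k2[i];
    deriv(tmp, k3);
    for (int i = 0; i <= M; ++i) tmp[i] = p[i] + h * k3[i];
    deriv(tmp, k4);
    for (int i = 0; i <= M; ++i)
      p[i] += h / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
  }
  return 1.0 - p[0];
}
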
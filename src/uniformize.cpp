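#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Action of the matrix exponential, w = exp(A*t) v, for a tridiagonal
// generator A via uniformization.  A is specified by its diagonal dg
// (dg[i] = A[i][i], all <= 0), the gain terms up[i] = A[i][i+1] (flow into
// state i from state i+1) and dn[i] = A[i+1][i] (flow into state i+1 from
// state i).  Column sums must be <= 0 (substochastic): mass may leak (e.g.
// extinction of an observed lineage kills the realization) but never grow.
//
// Uniformization: with L >= max(-dg), B = I + A/L has nonnegative entries
// and w = e^{-Lt} sum_j (Lt)^j/j! B^j v.  The time interval is chunked so
// that L*dt <= 500 per chunk, keeping e^{-L*dt} well inside double range.
static void expm_uniform(double t, const std::vector<double>& dg,
                         const std::vector<double>& up,
                         const std::vector<double>& dn,
                         std::vector<double>& cur, double tol = 1e-14) {
  int n = (int)dg.size();
  double L = 0.0;
  for (int i = 0; i < n; ++i) if (-dg[i] > L) L = -dg[i];
  if (L * t <= 0.0) return;

  int m = (int)std::ceil(L * t / 500.0);
  if (m < 1) m = 1;
  double dt = t / m, a = L * dt;
  std::vector<double> w(n), res(n), tmp(n);

  for (int chunk = 0; chunk < m; ++chunk) {
    double pw = std::exp(-a), cum = pw;
    for (int i = 0; i < n; ++i) { w[i] = cur[i]; res[i] = pw * cur[i]; }
    int jmax = (int)(a + 12.0 * std::sqrt(a + 1.0) + 30.0);
    for (int j = 1; j <= jmax; ++j) {
      // tmp = B w with B = I + A/L
      for (int i = 0; i < n; ++i) {
        double acc = w[i] + dg[i] * w[i] / L;
        if (i > 0) acc += dn[i - 1] * w[i - 1] / L;
        if (i < n - 1) acc += up[i] * w[i + 1] / L;
        tmp[i] = acc;
      }
      pw *= a / j;
      cum += pw;
      for (int i = 0; i < n; ++i) { w[i] = tmp[i]; res[i] += pw * w[i]; }
      if (cum > 1.0 - tol && j > (int)a) break;
    }
    cur = res;
  }
}

// [[Rcpp::export]]
NumericVector expm_tridiag_cpp(double t, NumericVector dg, NumericVector up,
                               NumericVector dn, NumericVector v,
                               double tol = 1e-14) {
  int n = dg.size();
  if (up.size() != n - 1 || dn.size() != n - 1 || v.size() != n)
    stop("inconsistent vector lengths in expm_tridiag_cpp");
  std::vector<double> dgv(dg.begin(), dg.end()), upv(up.begin(), up.end());
  std::vector<double> dnv(dn.begin(), dn.end()), cur(v.begin(), v.end());
  expm_uniform(t, dgv, upv, dnv, cur, tol);
  return NumericVector(cur.begin(), cur.end());
}

// Full hidden-state likelihood recursion over all inter-node intervals of a
// reconstructed tree: `times` are the branching times (crown at 0, sorted
// ascending, length n_tips - 1), T the crown age.  Between nodes, with k
// observed branches, the probability vector Q over the hidden-species count
// n (total diversity n + k, capped at `cap`) evolves under the tridiagonal
// generator with gain (n-1+2k)*lambda(n-1+k) from below (the 2k carries the
// two ways an eventually-extinct side branch of an observed lineage can be
// oriented), gain mu*(n+1) from above, and loss (n+k)*(lambda(n+k)+mu); at
// each node Q_n is multiplied by k*lambda(n+k).  Q is renormalized after
// every step with the log accumulated.  Returns log Q_0 at the present and
// the largest renormalized mass seen in the top three states (the
// truncation-quality diagnostic; exactly 0 mass leaks when cap closes the
// state space at floor(kprime)+1).
// [[Rcpp::export]]
List dd_pass_cpp(NumericVector times, double T, double lam0, double mu,
                 double kp, int cap) {
  int N = times.size() + 1;  // tip count
  std::vector<double> tp(times.begin(), times.end());
  tp.push_back(T);
  int k = 2, nm = cap - k;
  if (nm < 0) nm = 0;
  std::vector<double> Q(nm + 1, 0.0);
  Q[0] = 1.0;
  double logS = 0.0, top_mass = 0.0;
  std::vector<double> lamv, dg, up, dn;
  for (int j = 1; j <= N - 1; ++j) {
    k = j + 1;
    double dt = tp[j] - tp[j - 1];
    nm = (int)Q.size() - 1;
    lamv.resize(nm + 1); dg.resize(nm + 1); up.resize(nm); dn.resize(nm);
    for (int n = 0; n <= nm; ++n) {
      double l = R_FINITE(kp) ? lam0 * (1.0 - (n + k) / kp) : lam0;
      lamv[n] = l > 0.0 ? l : 0.0;
      dg[n] = -(n + k) * (lamv[n] + mu);
    }
    for (int n = 0; n < nm; ++n) {
      dn[n] = (n + 2.0 * k) * lamv[n];
      up[n] = mu * (n + 1);
    }
    expm_uniform(dt, dg, up, dn, Q);
    double s = 0.0;
    for (int n = 0; n <= nm; ++n) s += Q[n];
    if (!(s > 0.0))
      return List::create(_["loglik"] = R_NegInf, _["top_mass"] = top_mass);
    if (nm >= 3) {
      double t3 = (Q[nm - 2] + Q[nm - 1] + Q[nm]) / s;
      if (t3 > top_mass) top_mass = t3;
    }
    for (int n = 0; n <= nm; ++n) Q[n] /= s;
    logS += std::log(s);
    if (j < N - 1) {  // node: k -> k + 1
      for (int n = 0; n <= nm; ++n) Q[n] *= k * lamv[n];
      s = 0.0;
      for (int n = 0; n <= nm; ++n) s += Q[n];
      if (!(s > 0.0))
        return List::create(_["loglik"] = R_NegInf, _["top_mass"] = top_mass);
      for (int n = 0; n <= nm; ++n) Q[n] /= s;
      logS += std::log(s);
      if (Q.size() > 1) Q.pop_back();  // hidden cap shrinks with k
    }
  }
  if (!(Q[0] > 0.0))
    return List::create(_["loglik"] = R_NegInf, _["top_mass"] = top_mass);
  return List::create(_["loglik"] = std::log(Q[0]) + logS,
                      _["top_mass"] = top_mass);
}

// Probability that BOTH crown lineages still have living descendants at time
// T, under a single-community diversity-dependent birth-death process started
// from the two crown species.  State (m1, m2) = descendant counts of the two
// crown lineages; per-lineage speciation rate lambda(N) = max(0,
// lam0*(1 - N/kprime)) with N = m1 + m2, per-lineage extinction mu.  A crown
// lineage whose count hits 0 can never recover, so "both survive at T" is
// equivalent to neither count ever reaching 0; states with m1 = 0 or m2 = 0
// are lumped into one absorbing failure state.  Births that would push N
// beyond nmax are routed to an absorbing "escaped" state and counted as
// surviving; the returned top_mass (mass in the top two N-bands plus escaped
// mass) bounds the truncation error of that choice.
// [[Rcpp::export]]
List pair_survival_cpp(double lam0, double mu, double kprime, double T,
                       int nmax) {
  if (nmax < 2) stop("nmax must be >= 2");
  // index states (m1, m2), m1 >= 1, m2 >= 1, m1 + m2 <= nmax
  std::vector<int> off(nmax + 1, -1);
  int ns = 0;
  for (int m1 = 1; m1 <= nmax - 1; ++m1) { off[m1] = ns; ns += nmax - m1; }
  // state (m1, m2) -> off[m1] + (m2 - 1)
  std::vector<double> lamN(nmax + 2, 0.0);
  for (int N = 0; N <= nmax + 1; ++N) {
    double l = lam0 * (1.0 - N / kprime);
    lamN[N] = l > 0.0 ? l : 0.0;
  }
  double L = 0.0;
  for (int N = 2; N <= nmax; ++N) {
    double r = N * (lamN[N] + mu);
    if (r > L) L = r;
  }
  if (L <= 0.0)
    return List::create(_["p_survive"] = 1.0, _["top_mass"] = 0.0);

  // Gather form of B = I + A/L: per state, the stay coefficient and the
  // four possible inflows (birth of either crown clade from below, death of
  // either from above), precomputed so the hot loop is branch-free.  Source
  // index ns is a zero sentinel for absent inflows.
  std::vector<double> stay(ns), r1(ns), r2(ns), r3(ns), r4(ns);
  std::vector<int> s1(ns), s2(ns), s3(ns), s4(ns);
  // rate at which mass enters the absorbing fail / escape states from s
  std::vector<double> failr(ns, 0.0), escr(ns, 0.0);
  for (int m1 = 1; m1 <= nmax - 1; ++m1)
    for (int m2 = 1; m2 <= nmax - m1; ++m2) {
      int i = off[m1] + m2 - 1, N = m1 + m2;
      stay[i] = 1.0 - N * (lamN[N] + mu) / L;
      // birth in clade 1: (m1-1, m2) -> (m1, m2), rate (m1-1)*lambda(N-1)
      if (m1 > 1) { s1[i] = off[m1 - 1] + m2 - 1; r1[i] = (m1 - 1) * lamN[N - 1] / L; }
      else { s1[i] = ns; r1[i] = 0.0; }
      if (m2 > 1) { s2[i] = off[m1] + m2 - 2; r2[i] = (m2 - 1) * lamN[N - 1] / L; }
      else { s2[i] = ns; r2[i] = 0.0; }
      // death in clade 1: (m1+1, m2) -> (m1, m2), rate (m1+1)*mu
      if (N + 1 <= nmax) { s3[i] = off[m1 + 1] + m2 - 1; r3[i] = (m1 + 1) * mu / L; }
      else { s3[i] = ns; r3[i] = 0.0; }
      if (N + 1 <= nmax) { s4[i] = off[m1] + m2; r4[i] = (m2 + 1) * mu / L; }
      else { s4[i] = ns; r4[i] = 0.0; }
      if (m1 == 1) failr[i] += mu / L;            // clade 1 dies out
      if (m2 == 1) failr[i] += mu / L;            // clade 2 dies out
      if (N == nmax) escr[i] = N * lamN[N] / L;   // birth past the cap
    }

  std::vector<double> p(ns + 1, 0.0), w(ns + 1, 0.0), res(ns), tmp(ns + 1, 0.0);
  p[off[1] + 0] = 1.0;  // (1, 1)
  double fail = 0.0, escape = 0.0;

  int m = (int)std::ceil(L * T / 500.0);
  if (m < 1) m = 1;
  double dt = T / m, a = L * dt;
  int jmax = (int)(a + 12.0 * std::sqrt(a + 1.0) + 30.0);

  for (int chunk = 0; chunk < m; ++chunk) {
    double pw = std::exp(-a), cum = pw;
    double lpw = 0.0;  // log-scale fallback when exp(-a) underflows
    bool logmode = false;
    if (pw == 0.0) { logmode = true; lpw = -a; }
    double fw = fail, ew = escape;           // absorbing-state working copies
    double fres = pw * fail, eres = pw * escape;
    for (int i = 0; i < ns; ++i) { w[i] = p[i]; res[i] = pw * p[i]; }
    w[ns] = 0.0;
    for (int j = 1; j <= jmax; ++j) {
      double fnew = fw, enew = ew;
      for (int i = 0; i < ns; ++i) {
        tmp[i] = stay[i] * w[i] + r1[i] * w[s1[i]] + r2[i] * w[s2[i]]
               + r3[i] * w[s3[i]] + r4[i] * w[s4[i]];
        fnew += failr[i] * w[i];
        enew += escr[i] * w[i];
      }
      if (logmode) {
        lpw += std::log(a / j);
        pw = std::exp(lpw);
      } else {
        pw *= a / j;
      }
      cum += pw;
      fw = fnew; ew = enew;
      fres += pw * fw; eres += pw * ew;
      for (int i = 0; i < ns; ++i) { w[i] = tmp[i]; res[i] += pw * w[i]; }
      if (cum > 1.0 - 1e-14 && j > (int)a) break;
    }
    for (int i = 0; i < ns; ++i) p[i] = res[i];
    fail = fres; escape = eres;
  }

  double top = escape;
  for (int m1 = 1; m1 <= nmax - 1; ++m1)
    for (int m2 = 1; m2 <= nmax - m1; ++m2)
      if (m1 + m2 >= nmax - 1) top += p[off[m1] + m2 - 1];
  return List::create(_["p_survive"] = 1.0 - fail, _["top_mass"] = top);
}
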
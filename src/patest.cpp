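#include <Rcpp.h>
using namespace Rcpp;

// Unconditional degree pmf by the triangular spectral recursion.
//
// Laplace-transforming the phase/degree master equation at frequency 0
// gives, for A[a][k] = integral of p_{a,k}(t) over all time,
//   (f_k + M_a) A[a][k] = nu_a [k = 0] + f_{k-1} A[a][k-1]
//                         + sum_{b<a} Q[b][a] A[b][k],
// with f_k = 1 + tau k and M_a the total exit rate of phase a. Because Q
// is strictly upper triangular the system solves forward in (k, a) with no
// matrix inversion; d_k = sum_a mu_a A[a][k]. Cost O(m^2 kmax), O(m)
// working memory.
// [[Rcpp::export]]
NumericVector cpp_degree_pmf(NumericVector nu, NumericVector mu,
                             NumericMatrix Q, double tau, int kmax) {
  int m = nu.size();
  std::vector<double> M(m);
  for (int a = 0; a < m; ++a) {
    double s = mu[a];
    for (int b = a + 1; b < m; ++b) s += Q(a, b);
    M[a] = s;
  }
  NumericVector d(kmax + 1);
  std::vector<double> Aprev(m, 0.0), Acur(m, 0.0);
  for (int k = 0; k <= kmax; ++k) {
    double fk = 1.0 + tau * k;
    double fkm1 = 1.0 + tau * (k - 1);
    for (int a = 0; a < m; ++a) {
      double num = (k == 0) ? nu[a] : fkm1 * Aprev[a];
      for (int b = 0; b < a; ++b) num += Q(b, a) * Acur[b];
      Acur[a] = num / (fk + M[a]);
    }
    double dk = 0.0;
    for (int a = 0; a < m; ++a) dk += mu[a] * Acur[a];
    d[k] = dk;
    std::swap(Aprev, Acur);
  }
  return d;
}

// Negative zero-truncated multinomial log-likelihood in the unconstrained
// parameterisation used by the optimiser: log tau (if pa), log mu, log of
// the row-major strictly-upper-triangular Q entries, then m-1 softmax
// logits for nu (first logit pinned at 0). Returns a large sentinel
// instead of raising when the trial parameters make an observed degree
// impossible, so annealing can move away.
// [[Rcpp::export]]
double cpp_negloglik(NumericVector par, int m, bool pa,
                     IntegerVector kdeg, NumericVector ycnt, int kmax) {
  const double SENTINEL = 1e12;
  int idx = 0;
  double tau = 0.0;
  if (pa) tau = std::exp(par[idx++]);
  NumericVector mu(m), nu(m);
  NumericMatrix Q(m, m);
  for (int a = 0; a < m; ++a) mu[a] = std::exp(par[idx++]);
  for (int a = 0; a < m; ++a)
    for (int b = a + 1; b < m; ++b) Q(a, b) = std::exp(par[idx++]);
  double mx = 0.0;
  std::vector<double> eta(m, 0.0);
  for (int a = 1; a < m; ++a) {
    eta[a] = par[idx++];
    if (eta[a] > mx) mx = eta[a];
  }
  double Z = 0.0;
  for (int a = 0; a < m; ++a) Z += std::exp(eta[a] - mx);
  for (int a = 0; a < m; ++a) nu[a] = std::exp(eta[a] - mx) / Z;
  if (!std::isfinite(tau)) return SENTINEL;
  for (int a = 0; a < m; ++a) {
    if (!std::isfinite(mu[a]) || !std::isfinite(nu[a])) return SENTINEL;
    for (int b = a + 1; b < m; ++b)
      if (!std::isfinite(Q(a, b))) return SENTINEL;
  }
  NumericVector d = cpp_degree_pmf(nu, mu, Q, tau, kmax);
  double d0 = d[0];
  if (!(d0 >= 0.0 && d0 < 1.0)) return SENTINEL;
  double l1md0 = std::log1p(-d0);
  double ll = 0.0;
  for (int i = 0; i < kdeg.size(); ++i) {
    double dk = d[kdeg[i]];
    if (!(dk > 0.0) || !std::isfinite(dk)) return SENTINEL;
    ll += ycnt[i] * (std::log(dk) - l1md0);
  }
  if (!std::isfinite(ll)) return SENTINEL;
  return -ll;
}

// Exact event-driven (Gillespie) simulation of the contact process:
// competing exponential clocks for making a contact (rate 1 + tau k),
// moving to a later phase (rates Q[a][b]) and stopping (rate mu[a]).
// Draws the total-rate exponential then a categorical event choice;
// exactness matters because the simulator is the oracle for the solver.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_simulate(int n, NumericVector nu, NumericVector mu,
                  NumericMatrix Q, double tau) {
  int m = nu.size();
  IntegerVector deg(n);
  NumericVector stime(n);
  for (int i = 0; i < n; ++i) {
    double u = unif_rand(), c = 0.0;
    int a = m - 1;
    for (int j = 0; j < m; ++j) {
      c += nu[j];
      if (u <= c) { a = j; break; }
    }
    int k = 0;
    double t = 0.0;
    for (;;) {
      double rc = 1.0 + tau * k;
      double total = rc + mu[a];
      for (int b = a + 1; b < m; ++b) total += Q(a, b);
      t += exp_rand() / total;
      double v = unif_rand() * total;
      if (v < rc) { ++k; continue; }
      v -= rc;
      if (v < mu[a]) break;
      v -= mu[a];
      for (int b = a + 1; b < m; ++b) {
        if (v < Q(a, b)) { a = b; break; }
        v -= Q(a, b);
      }
    }
    deg[i] = k;
    stime[i] = t;
  }
  return List::create(_["degree"] = deg, _["time"] = stime);
}
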
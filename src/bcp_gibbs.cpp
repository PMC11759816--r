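// Gibbs sampler for the Barry-Hartigan product-partition change-point model.
//
// Model: x_i ~ N(theta_i, s2), theta constant within contiguous blocks. Block
// means draw from N(mu0, s2 (1-w)/w / n_j) so that, integrating theta, mu0
// (flat) and s2 (1/s2 prior) out, the density of the data given a partition
// with b blocks is proportional to
//      w^{(b-1)/2} / (W + w B)^{(n-1)/2}
// with W the within-block and B the between-block sum of squares. The block
// count prior is p^{b-1} (1-p)^{n-b}. p ~ U(0, p0) integrates to an incomplete
// beta (exact); w ~ U(0, w0) is integrated by Gauss-Legendre quadrature on
// [0, w0] (nodes supplied from R).
//
// Each sweep visits every interior position and flips its change indicator
// with the exact conditional odds; only the enclosing segment's contribution
// to T1 = sum_j (block sum)^2 / (block size) changes, so W and B update in
// O(1) once the segment is located.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static double log_sum_exp(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// log integral_0^w0 w^{(b-1)/2} / (W + w B)^{(n-1)/2} dw.
//
// Substituting t = wB/(W + wB) turns the integral into an incomplete beta
// function: I = W^{-s2} B^{-s1} Beta(s1, s2) P(t0; s1, s2) with
// s1 = (b+1)/2, s2 = (n-b)/2 - 1 and t0 = w0 B / (W + w0 B). That form is
// exact and handles the sharp peak near w = 0 that arises when W << B (a
// strong step). When s2 <= 0 (b >= n-2) the integrand is not peaked at zero
// and plain Gauss-Legendre quadrature on [0, w0] is accurate.
static double log_w_integral(int b, double W, double B, int n, double w0,
                             const std::vector<double>& lw,
                             const std::vector<double>& lnode,
                             const std::vector<double>& node) {
  const double s1 = 0.5 * (b + 1);
  const double s2 = 0.5 * (n - b) - 1.0;
  const double half_bm1 = 0.5 * (b - 1);
  const double half_nm1 = 0.5 * (n - 1);
  if (B <= 0.0) {
    // single effective level: integral of w^{(b-1)/2} W^{-(n-1)/2}
    return -half_nm1 * std::log(std::max(W, 1e-300)) + s1 * std::log(w0) -
           std::log(s1);
  }
  if (W <= 0.0) {
    // all variation between blocks; finite only for b > n-2
    double e = half_bm1 - half_nm1 + 1.0;  // (b-n)/2 + 1
    if (e <= 0.0) return 700.0;            // effectively infinite odds
    return -half_nm1 * std::log(B) + e * std::log(w0) - std::log(e);
  }
  if (s2 > 0.0) {
    return -s2 * std::log(W) - s1 * std::log(B) + R::lbeta(s1, s2) +
           R::pbeta(w0 * B / (W + w0 * B), s1, s2, 1, 1);
  }
  std::vector<double> terms(node.size());
  for (size_t k = 0; k < node.size(); ++k) {
    double denom = W + node[k] * B;
    terms[k] = lw[k] + half_bm1 * lnode[k] - half_nm1 * std::log(denom);
  }
  return log_sum_exp(terms);
}

// [[Rcpp::export]]
List bcp_gibbs_cpp(NumericVector x, double p0, double w0,
                   int n_iter, int burn_in,
                   NumericVector gl_nodes, NumericVector gl_weights) {
  const int n = x.size();
  std::vector<double> sx(n + 1, 0.0), sxx(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    sx[i + 1] = sx[i] + x[i];
    sxx[i + 1] = sxx[i] + x[i] * x[i];
  }
  const double SX = sx[n], SXX = sxx[n];
  const double gm2 = SX * SX / n;  // n * grand_mean^2 term for B

  std::vector<double> node(gl_nodes.begin(), gl_nodes.end());
  std::vector<double> lw(node.size()), lnode(node.size());
  for (size_t k = 0; k < node.size(); ++k) {
    lw[k] = std::log(gl_weights[k]);
    lnode[k] = std::log(node[k]);
  }

  // log of the p-prior factor for a partition with b blocks:
  // integral_0^p0 p^{b-1}(1-p)^{n-b} dp = Beta(b, n-b+1) * pbeta(p0, b, n-b+1)
  std::vector<double> logP(n + 1, 0.0);
  for (int b = 1; b <= n; ++b) {
    logP[b] = R::lbeta((double)b, (double)(n - b + 1)) +
              R::pbeta(p0, (double)b, (double)(n - b + 1), 1, 1);
  }

  std::vector<int> u(n, 0);  // u[i]=1: new block starts at i (0-based), i>=1
  int nblocks = 1;
  double T1 = SX * SX / n;   // sum over blocks of (block sum)^2 / size

  std::vector<double> prob(n, 0.0), pmean(n, 0.0);
  int kept = 0;

  RNGScope scope;
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int i = 1; i < n; ++i) {
      // enclosing segment [L, R) ignoring u[i]
      int L = i - 1;
      while (L > 0 && !u[L]) --L;
      int R = i + 1;
      while (R < n && !u[R]) ++R;
      const double sAll = sx[R] - sx[L];
      const int mAll = R - L;
      const double sA = sx[i] - sx[L], sB = sx[R] - sx[i];
      const int mA = i - L, mB = R - i;
      const double c_merged = sAll * sAll / mAll;
      const double c_split  = sA * sA / mA + sB * sB / mB;
      const double c_now = u[i] ? c_split : c_merged;
      const double T1_other = T1 - c_now;
      const int b0 = nblocks - (u[i] ? 1 : 0);
      const int b1 = b0 + 1;

      double T1_0 = T1_other + c_merged;
      double T1_1 = T1_other + c_split;
      double W0 = SXX - T1_0; if (W0 < 0) W0 = 0;
      double W1 = SXX - T1_1; if (W1 < 0) W1 = 0;
      double B0 = T1_0 - gm2; if (B0 < 0) B0 = 0;
      double B1 = T1_1 - gm2; if (B1 < 0) B1 = 0;

      double logodds = (logP[b1] - logP[b0]) +
        log_w_integral(b1, W1, B1, n, w0, lw, lnode, node) -
        log_w_integral(b0, W0, B0, n, w0, lw, lnode, node);
      double p1 = 1.0 / (1.0 + std::exp(-logodds));
      int newu = (unif_rand() < p1) ? 1 : 0;
      if (newu != u[i]) {
        u[i] = newu;
        if (newu) { T1 = T1_other + c_split; nblocks = b1; }
        else      { T1 = T1_other + c_merged; nblocks = b0; }
      }
    }
    if (iter >= burn_in) {
      ++kept;
      int start = 0;
      for (int i = 1; i <= n; ++i) {
        if (i == n || u[i]) {
          double bm = (sx[i] - sx[start]) / (i - start);
          for (int j = start; j < i; ++j) pmean[j] += bm;
          start = i;
        }
        if (i < n && u[i]) prob[i] += 1.0;
      }
    }
  }

  NumericVector post_prob(n), post_mean(n);
  for (int i = 0; i < n; ++i) {
    post_prob[i] = prob[i] / kept;
    post_mean[i] = pmean[i] / kept;
  }
  post_prob[0] = 0.0;
  return List::create(_["posterior_prob"] = post_prob,
                      _["posterior_mean"] = post_mean,
                      _["n_kept"] = kept);
}
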
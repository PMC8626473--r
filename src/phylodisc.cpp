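#include <Rcpp.h>
using namespace Rcpp;

// Per-site coalescent simulation for a 4-taxon tree (((P1,P2),P3),O) with an
// optional introgression pulse moving the P2 lineage into P3's population at
// time tau_gf (with probability gamma).  One mutation is placed uniformly on
// the genealogy (infinite sites); the derived-allele indicator for
// (P1,P2,P3,O) is returned per site.  Uses R's RNG so set.seed() governs
// reproducibility.

// [[Rcpp::export(name = ".sim_site_patterns_cpp")]]
IntegerMatrix sim_site_patterns_cpp(int n_sites, double gamma,
                                    double tau_gf, double tau12,
                                    double tau123, double tau_root) {
  IntegerMatrix geno(n_sites, 4);
  // lineage slots: mask bits 0..3 = P1,P2,P3,O
  int mask[8];
  double birth[8];
  int emask[8];
  double elen[8];

  for (int s = 0; s < n_sites; s++) {
    int nedge = 0;
    int k;  // active lineages excluding O until tau_root
    double t;
    // Phase A: before tau123 at most one pair can coalesce
    bool intro = (gamma > 0.0) && (unif_rand() < gamma);
    int m_pair = intro ? (2 | 4) : (1 | 2);       // P2,P3 or P1,P2
    double t_open = intro ? tau_gf : tau12;
    double w = exp_rand();
    bool coalA = (t_open + w < tau123);
    double tA = t_open + w;
    // set up lineages entering the (P1P2P3) ancestral population at tau123
    if (coalA) {
      // the two merged lineages contribute edges up to tA
      for (int b = 0; b < 3; b++) {
        int bit = 1 << b;
        if (m_pair & bit) { emask[nedge] = bit; elen[nedge] = tA; nedge++; }
      }
      mask[0] = m_pair; birth[0] = tA;
      // remaining singleton among P1..P3
      int rest = 7 & ~m_pair;
      mask[1] = rest; birth[1] = 0.0;
      k = 2;
    } else {
      mask[0] = 1; mask[1] = 2; mask[2] = 4;
      birth[0] = birth[1] = birth[2] = 0.0;
      k = 3;
    }
    // Phase B: [tau123, tau_root], k lineages
    t = tau123;
    while (k >= 2) {
      double rate = k * (k - 1) / 2.0;
      double wb = exp_rand() / rate;
      if (t + wb >= tau_root) break;
      t += wb;
      int npairs = k * (k - 1) / 2;
      int r = (int)(unif_rand() * npairs);
      if (r >= npairs) r = npairs - 1;
      int i = 0, j = 1, c = 0, done = 0;
      for (i = 0; i < k - 1 && !done; i++)
        for (j = i + 1; j < k; j++)
          if (c++ == r) { done = 1; break; }
      i--;  // loop incremented past
      emask[nedge] = mask[i]; elen[nedge] = t - birth[i]; nedge++;
      emask[nedge] = mask[j]; elen[nedge] = t - birth[j]; nedge++;
      mask[i] = mask[i] | mask[j]; birth[i] = t;
      mask[j] = mask[k - 1]; birth[j] = birth[k - 1];
      k--;
    }
    // Phase C: O joins at tau_root
    mask[k] = 8; birth[k] = 0.0; k++;
    t = tau_root;
    while (k >= 2) {
      double rate = k * (k - 1) / 2.0;
      t += exp_rand() / rate;
      int npairs = k * (k - 1) / 2;
      int r = (int)(unif_rand() * npairs);
      if (r >= npairs) r = npairs - 1;
      int i = 0, j = 1, c = 0, done = 0;
      for (i = 0; i < k - 1 && !done; i++)
        for (j = i + 1; j < k; j++)
          if (c++ == r) { done = 1; break; }
      i--;
      emask[nedge] = mask[i]; elen[nedge] = t - birth[i]; nedge++;
      emask[nedge] = mask[j]; elen[nedge] = t - birth[j]; nedge++;
      mask[i] = mask[i] | mask[j]; birth[i] = t;
      mask[j] = mask[k - 1]; birth[j] = birth[k - 1];
      k--;
    }
    // uniform mutation on the genealogy
    double total = 0.0;
    for (int e = 0; e < nedge; e++) total += elen[e];
    double u = unif_rand() * total;
    int dmask = emask[nedge - 1];
    for (int e = 0; e < nedge; e++) {
      if (u < elen[e]) { dmask = emask[e]; break; }
      u -= elen[e];
    }
    geno(s, 0) = (dmask & 1) ? 1 : 0;
    geno(s, 1) = (dmask & 2) ? 1 : 0;
    geno(s, 2) = (dmask & 4) ? 1 : 0;
    geno(s, 3) = (dmask & 8) ? 1 : 0;
  }
  return geno;
}

// EM for the shifted-exponential mixture profiled over a grid of shifts K.
// Model: pi * (K + Exp(lambda))  +  (1 - pi) * Exp(lambda), shared lambda.
// Because lambda is shared, the responsibility of the shifted component is
// identical for every observation with t >= K (and zero below K), so each
// EM iteration is O(1) given n_ge = #{t_i >= K} and sum(t):
//   R        = pi / (pi + (1 - pi) * exp(-K / lambda))
//   pi'      = n_ge * R / N
//   lambda'  = (sum(t) - K * n_ge * R) / N
//   logL     = -N log lambda - sum(t)/lambda
//              + n_ge * (K/lambda + log(pi + (1 - pi) exp(-K/lambda)))
//              + (N - n_ge) * log(1 - pi)
// Runs from (pi0, lam0) until the log-likelihood change drops below tol.
// Returns a G x 3 matrix: logL, pi, lambda.

// [[Rcpp::export(name = ".em_profile_cpp")]]
NumericMatrix em_profile_cpp(NumericVector t, NumericVector K,
                             double pi0, double lam0,
                             double tol, int maxit) {
  int N = t.size(), G = K.size();
  NumericMatrix out(G, 3);
  double sumt = 0.0;
  for (int i = 0; i < N; i++) sumt += t[i];
  for (int g = 0; g < G; g++) {
    double kk = K[g];
    int n_ge = 0;
    for (int i = 0; i < N; i++) if (t[i] >= kk) n_ge++;
    double pi = pi0, lam = lam0, ll = R_NegInf;
    for (int it = 0; it < maxit; it++) {
      double em = std::exp(-kk / lam);            // <= 1, no overflow
      double ll_new = -N * std::log(lam) - sumt / lam
        + n_ge * (kk / lam + std::log(pi + (1.0 - pi) * em));
      if (N > n_ge) {
        double om = 1.0 - pi;
        if (om < 1e-300) om = 1e-300;
        ll_new += (N - n_ge) * std::log(om);
      }
      double R = pi / (pi + (1.0 - pi) * em);
      double sumr = n_ge * R;
      pi = sumr / N;
      lam = (sumt - kk * sumr) / N;
      if (lam < 1e-12) lam = 1e-12;
      if (R_finite(ll) && std::fabs(ll_new - ll) <=
          tol * (std::fabs(ll) + 1e-12)) { ll = ll_new; break; }
      ll = ll_new;
    }
    // final evaluation at the converged parameters
    double em = std::exp(-kk / lam);
    double llf = -N * std::log(lam) - sumt / lam
      + n_ge * (kk / lam + std::log(pi + (1.0 - pi) * em));
    if (N > n_ge) {
      double om = 1.0 - pi;
      if (om < 1e-300) om = 1e-300;
      llf += (N - n_ge) * std::log(om);
    }
    out(g, 0) = llf;
    out(g, 1) = pi;
    out(g, 2) = lam;
  }
  return out;
}
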
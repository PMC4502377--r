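#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Collapsed-Z Gibbs sampler for the independent-frequency admixture model.
//
// Data: diploid dosages (0/1/2, NA = missing) at biallelic loci. Each allele
// copy carries a latent origin z in 1..K; given origins, population
// frequencies P get conjugate Beta(1 + alt, 1 + ref) updates and individual
// ancestry rows Q get Dirichlet(alpha + counts) updates. Point estimates are
// posterior means over post-burn-in sweeps. The likelihood trace records, at
// every sweep, the log mixture probability of all called allele copies under
// the current (Q, P).
//
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List gibbs_admixture(IntegerMatrix dosage, int K, int burn_in, int n_reps,
                     double alpha) {
  const int N = dosage.nrow(), L = dosage.ncol();
  const int total = burn_in + n_reps;

  NumericMatrix q(N, K), p(K, L), q_sum(N, K), p_sum(K, L);
  NumericVector lnl(total);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) q(i, k) = 1.0 / K;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) p(k, l) = R::runif(0.05, 0.95);

  std::vector<double> nq(N * K), nalt(K * L), ntot(K * L), prob(K);

  for (int t = 0; t < total; ++t) {
    std::fill(nq.begin(), nq.end(), 0.0);
    std::fill(nalt.begin(), nalt.end(), 0.0);
    std::fill(ntot.begin(), ntot.end(), 0.0);
    double ll = 0.0;

    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        const int d = dosage(i, l);
        if (d == NA_INTEGER) continue;
        for (int copy = 0; copy < 2; ++copy) {
          const int a = (d == 2) ? 1 : (d == 1 && copy == 0 ? 1 : 0);
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            const double f = a ? p(k, l) : 1.0 - p(k, l);
            prob[k] = q(i, k) * f;
            s += prob[k];
          }
          ll += std::log(s);
          double u = unif_rand() * s, c = 0.0;
          int z = K - 1;
          for (int k = 0; k < K; ++k) {
            c += prob[k];
            if (u <= c) { z = k; break; }
          }
          nq[i * K + z] += 1.0;
          ntot[z * L + l] += 1.0;
          if (a) nalt[z * L + l] += 1.0;
        }
      }
    }
    lnl[t] = ll;

    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        const double na = nalt[k * L + l], nt = ntot[k * L + l];
        p(k, l) = R::rbeta(1.0 + na, 1.0 + (nt - na));
      }

    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        const double g = R::rgamma(alpha + nq[i * K + k], 1.0);
        q(i, k) = g;
        s += g;
      }
      for (int k = 0; k < K; ++k) q(i, k) /= s;
    }

    if (t >= burn_in) {
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) q_sum(i, k) += q(i, k);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l) p_sum(k, l) += p(k, l);
    }
  }

  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) q_sum(i, k) /= n_reps;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) p_sum(k, l) /= n_reps;

  return List::create(_["Q"] = q_sum, _["P"] = p_sum, _["lnl"] = lnl);
}
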
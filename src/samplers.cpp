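#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Monte Carlo core of the Hardy-Weinberg exact test.  Alleles are coded
// 1..n_alleles; the statistic is the log conditional (Levene) probability
// of the genotype table given allele counts, of which only the
// configuration-dependent part h*log(2) - sum_g log(n_g!) varies under
// re-pairing, so that is what gets compared.
// [[Rcpp::export]]
List hwe_mc_cpp(IntegerVector g1, IntegerVector g2, int n_alleles,
                int n_perm) {
  const int n = g1.size();
  const int ncells = n_alleles * n_alleles;
  std::vector<double> lfact(2 * n + 1);
  lfact[0] = 0.0;
  for (int i = 1; i <= 2 * n; ++i) lfact[i] = lfact[i - 1] + std::log((double)i);
  const double log2c = std::log(2.0);

  std::vector<int> alleles(2 * n);
  for (int i = 0; i < n; ++i) {
    alleles[2 * i] = g1[i] - 1;
    alleles[2 * i + 1] = g2[i] - 1;
  }

  std::vector<int> cells(ncells, 0);
  std::vector<int> touched;
  touched.reserve(n);
  // statistic of an allele pairing laid out in `alleles`
  auto config_stat = [&]() {
    touched.clear();
    int h = 0;
    for (int i = 0; i < n; ++i) {
      int a = alleles[2 * i], b = alleles[2 * i + 1];
      if (a > b) std::swap(a, b);
      if (a != b) ++h;
      int cell = a * n_alleles + b;
      if (cells[cell] == 0) touched.push_back(cell);
      cells[cell] += 1;
    }
    double s = h * log2c;
    for (int cell : touched) {
      s -= lfact[cells[cell]];
      cells[cell] = 0;
    }
    return s;
  };

  const double obs = config_stat();

  // full log conditional probability of the observed table (for reporting)
  std::vector<int> acount(n_alleles, 0);
  for (int i = 0; i < 2 * n; ++i) acount[alleles[i]] += 1;
  double log_prob_obs = obs + lfact[n] - lfact[2 * n];
  for (int a = 0; a < n_alleles; ++a) log_prob_obs += lfact[acount[a]];

  int count_leq = 0;
  for (int r = 0; r < n_perm; ++r) {
    // Fisher-Yates shuffle of the 2n allele copies, then pair consecutive
    for (int i = 2 * n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(alleles[i], alleles[j]);
    }
    if (config_stat() <= obs + 1e-9) ++count_leq;
  }
  return List::create(Named("log_prob_obs") = log_prob_obs,
                      Named("count_leq") = count_leq);
}

// Gibbs sampler for the no-admixture-prior ("vanilla") admixture model:
// alleles carry origin indicators z; cluster allele frequencies P and
// individual admixture proportions Q have Dirichlet full conditionals.
// alleles: n x 2L matrix of allele codes (1-based, 0 = missing);
// n_alleles: codes per locus.  Returns the posterior-mean Q over the
// retained sweeps and the full log-likelihood trace.
// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix alleles, IntegerVector n_alleles,
                         int K, int burn_in, int n_sweeps,
                         double alpha, double lambda, bool infer_alpha,
                         double alpha_max, double alpha_prop_sd) {
  const int n = alleles.nrow();
  const int L = n_alleles.size();
  const int total = burn_in + n_sweeps;

  // flat storage for P: per locus an K x A block
  std::vector<int> loc_off(L + 1, 0);
  for (int l = 0; l < L; ++l) loc_off[l + 1] = loc_off[l] + n_alleles[l];
  const int A_total = loc_off[L];

  std::vector<double> P(K * A_total, 0.0);      // [k * A_total + loc_off[l] + a]
  std::vector<double> Q(n * K, 1.0 / K);        // [i * K + k]
  std::vector<int> z(n * 2 * L, 0);
  std::vector<double> pcount(K * A_total, 0.0);
  std::vector<double> qcount(n * K, 0.0);
  std::vector<double> Qsum(n * K, 0.0);
  std::vector<double> prob(K, 0.0);
  NumericVector loglik(total);
  NumericVector loglik_mix(total);
  NumericVector alpha_trace(total);

  // log density of all Q rows under a symmetric Dirichlet(a, ..., a)
  auto q_logprior = [&](double a) {
    double s = n * (R::lgammafn(K * a) - K * R::lgammafn(a));
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < K; ++k) {
        double q = Q[i * K + k];
        if (q < 1e-300) q = 1e-300;
        s += (a - 1.0) * std::log(q);
      }
    return s;
  };

  // init z uniformly at random
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 2 * L; ++c) {
      if (alleles(i, c) > 0) {
        int k = (int)std::floor(unif_rand() * K);
        if (k >= K) k = K - 1;
        z[(i * 2 * L) + c] = k;
      } else {
        z[(i * 2 * L) + c] = -1;
      }
    }

  for (int sweep = 0; sweep < total; ++sweep) {
    // --- P | z : Dirichlet(lambda + counts) per (k, locus)
    std::fill(pcount.begin(), pcount.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 2 * L; ++c) {
        int a = alleles(i, c);
        if (a > 0) {
          int l = c / 2;
          pcount[z[i * 2 * L + c] * A_total + loc_off[l] + (a - 1)] += 1.0;
        }
      }
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        double s = 0.0;
        for (int a = 0; a < n_alleles[l]; ++a) {
          double g = R::rgamma(lambda + pcount[k * A_total + loc_off[l] + a], 1.0);
          P[k * A_total + loc_off[l] + a] = g;
          s += g;
        }
        for (int a = 0; a < n_alleles[l]; ++a)
          P[k * A_total + loc_off[l] + a] /= s;
      }

    // --- Q | z : Dirichlet(alpha + counts) per individual
    std::fill(qcount.begin(), qcount.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 2 * L; ++c)
        if (z[i * 2 * L + c] >= 0) qcount[i * K + z[i * 2 * L + c]] += 1.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + qcount[i * K + k], 1.0);
        Q[i * K + k] = g;
        s += g;
      }
      for (int k = 0; k < K; ++k) Q[i * K + k] /= s;
    }

    // --- alpha | Q : Metropolis step with uniform prior on (0, alpha_max],
    // symmetric normal proposal (the convention of the clustering program
    // this sampler stands in for)
    if (infer_alpha && K > 1) {
      double prop = alpha + norm_rand() * alpha_prop_sd;
      if (prop > 0.0 && prop <= alpha_max) {
        double lr = q_logprior(prop) - q_logprior(alpha);
        if (lr >= 0.0 || unif_rand() < std::exp(lr)) alpha = prop;
      }
    }
    alpha_trace[sweep] = alpha;

    // --- z | Q, P, plus the two log-likelihood traces: the complete-data
    // log P(X | Z, P) at the freshly sampled assignments (what the
    // deviance-style L_estimate is built from, following the clustering
    // program this sampler stands in for) and the observed-data mixture
    // log P(X | Q, P).
    double lnl_complete = 0.0, lnl_mix = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < 2 * L; ++c) {
        int a = alleles(i, c);
        if (a <= 0) continue;
        int l = c / 2;
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          double pr = Q[i * K + k] * P[k * A_total + loc_off[l] + (a - 1)];
          prob[k] = pr;
          s += pr;
        }
        lnl_mix += std::log(s);
        double u = unif_rand() * s;
        int k = 0;
        double acc = prob[0];
        while (u > acc && k < K - 1) { ++k; acc += prob[k]; }
        z[i * 2 * L + c] = k;
        lnl_complete += std::log(P[k * A_total + loc_off[l] + (a - 1)]);
      }
    }
    loglik[sweep] = lnl_complete;
    loglik_mix[sweep] = lnl_mix;

    if (sweep >= burn_in)
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum[i * K + k] += Q[i * K + k];
  }

  NumericMatrix Qmean(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qmean(i, k) = Qsum[i * K + k] / n_sweeps;
  return List::create(Named("Q") = Qmean, Named("loglik") = loglik,
                      Named("loglik_mix") = loglik_mix,
                      Named("alpha_trace") = alpha_trace);
}
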
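#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gibbs sampler for the admixture clustering model: individuals carry
// ancestry proportions q_i over K source populations; each observed
// allele copy has a latent origin z sampled from the posterior
// proportional to q_ik * p_{k,l,a}; allele frequencies and ancestries
// get conjugate Dirichlet updates.  An optional location-informed
// prior replaces the symmetric Dirichlet on q_i by Dirichlet
// (alpha * K * eta_g) with a per-location mean-ancestry vector eta_g
// updated by Metropolis-Hastings.  All randomness comes from R's RNG,
// so runs are reproducible under set.seed().

static int sample_cat(const double *w, int K, double tot) {
  double u = unif_rand() * tot, c = 0.0;
  for (int k = 0; k < K; ++k) {
    c += w[k];
    if (u <= c) return k;
  }
  return K - 1;
}

static void rdirichlet(double *out, const double *a, int K) {
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    out[k] = R::rgamma(a[k] > 0 ? a[k] : 1e-8, 1.0);
    if (out[k] < 1e-300) out[k] = 1e-300;
    s += out[k];
  }
  for (int k = 0; k < K; ++k) out[k] /= s;
}

static double ldirichlet(const double *x, const double *a, int K) {
  double s = 0.0, sa = 0.0;
  for (int k = 0; k < K; ++k) {
    s += (a[k] - 1.0) * log(x[k]) - R::lgammafn(a[k]);
    sa += a[k];
  }
  return s + R::lgammafn(sa);
}

// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix geno, IntegerVector n_alleles,
                         int K, double alpha, double lambda,
                         IntegerVector loc, int burnin, int sweeps,
                         bool update_alpha) {
  int n = geno.nrow();
  int L = n_alleles.size();
  bool locprior = loc.size() == n;
  int G = 0;
  if (locprior) {
    for (int i = 0; i < n; ++i) if (loc[i] > G) G = loc[i];
  }
  RNGScope scope;

  std::vector<std::vector<double> > P(K * L);
  std::vector<std::vector<double> > Pcnt(K * L);
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) {
      P[k * L + l].assign(n_alleles[l], 1.0 / n_alleles[l]);
      Pcnt[k * L + l].assign(n_alleles[l], 0.0);
    }
  std::vector<double> Q(n * K, 1.0 / K);
  std::vector<double> Qcnt(n * K, 0.0);
  std::vector<double> eta(G * K, 1.0 / std::max(K, 1));
  std::vector<double> Qsum(n * K, 0.0);
  std::vector<double> etasum(G * K, 0.0);
  std::vector<double> w(K), tmp(K), prop(K), apar(K);
  NumericVector ll_trace(sweeps - burnin);
  double cur_alpha = alpha;
  int eta_acc = 0, eta_try = 0;
  int kept = 0;

  for (int sweep = 0; sweep < sweeps; ++sweep) {
    std::fill(Qcnt.begin(), Qcnt.end(), 0.0);
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        std::fill(Pcnt[k * L + l].begin(), Pcnt[k * L + l].end(), 0.0);

    // latent origins
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a <= 0) continue;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            w[k] = Q[i * K + k] * P[k * L + l][a - 1];
            tot += w[k];
          }
          int z = (tot > 0) ? sample_cat(&w[0], K, tot)
                            : (int)(unif_rand() * K);
          Qcnt[i * K + z] += 1.0;
          Pcnt[z * L + l][a - 1] += 1.0;
        }
      }
    }
    // allele frequencies
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        int J = n_alleles[l];
        std::vector<double> ap(J);
        for (int j = 0; j < J; ++j) ap[j] = lambda + Pcnt[k * L + l][j];
        rdirichlet(&P[k * L + l][0], &ap[0], J);
      }
    // ancestries
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < K; ++k) {
        double pr = locprior ? cur_alpha * K * eta[(loc[i] - 1) * K + k]
                             : cur_alpha;
        apar[k] = pr + Qcnt[i * K + k];
      }
      rdirichlet(&Q[i * K], &apar[0], K);
    }
    // location prior update (MH on each eta_g)
    if (locprior && K > 1) {
      const double cprop = 200.0;
      for (int g = 0; g < G; ++g) {
        ++eta_try;
        std::vector<double> pa(K), cur(K);
        for (int k = 0; k < K; ++k) {
          cur[k] = eta[g * K + k];
          pa[k] = cprop * cur[k] + 0.5;
        }
        rdirichlet(&prop[0], &pa[0], K);
        std::vector<double> pa_rev(K), acur(K), aprop(K);
        for (int k = 0; k < K; ++k) {
          pa_rev[k] = cprop * prop[k] + 0.5;
          acur[k] = cur_alpha * K * cur[k];
          aprop[k] = cur_alpha * K * prop[k];
        }
        double lr = 0.0;
        for (int i = 0; i < n; ++i) {
          if (loc[i] - 1 != g) continue;
          lr += ldirichlet(&Q[i * K], &aprop[0], K) -
                ldirichlet(&Q[i * K], &acur[0], K);
        }
        lr += ldirichlet(&cur[0], &pa_rev[0], K) -
              ldirichlet(&prop[0], &pa[0], K);
        if (log(unif_rand()) < lr) {
          for (int k = 0; k < K; ++k) eta[g * K + k] = prop[k];
          ++eta_acc;
        }
      }
    }
    // optional MH update of the ancestry hyperparameter
    if (update_alpha && K > 1) {
      double lprop = log(cur_alpha) + norm_rand() * 0.1;
      double aprop = exp(lprop);
      if (aprop > 1e-3 && aprop < 10.0) {
        double lr = 0.0;
        for (int i = 0; i < n; ++i) {
          std::vector<double> a1(K), a2(K);
          for (int k = 0; k < K; ++k) {
            double e = locprior ? K * eta[(loc[i] - 1) * K + k] : 1.0;
            a1[k] = aprop * e;
            a2[k] = cur_alpha * e;
          }
          lr += ldirichlet(&Q[i * K], &a1[0], K) -
                ldirichlet(&Q[i * K], &a2[0], K);
        }
        lr += lprop - log(cur_alpha);  // log-normal proposal Jacobian
        if (log(unif_rand()) < lr) cur_alpha = aprop;
      }
    }
    // data log-likelihood given (P, Q)
    double ll = 0.0;
    for (int i = 0; i < n; ++i)
      for (int l = 0; l < L; ++l)
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a <= 0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k)
            s += Q[i * K + k] * P[k * L + l][a - 1];
          ll += log(s > 1e-300 ? s : 1e-300);
        }
    if (sweep >= burnin) {
      ll_trace[sweep - burnin] = ll;
      for (int i = 0; i < n * K; ++i) Qsum[i] += Q[i];
      for (int i = 0; i < G * K; ++i) etasum[i] += eta[i];
      ++kept;
    }
  }

  NumericMatrix Qmean(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qmean(i, k) = Qsum[i * K + k] / kept;
  // exact normalisation (guards round-off; K = 1 gives exactly 1)
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += Qmean(i, k);
    for (int k = 0; k < K; ++k) Qmean(i, k) /= s;
  }
  NumericMatrix etam(G, K);
  for (int g = 0; g < G; ++g)
    for (int k = 0; k < K; ++k) etam(g, k) = etasum[g * K + k] / kept;
  return List::create(_["Q"] = Qmean, _["loglik"] = ll_trace,
                      _["eta"] = etam,
                      _["eta_accept"] =
                        eta_try ? (double)eta_acc / eta_try : NA_REAL,
                      _["alpha"] = cur_alpha);
}
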
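#include <Rcpp.h>
using namespace Rcpp;

// STRUCTURE-style admixture model with correlated allele frequencies.
// Gibbs sweep: (i) cluster assignment of every gene copy given Q and
// cluster frequencies, (ii) cluster frequencies from their Dirichlet
// full conditional around the ancestral frequencies with drift F_k,
// (iii) Q rows from Dirichlet(alpha + counts). Ancestral frequencies
// and F_k get Metropolis updates; alpha gets a Metropolis step with a
// uniform(0, alpha_max) prior. All draws use R's RNG.

static void rdirichlet(const std::vector<double> &shape, std::vector<double> &out) {
  double tot = 0.0;
  for (size_t a = 0; a < shape.size(); ++a) {
    out[a] = R::rgamma(shape[a], 1.0);
    if (out[a] < 1e-300) out[a] = 1e-300;
    tot += out[a];
  }
  for (size_t a = 0; a < shape.size(); ++a) out[a] /= tot;
}

// log Dirichlet(c * pA) density of f
static double ldirich(const std::vector<double> &f, const std::vector<double> &pA, double c) {
  double ll = R::lgammafn(c);
  for (size_t a = 0; a < f.size(); ++a)
    ll += (c * pA[a] - 1.0) * std::log(f[a]) - R::lgammafn(c * pA[a]);
  return ll;
}

// [[Rcpp::export]]
List cpp_admixture(IntegerMatrix geno,   // 2n x L, allele index 0..A_l-1, -1 missing
                   IntegerVector nalleles,
                   int n_ind, int K,
                   int burn_in, int n_iter,
                   double alpha_init, double alpha_max, double sd_alpha_prop,
                   double lambda,       // ancestral frequency prior
                   double f_init, double sd_f_prop, double p_eps) {
  const int L = geno.ncol();
  const int ncopy = geno.nrow(); // 2 * n_ind

  // state
  std::vector<std::vector<std::vector<double> > > freq(L); // [l][k][a]
  std::vector<std::vector<double> > pA(L);                 // [l][a]
  for (int l = 0; l < L; ++l) {
    int A = nalleles[l];
    pA[l].assign(A, 1.0 / A);
    freq[l].assign(K, std::vector<double>(A, 1.0 / A));
  }
  std::vector<double> Fk(K, f_init);
  std::vector<std::vector<double> > q(n_ind, std::vector<double>(K, 1.0 / K));
  double alpha = alpha_init;

  // accumulators
  NumericMatrix qsum(n_ind, K);
  std::vector<double> fk_sum(K, 0.0);
  double ll_sum = 0.0, ll2_sum = 0.0;
  int nkept = 0;

  std::vector<std::vector<std::vector<double> > > cnt(L); // [l][k][a]
  for (int l = 0; l < L; ++l) cnt[l].assign(K, std::vector<double>(nalleles[l], 0.0));
  std::vector<std::vector<double> > icnt(n_ind, std::vector<double>(K, 0.0));
  std::vector<double> probs(K), shape;

  int total = burn_in + n_iter;
  for (int it = 0; it < total; ++it) {
    // (i) assignments
    for (int l = 0; l < L; ++l)
      for (int k = 0; k < K; ++k)
        std::fill(cnt[l][k].begin(), cnt[l][k].end(), 0.0);
    for (int i = 0; i < n_ind; ++i) std::fill(icnt[i].begin(), icnt[i].end(), 0.0);
    double loglik = 0.0;
    for (int c = 0; c < ncopy; ++c) {
      int ind = c / 2;
      for (int l = 0; l < L; ++l) {
        int a = geno(c, l);
        if (a < 0) continue;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) { probs[k] = q[ind][k] * freq[l][k][a]; tot += probs[k]; }
        loglik += std::log(tot);
        double u = unif_rand() * tot, acc = 0.0;
        int z = K - 1;
        for (int k = 0; k < K; ++k) { acc += probs[k]; if (u <= acc) { z = k; break; } }
        cnt[l][z][a] += 1.0;
        icnt[ind][z] += 1.0;
      }
    }
    // (ii) cluster frequencies
    for (int l = 0; l < L; ++l) {
      int A = nalleles[l];
      shape.assign(A, 0.0);
      for (int k = 0; k < K; ++k) {
        double c0 = (1.0 - Fk[k]) / Fk[k];
        for (int a = 0; a < A; ++a) shape[a] = pA[l][a] * c0 + cnt[l][k][a];
        rdirichlet(shape, freq[l][k]);
      }
    }
    // (iii) Q rows
    for (int i = 0; i < n_ind; ++i) {
      shape.assign(K, 0.0);
      for (int k = 0; k < K; ++k) shape[k] = alpha + icnt[i][k];
      rdirichlet(shape, q[i]);
    }
    // ancestral frequencies: two-allele mass transfer MH (Dirichlet(lambda) prior)
    for (int l = 0; l < L; ++l) {
      int A = nalleles[l];
      if (A < 2) continue;
      int a1 = (int)(unif_rand() * A);
      int a2 = (int)(unif_rand() * (A - 1)); if (a2 >= a1) ++a2;
      double d = (unif_rand() * 2.0 - 1.0) * p_eps;
      double n1 = pA[l][a1] + d, n2 = pA[l][a2] - d;
      if (n1 <= 1e-6 || n2 <= 1e-6 || n1 >= 1 || n2 >= 1) continue;
      std::vector<double> pnew(pA[l]);
      pnew[a1] = n1; pnew[a2] = n2;
      double dll = (lambda - 1.0) * (std::log(n1 / pA[l][a1]) + std::log(n2 / pA[l][a2]));
      for (int k = 0; k < K; ++k) {
        double c0 = (1.0 - Fk[k]) / Fk[k];
        dll += ldirich(freq[l][k], pnew, c0) - ldirich(freq[l][k], pA[l], c0);
      }
      if (std::log(unif_rand()) < dll) pA[l] = pnew;
    }
    // drift parameters F_k: logit random walk, uniform(0,1) prior
    for (int k = 0; k < K; ++k) {
      double lo = std::log(Fk[k] / (1.0 - Fk[k]));
      double ln = lo + norm_rand() * sd_f_prop;
      double fn = 1.0 / (1.0 + std::exp(-ln));
      if (fn <= 1e-6 || fn >= 1.0 - 1e-6) continue;
      double co = (1.0 - Fk[k]) / Fk[k], cn = (1.0 - fn) / fn;
      // Jacobian of logit walk: |df/dl| = f(1-f)
      double dll = std::log(fn * (1.0 - fn)) - std::log(Fk[k] * (1.0 - Fk[k]));
      for (int l = 0; l < L; ++l)
        dll += ldirich(freq[l][k], pA[l], cn) - ldirich(freq[l][k], pA[l], co);
      if (std::log(unif_rand()) < dll) Fk[k] = fn;
    }
    // alpha: random walk MH, uniform(0, alpha_max) prior
    if (K > 1) {
      double an = alpha + norm_rand() * sd_alpha_prop;
      if (an > 1e-4 && an < alpha_max) {
        double dll = n_ind * (R::lgammafn(K * an) - K * R::lgammafn(an)
                            - R::lgammafn(K * alpha) + K * R::lgammafn(alpha));
        for (int i = 0; i < n_ind; ++i)
          for (int k = 0; k < K; ++k) dll += (an - alpha) * std::log(q[i][k]);
        if (std::log(unif_rand()) < dll) alpha = an;
      }
    }
    if (it >= burn_in) {
      for (int i = 0; i < n_ind; ++i)
        for (int k = 0; k < K; ++k) qsum(i, k) += q[i][k];
      for (int k = 0; k < K; ++k) fk_sum[k] += Fk[k];
      ll_sum += loglik; ll2_sum += loglik * loglik;
      ++nkept;
    }
  }
  NumericMatrix Q(n_ind, K);
  for (int i = 0; i < n_ind; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = qsum(i, k) / nkept;
  NumericVector Fout(K);
  for (int k = 0; k < K; ++k) Fout[k] = fk_sum[k] / nkept;
  double mean_ll = ll_sum / nkept;
  double var_ll = ll2_sum / nkept - mean_ll * mean_ll;
  return List::create(
    _["Q"] = Q, _["F"] = Fout, _["alpha"] = alpha,
    _["mean_loglik"] = mean_ll, _["var_loglik"] = var_ll,
    _["lnP"] = mean_ll - var_ll / 2.0);
}
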
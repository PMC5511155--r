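#include <Rcpp.h>
using namespace Rcpp;

// Multinomial-Dirichlet FST outlier model (BayeScan-type) fitted by
// reversible-jump MCMC. For locus i in population j the allele counts
// are multinomial-Dirichlet with parameters theta_ij * p_i, where
// logit(F_ij) = alpha_i + beta_j and theta_ij = 1/F_ij - 1
// = exp(-(alpha_i + beta_j)). The reversible jump toggles the
// locus-specific alpha_i in and out of the model.

static double md_loglik(const IntegerVector &counts, int ntot,
                        const NumericVector &p, double theta) {
  double ll = R::lgammafn(theta) - R::lgammafn(theta + ntot);
  for (int a = 0; a < counts.size(); ++a) {
    double tp = theta * p[a];
    ll += R::lgammafn(tp + counts[a]) - R::lgammafn(tp);
  }
  return ll;
}

// [[Rcpp::export]]
List cpp_outlier_scan(List count_mats,      // per locus: pops x alleles counts
                      int n_iter, int burn_in, int thin,
                      double prior_odds,    // prior odds for neutrality (10)
                      double sd_alpha_prior, double sd_beta_prior,
                      double sd_alpha_prop, double sd_beta_prop,
                      double sd_rj, double p_eps) {
  const int L = count_mats.size();
  std::vector<IntegerMatrix> cm(L);
  int J = 0;
  for (int l = 0; l < L; ++l) { cm[l] = as<IntegerMatrix>(count_mats[l]); J = cm[l].nrow(); }
  std::vector<IntegerVector> rowtot(L);
  for (int l = 0; l < L; ++l) {
    IntegerVector rt(J);
    for (int j = 0; j < J; ++j) {
      int s = 0;
      for (int a = 0; a < cm[l].ncol(); ++a) s += cm[l](j, a);
      rt[j] = s;
    }
    rowtot[l] = rt;
  }

  // state: ancestral freqs, alpha (with inclusion), beta
  std::vector<NumericVector> p(L);
  for (int l = 0; l < L; ++l) {
    int A = cm[l].ncol();
    NumericVector pl(A);
    double tot = 0;
    for (int a = 0; a < A; ++a) {
      double c = 1.0;
      for (int j = 0; j < J; ++j) c += cm[l](j, a);
      pl[a] = c; tot += c;
    }
    for (int a = 0; a < A; ++a) pl[a] /= tot;
    p[l] = pl;
  }
  NumericVector alpha(L, 0.0), beta(J, -1.0);
  LogicalVector incl(L, false);
  const double prior_incl = 1.0 / (1.0 + prior_odds);

  NumericMatrix ll(L, J);
  auto ll_cell = [&](int l, int j, double a_l) {
    double th = std::exp(-(a_l + beta[j]));
    IntegerVector row = cm[l](j, _);
    return md_loglik(row, rowtot[l][j], p[l], th);
  };
  for (int l = 0; l < L; ++l)
    for (int j = 0; j < J; ++j) ll(l, j) = ll_cell(l, j, alpha[l]);

  int total_iter = burn_in + n_iter;
  int nsamp = n_iter / thin;
  NumericMatrix alpha_s(nsamp, L);
  IntegerMatrix incl_s(nsamp, L);
  NumericMatrix beta_s(nsamp, J);
  NumericVector ll_s(nsamp);
  int si = 0;
  double acc_p = 0, try_p = 0, acc_a = 0, try_a = 0, acc_b = 0, try_b = 0;

  for (int it = 0; it < total_iter; ++it) {
    // ancestral allele frequencies: two-allele mass transfer
    for (int l = 0; l < L; ++l) {
      int A = p[l].size();
      if (A < 2) continue;
      int a1 = (int)(unif_rand() * A);
      int a2 = (int)(unif_rand() * (A - 1)); if (a2 >= a1) ++a2;
      double d = (unif_rand() * 2.0 - 1.0) * p_eps;
      double n1 = p[l][a1] + d, n2 = p[l][a2] - d;
      ++try_p;
      if (n1 <= 1e-9 || n2 <= 1e-9 || n1 >= 1 || n2 >= 1) continue;
      NumericVector pnew = clone(p[l]);
      pnew[a1] = n1; pnew[a2] = n2;
      double dll = 0;
      std::vector<double> newll(J);
      NumericVector pold = p[l];
      p[l] = pnew;
      for (int j = 0; j < J; ++j) { newll[j] = ll_cell(l, j, alpha[l]); dll += newll[j] - ll(l, j); }
      if (std::log(unif_rand()) < dll) {
        for (int j = 0; j < J; ++j) ll(l, j) = newll[j];
        ++acc_p;
      } else p[l] = pold;
    }
    // beta updates
    for (int j = 0; j < J; ++j) {
      double bnew = beta[j] + norm_rand() * sd_beta_prop;
      double dll = R::dnorm(bnew, 0.0, sd_beta_prior, 1) - R::dnorm(beta[j], 0.0, sd_beta_prior, 1);
      std::vector<double> newll(L);
      double bold = beta[j];
      beta[j] = bnew;
      for (int l = 0; l < L; ++l) { newll[l] = ll_cell(l, j, alpha[l]); dll += newll[l] - ll(l, j); }
      ++try_b;
      if (std::log(unif_rand()) < dll) {
        for (int l = 0; l < L; ++l) ll(l, j) = newll[l];
        ++acc_b;
      } else beta[j] = bold;
    }
    // alpha random-walk updates (included loci only)
    for (int l = 0; l < L; ++l) {
      if (!incl[l]) continue;
      double anew = alpha[l] + norm_rand() * sd_alpha_prop;
      double dll = R::dnorm(anew, 0.0, sd_alpha_prior, 1) - R::dnorm(alpha[l], 0.0, sd_alpha_prior, 1);
      std::vector<double> newll(J);
      for (int j = 0; j < J; ++j) { newll[j] = ll_cell(l, j, anew); dll += newll[j] - ll(l, j); }
      ++try_a;
      if (std::log(unif_rand()) < dll) {
        alpha[l] = anew;
        for (int j = 0; j < J; ++j) ll(l, j) = newll[j];
        ++acc_a;
      }
    }
    // reversible jump: toggle inclusion of alpha_l
    for (int l = 0; l < L; ++l) {
      if (incl[l]) {
        // propose removal: alpha -> 0
        double dll = 0;
        std::vector<double> newll(J);
        for (int j = 0; j < J; ++j) { newll[j] = ll_cell(l, j, 0.0); dll += newll[j] - ll(l, j); }
        double lacc = dll
          + std::log(1.0 - prior_incl) - std::log(prior_incl)
          + R::dnorm(alpha[l], 0.0, sd_rj, 1)     // q(alpha) reappears
          - R::dnorm(alpha[l], 0.0, sd_alpha_prior, 1); // prior density leaves
        if (std::log(unif_rand()) < lacc) {
          incl[l] = false; alpha[l] = 0.0;
          for (int j = 0; j < J; ++j) ll(l, j) = newll[j];
        }
      } else {
        double astar = norm_rand() * sd_rj;
        double dll = 0;
        std::vector<double> newll(J);
        for (int j = 0; j < J; ++j) { newll[j] = ll_cell(l, j, astar); dll += newll[j] - ll(l, j); }
        double lacc = dll
          + std::log(prior_incl) - std::log(1.0 - prior_incl)
          + R::dnorm(astar, 0.0, sd_alpha_prior, 1)
          - R::dnorm(astar, 0.0, sd_rj, 1);
        if (std::log(unif_rand()) < lacc) {
          incl[l] = true; alpha[l] = astar;
          for (int j = 0; j < J; ++j) ll(l, j) = newll[j];
        }
      }
    }
    // record
    if (it >= burn_in && ((it - burn_in + 1) % thin == 0) && si < nsamp) {
      double tl = 0;
      for (int l = 0; l < L; ++l) for (int j = 0; j < J; ++j) tl += ll(l, j);
      for (int l = 0; l < L; ++l) { alpha_s(si, l) = alpha[l]; incl_s(si, l) = incl[l] ? 1 : 0; }
      for (int j = 0; j < J; ++j) beta_s(si, j) = beta[j];
      ll_s[si] = tl;
      ++si;
    }
  }
  return List::create(
    _["alpha"] = alpha_s, _["included"] = incl_s, _["beta"] = beta_s,
    _["loglik"] = ll_s,
    _["acc_rates"] = NumericVector::create(
      _["p"] = try_p > 0 ? acc_p / try_p : NA_REAL,
      _["alpha"] = try_a > 0 ? acc_a / try_a : NA_REAL,
      _["beta"] = try_b > 0 ? acc_b / try_b : NA_REAL));
}
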
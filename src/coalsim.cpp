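#include <Rcpp.h>
using namespace Rcpp;

// Structured coalescent for two demes plus an ancestral deme, with
// generalized stepwise microsatellite mutation. Time is measured in
// generations backwards from the present; all randomness comes from R's
// RNG stream so set.seed() in R gives bit-identical output.

// One locus: returns allele states for n1 + n2 sampled gene copies
// (deme-1 copies first). Migration windows are rows of `epochs`
// (start, end, m1, m2): m1 is the backward rate at which a deme-1
// lineage jumps to deme 2 (= forward immigrant fraction into deme 1).
static void sim_locus(int n1, int n2,
                      double N1, double N2, double Nanc, double t2,
                      const NumericMatrix &epochs,
                      double mu, double pgeom,
                      IntegerVector out, int locus_col_offset,
                      IntegerMatrix &outmat) {
  const int n = n1 + n2;
  const int nnodes = 2 * n - 1;
  std::vector<int> parent(nnodes, -1);
  std::vector<double> blen(nnodes, 0.0);
  std::vector<double> node_time(nnodes, 0.0);

  // active[i] = node id of i-th live lineage; deme[i] = its deme (positional)
  std::vector<int> active(n);
  std::vector<int> deme(n);
  for (int i = 0; i < n; ++i) { active[i] = i; deme[i] = (i < n1) ? 0 : 1; }
  int nact = n, next_node = n;
  double t = 0.0;

  // piecewise-constant event-rate loop. Deme counts k1/k2 are
  // maintained incrementally; phase boundaries (epoch edges and t2)
  // are precomputed so each event costs O(1) plus one short scan to
  // pick the affected lineage(s).
  std::vector<double> bounds;
  for (int e = 0; e < epochs.nrow(); ++e) {
    if (epochs(e, 0) < t2) bounds.push_back(epochs(e, 0));
    if (epochs(e, 1) < t2) bounds.push_back(epochs(e, 1));
  }
  bounds.push_back(t2);
  std::sort(bounds.begin(), bounds.end());
  int k1 = n1, k2 = n2;
  size_t bi = 0;
  while (bi < bounds.size() && bounds[bi] <= t) ++bi;
  double m1 = 0.0, m2 = 0.0;
  bool anc = (t >= t2);
  auto set_rates = [&]() {
    anc = (t >= t2);
    m1 = m2 = 0.0;
    if (!anc)
      for (int e = 0; e < epochs.nrow(); ++e)
        if (t >= epochs(e, 0) && t < epochs(e, 1)) {
          m1 = epochs(e, 2); m2 = epochs(e, 3);
        }
  };
  set_rates();
  // pick the r-th active lineage of deme d (0-based r)
  auto pick = [&](int d, int r) {
    for (int i = 0; i < nact; ++i)
      if (anc || deme[i] == d) { if (r == 0) return i; --r; }
    return nact - 1; // unreachable for valid r
  };
  while (nact > 1) {
    double rc1, rc2, rm1, rm2;
    if (anc) {
      rc1 = nact * (nact - 1) / 2.0 / (2.0 * Nanc);
      rc2 = rm1 = rm2 = 0.0;
    } else {
      rc1 = k1 * (k1 - 1) / 2.0 / (2.0 * N1);
      rc2 = k2 * (k2 - 1) / 2.0 / (2.0 * N2);
      rm1 = k1 * m1;
      rm2 = k2 * m2;
    }
    double tot = rc1 + rc2 + rm1 + rm2;
    double next_b = (bi < bounds.size()) ? bounds[bi] : R_PosInf;
    if (tot <= 0.0) {
      if (next_b == R_PosInf) break; // cannot happen: rates resume at t2
      t = next_b; ++bi; set_rates(); continue;
    }
    double dt = R::rexp(1.0 / tot);
    if (t + dt >= next_b) { t = next_b; ++bi; set_rates(); continue; }
    t += dt;
    double u = unif_rand() * tot;
    if (u < rc1 + rc2) {
      int target = (u < rc1) ? 0 : 1;
      int kd = anc ? nact : (target == 0 ? k1 : k2);
      int a = (int)(unif_rand() * kd);
      int b = (int)(unif_rand() * (kd - 1));
      if (b >= a) ++b;
      int ia = pick(target, a < b ? a : b);
      int ib = pick(target, (a < b ? b : a));
      int na = active[ia], nb = active[ib];
      int np = next_node++;
      parent[na] = np; parent[nb] = np;
      blen[na] = t - node_time[na];
      blen[nb] = t - node_time[nb];
      node_time[np] = t;
      active[ia] = np; deme[ia] = anc ? 0 : target;
      active[ib] = active[nact - 1]; deme[ib] = deme[nact - 1];
      --nact;
      if (!anc) { if (target == 0) --k1; else --k2; }
      else { k1 = nact; k2 = 0; }
    } else {
      int target = (u < rc1 + rc2 + rm1) ? 0 : 1;
      int kd = (target == 0) ? k1 : k2;
      int i = pick(target, (int)(unif_rand() * kd));
      deme[i] = 1 - target;
      if (target == 0) { --k1; ++k2; } else { --k2; ++k1; }
    }
  }
  int root = next_node - 1;

  // drop mutations root -> tips; parent index always > child index
  std::vector<int> state(nnodes, 0);
  state[root] = 100;
  for (int i = root - 1; i >= 0; --i) {
    int s = state[parent[i]];
    int nm = (int)R::rpois(mu * blen[i]);
    for (int m = 0; m < nm; ++m) {
      int step = 1;
      if (pgeom > 0.0) step += (int)R::rgeom(1.0 - pgeom);
      s += (unif_rand() < 0.5) ? step : -step;
    }
    state[i] = s;
  }
  for (int i = 0; i < n; ++i) outmat(i, locus_col_offset) = state[i];
}

//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_simulate_copies(int n1, int n2,
                                  double N1, double N2, double Nanc,
                                  double t2, NumericMatrix epochs,
                                  NumericVector mu, double pgeom) {
  const int L = mu.size();
  IntegerMatrix out(n1 + n2, L);
  IntegerVector dummy(0);
  for (int l = 0; l < L; ++l)
    sim_locus(n1, n2, N1, N2, Nanc, t2, epochs, mu[l], pgeom, dummy, l, out);
  return out;
}

// Two-group AMOVA-style FST on identity distances, summed over loci.
// counts: per-locus allele counts for the two groups.
static double pair_fst(const std::vector<std::map<int,int> > &cnt_a,
                       const std::vector<std::map<int,int> > &cnt_b) {
  const int L = cnt_a.size();
  double SSw = 0.0, SStot = 0.0, Ntot_acc = 0.0, Na_acc = 0.0, Nb_acc = 0.0;
  int used = 0;
  for (int l = 0; l < L; ++l) {
    double Na = 0, Nb = 0, s2a = 0, s2b = 0;
    std::map<int,int> pool(cnt_a[l]);
    for (auto &kv : cnt_a[l]) { Na += kv.second; s2a += (double)kv.second * kv.second; }
    for (auto &kv : cnt_b[l]) { Nb += kv.second; s2b += (double)kv.second * kv.second; pool[kv.first] += kv.second; }
    if (Na < 1 || Nb < 1) continue;
    double N = Na + Nb, s2p = 0;
    for (auto &kv : pool) s2p += (double)kv.second * kv.second;
    SSw += (Na * Na - s2a) / (2.0 * Na) + (Nb * Nb - s2b) / (2.0 * Nb);
    SStot += (N * N - s2p) / (2.0 * N);
    Ntot_acc += N; Na_acc += Na; Nb_acc += Nb;
    ++used;
  }
  if (used == 0 || SStot <= 0) return NA_REAL; // no variation: undefined
  double N = Ntot_acc / used, Na = Na_acc / used, Nb = Nb_acc / used;
  double dfw = N - 2.0, dfa = 1.0;
  if (dfw <= 0) return NA_REAL;
  double MSw = SSw / dfw, MSa = (SStot - SSw) / dfa;
  double n0 = (N - (Na * Na + Nb * Nb) / N) / 1.0;
  double sa = (MSa - MSw) / n0, sw = MSw;
  if (sa < 0) sa = 0;   // negative pair estimate: no differentiation
  double tot = sa + sw;
  if (tot <= 0) return 0.0;
  return sa / tot;
}

//' Summary statistics from a copies x loci allele matrix.
//' pop: 0-based population index per gene copy (row). NA allele = missing.
//' Returns named vector: per pop K,H,V,M then per pair FST, dmu2, shared.
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_sumstats(IntegerMatrix alleles, IntegerVector pop, int npop) {
  const int n = alleles.nrow(), L = alleles.ncol();
  // per pop per locus allele counts
  std::vector<std::vector<std::map<int,int> > > cnt(npop,
      std::vector<std::map<int,int> >(L));
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l)
      if (alleles(i, l) != NA_INTEGER) cnt[pop[i]][l][alleles(i, l)]++;

  int npair = npop * (npop - 1) / 2;
  NumericVector out(4 * npop + 3 * npair);
  CharacterVector nm(out.size());
  // per-population means across loci
  for (int p = 0; p < npop; ++p) {
    double K = 0, H = 0, V = 0, M = 0; int used = 0;
    for (int l = 0; l < L; ++l) {
      double N = 0, s2 = 0, mean = 0, ss = 0;
      int k = cnt[p][l].size();
      if (k == 0) continue;
      int amin = cnt[p][l].begin()->first, amax = cnt[p][l].rbegin()->first;
      for (auto &kv : cnt[p][l]) {
        N += kv.second; s2 += (double)kv.second * kv.second;
        mean += (double)kv.first * kv.second;
      }
      mean /= N;
      for (auto &kv : cnt[p][l]) ss += kv.second * ((double)kv.first - mean) * ((double)kv.first - mean);
      K += k;
      H += 1.0 - s2 / (N * N);
      V += (N > 1) ? ss / (N - 1) : 0.0;
      M += (double)k / (amax - amin + 1.0);
      ++used;
    }
    if (used > 0) { K /= used; H /= used; V /= used; M /= used; }
    out[4 * p] = K; out[4 * p + 1] = H; out[4 * p + 2] = V; out[4 * p + 3] = M;
    std::string s = std::to_string(p + 1);
    nm[4 * p] = "K_" + s; nm[4 * p + 1] = "H_" + s;
    nm[4 * p + 2] = "V_" + s; nm[4 * p + 3] = "M_" + s;
  }
  int o = 4 * npop, pr = 0;
  for (int a = 0; a < npop; ++a) for (int b = a + 1; b < npop; ++b, ++pr) {
    double fst = pair_fst(cnt[a], cnt[b]);
    double dmu2 = 0, shared = 0; int used = 0;
    for (int l = 0; l < L; ++l) {
      double Na = 0, Nb = 0, ma = 0, mb = 0;
      for (auto &kv : cnt[a][l]) { Na += kv.second; ma += (double)kv.first * kv.second; }
      for (auto &kv : cnt[b][l]) { Nb += kv.second; mb += (double)kv.first * kv.second; }
      if (Na < 1 || Nb < 1) continue;
      ma /= Na; mb /= Nb;
      dmu2 += (ma - mb) * (ma - mb);
      int inter = 0, uni = cnt[b][l].size();
      for (auto &kv : cnt[a][l]) {
        if (cnt[b][l].count(kv.first)) ++inter; else ++uni;
      }
      shared += uni > 0 ? (double)inter / uni : 0.0;
      ++used;
    }
    if (used > 0) { dmu2 /= used; shared /= used; }
    out[o + 3 * pr]     = ISNAN(fst) ? NA_REAL : fst;
    out[o + 3 * pr + 1] = dmu2;
    out[o + 3 * pr + 2] = shared;
    std::string s = std::to_string(a + 1) + std::to_string(b + 1);
    nm[o + 3 * pr] = "FST_" + s; nm[o + 3 * pr + 1] = "dmu2_" + s;
    nm[o + 3 * pr + 2] = "shared_" + s;
  }
  out.names() = nm;
  return out;
}
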
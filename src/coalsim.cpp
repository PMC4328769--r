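#include <Rcpp.h>
using namespace Rcpp;

// Backward-time n-coalescent with piecewise population merges.
//
// Node numbering: tips 0..n-1 (time 0), internal nodes n..2n-2 created in
// order of increasing coalescence time, so the root is node 2n-2 and every
// parent has a larger index than its children. All times in generations.
// Population labels are 0-based indices into two_ne; two_ne[r] = 2 * Ne of
// the marker (so the pairwise coalescence rate within r is 1/two_ne[r]).

static void sim_tree_core(const IntegerVector& sample_region, int n_labels,
                          const NumericVector& two_ne,
                          const NumericVector& ev_time,
                          const IntegerVector& ev_from,
                          const IntegerVector& ev_to,
                          std::vector<int>& parent, std::vector<double>& ntime) {
  const int n = sample_region.size();
  const int nnode = 2 * n - 1;
  parent.assign(nnode, -1);
  ntime.assign(nnode, 0.0);
  std::vector< std::vector<int> > pool(n_labels);
  for (int i = 0; i < n; ++i) pool[sample_region[i]].push_back(i);

  double t = 0.0;
  int ev = 0;
  const int nev = ev_time.size();
  int next_node = n;
  int active = n;
  std::vector<double> rate(n_labels);

  while (active > 1) {
    double tot = 0.0;
    for (int r = 0; r < n_labels; ++r) {
      const double k = (double) pool[r].size();
      rate[r] = (k >= 2.0) ? k * (k - 1.0) / 2.0 / two_ne[r] : 0.0;
      tot += rate[r];
    }
    const double tnext = (ev < nev) ? ev_time[ev] : R_PosInf;
    const double w = (tot > 0.0) ? R::rexp(1.0 / tot) : R_PosInf;
    if (t + w < tnext) {
      t += w;
      double u = R::runif(0.0, tot);
      int r = 0;
      while (r < n_labels - 1 && u >= rate[r]) { u -= rate[r]; ++r; }
      while (rate[r] <= 0.0 && r > 0) --r;  // numeric guard
      const int k = (int) pool[r].size();
      int i = (int) (R::unif_rand() * k); if (i >= k) i = k - 1;
      int j = (int) (R::unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      const int a = pool[r][i], b = pool[r][j];
      const int v = next_node++;
      parent[a] = v; parent[b] = v; ntime[v] = t;
      // swap-remove the larger index first, then the smaller, then add v
      const int hi = (i > j) ? i : j, lo = (i > j) ? j : i;
      pool[r][hi] = pool[r].back(); pool[r].pop_back();
      pool[r][lo] = pool[r].back(); pool[r].pop_back();
      pool[r].push_back(v);
      --active;
    } else {
      if (ev >= nev)
        stop("disconnected history: lineages remain in separate populations after all events");
      t = tnext;
      const int from = ev_from[ev], to = ev_to[ev];
      for (size_t x = 0; x < pool[from].size(); ++x) pool[to].push_back(pool[from][x]);
      pool[from].clear();
      ++ev;
    }
  }
}

// [[Rcpp::export]]
List cpp_coal_tree(IntegerVector sample_region, int n_labels, NumericVector two_ne,
                   NumericVector ev_time, IntegerVector ev_from, IntegerVector ev_to) {
  std::vector<int> parent;
  std::vector<double> ntime;
  sim_tree_core(sample_region, n_labels, two_ne, ev_time, ev_from, ev_to, parent, ntime);
  return List::create(_["parent"] = wrap(parent), _["node_time"] = wrap(ntime),
                      _["n_tip"] = (int) sample_region.size());
}

static inline int draw_base(const NumericVector& base_freq) {
  double u = R::unif_rand();
  for (int b = 0; b < 3; ++b) {
    u -= base_freq[b];
    if (u < 0.0) return b + 1;
  }
  return 4;
}

// Finite-sites 4-state mutation on the variable sites of one locus.
// Mutations per branch ~ Poisson(mu * L_var * branch_length); mutated site
// uniform over variable sites, new state uniform over the other three.
static void mutate_core(const std::vector<int>& parent, const std::vector<double>& ntime,
                        int ntip, int L_var, double mu, const NumericVector& base_freq,
                        IntegerMatrix& tips) {
  const int nnode = (int) parent.size();
  if (L_var == 0) return;
  IntegerMatrix seq(nnode, L_var);
  const int root = nnode - 1;
  for (int s = 0; s < L_var; ++s) seq(root, s) = draw_base(base_freq);
  for (int v = nnode - 2; v >= 0; --v) {
    const int p = parent[v];
    for (int s = 0; s < L_var; ++s) seq(v, s) = seq(p, s);
    const double len = ntime[p] - ntime[v];
    const int nmut = (int) R::rpois(mu * (double) L_var * len);
    for (int m = 0; m < nmut; ++m) {
      int s = (int) (R::unif_rand() * L_var); if (s >= L_var) s = L_var - 1;
      int d = 1 + (int) (R::unif_rand() * 3.0); if (d > 3) d = 3;
      seq(v, s) = ((seq(v, s) - 1 + d) % 4) + 1;
    }
  }
  for (int i = 0; i < ntip; ++i)
    for (int s = 0; s < L_var; ++s) tips(i, s) = seq(i, s);
}

// [[Rcpp::export]]
IntegerMatrix cpp_mutate_tree(IntegerVector parent, NumericVector node_time, int n_tip,
                              int L_var, double mu, NumericVector base_freq) {
  std::vector<int> par(parent.begin(), parent.end());
  std::vector<double> ntime(node_time.begin(), node_time.end());
  IntegerMatrix tips(n_tip, L_var);
  mutate_core(par, ntime, n_tip, L_var, mu, base_freq, tips);
  return tips;
}

// Simulate n_loci independent genealogies + mutations in one call.
// Returns an n x (n_loci * L_var) matrix of states 1..4 (columns grouped by
// locus). Used by the dataset simulator and the ABC reference-table builder.
// [[Rcpp::export]]
IntegerMatrix cpp_sim_loci(int n_loci, IntegerVector sample_region, int n_labels,
                           NumericVector two_ne, NumericVector ev_time,
                           IntegerVector ev_from, IntegerVector ev_to,
                           int L_var, double mu, NumericVector base_freq) {
  const int n = sample_region.size();
  IntegerMatrix out(n, n_loci * L_var);
  std::vector<int> parent;
  std::vector<double> ntime;
  IntegerMatrix tips(n, L_var);
  for (int l = 0; l < n_loci; ++l) {
    sim_tree_core(sample_region, n_labels, two_ne, ev_time, ev_from, ev_to, parent, ntime);
    mutate_core(parent, ntime, n, L_var, mu, base_freq, tips);
    for (int i = 0; i < n; ++i)
      for (int s = 0; s < L_var; ++s)
        out(i, l * L_var + s) = tips(i, s);
  }
  return out;
}

// Pairwise differences with pairwise deletion; 0 or NA codes mean missing.
// Returns list(diff = n x n counts, comp = n x n comparable-site counts).
// [[Rcpp::export]]
List cpp_pair_diffs(IntegerMatrix seqs) {
  const int n = seqs.nrow(), L = seqs.ncol();
  IntegerMatrix diff(n, n), comp(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = 0, c = 0;
      for (int s = 0; s < L; ++s) {
        const int a = seqs(i, s), b = seqs(j, s);
        if (a == NA_INTEGER || b == NA_INTEGER || a == 0 || b == 0) continue;
        ++c;
        if (a != b) ++d;
      }
      diff(i, j) = d; diff(j, i) = d;
      comp(i, j) = c; comp(j, i) = c;
    }
  }
  return List::create(_["diff"] = diff, _["comp"] = comp);
}
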
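#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Topological generation numbers for a parent-pointer forest.
// father/mother are 0-based indices, NA_INTEGER when absent.
// Returns generation per individual (founders = 0); -1 marks individuals
// that were never reached, i.e. individuals on (or below) a parental cycle.
// [[Rcpp::export]]
IntegerVector cpp_generation(IntegerVector father, IntegerVector mother) {
  int n = father.size();
  std::vector<int> gen(n, -1), npar(n, 0);
  std::vector<std::vector<int>> children(n);
  for (int i = 0; i < n; ++i) {
    if (father[i] != NA_INTEGER) { children[father[i]].push_back(i); ++npar[i]; }
    if (mother[i] != NA_INTEGER) { children[mother[i]].push_back(i); ++npar[i]; }
  }
  std::vector<int> queue;
  for (int i = 0; i < n; ++i) if (npar[i] == 0) { gen[i] = 0; queue.push_back(i); }
  for (size_t q = 0; q < queue.size(); ++q) {
    int v = queue[q];
    for (int c : children[v]) {
      int pg = gen[v] + 1;
      if (pg > gen[c]) gen[c] = pg;           // provisional max over parents
      if (--npar[c] == 0) queue.push_back(c);
      else if (npar[c] < 0) stop("internal error: negative in-degree");
    }
  }
  // individuals with unresolved parents keep gen as provisional; mark unreached
  IntegerVector out(n);
  std::vector<bool> done(n, false);
  for (int v : queue) done[v] = true;
  for (int i = 0; i < n; ++i) out[i] = done[i] ? gen[i] : -1;
  return out;
}

// Full Malecot kinship matrix. `ord` is a 0-based topological order
// (every parent before its children). phi(i,i) = (1 + phi(f_i, m_i)) / 2.
// [[Rcpp::export]]
NumericMatrix cpp_kinship_matrix(IntegerVector father, IntegerVector mother,
                                 IntegerVector ord) {
  int n = father.size();
  NumericMatrix K(n, n);
  std::vector<int> pos(n, -1);  // processing rank
  for (int r = 0; r < n; ++r) pos[ord[r]] = r;
  for (int r = 0; r < n; ++r) {
    int i = ord[r];
    int f = father[i], m = mother[i];
    double self = 0.5;
    if (f != NA_INTEGER && m != NA_INTEGER) self = 0.5 * (1.0 + K(f, m));
    K(i, i) = self;
    for (int s = 0; s < r; ++s) {
      int j = ord[s];
      double v = 0.0;
      if (f != NA_INTEGER) v += 0.5 * K(f, j);
      if (m != NA_INTEGER) v += 0.5 * K(m, j);
      K(i, j) = v;
      K(j, i) = v;
    }
  }
  return K;
}

// Ancestor table: for each individual, all ancestors (self included at depth
// 0) reachable within max_depth meioses, with the minimum meiotic depth.
// Computed by dynamic programming in topological order: an individual's
// list is the sorted merge of the parents' lists shifted one meiosis up.
// Flattened CSR layout: ptr (n+1), idx, depth; idx sorted within individual.
// [[Rcpp::export]]
List cpp_ancestor_table(IntegerVector father, IntegerVector mother,
                        IntegerVector ord, int max_depth) {
  int n = father.size();
  std::vector<std::vector<std::pair<int,int>>> anc(n);
  for (int r = 0; r < n; ++r) {
    int i = ord[r];
    int f = father[i], m = mother[i];
    const std::vector<std::pair<int,int>> empty;
    const auto &af = (f != NA_INTEGER) ? anc[f] : empty;
    const auto &am = (m != NA_INTEGER) ? anc[m] : empty;
    std::vector<std::pair<int,int>> out;
    out.reserve(af.size() + am.size() + 1);
    size_t a = 0, b = 0;
    while (a < af.size() || b < am.size()) {
      int node, d;
      if (b >= am.size() || (a < af.size() && af[a].first < am[b].first)) {
        node = af[a].first; d = af[a].second + 1; ++a;
      } else if (a >= af.size() || am[b].first < af[a].first) {
        node = am[b].first; d = am[b].second + 1; ++b;
      } else {
        node = af[a].first;
        d = std::min(af[a].second, am[b].second) + 1;
        ++a; ++b;
      }
      if (d <= max_depth) out.push_back({node, d});
    }
    out.push_back({i, 0});
    std::sort(out.begin(), out.end());
    anc[i] = out;
  }
  int total = 0;
  for (int i = 0; i < n; ++i) total += anc[i].size();
  IntegerVector ptr(n + 1), idx(total), dep(total);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    ptr[i] = k;
    for (auto &p : anc[i]) { idx[k] = p.first; dep[k] = p.second; ++k; }
  }
  ptr[n] = k;
  return List::create(_["ptr"] = ptr, _["idx"] = idx, _["depth"] = dep);
}

static inline int pair_distance(const int *idx, const int *dep,
                                int a0, int a1, int b0, int b1) {
  // merge-intersect two sorted ancestor slices; min of summed depths
  int best = -1;
  int i = a0, j = b0;
  while (i < a1 && j < b1) {
    if (idx[i] < idx[j]) ++i;
    else if (idx[i] > idx[j]) ++j;
    else {
      int d = dep[i] + dep[j];
      if (best < 0 || d < best) best = d;
      ++i; ++j;
    }
  }
  return best; // -1 = no common ancestor within the depth horizon
}

// Minimum meiotic distance for each pair (a[k], b[k]); -1 when unrelated
// within the table's depth horizon.
// [[Rcpp::export]]
IntegerVector cpp_pair_distances(IntegerVector a, IntegerVector b,
                                 IntegerVector ptr, IntegerVector idx,
                                 IntegerVector depth) {
  int m = a.size();
  IntegerVector out(m);
  const int *pidx = INTEGER(idx), *pdep = INTEGER(depth);
  for (int k = 0; k < m; ++k) {
    out[k] = pair_distance(pidx, pdep, ptr[a[k]], ptr[a[k] + 1],
                           ptr[b[k]], ptr[b[k] + 1]);
  }
  return out;
}

// Kinship sum over unordered pairs of `members`, binned by minimum meiotic
// distance. Pairs with distance outside [min_d, max_d] (or unrelated within
// the horizon) contribute nothing. Returns a vector of length max_d whose
// d-th entry is the kinship sum of pairs classified at distance d.
// [[Rcpp::export]]
NumericVector cpp_kin_by_distance(IntegerVector members, NumericMatrix K,
                                  IntegerVector ptr, IntegerVector idx,
                                  IntegerVector depth,
                                  int min_d, int max_d) {
  int m = members.size();
  NumericVector bins(max_d);
  const int *pidx = INTEGER(idx), *pdep = INTEGER(depth);
  for (int u = 0; u < m; ++u) {
    int i = members[u];
    for (int v = u + 1; v < m; ++v) {
      int j = members[v];
      if (K(i, j) == 0.0) continue;      // unrelated: contributes 0 anyway
      int d = pair_distance(pidx, pdep, ptr[i], ptr[i + 1], ptr[j], ptr[j + 1]);
      if (d < min_d || d > max_d || d < 0) continue;
      bins[d - 1] += K(i, j);
    }
  }
  return bins;
}

// --- indirect kinship machinery (gene-flow factorization A = T D T') ---
//
// Inbreeding coefficients for everyone by the sparse-climb identity
// A_jj = u' D u with u = T' e_j supported on j's ancestors, processed
// one generation at a time from j upward (Meuwissen-Luo style). `d` is
// the within-family Mendelian-sampling variance diagonal, which only
// depends on parental inbreeding already available in topological order.
struct GeneFlow {
  int n;
  const int *father, *mother, *gen;
  int max_gen;
  std::vector<double> F;   // inbreeding coefficient
  std::vector<double> d;   // Mendelian sampling diagonal
  GeneFlow(const int *f, const int *m, const int *g, int n_)
      : n(n_), father(f), mother(m), gen(g) {
    max_gen = 0;
    for (int i = 0; i < n; ++i) if (g[i] > max_gen) max_gen = g[i];
    F.assign(n, 0.0);
    d.assign(n, 1.0);
    std::vector<double> u(n, 0.0);
    // topological sweep: F and d filled founders-first
    std::vector<int> topo(n);
    std::vector<int> cnt(max_gen + 2, 0);
    for (int i = 0; i < n; ++i) ++cnt[g[i] + 1];
    for (int k = 1; k <= max_gen + 1; ++k) cnt[k] += cnt[k - 1];
    for (int i = 0; i < n; ++i) topo[cnt[g[i]]++] = i;
    std::vector<int> touched;
    for (int t = 0; t < n; ++t) {
      int j = topo[t];
      int fj = father[j], mj = mother[j];
      if (fj == NA_INTEGER && mj == NA_INTEGER) { d[j] = 1.0; F[j] = 0.0; continue; }
      if (fj == NA_INTEGER) d[j] = 0.75 - 0.25 * F[mj];
      else if (mj == NA_INTEGER) d[j] = 0.75 - 0.25 * F[fj];
      else d[j] = 0.5 - 0.25 * (F[fj] + F[mj]);
      if (fj == NA_INTEGER || mj == NA_INTEGER) { F[j] = 0.0; continue; }
      // F_j = phi(father, mother) = (u' D u with u = T' e_f evaluated at m)?
      // cheaper: A_jj = sum d_v u_v^2 with u = T' e_j
      double ajj = climb(j, u, touched);
      F[j] = ajj - 1.0;
      for (int v : touched) u[v] = 0.0;
      touched.clear();
    }
  }
  // u = T' e_j over ancestors of j (generation-bucketed downward sweep);
  // returns A_jj = sum_v d_v u_v^2; `touched` collects support for reset
  double climb(int j, std::vector<double> &u, std::vector<int> &touched) const {
    std::vector<std::vector<int>> bucket(gen[j] + 1);
    u[j] = 1.0;
    touched.push_back(j);
    bucket[gen[j]].push_back(j);
    double ajj = 0.0;
    for (int gg = gen[j]; gg >= 0; --gg) {
      for (size_t q = 0; q < bucket[gg].size(); ++q) {
        int v = bucket[gg][q];
        ajj += d[v] * u[v] * u[v];
        int fv = father[v], mv = mother[v];
        if (fv != NA_INTEGER) {
          if (u[fv] == 0.0) { touched.push_back(fv); bucket[gen[fv]].push_back(fv); }
          u[fv] += 0.5 * u[v];
        }
        if (mv != NA_INTEGER) {
          if (u[mv] == 0.0) { touched.push_back(mv); bucket[gen[mv]].push_back(mv); }
          u[mv] += 0.5 * u[v];
        }
      }
    }
    return ajj;
  }
  // full column w = A e_j = T D (T' e_j): sparse climb then dense forward
  // pass in topological order. phi(i, j) = w[i] / 2.
  void column(int j, const std::vector<int> &topo,
              std::vector<double> &u, std::vector<int> &touched,
              std::vector<double> &w) const {
    climb(j, u, touched);
    for (int t = 0; t < n; ++t) {
      int i = topo[t];
      double wi = d[i] * u[i];
      if (father[i] != NA_INTEGER) wi += 0.5 * w[father[i]];
      if (mother[i] != NA_INTEGER) wi += 0.5 * w[mother[i]];
      w[i] = wi;
    }
    for (int v : touched) u[v] = 0.0;
    touched.clear();
  }
};

// Distance-binned kinship sums for many member sets at once. Kinship is
// exact full-pedigree Malecot kinship (inbreeding loops included) computed
// by the indirect gene-flow method: one O(pedigree) column solve per
// distinct set member, shared across sets. Row s of the result holds, for
// set s, the kinship sum of its pairs classified at each minimum meiotic
// distance 1..max_d; pairs unrelated within the horizon contribute 0.
// [[Rcpp::export]]
NumericMatrix cpp_gif_sets(IntegerVector father, IntegerVector mother,
                           IntegerVector gen,
                           IntegerVector ptr, IntegerVector idx,
                           IntegerVector depth, List sets, int max_d) {
  int S = sets.size();
  int n = father.size();
  NumericMatrix bins(S, max_d);
  const int *pidx = INTEGER(idx), *pdep = INTEGER(depth);
  const int *pf = INTEGER(father), *pm = INTEGER(mother), *pg = INTEGER(gen);
  GeneFlow gf(pf, pm, pg, n);
  // topological order (founders first), counting sort by generation
  std::vector<int> topo(n), cnt(gf.max_gen + 2, 0);
  for (int i = 0; i < n; ++i) ++cnt[pg[i] + 1];
  for (int k = 1; k <= gf.max_gen + 1; ++k) cnt[k] += cnt[k - 1];
  for (int i = 0; i < n; ++i) topo[cnt[pg[i]]++] = i;
  // membership lists: which (set, slot) each distinct individual occupies
  std::unordered_map<int, std::vector<int>> member_sets;
  std::vector<std::vector<int>> mem(S);
  for (int s = 0; s < S; ++s) {
    IntegerVector v = sets[s];
    mem[s].assign(v.begin(), v.end());
    for (int i : mem[s]) member_sets[i].push_back(s);
  }
  std::vector<double> u(n, 0.0), w(n, 0.0);
  std::vector<int> touched;
  for (auto &kv : member_sets) {
    int j = kv.first;
    gf.column(j, topo, u, touched, w);
    for (int s : kv.second) {
      for (int i : mem[s]) {
        if (i >= j) continue;           // each unordered pair once
        double kin = 0.5 * w[i];
        if (kin <= 0.0) continue;
        int dd = pair_distance(pidx, pdep, ptr[i], ptr[i + 1],
                               ptr[j], ptr[j + 1]);
        if (dd < 1 || dd > max_d) continue;
        bins(s, dd - 1) += kin;
      }
    }
  }
  return bins;
}

// Transitive descendant closure of `roots` through the child relation,
// excluding the roots themselves. 0-based indices.
// [[Rcpp::export]]
IntegerVector cpp_descendants(IntegerVector father, IntegerVector mother,
                              IntegerVector roots) {
  int n = father.size();
  std::vector<std::vector<int>> children(n);
  for (int i = 0; i < n; ++i) {
    if (father[i] != NA_INTEGER) children[father[i]].push_back(i);
    if (mother[i] != NA_INTEGER) children[mother[i]].push_back(i);
  }
  std::vector<bool> seen(n, false), isroot(n, false);
  std::vector<int> queue;
  for (int r : roots) { isroot[r] = true; }
  for (int r : roots) for (int c : children[r]) if (!seen[c]) { seen[c] = true; queue.push_back(c); }
  for (size_t q = 0; q < queue.size(); ++q)
    for (int c : children[queue[q]])
      if (!seen[c]) { seen[c] = true; queue.push_back(c); }
  std::vector<int> out;
  for (int v : queue) if (!isroot[v]) out.push_back(v);
  return wrap(out);
}
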
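#include <Rcpp.h>
using namespace Rcpp;

// Connected edge-subgraph machinery for the Kier-Hall style descriptors.
//
// Edges of the molecular graph are vertices of its line graph; connected
// m-edge subgraphs are enumerated by the ESU scheme (Wernicke 2006) applied
// to the line graph: each subgraph is generated exactly once, anchored at
// its smallest edge index, extending only with larger indices whose first
// contact with the growing set is the edge being added. Every recursion
// node is itself a distinct connected subset, so all orders 1..m_max come
// out of a single sweep.

namespace {

struct Census {
  // [type][m]: counts and accumulated products
  // types: 0 = P, 1 = C, 2 = PC, 3 = Ch
  double cnt[4][8] = {{0}};
  double atom_sum[4][8] = {{0}};
  double edge_sum[4][8] = {{0}};
};

struct Ctx {
  int n_edges, n_atoms, m_max;
  const int *bi, *bj;                 // 0-based endpoints per edge
  std::vector<std::vector<int>> enb;  // edge adjacency (shared atom)
  const double *atom_val;             // per-atom factor (e.g. dv^-1/2)
  const double *edge_val;             // per-edge factor (e.g. eps^-1/2)
  bool collect;                       // also store edge sets
  std::vector<std::vector<int>> sets;
  Census census;

  std::vector<int> sub;
  std::vector<int> atom_deg;          // subgraph degree per atom
  std::vector<int> atom_stamp;        // stamp marker
  std::vector<int> touched;           // atoms touched by current sub

  int classify(int m) const {
    int na = (int)touched.size();
    if (m >= na) return 3;            // connected with a cycle -> Ch
    int nbig = 0;
    bool allleaf = true;
    int center = -1;
    for (int a : touched) {
      int d = atom_deg[a];
      if (d >= 3) { nbig++; center = a; }
    }
    if (nbig == 0) return 0;          // P
    if (nbig == 1) {
      for (int a : touched)
        if (a != center && atom_deg[a] != 1) { allleaf = false; break; }
      if (allleaf) return 1;          // C (star)
      return 2;                       // PC
    }
    return 2;                         // PC
  }

  void emit() {
    int m = (int)sub.size();
    int type = classify(m);
    census.cnt[type][m] += 1.0;
    double ap = 1.0, ep = 1.0;
    for (int a : touched) ap *= atom_val[a];
    for (int e : sub) ep *= edge_val[e];
    census.atom_sum[type][m] += ap;
    census.edge_sum[type][m] += ep;
    if (collect) sets.push_back(sub);
  }

  void add_edge(int e, std::vector<int> &newly) {
    sub.push_back(e);
    int ends[2] = {bi[e], bj[e]};
    for (int a : ends) {
      if (atom_stamp[a] == 0) {
        atom_stamp[a] = 1;
        touched.push_back(a);
        newly.push_back(a);
      }
      atom_deg[a]++;
    }
  }

  void remove_edge(int e, const std::vector<int> &newly) {
    sub.pop_back();
    atom_deg[bi[e]]--;
    atom_deg[bj[e]]--;
    for (int a : newly) {
      atom_stamp[a] = 0;
      touched.pop_back();
    }
  }

  void extend(int anchor, std::vector<int> ext,
              std::vector<char> &seen) {
    emit();
    if ((int)sub.size() >= m_max) return;
    while (!ext.empty()) {
      int w = ext.back();
      ext.pop_back();
      std::vector<int> ext2 = ext;
      std::vector<int> marked;
      for (int u : enb[w]) {
        if (u > anchor && !seen[u]) {
          seen[u] = 1;
          marked.push_back(u);
          ext2.push_back(u);
        }
      }
      std::vector<int> newly;
      add_edge(w, newly);
      extend(anchor, ext2, seen);
      remove_edge(w, newly);
      for (int u : marked) seen[u] = 0;
    }
  }

  void run() {
    std::vector<char> seen(n_edges, 0);
    for (int v = 0; v < n_edges; ++v) {
      seen[v] = 1;
      std::vector<int> ext, marked;
      for (int u : enb[v])
        if (u > v && !seen[u]) {
          seen[u] = 1;
          marked.push_back(u);
          ext.push_back(u);
        }
      std::vector<int> newly;
      add_edge(v, newly);
      extend(v, ext, seen);
      remove_edge(v, newly);
      for (int u : marked) seen[u] = 0;
      seen[v] = 0;
    }
  }
};

Ctx make_ctx(IntegerVector bi, IntegerVector bj, int n_atoms, int m_max,
             NumericVector atom_val, NumericVector edge_val, bool collect) {
  Ctx c;
  c.n_edges = bi.size();
  c.n_atoms = n_atoms;
  c.m_max = m_max;
  c.bi = INTEGER(bi);
  c.bj = INTEGER(bj);
  c.atom_val = REAL(atom_val);
  c.edge_val = REAL(edge_val);
  c.collect = collect;
  c.enb.assign(c.n_edges, {});
  for (int e = 0; e < c.n_edges; ++e)
    for (int f = e + 1; f < c.n_edges; ++f)
      if (bi[e] == bi[f] || bi[e] == bj[f] ||
          bj[e] == bi[f] || bj[e] == bj[f]) {
        c.enb[e].push_back(f);
        c.enb[f].push_back(e);
      }
  c.atom_deg.assign(n_atoms, 0);
  c.atom_stamp.assign(n_atoms, 0);
  return c;
}

} // namespace

// [[Rcpp::export]]
DataFrame subgraph_census_cpp(IntegerVector bi, IntegerVector bj,
                              int n_atoms, int m_max,
                              NumericVector atom_val,
                              NumericVector edge_val) {
  if (m_max < 1 || m_max > 7) stop("m_max must be in 1..7");
  Ctx c = make_ctx(bi, bj, n_atoms, m_max, atom_val, edge_val, false);
  c.run();
  std::vector<std::string> type_lab = {"P", "C", "PC", "Ch"};
  std::vector<std::string> type_out;
  std::vector<int> m_out;
  std::vector<double> cnt_out, as_out, es_out;
  for (int t = 0; t < 4; ++t)
    for (int m = 1; m <= m_max; ++m) {
      type_out.push_back(type_lab[t]);
      m_out.push_back(m);
      cnt_out.push_back(c.census.cnt[t][m]);
      as_out.push_back(c.census.atom_sum[t][m]);
      es_out.push_back(c.census.edge_sum[t][m]);
    }
  return DataFrame::create(_["type"] = type_out, _["m"] = m_out,
                           _["count"] = cnt_out,
                           _["atom_sum"] = as_out,
                           _["edge_sum"] = es_out,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List enumerate_subgraphs_cpp(IntegerVector bi, IntegerVector bj,
                             int n_atoms, int m_max) {
  if (m_max < 1 || m_max > 7) stop("m_max must be in 1..7");
  NumericVector ones_a(n_atoms, 1.0), ones_e(bi.size(), 1.0);
  Ctx c = make_ctx(bi, bj, n_atoms, m_max, ones_a, ones_e, true);
  c.run();
  List out(c.sets.size());
  for (size_t i = 0; i < c.sets.size(); ++i) {
    std::vector<int> s = c.sets[i];
    std::sort(s.begin(), s.end());
    for (int &x : s) x += 1;  // 1-based edge indices for R
    out[i] = wrap(s);
  }
  return out;
}
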
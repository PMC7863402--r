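#include <Rcpp.h>
#include <string>
#include <vector>
#include <queue>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// Partial-order alignment: weighted DAG of bases; sequences are added by
// affine-gap alignment against the graph (DP in topological order) and the
// consensus is the heaviest start-to-end path.

static const int NEG = std::numeric_limits<int>::min() / 4;

struct PGraph {
  std::string base;                     // one letter per node
  std::vector<int> support;             // sequences visiting the node
  std::vector<int> start_w, end_w;      // virtual start/end edge weights
  std::vector<int> col;                 // alignment column id (ring) of the node
  std::vector<std::vector<std::pair<int,int>>> out; // (to, weight)
  std::vector<int> topo;                // topological order (node ids)
  std::vector<int> topo_pos;            // node id -> rank in topo
  int next_col = 0;

  int n() const { return (int) base.size(); }

  void rebuild_topo() {
    int N = n();
    std::vector<int> indeg(N, 0);
    for (int u = 0; u < N; ++u)
      for (auto &e : out[u]) indeg[e.first]++;
    std::priority_queue<int, std::vector<int>, std::greater<int>> q;
    for (int v = 0; v < N; ++v) if (indeg[v] == 0) q.push(v);
    topo.clear(); topo.reserve(N);
    while (!q.empty()) {
      int v = q.top(); q.pop();
      topo.push_back(v);
      for (auto &e : out[v]) if (--indeg[e.first] == 0) q.push(e.first);
    }
    if ((int) topo.size() != N) stop("internal error: POA graph is not a DAG");
    topo_pos.assign(N, -1);
    for (int r = 0; r < N; ++r) topo_pos[topo[r]] = r;
  }

  int find_edge(int u, int v) const {
    for (size_t e = 0; e < out[u].size(); ++e)
      if (out[u][e].first == v) return (int) e;
    return -1;
  }

  void bump_edge(int u, int v) {
    int e = find_edge(u, v);
    if (e >= 0) out[u][e].second++;
    else out[u].push_back(std::make_pair(v, 1));
  }

  int add_node(char b, int column) {
    base.push_back(b);
    support.push_back(0);
    start_w.push_back(0);
    end_w.push_back(0);
    if (column < 0) column = next_col++;
    col.push_back(column);
    out.push_back(std::vector<std::pair<int,int>>());
    return n() - 1;
  }
};

// ---------------------------------------------------------------------------
// list <-> struct
// ---------------------------------------------------------------------------

static PGraph graph_from_list(List g) {
  PGraph pg;
  pg.base = as<std::string>(g["bases"]);
  pg.support = as<std::vector<int>>(g["support"]);
  pg.start_w = as<std::vector<int>>(g["start_w"]);
  pg.end_w = as<std::vector<int>>(g["end_w"]);
  pg.col = as<std::vector<int>>(g["column"]);
  pg.next_col = pg.col.empty() ? 0 : (*std::max_element(pg.col.begin(), pg.col.end()) + 1);
  IntegerVector ef = g["edge_from"], et = g["edge_to"], ew = g["edge_weight"];
  pg.out.assign(pg.n(), std::vector<std::pair<int,int>>());
  for (int i = 0; i < ef.size(); ++i)
    pg.out[ef[i]].push_back(std::make_pair(et[i], ew[i]));
  pg.rebuild_topo();
  return pg;
}

static List graph_to_list(const PGraph &pg) {
  std::vector<int> ef, et, ew;
  for (int u = 0; u < pg.n(); ++u)
    for (auto &e : pg.out[u]) { ef.push_back(u); et.push_back(e.first); ew.push_back(e.second); }
  return List::create(
    _["bases"] = pg.base, _["support"] = pg.support,
    _["start_w"] = pg.start_w, _["end_w"] = pg.end_w,
    _["column"] = pg.col,
    _["edge_from"] = ef, _["edge_to"] = et, _["edge_weight"] = ew,
    _["topo"] = pg.topo);
}

// [[Rcpp::export(name = ".poa_empty_cpp")]]
List poa_empty_cpp() {
  PGraph pg;
  pg.rebuild_topo();
  return graph_to_list(pg);
}

// ---------------------------------------------------------------------------
// alignment of a sequence to the graph (global, affine gaps)
// ---------------------------------------------------------------------------

struct PoaAln {
  int score;
  std::vector<int> col_node, col_qpos;  // -1 = gap
};

static PoaAln poa_align(const PGraph &pg, const std::string &seq,
                        int match, int mismatch, int gap_open, int gap_extend) {
  int N = pg.n(), m = (int) seq.size();
  if (m == 0) stop("cannot align an empty sequence to a POA graph");
  PoaAln res;
  if (N == 0) {           // trivial all-insertion path
    res.score = 0;
    for (int j = 0; j < m; ++j) { res.col_node.push_back(-1); res.col_qpos.push_back(j); }
    return res;
  }

  // in-edges and S-predecessor flags
  std::vector<std::vector<int>> preds(N);
  std::vector<int> indeg(N, 0);
  for (int u = 0; u < N; ++u)
    for (auto &e : pg.out[u]) { preds[e.first].push_back(u); indeg[e.first]++; }
  for (int v = 0; v < N; ++v)   // deterministic pred order: by topo rank
    std::sort(preds[v].begin(), preds[v].end(),
              [&](int a, int b) { return pg.topo_pos[a] < pg.topo_pos[b]; });

  size_t W = (size_t) m + 1;
  std::vector<int> M((size_t) N * W, NEG), D((size_t) N * W, NEG), I((size_t) N * W, NEG);
  // traceback: predecessor node (-2 = virtual start) and state (0=M,1=D,2=I)
  std::vector<int> pM((size_t) N * W, -3), pD((size_t) N * W, -3), pI((size_t) N * W, -3);
  std::vector<signed char> sM((size_t) N * W, -1), sD((size_t) N * W, -1), sI((size_t) N * W, -1);
  auto S_all = [&](int j) { return j == 0 ? 0 : gap_open + (j - 1) * gap_extend; };

  for (int r = 0; r < N; ++r) {
    int v = pg.topo[r];
    bool from_S = (indeg[v] == 0) || (pg.start_w[v] > 0);
    size_t row = (size_t) v * W;
    for (int j = 0; j <= m; ++j) {
      // M: seq[j-1] aligned to node v
      if (j >= 1) {
        int s = (pg.base[v] == seq[j - 1]) ? match : mismatch;
        int best = NEG; int bp = -3; signed char bs = -1;
        if (from_S) { best = S_all(j - 1) + s; bp = -2; bs = (signed char)(j - 1 == 0 ? 0 : 2); }
        for (int u : preds[v]) {
          size_t pu = (size_t) u * W + (j - 1);
          if (M[pu] > NEG / 2 && M[pu] + s > best) { best = M[pu] + s; bp = u; bs = 0; }
          if (D[pu] > NEG / 2 && D[pu] + s > best) { best = D[pu] + s; bp = u; bs = 1; }
          if (I[pu] > NEG / 2 && I[pu] + s > best) { best = I[pu] + s; bp = u; bs = 2; }
        }
        M[row + j] = best; pM[row + j] = bp; sM[row + j] = bs;
      }
      // D: node v consumed, no seq base
      {
        int best = NEG; int bp = -3; signed char bs = -1;
        if (from_S) { best = S_all(j) + gap_open; bp = -2; bs = (signed char)(j == 0 ? 0 : 2); }
        for (int u : preds[v]) {
          size_t pu = (size_t) u * W + j;
          if (M[pu] > NEG / 2 && M[pu] + gap_open > best) { best = M[pu] + gap_open; bp = u; bs = 0; }
          if (D[pu] > NEG / 2 && D[pu] + gap_extend > best) { best = D[pu] + gap_extend; bp = u; bs = 1; }
          if (I[pu] > NEG / 2 && I[pu] + gap_open > best) { best = I[pu] + gap_open; bp = u; bs = 2; }
        }
        D[row + j] = best; pD[row + j] = bp; sD[row + j] = bs;
      }
      // I: seq[j-1] consumed at node v without a node
      if (j >= 1) {
        int best = NEG; int bp = -3; signed char bs = -1;
        if (M[row + j - 1] > NEG / 2) { best = M[row + j - 1] + gap_open; bp = v; bs = 0; }
        if (D[row + j - 1] > NEG / 2 && D[row + j - 1] + gap_open > best) { best = D[row + j - 1] + gap_open; bp = v; bs = 1; }
        if (I[row + j - 1] > NEG / 2 && I[row + j - 1] + gap_extend > best) { best = I[row + j - 1] + gap_extend; bp = v; bs = 2; }
        I[row + j] = best; pI[row + j] = bp; sI[row + j] = bs;
      }
    }
  }

  // terminal: best over nodes that end a sequence or have no out-edges
  int bt = -1; signed char bst = -1; int bscore = NEG;
  for (int r = 0; r < N; ++r) {
    int v = pg.topo[r];
    if (!(pg.out[v].empty() || pg.end_w[v] > 0)) continue;
    size_t c = (size_t) v * W + m;
    int vals[3] = { M[c], D[c], I[c] };
    for (int st = 0; st < 3; ++st)
      if (vals[st] > bscore) { bscore = vals[st]; bt = v; bst = (signed char) st; }
  }
  if (bt < 0) stop("internal error: POA alignment found no terminal");
  res.score = bscore;

  // traceback
  int v = bt, j = m; signed char st = bst;
  std::vector<int> cn, cq;
  while (true) {
    if (v == -2) {                 // virtual start: remaining seq = leading insertions
      while (j > 0) { cn.push_back(-1); cq.push_back(j - 1); --j; }
      break;
    }
    size_t c = (size_t) v * W + j;
    if (st == 0) {
      cn.push_back(v); cq.push_back(j - 1);
      int pv = pM[c]; signed char ps = sM[c];
      --j; v = pv; st = ps;
    } else if (st == 1) {
      cn.push_back(v); cq.push_back(-1);
      int pv = pD[c]; signed char ps = sD[c];
      v = pv; st = ps;
    } else {
      cn.push_back(-1); cq.push_back(j - 1);
      int pv = pI[c]; signed char ps = sI[c];
      --j; v = pv; st = ps;
    }
  }
  std::reverse(cn.begin(), cn.end());
  std::reverse(cq.begin(), cq.end());
  res.col_node = cn; res.col_qpos = cq;
  return res;
}

// ---------------------------------------------------------------------------
// add an aligned sequence to the graph
// ---------------------------------------------------------------------------

static void poa_add(PGraph &pg, const std::string &seq,
                    const std::vector<int> &col_node, const std::vector<int> &col_qpos) {
  int m = (int) seq.size();
  size_t L = col_node.size();
  if (col_qpos.size() != L) stop("inconsistent alignment path");
  // sanity: every seq position consumed exactly once, in order
  {
    int next = 0;
    for (size_t c = 0; c < L; ++c) {
      if (col_qpos[c] >= 0) {
        if (col_qpos[c] != next) stop("inconsistent alignment path: sequence positions out of order");
        ++next;
      }
      if (col_node[c] >= pg.n()) stop("inconsistent alignment path: node out of range");
    }
    if (next != m) stop("inconsistent alignment path: sequence not fully consumed");
  }

  int n_old = pg.n();
  // next matched anchor (same-base aligned node) at or after each column
  std::vector<int> next_anchor(L + 1, -1);
  for (int c = (int) L - 1; c >= 0; --c) {
    next_anchor[c] = next_anchor[c + 1];
    if (col_node[c] >= 0 && col_qpos[c] >= 0 && pg.base[col_node[c]] == seq[col_qpos[c]])
      next_anchor[c] = col_node[c];
  }

  // ring index: nodes sharing an alignment column, for mismatch fusion
  std::vector<std::vector<int>> ring(pg.next_col);
  for (int u = 0; u < n_old; ++u) ring[pg.col[u]].push_back(u);

  std::vector<int> chosen(m, -1);
  int prev = -2;  // virtual start
  for (size_t c = 0; c < L; ++c) {
    int v = col_node[c], q = col_qpos[c];
    if (q < 0) continue;            // deletion: graph node skipped by this sequence
    char b = seq[q];
    int node = -1;
    if (v >= 0 && pg.base[v] == b) {
      node = v;                     // match: reuse aligned node
    } else {
      // fuse with an existing node carrying this base when that cannot
      // create a cycle: a same-column alternative of the aligned node
      // (mismatch ring) or a same-base successor of the previous node
      int anchor = next_anchor[c + 1];
      bool prev_ok = (prev == -2) || (prev >= 0 && prev < n_old);
      int prev_pos = (prev >= 0 && prev < n_old) ? pg.topo_pos[prev] : -1;
      auto safe = [&](int u) {
        if (pg.base[u] != b || u == prev) return false;
        if (prev_pos >= 0 && !(pg.topo_pos[u] > prev_pos)) return false;
        if (anchor >= 0 && !(pg.topo_pos[u] < pg.topo_pos[anchor])) return false;
        return true;
      };
      if (v >= 0 && prev_ok) {                 // mismatch: search the column ring
        for (int u : ring[pg.col[v]]) if (safe(u)) { node = u; break; }
      }
      if (node < 0 && prev >= 0 && prev < n_old) {
        for (auto &e : pg.out[prev]) if (safe(e.first)) { node = e.first; break; }
      } else if (node < 0 && prev == -2) {     // at the very start: same-base start node
        for (int u = 0; u < n_old; ++u)
          if (pg.start_w[u] > 0 && safe(u)) { node = u; break; }
      }
      if (node < 0) node = pg.add_node(b, v >= 0 ? pg.col[v] : -1);
    }
    chosen[q] = node;
    prev = node;
  }

  for (int q = 0; q < m; ++q) pg.support[chosen[q]]++;
  pg.start_w[chosen[0]]++;
  for (int q = 0; q + 1 < m; ++q) pg.bump_edge(chosen[q], chosen[q + 1]);
  pg.end_w[chosen[m - 1]]++;
  pg.rebuild_topo();
}

// ---------------------------------------------------------------------------
// heaviest-path consensus
// ---------------------------------------------------------------------------

// Consensus: the path from start to end maximizing the depth-penalized
// weight sum over traversed edges, score(e) = 2*w(e) - (n_seq + 1) where
// n_seq is the number of sequences in the graph. An edge contributes
// positively only with majority support, so low-support detours through
// phase-split repeat branches (which inflate a plain heaviest-sum path)
// never pay off, while any true majority bubble still does.
static std::string poa_consensus_string(const PGraph &pg) {
  int N = pg.n();
  if (N == 0) stop("cannot call a consensus from an empty POA graph");
  long long n_seq = 0;
  for (int v = 0; v < N; ++v) n_seq += pg.start_w[v];
  const long long pen = n_seq + 1;
  std::vector<long long> best(N, NEG);
  std::vector<int> from(N, -3);  // -2 = start
  // in-edges
  std::vector<std::vector<std::pair<int,int>>> in(N);
  for (int u = 0; u < N; ++u)
    for (auto &e : pg.out[u]) in[e.first].push_back(std::make_pair(u, e.second));

  for (int r = 0; r < N; ++r) {
    int v = pg.topo[r];
    long long bv = NEG; int bf = -3;
    int bsupp = -1, btopo = N + 1;
    if (pg.start_w[v] > 0) { bv = 2LL * pg.start_w[v] - pen; bf = -2; bsupp = -1; btopo = -1; }
    for (auto &e : in[v]) {
      int u = e.first, w = e.second;
      if (best[u] <= NEG / 2) continue;
      long long cand = best[u] + 2LL * w - pen;
      bool take = cand > bv;
      if (!take && cand == bv && bf != -3) {
        // tie: prefer higher-support predecessor, then lower topo rank
        if (pg.support[u] > bsupp) take = true;
        else if (pg.support[u] == bsupp && pg.topo_pos[u] < btopo) take = true;
      }
      if (take) { bv = cand; bf = u; bsupp = pg.support[u]; btopo = pg.topo_pos[u]; }
    }
    best[v] = bv; from[v] = bf;
  }

  long long btot = NEG; int bend = -1;
  for (int r = 0; r < N; ++r) {
    int v = pg.topo[r];
    if (pg.end_w[v] <= 0 || best[v] <= NEG / 2) continue;
    long long cand = best[v] + 2LL * pg.end_w[v] - pen;
    bool take = cand > btot;
    if (!take && cand == btot && bend >= 0) {
      if (pg.support[v] > pg.support[bend]) take = true;
      else if (pg.support[v] == pg.support[bend] && pg.topo_pos[v] < pg.topo_pos[bend]) take = true;
    }
    if (take) { btot = cand; bend = v; }
  }
  if (bend < 0) stop("cannot call a consensus from an empty POA graph");

  std::string s;
  for (int v = bend; v != -2; v = from[v]) {
    if (v < 0) stop("internal error: broken consensus path");
    s.push_back(pg.base[v]);
  }
  std::reverse(s.begin(), s.end());
  return s;
}

// ---------------------------------------------------------------------------
// exported surface
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".poa_align_cpp")]]
List poa_align_cpp(List graph, std::string seq,
                   int match, int mismatch, int gap_open, int gap_extend) {
  PGraph pg = graph_from_list(graph);
  PoaAln a = poa_align(pg, seq, match, mismatch, gap_open, gap_extend);
  return List::create(_["score"] = a.score,
                      _["col_node"] = a.col_node, _["col_qpos"] = a.col_qpos);
}

// [[Rcpp::export(name = ".poa_add_cpp")]]
List poa_add_cpp(List graph, std::string seq, IntegerVector col_node, IntegerVector col_qpos) {
  PGraph pg = graph_from_list(graph);
  poa_add(pg, seq, as<std::vector<int>>(col_node), as<std::vector<int>>(col_qpos));
  return graph_to_list(pg);
}

// [[Rcpp::export(name = ".poa_consensus_graph_cpp")]]
std::string poa_consensus_graph_cpp(List graph) {
  PGraph pg = graph_from_list(graph);
  return poa_consensus_string(pg);
}

// [[Rcpp::export(name = ".poa_consensus_cpp")]]
std::string poa_consensus_cpp(CharacterVector seqs,
                              int match, int mismatch, int gap_open, int gap_extend) {
  if (seqs.size() == 0) stop("cannot build a consensus from zero sequences");
  PGraph pg;
  pg.rebuild_topo();
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    PoaAln a = poa_align(pg, s, match, mismatch, gap_open, gap_extend);
    poa_add(pg, s, a.col_node, a.col_qpos);
  }
  return poa_consensus_string(pg);
}
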
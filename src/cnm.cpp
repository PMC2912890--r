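// Greedy modularity agglomeration (Clauset-Newman-Moore style sparse dQ
// bookkeeping). Unweighted modularity: Q = sum_c (l_c / m - (d_c / 2m)^2).
// Starting from singleton communities, repeatedly merge the edge-connected
// community pair with maximal dQ; ties are broken deterministically by the
// smallest vertex index contained in the merged community (then by the other
// community's smallest index). Merging continues until one community per
// connected component remains, recording (u, v, dQ, Q_after) per step.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

struct HeapEntry {
  double dq;
  int key1, key2;  // tie-break: min vertex index of merged community, then other
  int u, v;        // community slots
};

struct HeapCmp {
  bool operator()(const HeapEntry& a, const HeapEntry& b) const {
    if (a.dq != b.dq) return a.dq < b.dq;        // max-heap on dq
    if (a.key1 != b.key1) return a.key1 > b.key1;  // then smallest key1
    return a.key2 > b.key2;                        // then smallest key2
  }
};

// edges as 1-based vertex index pairs; n vertices. Returns the merge list
// (community ids: leaves 1..n, merge t creates id n+t) plus the singleton-
// partition modularity q0.
// [[Rcpp::export(name = ".cnm_cpp")]]
List cnm_cpp(IntegerVector ei, IntegerVector ej, int n) {
  const int m = ei.size();
  if (n < 1 || m < 1) stop("graph must have at least one edge");

  std::vector<double> a(n);            // d_i / 2m per community
  std::vector<int> minid(n), commid(n);
  std::vector<char> alive(n, 1);
  std::vector<std::unordered_map<int, double>> nbr(n);

  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) {
    int u = ei[e] - 1, v = ej[e] - 1;
    if (u == v) stop("self-edge encountered");
    ++deg[u]; ++deg[v];
  }
  double q0 = 0.0;
  for (int i = 0; i < n; ++i) {
    a[i] = deg[i] / (2.0 * m);
    q0 -= a[i] * a[i];
    minid[i] = i;
    commid[i] = i + 1;
  }

  std::priority_queue<HeapEntry, std::vector<HeapEntry>, HeapCmp> heap;
  auto push_pair = [&](int u, int v, double dq) {
    int k1 = std::min(minid[u], minid[v]);
    int k2 = std::max(minid[u], minid[v]);
    heap.push({dq, k1, k2, u, v});
  };

  for (int e = 0; e < m; ++e) {
    int u = ei[e] - 1, v = ej[e] - 1;
    double dq = 1.0 / m - 2.0 * a[u] * a[v];
    nbr[u][v] = dq;
    nbr[v][u] = dq;
  }
  for (int u = 0; u < n; ++u)
    for (auto& kv : nbr[u])
      if (kv.first > u) push_pair(u, kv.first, kv.second);

  int max_steps = n - 1;
  std::vector<int> out_u, out_v;
  std::vector<double> out_dq, out_q;
  out_u.reserve(max_steps);
  double q = q0;
  int step = 0;

  while (!heap.empty()) {
    HeapEntry top = heap.top();
    heap.pop();
    int u = top.u, v = top.v;
    if (!alive[u] || !alive[v]) continue;
    auto it = nbr[u].find(v);
    if (it == nbr[u].end() || it->second != top.dq) continue;  // stale
    int k1 = std::min(minid[u], minid[v]);
    int k2 = std::max(minid[u], minid[v]);
    if (k1 != top.key1 || k2 != top.key2) continue;  // stale tie-break key

    // merge v into u (slot u holds the union); keep larger map in u
    if (nbr[v].size() > nbr[u].size()) std::swap(u, v);
    ++step;
    q += top.dq;
    out_u.push_back(std::min(commid[top.u], commid[top.v]));
    out_v.push_back(std::max(commid[top.u], commid[top.v]));
    out_dq.push_back(top.dq);
    out_q.push_back(q);

    double au = a[u], av = a[v];
    nbr[u].erase(v);
    nbr[v].erase(u);
    // existing neighbors of u: connected to v too? handled below; else adjust
    for (auto& kv : nbr[u]) {
      int k = kv.first;
      auto itv = nbr[v].find(k);
      if (itv != nbr[v].end()) kv.second += itv->second;
      else kv.second -= 2.0 * av * a[k];
      nbr[k].erase(u);  // re-inserted with updated value below
    }
    for (auto& kv : nbr[v]) {
      int k = kv.first;
      if (nbr[u].find(k) == nbr[u].end())
        nbr[u][k] = kv.second - 2.0 * au * a[k];
      nbr[k].erase(v);
    }
    nbr[v].clear();
    alive[v] = 0;
    a[u] = au + av;
    minid[u] = std::min(minid[u], minid[v]);
    commid[u] = n + step;
    for (auto& kv : nbr[u]) {
      nbr[kv.first][u] = kv.second;
      push_pair(u, kv.first, kv.second);
    }
  }

  IntegerVector U(out_u.begin(), out_u.end());
  IntegerVector V(out_v.begin(), out_v.end());
  NumericVector DQ(out_dq.begin(), out_dq.end());
  NumericVector Q(out_q.begin(), out_q.end());
  return List::create(_["u"] = U, _["v"] = V, _["dq"] = DQ,
                      _["q_after"] = Q, _["q0"] = q0);
}
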
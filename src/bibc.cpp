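#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// BFS shortest-path counting from one root on an unweighted graph.
static void bfs_count(const std::vector<std::vector<int>> &adj, int root,
                      std::vector<int> &dist, std::vector<double> &sigma) {
  const int n = adj.size();
  dist.assign(n, -1);
  sigma.assign(n, 0.0);
  dist[root] = 0;
  sigma[root] = 1.0;
  std::queue<int> q;
  q.push(root);
  while (!q.empty()) {
    int v = q.front(); q.pop();
    for (int w : adj[v]) {
      if (dist[w] < 0) {
        dist[w] = dist[v] + 1;
        q.push(w);
      }
      if (dist[w] == dist[v] + 1) sigma[w] += sigma[v];
    }
  }
}

// Bipartite betweenness centrality between two disjoint node groups.
// edges_from/edges_to: 0-based endpoints; src/tgt: 0-based node indices.
// For each unordered pair (s, t) with a connecting path, node v accrues
// sigma_s(v) * sigma_t(v) / sigma_s(t) when d_s(v) + d_t(v) == d_s(t),
// v excluded only for its own pairs (v == s or v == t).
// [[Rcpp::export]]
NumericVector bibc_core(int n_nodes, IntegerVector edges_from,
                        IntegerVector edges_to, IntegerVector src,
                        IntegerVector tgt) {
  std::vector<std::vector<int>> adj(n_nodes);
  for (int e = 0; e < edges_from.size(); ++e) {
    int a = edges_from[e], b = edges_to[e];
    if (a < 0 || b < 0 || a >= n_nodes || b >= n_nodes)
      stop("edge endpoint out of range");
    if (a == b) continue;
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  const int ns = src.size(), nt = tgt.size();
  std::vector<std::vector<int>> dist_s(ns), dist_t(nt);
  std::vector<std::vector<double>> sig_s(ns), sig_t(nt);
  for (int i = 0; i < ns; ++i) bfs_count(adj, src[i], dist_s[i], sig_s[i]);
  for (int j = 0; j < nt; ++j) bfs_count(adj, tgt[j], dist_t[j], sig_t[j]);

  NumericVector bibc(n_nodes, 0.0);
  for (int i = 0; i < ns; ++i) {
    for (int j = 0; j < nt; ++j) {
      int s = src[i], t = tgt[j];
      int D = dist_s[i][t];
      if (D < 0) continue;  // disconnected pair contributes nothing
      double sig_st = sig_s[i][t];
      for (int v = 0; v < n_nodes; ++v) {
        if (v == s || v == t) continue;
        if (dist_s[i][v] < 0 || dist_t[j][v] < 0) continue;
        if (dist_s[i][v] + dist_t[j][v] == D)
          bibc[v] += sig_s[i][v] * sig_t[j][v] / sig_st;
      }
    }
  }
  return bibc;
}
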
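#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
using namespace Rcpp;

// Node ids are 1..n.  Id 0 is the virtual source, id -1 the virtual sink;
// both appear only in the edge table, never in the node list.

// Kahn's algorithm over the real-node subgraph.  Ties are broken by taking
// the highest node id first, so nodes created later (parallel alternatives)
// rank ahead of the consensus backbone node they compete with.  The cut "in
// front of" a backbone base then keeps same-locus alternatives on the
// upstream side of the cut, which is what the parallel-base attribution
// relies on.
// [[Rcpp::export(name = ".cpp_topo_order")]]
IntegerVector cpp_topo_order(int n, IntegerVector from, IntegerVector to) {
  std::vector<int> indeg(n + 1, 0);
  std::vector<std::vector<int> > children(n + 1);
  int m = from.size();
  for (int i = 0; i < m; ++i) {
    int u = from[i], v = to[i];
    if (u >= 1 && v >= 1) {
      children[u].push_back(v);
      indeg[v]++;
    }
  }
  std::priority_queue<int> frontier; // max-heap: highest id first
  for (int v = 1; v <= n; ++v)
    if (indeg[v] == 0) frontier.push(v);
  IntegerVector order(n);
  int k = 0;
  while (!frontier.empty()) {
    int v = frontier.top(); frontier.pop();
    order[k++] = v;
    for (size_t j = 0; j < children[v].size(); ++j) {
      if (--indeg[children[v][j]] == 0) frontier.push(children[v][j]);
    }
  }
  if (k < n) stop("cycle detected in POA graph");
  return order;
}

// Global alignment of a sequence against the DAG (dynamic programming over
// nodes in topological order).  bases/seq are coded 0=A,1=C,2=G,3=T,4=N
// (N mismatches everything, including N).  Returns the optimal score and the
// aligned path as (node id | NA, sequence position | NA) pairs.
//
// Tie-break when scores are equal: match > deletion (gap in sequence)
// > mismatch > insertion (gap in graph); remaining ties prefer the parent
// with the smallest node id.  Preferring a deletion over a mismatch keeps a
// substitution adjacent to a deletion anchored on the substituted locus
// rather than sliding onto its neighbour.
// [[Rcpp::export(name = ".cpp_align_graph")]]
List cpp_align_graph(int n, IntegerVector bases, IntegerVector from,
                     IntegerVector to, IntegerVector order,
                     IntegerVector seq, int ma, int mi, int gap) {
  const int L = seq.size();
  const int NEG = std::numeric_limits<int>::min() / 4;

  if (n == 0) {
    IntegerMatrix path(L, 2);
    for (int j = 0; j < L; ++j) {
      path(j, 0) = NA_INTEGER;
      path(j, 1) = j + 1;
    }
    return List::create(_["score"] = gap * L, _["path"] = path);
  }

  // row index for each node: row 0 = source, row i = order[i-1]
  std::vector<int> rowOf(n + 1, -1);
  rowOf[0] = 0; // virtual source
  for (int i = 0; i < n; ++i) rowOf[order[i]] = i + 1;

  std::vector<std::vector<int> > parents(n + 1);
  std::vector<bool> sinkEdge(n + 1, false);
  int m = from.size();
  for (int i = 0; i < m; ++i) {
    int u = from[i], v = to[i];
    if (v == -1) { if (u >= 1) sinkEdge[u] = true; continue; }
    parents[v].push_back(u); // u may be 0 (source)
  }
  for (int v = 1; v <= n; ++v) std::sort(parents[v].begin(), parents[v].end());

  const int R = n + 1, C = L + 1;
  std::vector<int> S((size_t)R * C, NEG);
  std::vector<signed char> ptrType((size_t)R * C, -1); // 0 diag 1 vert 2 horiz
  std::vector<int> ptrNode((size_t)R * C, 0);
#define IDX(r, c) ((size_t)(r) * C + (c))

  for (int j = 0; j <= L; ++j) {
    S[IDX(0, j)] = gap * j;
    if (j > 0) ptrType[IDX(0, j)] = 2;
  }
  for (int i = 1; i <= R - 1; ++i) {
    int v = order[i - 1];
    int bv = bases[v - 1];
    for (int j = 0; j <= L; ++j) {
      int bestDiag = NEG, diagP = 0, bestVert = NEG, vertP = 0;
      bool isMatch = false;
      if (j > 0) {
        int sj = seq[j - 1];
        isMatch = (bv == sj && bv < 4);
        int sub = isMatch ? ma : mi;
        for (size_t k = 0; k < parents[v].size(); ++k) {
          int u = parents[v][k];
          int s = S[IDX(rowOf[u], j - 1)];
          if (s > NEG / 2 && s + sub > bestDiag) { bestDiag = s + sub; diagP = u; }
        }
      }
      for (size_t k = 0; k < parents[v].size(); ++k) {
        int u = parents[v][k];
        int s = S[IDX(rowOf[u], j)];
        if (s > NEG / 2 && s + gap > bestVert) { bestVert = s + gap; vertP = u; }
      }
      int bestHoriz = NEG;
      if (j > 0 && S[IDX(i, j - 1)] > NEG / 2) bestHoriz = S[IDX(i, j - 1)] + gap;

      int best = std::max(bestDiag, std::max(bestVert, bestHoriz));
      if (best <= NEG / 2) continue;
      S[IDX(i, j)] = best;
      if (isMatch && bestDiag == best) {
        ptrType[IDX(i, j)] = 0; ptrNode[IDX(i, j)] = diagP;
      } else if (bestVert == best) {
        ptrType[IDX(i, j)] = 1; ptrNode[IDX(i, j)] = vertP;
      } else if (bestDiag == best) {
        ptrType[IDX(i, j)] = 0; ptrNode[IDX(i, j)] = diagP;
      } else {
        ptrType[IDX(i, j)] = 2;
      }
    }
  }

  // global end: best sink-connected node at column L (ties: smallest id)
  int bestScore = NEG, endNode = -1;
  for (int v = 1; v <= n; ++v) {
    if (!sinkEdge[v]) continue;
    int s = S[IDX(rowOf[v], L)];
    if (s > bestScore || (s == bestScore && (endNode == -1 || v < endNode))) {
      bestScore = s; endNode = v;
    }
  }
  if (endNode == -1) stop("graph has no sink-connected node");

  std::vector<int> pnode, ppos;
  int r = rowOf[endNode], j = L, node = endNode;
  while (!(r == 0 && j == 0)) {
    signed char t = ptrType[IDX(r, j)];
    if (r == 0) { // insertions against the virtual source
      pnode.push_back(NA_INTEGER); ppos.push_back(j); --j; continue;
    }
    if (t == 0) {
      pnode.push_back(node); ppos.push_back(j);
      int u = ptrNode[IDX(r, j)];
      --j; node = u; r = (u == 0) ? 0 : rowOf[u];
    } else if (t == 1) {
      pnode.push_back(node); ppos.push_back(NA_INTEGER);
      int u = ptrNode[IDX(r, j)];
      node = u; r = (u == 0) ? 0 : rowOf[u];
    } else if (t == 2) {
      pnode.push_back(NA_INTEGER); ppos.push_back(j); --j;
    } else {
      stop("traceback failed (unreachable cell)");
    }
  }
  int P = pnode.size();
  IntegerMatrix path(P, 2);
  for (int i = 0; i < P; ++i) {
    path(i, 0) = pnode[P - 1 - i];
    path(i, 1) = ppos[P - 1 - i];
  }
  return List::create(_["score"] = bestScore, _["path"] = path);
#undef IDX
}

// Maximum-total-edge-weight path from virtual source to virtual sink.
// Ties prefer the smaller predecessor node id, and the smaller end node.
// [[Rcpp::export(name = ".cpp_heaviest_path")]]
IntegerVector cpp_heaviest_path(int n, IntegerVector from, IntegerVector to,
                                IntegerVector weight, IntegerVector order) {
  if (n == 0) return IntegerVector(0);
  const long long NEG = std::numeric_limits<long long>::min() / 4;
  std::vector<long long> best(n + 1, NEG);
  std::vector<int> pred(n + 1, -2);
  std::vector<std::vector<int> > inEdges(n + 1);
  std::vector<int> sinkU; std::vector<long long> sinkW;
  int m = from.size();
  for (int i = 0; i < m; ++i) {
    if (to[i] == -1) { sinkU.push_back(from[i]); sinkW.push_back(weight[i]); }
    else inEdges[to[i]].push_back(i);
  }
  // best[0] (source) = 0
  std::vector<long long> bestAll(n + 1, NEG);
  bestAll[0] = 0;
  for (int k = 0; k < n; ++k) {
    int v = order[k];
    long long b = NEG; int p = -2;
    for (size_t e = 0; e < inEdges[v].size(); ++e) {
      int i = inEdges[v][e];
      int u = from[i];
      if (bestAll[u] <= NEG / 2) continue;
      long long cand = bestAll[u] + weight[i];
      if (cand > b || (cand == b && u < p)) { b = cand; p = u; }
    }
    bestAll[v] = b; pred[v] = p;
  }
  long long bEnd = NEG; int endNode = -2;
  for (size_t e = 0; e < sinkU.size(); ++e) {
    int u = sinkU[e];
    if (bestAll[u] <= NEG / 2) continue;
    long long cand = bestAll[u] + sinkW[e];
    if (cand > bEnd || (cand == bEnd && u < endNode)) { bEnd = cand; endNode = u; }
  }
  if (endNode < 0) stop("no source-to-sink path");
  std::vector<int> rev;
  for (int v = endNode; v != 0; v = pred[v]) {
    rev.push_back(v);
    if (pred[v] < 0) { if (pred[v] == -2) stop("broken predecessor chain"); break; }
  }
  IntegerVector out(rev.size());
  for (size_t i = 0; i < rev.size(); ++i) out[i] = rev[rev.size() - 1 - i];
  return out;
}
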
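// Exact transportation simplex for discrete optimal transport
// (Wasserstein-1 between karyotype distributions). Northwest-corner start,
// MODI pivoting with tree potentials; deterministic infinitesimal supply
// perturbation breaks degeneracy.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".transport_simplex")]]
List transport_simplex(NumericVector a0, NumericVector b0, NumericMatrix C) {
  const int m = a0.size(), n = b0.size();
  std::vector<double> a(a0.begin(), a0.end()), b(b0.begin(), b0.end());
  double sa = 0.0, sb = 0.0;
  for (double x : a) sa += x;
  for (double x : b) sb += x;
  if (sa <= 0 || sb <= 0) stop("empty distribution");
  if (std::abs(sa - sb) > 1e-9 * std::max(sa, sb))
    stop("unbalanced transportation problem");
  for (double &x : a) x /= sa;
  for (double &x : b) x /= sb;
  const double eps = 1e-11;
  for (int i = 0; i < m; i++) a[i] += eps * (i + 1);
  b[n - 1] += eps * (double)m * (m + 1) / 2.0;

  const int nb = m + n - 1;
  std::vector<int> bi(nb), bj(nb);
  std::vector<double> xb(nb);
  {
    // northwest-corner initial basic feasible solution
    std::vector<double> ra(a), rb(b);
    int i = 0, j = 0;
    for (int k = 0; k < nb; k++) {
      bi[k] = i; bj[k] = j;
      double v = std::min(ra[i], rb[j]);
      xb[k] = v;
      ra[i] -= v; rb[j] -= v;
      if (i < m - 1 && (ra[i] <= rb[j] || j == n - 1)) i++; else j++;
    }
  }

  const int nn = m + n;
  std::vector<std::vector<int>> adj(nn);
  std::vector<double> pot(nn);
  std::vector<int> parentEdge(nn), parentNode(nn), queue(nn);
  std::vector<signed char> seen(nn);
  std::vector<int> onFromPath(nn);
  const int maxIter = 200 * nn;
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < maxIter; iter++) {
    for (auto &v : adj) v.clear();
    for (int e = 0; e < nb; e++) {
      adj[bi[e]].push_back(e);
      adj[m + bj[e]].push_back(e);
    }
    // potentials via BFS over the basis tree, root = row node 0
    std::fill(seen.begin(), seen.end(), 0);
    pot[0] = 0.0; seen[0] = 1;
    parentEdge[0] = -1; parentNode[0] = -1;
    int qh = 0, qt = 0;
    queue[qt++] = 0;
    while (qh < qt) {
      int nd = queue[qh++];
      for (int e : adj[nd]) {
        int other = (bi[e] == nd) ? (m + bj[e]) : bi[e];
        if (!seen[other]) {
          seen[other] = 1;
          pot[other] = C(bi[e], bj[e]) - pot[nd];
          parentEdge[other] = e;
          parentNode[other] = nd;
          queue[qt++] = other;
        }
      }
    }
    // most negative reduced cost
    double best = -1e-12;
    int ei = -1, ej = -1;
    for (int j = 0; j < n; j++) {
      double vj = pot[m + j];
      for (int i = 0; i < m; i++) {
        double r = C(i, j) - pot[i] - vj;
        if (r < best) { best = r; ei = i; ej = j; }
      }
    }
    if (ei < 0) { converged = true; break; }

    // unique tree path between entering endpoints ei (row) and m+ej (col)
    std::fill(onFromPath.begin(), onFromPath.end(), -1);
    std::vector<int> pfEdges, pfNodes;
    int nd = ei;
    while (nd != -1) {
      onFromPath[nd] = (int)pfNodes.size();
      pfNodes.push_back(nd);
      if (parentNode[nd] == -1) break;
      pfEdges.push_back(parentEdge[nd]);
      nd = parentNode[nd];
    }
    std::vector<int> ptEdges;
    nd = m + ej;
    while (onFromPath[nd] < 0) {
      ptEdges.push_back(parentEdge[nd]);
      nd = parentNode[nd];
    }
    int lca = onFromPath[nd];
    std::vector<int> path;
    for (int k = 0; k < lca; k++) path.push_back(pfEdges[k]);
    for (int k = (int)ptEdges.size() - 1; k >= 0; k--)
      path.push_back(ptEdges[k]);

    // cycle: entering cell (+), then alternating (-, +, ...) along path
    double theta = R_PosInf;
    int leave = -1;
    for (size_t k = 0; k < path.size(); k += 2) {
      if (xb[path[k]] < theta) { theta = xb[path[k]]; leave = path[k]; }
    }
    for (size_t k = 0; k < path.size(); k++) {
      if (k % 2 == 0) xb[path[k]] -= theta; else xb[path[k]] += theta;
    }
    bi[leave] = ei; bj[leave] = ej;
    xb[leave] = theta;
  }
  if (!converged) stop("transportation simplex did not converge");

  double cost = 0.0;
  for (int e = 0; e < nb; e++) cost += C(bi[e], bj[e]) * xb[e];
  IntegerMatrix basis(nb, 2);
  NumericVector mass(nb);
  for (int e = 0; e < nb; e++) {
    basis(e, 0) = bi[e] + 1;
    basis(e, 1) = bj[e] + 1;
    mass[e] = xb[e];
  }
  return List::create(_["cost"] = cost, _["basis"] = basis,
                      _["mass"] = mass, _["iterations"] = iter + 1);
}
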
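#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Kantorovich-Rubinstein distance between two placement mass
// distributions under the tree path metric, by a single post-order sweep:
// for every edge segment (segments delimited by attachment points) the
// signed mass of P minus Q lying distal to the segment is accumulated,
// and the cost is the integral of |signed mass|^z over segment lengths.
// Exact for exponent 1 (equals minimum-cost transport on a tree).

namespace {

struct Pt { int node; double off; double w; };

double kr_sweep(const IntegerVector& parent, const NumericVector& brlen,
                const IntegerVector& postorder, std::vector<Pt>& pts,
                std::vector<double>& sub, std::vector<int>& run_start,
                std::vector<int>& run_len, double expon) {
  const int M = parent.size();
  std::fill(sub.begin(), sub.end(), 0.0);
  std::sort(pts.begin(), pts.end(), [](const Pt& a, const Pt& b) {
    return a.node != b.node ? a.node < b.node : a.off < b.off;
  });
  std::fill(run_start.begin(), run_start.end(), -1);
  for (int i = 0; i < (int)pts.size(); ++i) {
    int v = pts[i].node;
    if (run_start[v] < 0) { run_start[v] = i; run_len[v] = 0; }
    run_len[v]++;
  }
  double cost = 0.0;
  for (int idx = 0; idx < M; ++idx) {
    const int v = postorder[idx];          // 1-based node id
    double B = sub[v];
    double pos = 0.0;
    const double L = brlen[v - 1];
    if (run_start[v] >= 0) {
      const int s = run_start[v], n = run_len[v];
      for (int i = s; i < s + n; ++i) {
        double off = pts[i].off;
        if (off > L) off = L;
        if (off > pos) {
          cost += std::pow(std::fabs(B), expon) * (off - pos);
          pos = off;
        }
        B += pts[i].w;
      }
    }
    if (L > pos) cost += std::pow(std::fabs(B), expon) * (L - pos);
    const int p = parent[v - 1];
    if (p > 0) sub[p] += B;
  }
  return expon == 1.0 ? cost : std::pow(cost, 1.0 / expon);
}

} // namespace

// [[Rcpp::export]]
double kr_pair_cpp(IntegerVector parent, NumericVector brlen,
                   IntegerVector postorder,
                   IntegerVector nodeP, NumericVector offP, NumericVector wP,
                   IntegerVector nodeQ, NumericVector offQ, NumericVector wQ,
                   double expon) {
  const int M = parent.size();
  std::vector<Pt> pts;
  pts.reserve(nodeP.size() + nodeQ.size());
  for (int i = 0; i < nodeP.size(); ++i)
    pts.push_back({nodeP[i], offP[i], wP[i]});
  for (int i = 0; i < nodeQ.size(); ++i)
    pts.push_back({nodeQ[i], offQ[i], -wQ[i]});
  std::vector<double> sub(M + 1);
  std::vector<int> run_start(M + 1), run_len(M + 1);
  return kr_sweep(parent, brlen, postorder, pts, sub, run_start, run_len,
                  expon);
}

// Full pairwise matrix over records stored flat; starts is 0-based with
// length n_rec + 1 delimiting each record's rows in node/off/w.
// [[Rcpp::export]]
NumericMatrix kr_pairwise_cpp(IntegerVector parent, NumericVector brlen,
                              IntegerVector postorder,
                              IntegerVector node, NumericVector off,
                              NumericVector w, IntegerVector starts,
                              double expon) {
  const int M = parent.size();
  const int n = starts.size() - 1;
  NumericMatrix D(n, n);
  std::vector<double> sub(M + 1);
  std::vector<int> run_start(M + 1), run_len(M + 1);
  std::vector<Pt> pts;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      pts.clear();
      for (int a = starts[i]; a < starts[i + 1]; ++a)
        pts.push_back({node[a], off[a], w[a]});
      for (int b = starts[j]; b < starts[j + 1]; ++b)
        pts.push_back({node[b], off[b], -w[b]});
      double d = kr_sweep(parent, brlen, postorder, pts, sub, run_start,
                          run_len, expon);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
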
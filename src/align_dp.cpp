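#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Fit-style dynamic program matching the ordered interior fragments of a
// query Rmap against a contiguous stretch of reference fragments.
//
// A block pairs up to `delta` consecutive query fragments with up to `delta`
// consecutive reference fragments and costs
//   ((q - r) / (sigma * r))^2 + (nq - 1) * c_ec + (nr - 1) * c_mc
// where q, r are the block mass sums. The two terminal query fragments are
// molecule-end artifacts (random shear points) and are not scored; the
// interior must start and end exactly at reference cut sites, with the
// reference start position free (fitting alignment).
//
// D[i][j] = minimal cost of matching the first j interior query fragments so
// that the last block ends at reference cut i (i.e. after ref fragment i,
// 1-based).  D[i][0] = 0 for every i encodes the free start.

static const double INF = std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".dp_fit_align")]]
List dp_fit_align(NumericVector ref, NumericVector query_interior,
                  double sigma, double c_ec, double c_mc, int delta,
                  double z2_cap = R_PosInf) {
  const int R = ref.size();
  const int M = query_interior.size();
  if (M < 1 || R < 1)
    return List::create(_["cost"] = INF, _["blocks"] = R_NilValue);

  // prefix sums
  std::vector<double> pr(R + 1, 0.0), pq(M + 1, 0.0);
  for (int i = 0; i < R; ++i) pr[i + 1] = pr[i] + ref[i];
  for (int j = 0; j < M; ++j) pq[j + 1] = pq[j] + query_interior[j];

  std::vector<double> D((R + 1) * (M + 1), INF);
  std::vector<int> back((R + 1) * (M + 1), -1); // encodes a * 16 + b
  for (int i = 0; i <= R; ++i) D[i * (M + 1)] = 0.0;

  for (int j = 1; j <= M; ++j) {
    for (int i = 1; i <= R; ++i) {
      double best = INF; int arg = -1;
      int amax = std::min(delta, i);
      int bmax = std::min(delta, j);
      for (int a = 1; a <= amax; ++a) {
        double r = pr[i] - pr[i - a];
        if (r <= 0) continue;
        double mc = (a - 1) * c_mc;
        for (int b = 1; b <= bmax; ++b) {
          double prev = D[(i - a) * (M + 1) + (j - b)];
          if (prev == INF) continue;
          double q = pq[j] - pq[j - b];
          double z = (q - r) / (sigma * r);
          double z2 = z * z; if (z2 > z2_cap) z2 = z2_cap;
          double cost = prev + z2 + (b - 1) * c_ec + mc;
          if (cost < best) { best = cost; arg = a * 16 + b; }
        }
      }
      D[i * (M + 1) + j] = best;
      back[i * (M + 1) + j] = arg;
    }
  }

  // best end cut (leftmost on ties)
  double best = INF; int iend = -1;
  for (int i = 1; i <= R; ++i) {
    double v = D[i * (M + 1) + M];
    if (v < best) { best = v; iend = i; }
  }
  if (!R_FINITE(best))
    return List::create(_["cost"] = INF, _["blocks"] = R_NilValue);

  // traceback: blocks as (ref_start, ref_end, q_start, q_end), 1-based
  std::vector<int> rs, re, qs, qe;
  int i = iend, j = M;
  while (j > 0) {
    int code = back[i * (M + 1) + j];
    int a = code / 16, b = code % 16;
    rs.push_back(i - a + 1); re.push_back(i);
    qs.push_back(j - b + 1); qe.push_back(j);
    i -= a; j -= b;
  }
  const int nb = rs.size();
  IntegerMatrix blocks(nb, 4);
  NumericVector bcost(nb);
  for (int k = 0; k < nb; ++k) {
    int row = nb - 1 - k; // reverse into left-to-right order
    blocks(row, 0) = rs[k]; blocks(row, 1) = re[k];
    blocks(row, 2) = qs[k]; blocks(row, 3) = qe[k];
    double r = pr[re[k]] - pr[rs[k] - 1];
    double q = pq[qe[k]] - pq[qs[k] - 1];
    double z = (q - r) / (sigma * r);
    double z2 = z * z; if (z2 > z2_cap) z2 = z2_cap;
    bcost(row) = z2; // sizing term only; cut penalties recoverable from spans
  }
  colnames(blocks) = CharacterVector::create("ref_start", "ref_end",
                                             "q_start", "q_end");
  return List::create(_["cost"] = best, _["blocks"] = blocks,
                      _["block_sizing_cost"] = bcost,
                      _["ref_first"] = blocks(0, 0), _["ref_last"] = iend);
}

// Align a batch of interior-fragment vectors against one reference map,
// both orientations, returning one row of summaries per query.
// [[Rcpp::export(name = ".dp_align_many")]]
List dp_align_many(List queries_interior, NumericVector ref,
                   double sigma, double c_ec, double c_mc, int delta,
                   double z2_cap = R_PosInf) {
  const int n = queries_interior.size();
  List out(n);
  for (int k = 0; k < n; ++k) {
    NumericVector q = queries_interior[k];
    List fwd = dp_fit_align(ref, q, sigma, c_ec, c_mc, delta, z2_cap);
    NumericVector qr(q.size());
    for (int t = 0; t < q.size(); ++t) qr[t] = q[q.size() - 1 - t];
    List rev = dp_fit_align(ref, qr, sigma, c_ec, c_mc, delta, z2_cap);
    double cf = as<double>(fwd["cost"]);
    double cr = as<double>(rev["cost"]);
    bool forward = cf <= cr; // ties broken toward forward orientation
    List chosen = forward ? fwd : rev;
    chosen["orientation"] = forward ? "+" : "-";
    out[k] = chosen;
  }
  return out;
}
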
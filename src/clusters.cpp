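#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labeling of suprathreshold cells in a channels x
// samples t-map. Connectivity: same channel at adjacent samples, or
// spatially neighbouring channels at the same sample; members must share
// the sign of t. Cells with |t| <= thr get label 0.

static void label_impl(const NumericMatrix& t, double thr,
                       const std::vector< std::vector<int> >& nb,
                       IntegerMatrix& lab, std::vector<double>& sums) {
  int nch = t.nrow(), ns = t.ncol();
  int next = 0;
  std::vector<int> stack;
  for (int s = 0; s < ns; ++s) {
    for (int c = 0; c < nch; ++c) {
      if (lab(c, s) != 0) continue;
      double v = t(c, s);
      if (!(v > thr || v < -thr)) continue;
      int sign = v > 0 ? 1 : -1;
      ++next;
      double acc = 0.0;
      stack.clear();
      stack.push_back(c + nch * s);
      lab(c, s) = next;
      while (!stack.empty()) {
        int cell = stack.back();
        stack.pop_back();
        int cc = cell % nch, ss = cell / nch;
        acc += t(cc, ss);
        // temporal neighbours
        for (int ds = -1; ds <= 1; ds += 2) {
          int s2 = ss + ds;
          if (s2 < 0 || s2 >= ns) continue;
          double v2 = t(cc, s2);
          if (lab(cc, s2) == 0 && ((sign > 0 && v2 > thr) ||
                                   (sign < 0 && v2 < -thr))) {
            lab(cc, s2) = next;
            stack.push_back(cc + nch * s2);
          }
        }
        // spatial neighbours
        const std::vector<int>& nbc = nb[cc];
        for (size_t k = 0; k < nbc.size(); ++k) {
          int c2 = nbc[k];
          double v2 = t(c2, ss);
          if (lab(c2, ss) == 0 && ((sign > 0 && v2 > thr) ||
                                   (sign < 0 && v2 < -thr))) {
            lab(c2, ss) = next;
            stack.push_back(c2 + nch * ss);
          }
        }
      }
      sums.push_back(acc);
    }
  }
}

static std::vector< std::vector<int> > as_nb(const List& neighbours) {
  int nch = neighbours.size();
  std::vector< std::vector<int> > nb(nch);
  for (int c = 0; c < nch; ++c) {
    IntegerVector v = neighbours[c];
    nb[c].reserve(v.size());
    for (int k = 0; k < v.size(); ++k) nb[c].push_back(v[k] - 1); // 1-based in
  }
  return nb;
}

// [[Rcpp::export(name = ".clusterLabel")]]
List clusterLabel(NumericMatrix t, double thr, List neighbours) {
  IntegerMatrix lab(t.nrow(), t.ncol());
  std::vector<double> sums;
  std::vector< std::vector<int> > nb = as_nb(neighbours);
  label_impl(t, thr, nb, lab, sums);
  return List::create(_["labels"] = lab, _["sums"] = wrap(sums));
}

// Maximum |summed t| over clusters for each row of a permutations x cells
// matrix (cells in channel-fastest order). Returns one value per row.
// [[Rcpp::export(name = ".permMaxClusterSums")]]
NumericVector permMaxClusterSums(NumericMatrix tperm, int nch, int ns,
                                 double thr, List neighbours) {
  std::vector< std::vector<int> > nb = as_nb(neighbours);
  int np = tperm.nrow();
  NumericVector out(np);
  NumericMatrix t(nch, ns);
  for (int p = 0; p < np; ++p) {
    for (int j = 0; j < nch * ns; ++j) t[j] = tperm(p, j);
    IntegerMatrix lab(nch, ns);
    std::vector<double> sums;
    label_impl(t, thr, nb, lab, sums);
    double mx = 0.0;
    for (size_t k = 0; k < sums.size(); ++k) {
      double a = sums[k] < 0 ? -sums[k] : sums[k];
      if (a > mx) mx = a;
    }
    out[p] = mx;
  }
  return out;
}
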
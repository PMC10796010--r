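#include <Rcpp.h>
using namespace Rcpp;

// Global alignment with affine gaps (Gotoh three-state DP).
//
// Gap scoring convention: a gap of length L costs
//   gap_open + (L - 1) * gap_extend
// i.e. gap_open is charged for the first gap position and gap_extend for
// each additional one.  Scores are maximised.  Traceback ties are broken
// deterministically in the order diagonal > up (gap in b) > left (gap in
// a), applied both to state choice within a cell and to the final state.
//
// a, b: 0-based integer encodings into the rows/cols of `subst`.
// Returns aligned index vectors (1-based positions, 0 = gap) and score.

// [[Rcpp::export(name = ".nw_affine_cpp")]]
List nw_affine_cpp(IntegerVector a, IntegerVector b, NumericMatrix subst,
                   double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  // state 0 = M (diagonal), 1 = U (gap in b, consumes a), 2 = L (gap in a)
  NumericMatrix M(n + 1, m + 1), U(n + 1, m + 1), L(n + 1, m + 1);
  M(0, 0) = 0.0; U(0, 0) = NEG; L(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; L(i, 0) = NEG;
    U(i, 0) = gap_open + (i - 1) * gap_extend;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; U(0, j) = NEG;
    L(0, j) = gap_open + (j - 1) * gap_extend;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = subst(a[i - 1], b[j - 1]);
      double dM = M(i - 1, j - 1), dU = U(i - 1, j - 1), dL = L(i - 1, j - 1);
      double best = dM;                     // tie order: M > U > L
      if (dU > best) best = dU;
      if (dL > best) best = dL;
      M(i, j) = best + s;
      // U: gap in b; open from M or L, extend from U
      double uo = std::max(M(i - 1, j), L(i - 1, j)) + gap_open;
      double ue = U(i - 1, j) + gap_extend;
      U(i, j) = std::max(uo, ue);
      double lo = std::max(M(i, j - 1), U(i, j - 1)) + gap_open;
      double le = L(i, j - 1) + gap_extend;
      L(i, j) = std::max(lo, le);
    }
  }
  double fm = M(n, m), fu = U(n, m), fl = L(n, m);
  int state = 0; double score = fm;
  if (fu > score) { score = fu; state = 1; }
  if (fl > score) { score = fl; state = 2; }

  std::vector<int> pa, pb;
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      double target = M(i, j) - subst(a[i - 1], b[j - 1]);
      double dM = M(i - 1, j - 1), dU = U(i - 1, j - 1), dL = L(i - 1, j - 1);
      if (std::abs(dM - target) < eps) state = 0;
      else if (std::abs(dU - target) < eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      double here = U(i, j);
      if (std::abs(M(i - 1, j) + gap_open - here) < eps) state = 0;
      else if (std::abs(U(i - 1, j) + gap_extend - here) < eps) state = 1;
      else state = 2;
      --i;
    } else {
      pa.push_back(0); pb.push_back(j);
      double here = L(i, j);
      if (std::abs(M(i, j - 1) + gap_open - here) < eps) state = 0;
      else if (std::abs(U(i, j - 1) + gap_open - here) < eps) state = 1;
      else state = 2;
      --j;
    }
    if (i == 0 && j > 0) state = 2;
    if (j == 0 && i > 0) state = 1;
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["pos_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["pos_b"] = IntegerVector(pb.begin(), pb.end()));
}
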
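#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment over integer-encoded segments with a
// linear gap penalty. Codes are 1-based row/column indices into S.
// Traceback tie-break: diagonal, then gap on the left side (consume right),
// then gap on the right side (consume left). All candidate values are
// recomputed from the same operands, so exact floating-point comparison in
// the traceback reproduces the fill deterministically.
static void nw_core(const IntegerVector& a, const IntegerVector& b,
                    const NumericMatrix& S, double gap,
                    std::vector<int>& la, std::vector<int>& ra,
                    double& score) {
  const int n = a.size(), m = b.size();
  NumericMatrix F(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) F(i, 0) = i * gap;
  for (int j = 1; j <= m; ++j) F(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = F(i - 1, j - 1) + S(a[i - 1] - 1, b[j - 1] - 1);
      double l = F(i, j - 1) + gap;
      double u = F(i - 1, j) + gap;
      double best = d;
      if (l > best) best = l;
      if (u > best) best = u;
      F(i, j) = best;
    }
  }
  score = F(n, m);
  la.clear(); ra.clear();
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        F(i, j) == F(i - 1, j - 1) + S(a[i - 1] - 1, b[j - 1] - 1)) {
      la.push_back(i); ra.push_back(j); --i; --j;
    } else if (j > 0 && F(i, j) == F(i, j - 1) + gap) {
      la.push_back(0); ra.push_back(j); --j;
    } else {
      la.push_back(i); ra.push_back(0); --i;
    }
  }
  std::reverse(la.begin(), la.end());
  std::reverse(ra.begin(), ra.end());
}

// [[Rcpp::export(name = ".nw_align_int")]]
List nw_align_int(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap) {
  std::vector<int> la, ra;
  double score = 0.0;
  nw_core(a, b, S, gap, la, ra, score);
  return List::create(_["la"] = wrap(la), _["ra"] = wrap(ra),
                      _["score"] = score);
}

// Align many pairs in one call. seqs is a list of integer vectors; pi and
// pj are 1-based indices into seqs. Cells of all alignments come back
// concatenated, with pair_id marking which alignment each cell belongs to.
// [[Rcpp::export(name = ".nw_align_batch")]]
List nw_align_batch(List seqs, IntegerVector pi, IntegerVector pj,
                    NumericMatrix S, double gap) {
  const int np = pi.size();
  std::vector<int> la_all, ra_all, pid;
  NumericVector scores(np);
  std::vector<int> la, ra;
  la_all.reserve(np * 8); ra_all.reserve(np * 8); pid.reserve(np * 8);
  for (int p = 0; p < np; ++p) {
    IntegerVector a = seqs[pi[p] - 1];
    IntegerVector b = seqs[pj[p] - 1];
    double score = 0.0;
    nw_core(a, b, S, gap, la, ra, score);
    scores[p] = score;
    for (size_t c = 0; c < la.size(); ++c) {
      la_all.push_back(la[c]);
      ra_all.push_back(ra[c]);
      pid.push_back(p + 1);
    }
  }
  return List::create(_["la"] = wrap(la_all), _["ra"] = wrap(ra_all),
                      _["pair_id"] = wrap(pid), _["score"] = scores);
}
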
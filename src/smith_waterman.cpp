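#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment (Gotoh affine gaps): a gap of length
// L costs gap_open + L * gap_extend, the usual EMBOSS/Biostrings
// convention.  Returns the single best-scoring local alignment with
// traceback; ties resolve to the earliest end cell and, within a
// cell, to substitution over gaps.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b,
                  double match = 1.0, double mismatch = -1.0,
                  double gap_open = 2.0, double gap_extend = 2.0) {
  int n = a.size(), m = b.size();
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  // traceback: 0 stop, 1 diag, 2 up from H, 3 up extend, 4 left from H,
  // 5 left extend (up = gap in b / consumes a; left = gap in a)
  IntegerMatrix tbH(n + 1, m + 1), tbE(n + 1, m + 1), tbF(n + 1, m + 1);
  const double NEG = -1e18;
  for (int j = 0; j <= m; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // E: gap in b (vertical, consumes a[i-1])
      double e_open = H(i - 1, j) - gap_open - gap_extend;
      double e_ext = E(i - 1, j) - gap_extend;
      E(i, j) = std::max(e_open, e_ext);
      tbE(i, j) = (e_open >= e_ext) ? 2 : 3;
      // F: gap in a (horizontal, consumes b[j-1])
      double f_open = H(i, j - 1) - gap_open - gap_extend;
      double f_ext = F(i, j - 1) - gap_extend;
      F(i, j) = std::max(f_open, f_ext);
      tbF(i, j) = (f_open >= f_ext) ? 4 : 5;
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double diag = H(i - 1, j - 1) + s;
      double h = diag;
      int t = 1;
      if (E(i, j) > h) { h = E(i, j); t = 2; }
      if (F(i, j) > h) { h = F(i, j); t = 4; }
      if (h <= 0.0) { h = 0.0; t = 0; }
      H(i, j) = h;
      tbH(i, j) = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::string aa, bb;
  int i = bi, j = bj, state = 0; // 0 = in H, 1 = in E, 2 = in F
  while (i > 0 && j > 0) {
    if (state == 0) {
      int t = tbH(i, j);
      if (t == 0 || H(i, j) <= 0.0) break;
      if (t == 1) { aa += a[i - 1]; bb += b[j - 1]; --i; --j; }
      else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      int t = tbE(i, j);
      aa += a[i - 1]; bb += '-'; --i;
      state = (t == 2) ? 0 : 1;
    } else {
      int t = tbF(i, j);
      aa += '-'; bb += b[j - 1]; --j;
      state = (t == 4) ? 0 : 2;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(
    _["score"] = best,
    _["a_start"] = i + 1, _["a_end"] = bi,
    _["b_start"] = j + 1, _["b_end"] = bj,
    _["a_aln"] = aa, _["b_aln"] = bb);
}
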
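#include <Rcpp.h>
using namespace Rcpp;

// Exact affine-gap local alignment (Gotoh) with traceback.
//
// Sequences arrive as 0-based integer codes into `submat` rows/columns.
// Gap cost follows the BLAST convention: a gap of length L costs
// gap_open + L * gap_extend.
//
// Identity over aligned columns: a column counts as identical only when
// both residues are equal AND neither is the mask code `x_code`
// (masked/ambiguous X never counts as a match).

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix submat,
                  double gap_open, double gap_extend, int x_code) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0.0, _["n_identical"] = 0,
                        _["align_length"] = 0, _["qstart"] = 0, _["qend"] = 0,
                        _["sstart"] = 0, _["send"] = 0);

  const double gop = gap_open + gap_extend;  // cost of first gapped column
  const double NEG = -1e30;

  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, NEG), Ecur(n + 1, NEG);  // gap in query (vertical)
  // F: gap in subject (horizontal), kept per-row
  // traceback matrices: 0 = stop, 1 = diag, 2 = up (gap in b), 3 = left (gap in a)
  std::vector<unsigned char> tbH((m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbE((m + 1) * (n + 1), 0);  // 1 = opened here, 0 = extended
  std::vector<unsigned char> tbF((m + 1) * (n + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    double F = NEG;
    Hcur[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      // E: gap in subject direction? Define E = best ending with gap in b
      // (consuming a[i]), i.e. vertical move i-1 -> i at fixed j.
      double e_open = Hprev[j] - gop;
      double e_ext  = Eprev[j] - gap_extend;
      double E = std::max(e_open, e_ext);
      tbE[i * (n + 1) + j] = (e_open >= e_ext) ? 1 : 0;

      double f_open = Hcur[j - 1] - gop;
      double f_ext  = F - gap_extend;
      F = std::max(f_open, f_ext);
      tbF[i * (n + 1) + j] = (f_open >= f_ext) ? 1 : 0;

      double diag = Hprev[j - 1] + submat(a[i - 1], b[j - 1]);
      double h = 0.0;
      unsigned char tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E > h)    { h = E;    tb = 2; }
      if (F > h)    { h = F;    tb = 3; }
      Hcur[j] = h;
      Ecur[j] = E;
      tbH[i * (n + 1) + j] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }

  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["n_identical"] = 0,
                        _["align_length"] = 0, _["qstart"] = 0, _["qend"] = 0,
                        _["sstart"] = 0, _["send"] = 0);

  // Traceback from (bi, bj). State 0 = in H, 1 = in E, 2 = in F.
  int i = bi, j = bj, state = 0;
  int n_id = 0, alen = 0;
  int qend = bi, send = bj, qstart = bi, sstart = bj;
  while (i > 0 && j > 0) {
    if (state == 0) {
      unsigned char tb = tbH[i * (n + 1) + j];
      if (tb == 0) break;
      if (tb == 1) {
        ++alen;
        if (a[i - 1] == b[j - 1] && a[i - 1] != x_code) ++n_id;
        qstart = i; sstart = j;
        --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {           // vertical gap: consumes a[i]
      ++alen;
      qstart = i;
      unsigned char opened = tbE[i * (n + 1) + j];
      --i;
      if (opened) state = 0;
    } else {                           // horizontal gap: consumes b[j]
      ++alen;
      sstart = j;
      unsigned char opened = tbF[i * (n + 1) + j];
      --j;
      if (opened) state = 0;
    }
  }

  return List::create(_["score"] = best, _["n_identical"] = n_id,
                      _["align_length"] = alen, _["qstart"] = qstart,
                      _["qend"] = qend, _["sstart"] = sstart, _["send"] = send);
}

// Score-only variant without traceback storage, used for the all-vs-all
// sweep's first pass and for masking monotonicity checks. Linear memory.

// [[Rcpp::export]]
double sw_score_cpp(IntegerVector a, IntegerVector b, NumericMatrix submat,
                    double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) return 0.0;
  const double gop = gap_open + gap_extend;
  const double NEG = -1e30;
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, NEG), Ecur(n + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    double F = NEG;
    Hcur[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      double E = std::max(Hprev[j] - gop, Eprev[j] - gap_extend);
      F = std::max(Hcur[j - 1] - gop, F - gap_extend);
      double h = Hprev[j - 1] + submat(a[i - 1], b[j - 1]);
      h = std::max(0.0, std::max(h, std::max(E, F)));
      Hcur[j] = h; Ecur[j] = E;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  return best;
}
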
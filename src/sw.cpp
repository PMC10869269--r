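#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman over a precomputed position-pair score matrix.
// S(i, j) is the (real-valued) score of matching query residue i with target
// residue j; the combined amino-acid + structural-state weighting and the
// compositional bias offsets are already folded into S by the caller.
// Gap of length g costs gap_open + (g - 1) * gap_extend.
//
// Returns the best local score, the 1-based alignment ranges and the aligned
// residue pairs of one optimal path (ties resolved diagonal > up > left,
// which makes the traceback deterministic).
// [[Rcpp::export]]
List sw_align_cpp(NumericMatrix S, double gap_open, double gap_extend,
                  bool traceback = true) {
  const int n = S.nrow(), m = S.ncol();
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0),
      Ecur(m + 1, R_NegInf), Fcol(m + 1, R_NegInf);
  // direction codes: 0 stop, 1 diag, 2 up (gap in target, consume query),
  // 3 left (gap in query, consume target)
  std::vector<unsigned char> dirH, dirE, dirF;
  if (traceback) {
    dirH.assign((size_t)(n + 1) * (m + 1), 0);
    dirE.assign((size_t)(n + 1) * (m + 1), 0);
    dirF.assign((size_t)(n + 1) * (m + 1), 0);
  }
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    std::fill(Ecur.begin(), Ecur.end(), R_NegInf);
    Hcur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      // E: gap in query (move left), F: gap in target (move up)
      double e_open = Hcur[j - 1] - gap_open;
      double e_ext = Ecur[j - 1] - gap_extend;
      double e = std::max(e_open, e_ext);
      double f_open = Hprev[j] - gap_open;
      double f_ext = Fcol[j] - gap_extend;
      double f = std::max(f_open, f_ext);
      double diag = Hprev[j - 1] + S(i - 1, j - 1);
      double h = std::max(0.0, std::max(diag, std::max(f, e)));
      if (traceback) {
        size_t off = (size_t)i * (m + 1) + j;
        dirE[off] = (e_ext >= e_open) ? 3 : 1;   // from E (extend) or H (open)
        dirF[off] = (f_ext >= f_open) ? 2 : 1;
        unsigned char dh = 0;
        if (h > 0) {
          if (h == diag) dh = 1;
          else if (h == f) dh = 2;
          else dh = 3;
        }
        dirH[off] = dh;
      }
      Ecur[j] = e;
      Fcol[j] = f;
      Hcur[j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  if (!traceback || best <= 0.0) {
    return List::create(_["score"] = best, _["q_end"] = bi, _["t_end"] = bj,
                        _["q_start"] = NA_INTEGER, _["t_start"] = NA_INTEGER,
                        _["pairs"] = R_NilValue, _["cigar"] = NA_STRING);
  }
  // traceback
  std::vector<int> qi, tj;
  std::string ops;
  int i = bi, j = bj, state = 0;  // 0 = H, 2 = F(up), 3 = E(left)
  while (i > 0 && j > 0) {
    size_t off = (size_t)i * (m + 1) + j;
    if (state == 0) {
      unsigned char d = dirH[off];
      if (d == 0) break;
      if (d == 1) {
        qi.push_back(i); tj.push_back(j); ops.push_back('M');
        --i; --j;
      } else {
        state = d;
      }
    } else if (state == 2) {  // F: gap in target, consume query
      ops.push_back('I');
      state = (dirF[off] == 2) ? 2 : 0;
      --i;
    } else {  // E: gap in query, consume target
      ops.push_back('D');
      state = (dirE[off] == 3) ? 3 : 0;
      --j;
    }
  }
  int qs = i + 1, ts = j + 1;
  std::reverse(ops.begin(), ops.end());
  std::reverse(qi.begin(), qi.end());
  std::reverse(tj.begin(), tj.end());
  // run-length encode the cigar
  std::string cigar;
  for (size_t p = 0; p < ops.size();) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cigar += std::to_string(q - p);
    cigar.push_back(ops[p]);
    p = q;
  }
  IntegerMatrix pairs(qi.size(), 2);
  for (size_t r = 0; r < qi.size(); ++r) {
    pairs(r, 0) = qi[r];
    pairs(r, 1) = tj[r];
  }
  return List::create(_["score"] = best, _["q_end"] = bi, _["t_end"] = bj,
                      _["q_start"] = qs, _["t_start"] = ts,
                      _["pairs"] = pairs, _["cigar"] = cigar);
}
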
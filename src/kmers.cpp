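#include <Rcpp.h>
using namespace Rcpp;

// Branch-and-bound enumeration of all k-mers over an alphabet of A letters
// whose summed per-position score reaches the threshold. `sc` holds the
// integer substitution scores of every candidate letter (rows) against the
// query k-mer's letter at each position (columns); `ord` gives, per
// position, the candidate letters sorted by descending score (1-based).
// Returns the letter indices (1-based) of all qualifying k-mers, one row
// per k-mer.
// [[Rcpp::export]]
IntegerMatrix enumerate_similar_kmers_cpp(NumericMatrix sc, IntegerMatrix ord,
                                          double threshold) {
  const int A = sc.nrow(), k = sc.ncol();
  std::vector<double> suffix_best(k + 1, 0.0);
  for (int p = k - 1; p >= 0; --p) {
    double mx = sc(ord(0, p) - 1, p);
    suffix_best[p] = suffix_best[p + 1] + mx;
  }
  std::vector<int> cur(k);
  std::vector<int> out;  // flattened rows
  // iterative DFS with explicit rank stack
  std::vector<int> rank(k, 0);
  std::vector<double> acc(k + 1, 0.0);
  int pos = 0;
  while (pos >= 0) {
    if (rank[pos] >= A) { --pos; if (pos >= 0) ++rank[pos]; continue; }
    int li = ord(rank[pos], pos) - 1;
    double s = acc[pos] + sc(li, pos);
    if (s + suffix_best[pos + 1] < threshold) {
      // letters are score-sorted: nothing further at this position qualifies
      --pos;
      if (pos >= 0) ++rank[pos];
      continue;
    }
    cur[pos] = li + 1;
    if (pos == k - 1) {
      for (int p = 0; p < k; ++p) out.push_back(cur[p]);
      ++rank[pos];
    } else {
      acc[pos + 1] = s;
      ++pos;
      rank[pos] = 0;
    }
  }
  const int n = out.size() / k;
  IntegerMatrix res(n, k);
  for (int r = 0; r < n; ++r)
    for (int p = 0; p < k; ++p) res(r, p) = out[(size_t)r * k + p];
  return res;
}
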
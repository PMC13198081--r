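#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment of a read against a short locus reference
// with linear gap penalties. 'N' never matches. Among co-optimal endpoints
// the alignment with the leftmost reference start is returned (then the
// leftmost read start, then the leftmost reference end) so results are
// deterministic regardless of traversal order.
//
// Returns score, 0-based half-open coordinates on both sequences, the two
// gapped alignment strings, and match/column counts for identity filtering.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string read, std::string ref,
                  double match, double mismatch, double gap) {
  const int n = (int) read.size();
  const int m = (int) ref.size();
  const int W = m + 1;
  std::vector<double> H((size_t)(n + 1) * W, 0.0);
  // traceback: 0 = stop, 1 = diagonal, 2 = up (gap in ref), 3 = left (gap in read)
  std::vector<unsigned char> tb((size_t)(n + 1) * W, 0);

  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    const char a = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char b = ref[j - 1];
      const bool amb = (a == 'N' || b == 'N');
      const double s = (!amb && a == b) ? match : mismatch;
      const double diag = H[(size_t)(i - 1) * W + (j - 1)] + s;
      const double up   = H[(size_t)(i - 1) * W + j] + gap;
      const double left = H[(size_t)i * W + (j - 1)] + gap;
      double h = diag; unsigned char t = 1;
      if (up > h)   { h = up;   t = 2; }
      if (left > h) { h = left; t = 3; }
      if (h <= 0.0) { h = 0.0;  t = 0; }
      H[(size_t)i * W + j] = h;
      tb[(size_t)i * W + j] = t;
      if (h > best) best = h;
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["accepted_raw"] = false);
  }

  // Collect all co-optimal endpoints, trace each back, keep the preferred one.
  int best_rs = -1, best_qs = -1, best_re = -1, best_qe = -1;
  std::string best_ra, best_qa;
  int best_matches = 0, best_cols = 0;
  const double eps = 1e-9;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (H[(size_t)i * W + j] < best - eps) continue;
      // traceback
      int ci = i, cj = j;
      std::string ra, qa;  // ref-aligned, read(query)-aligned, built reversed
      int matches = 0, cols = 0;
      while (ci > 0 && cj > 0) {
        unsigned char t = tb[(size_t)ci * W + cj];
        if (t == 0) break;
        if (t == 1) {
          const char a = read[ci - 1], b = ref[cj - 1];
          ra.push_back(b); qa.push_back(a);
          if (a == b && a != 'N') ++matches;
          --ci; --cj;
        } else if (t == 2) {
          ra.push_back('-'); qa.push_back(read[ci - 1]);
          --ci;
        } else {
          ra.push_back(ref[cj - 1]); qa.push_back('-');
          --cj;
        }
        ++cols;
      }
      const int rs = cj, qs = ci;  // 0-based start positions
      bool take = false;
      if (best_rs < 0) take = true;
      else if (rs != best_rs) take = rs < best_rs;
      else if (qs != best_qs) take = qs < best_qs;
      else if (j != best_re)  take = j < best_re;
      if (take) {
        std::reverse(ra.begin(), ra.end());
        std::reverse(qa.begin(), qa.end());
        best_rs = rs; best_qs = qs; best_re = j; best_qe = i;
        best_ra = ra; best_qa = qa;
        best_matches = matches; best_cols = cols;
      }
    }
  }

  const double identity = best_cols > 0 ? (double) best_matches / best_cols : 0.0;
  return List::create(
    _["score"] = best,
    _["accepted_raw"] = true,
    _["ref_start"] = best_rs,
    _["ref_end"] = best_re,
    _["read_start"] = best_qs,
    _["read_end"] = best_qe,
    _["n_matches"] = best_matches,
    _["n_columns"] = best_cols,
    _["identity"] = identity,
    _["ref_aligned"] = best_ra,
    _["read_aligned"] = best_qa);
}

// Batched version: aligns many reads against one reference, returning only
// the per-read summary needed for filtering plus the codon bases mapped to
// ref positions codon_offset..codon_offset+2 ("-" for gap, "" when the
// alignment does not cover that position).
// [[Rcpp::export(name = ".sw_align_batch_cpp")]]
DataFrame sw_align_batch_cpp(CharacterVector reads, std::string ref,
                             double match, double mismatch, double gap,
                             int codon_offset) {
  const int N = reads.size();
  NumericVector score(N), identity(N);
  IntegerVector ref_start(N), ref_end(N), n_columns(N);
  CharacterVector codon(N);
  for (int k = 0; k < N; ++k) {
    std::string rd = as<std::string>(reads[k]);
    List al = sw_align_cpp(rd, ref, match, mismatch, gap);
    if (!as<bool>(al["accepted_raw"])) {
      score[k] = 0; identity[k] = 0; ref_start[k] = NA_INTEGER;
      ref_end[k] = NA_INTEGER; n_columns[k] = 0; codon[k] = NA_STRING;
      continue;
    }
    score[k] = as<double>(al["score"]);
    identity[k] = as<double>(al["identity"]);
    const int rs = as<int>(al["ref_start"]);
    const int re = as<int>(al["ref_end"]);
    ref_start[k] = rs; ref_end[k] = re;
    n_columns[k] = as<int>(al["n_columns"]);
    std::string ra = as<std::string>(al["ref_aligned"]);
    std::string qa = as<std::string>(al["read_aligned"]);
    // walk columns, record read bases at the three codon ref positions
    std::string cd = "";
    bool covered[3] = {false, false, false};
    char bases[3] = {'-', '-', '-'};
    int rp = rs;
    for (size_t c = 0; c < ra.size(); ++c) {
      if (ra[c] != '-') {
        const int off = rp - codon_offset;
        if (off >= 0 && off < 3) { covered[off] = true; bases[off] = qa[c]; }
        ++rp;
      }
    }
    if (covered[0] && covered[1] && covered[2]) {
      cd.push_back(bases[0]); cd.push_back(bases[1]); cd.push_back(bases[2]);
      codon[k] = cd;
    } else {
      codon[k] = NA_STRING;
    }
  }
  return DataFrame::create(
    _["score"] = score, _["identity"] = identity,
    _["ref_start"] = ref_start, _["ref_end"] = ref_end,
    _["n_columns"] = n_columns, _["codon"] = codon,
    _["stringsAsFactors"] = false);
}
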
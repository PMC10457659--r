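#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// Affine-gap local alignment (Gotoh) with deterministic tie-breaking.
//
// A gap of length L costs gap_open + L * gap_extend (both penalties <= 0).
// All scores are multiples of 0.5 in the default scheme, so double
// comparisons are exact.
//
// Tie-breaking contract (mirrored by the pure-R oracle in the test suite):
//   * best cell = highest score, then smallest target end, then smallest
//     query end (scan order: target index outer ascending, query inner);
//   * traceback prefers diagonal (M) over target-consuming gap (D) over
//     query-consuming gap (I); ties inside a gap prefer closing the gap.
// Preferring the diagonal during the backward walk pushes gaps toward the
// start of the alignment, i.e. indels come out left-aligned.
//
// 'N' never scores as a match (always the mismatch score).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string target,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int m = (int) query.size();
  const int n = (int) target.size();
  if (m < 1 || n < 1)
    stop("query and target must be nonempty");

  const int w = m + 1;  // row stride: query index is the fast dimension
  std::vector<double> H((size_t) w * (n + 1), 0.0);
  std::vector<double> E((size_t) w * (n + 1), NEG_INF);  // gap consuming target (D)
  std::vector<double> F((size_t) w * (n + 1), NEG_INF);  // gap consuming query (I)

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int j = 1; j <= n; ++j) {
    const char tc = target[j - 1];
    for (int i = 1; i <= m; ++i) {
      const char qc = query[i - 1];
      const size_t idx = (size_t) j * w + i;
      const size_t up = (size_t) j * w + (i - 1);          // i-1, j
      const size_t left = (size_t) (j - 1) * w + i;        // i, j-1
      const size_t diag = (size_t) (j - 1) * w + (i - 1);  // i-1, j-1

      const double sub = (qc == tc && qc != 'N') ? match : mismatch;

      double e = H[left] + gap_open + gap_extend;
      const double e_ext = E[left] + gap_extend;
      if (e_ext > e) e = e_ext;
      E[idx] = e;

      double f = H[up] + gap_open + gap_extend;
      const double f_ext = F[up] + gap_extend;
      if (f_ext > f) f = f_ext;
      F[idx] = f;

      double h = H[diag] + sub;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0.0) h = 0.0;
      H[idx] = h;

      if (h > best) {  // strict: keeps smallest (j, i) on ties
        best = h;
        bi = i;
        bj = j;
      }
    }
  }

  // Traceback.
  std::vector<char> ops;      // reversed op stream
  int i = bi, j = bj;
  int n_mismatch = 0;
  int state = 0;  // 0 = H, 1 = E (D), 2 = F (I)

  if (best > 0.0) {
    for (;;) {
      const size_t idx = (size_t) j * w + i;
      if (state == 0) {
        const double h = H[idx];
        if (h <= 0.0) break;
        const size_t diag = (size_t) (j - 1) * w + (i - 1);
        const char qc = query[i - 1];
        const char tc = target[j - 1];
        const double sub = (qc == tc && qc != 'N') ? match : mismatch;
        if (i > 0 && j > 0 && h == H[diag] + sub) {
          ops.push_back('M');
          if (!(qc == tc && qc != 'N')) ++n_mismatch;
          --i; --j;
        } else if (h == E[idx]) {
          state = 1;
        } else if (h == F[idx]) {
          state = 2;
        } else {
          stop("traceback failure (H)");  // should not happen
        }
      } else if (state == 1) {
        const size_t left = (size_t) (j - 1) * w + i;
        ops.push_back('D');
        if (E[idx] == H[left] + gap_open + gap_extend) {
          state = 0;
        }  // else stay in E (gap extension)
        --j;
      } else {
        const size_t up = (size_t) j * w + (i - 1);
        ops.push_back('I');
        if (F[idx] == H[up] + gap_open + gap_extend) {
          state = 0;
        }
        --i;
      }
      if (i == 0 && j == 0) break;
    }
  }

  // Run-length encode the reversed op stream (reading it backwards gives the
  // forward CIGAR).
  std::vector<int> lens;
  std::vector<std::string> kinds;
  for (int k = (int) ops.size() - 1; k >= 0; --k) {
    const char op = ops[k];
    if (!kinds.empty() && kinds.back()[0] == op) {
      lens.back() += 1;
    } else {
      lens.push_back(1);
      kinds.push_back(std::string(1, op));
    }
  }

  return List::create(
      _["score"] = best,
      _["query_start"] = i,   // 0-based, half-open [query_start, query_end)
      _["query_end"] = bi,
      _["target_start"] = j,
      _["target_end"] = bj,
      _["n_mismatch"] = n_mismatch,
      _["cigar_len"] = IntegerVector(lens.begin(), lens.end()),
      _["cigar_op"] = CharacterVector(kinds.begin(), kinds.end()));
}
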
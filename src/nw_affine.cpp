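#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh's three-state
// recurrence. A gap of length L costs open + L * extend. Intended for the
// short segments between exact anchor blocks of near-identical genomes, so
// full dense matrices are affordable. Ties break deterministically in the
// order M (substitution) > X (gap in query) > Y (gap in reference).

// [[Rcpp::export]]
List nw_affine(std::string ref, std::string qry,
               int match = 1, int mismatch = -2,
               int gap_open = 5, int gap_extend = 1) {
  const int n = ref.size(), m = qry.size();
  const long NEG = std::numeric_limits<int>::min() / 4;
  const long W = m + 1;
  std::vector<long> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  M[0] = 0;
  for (int i = 1; i <= n; ++i) X[i * W] = -(gap_open + (long)i * gap_extend);
  for (int j = 1; j <= m; ++j) Y[j] = -(gap_open + (long)j * gap_extend);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      long s = (ref[i - 1] == qry[j - 1] &&
                ref[i - 1] != 'N') ? match : mismatch;
      long prev = std::max(M[(i - 1) * W + j - 1],
                 std::max(X[(i - 1) * W + j - 1], Y[(i - 1) * W + j - 1]));
      M[i * W + j] = prev + s;
      X[i * W + j] = std::max(
          std::max(M[(i - 1) * W + j], Y[(i - 1) * W + j]) -
              (gap_open + gap_extend),
          X[(i - 1) * W + j] - gap_extend);
      Y[i * W + j] = std::max(
          std::max(M[i * W + j - 1], X[i * W + j - 1]) -
              (gap_open + gap_extend),
          Y[i * W + j - 1] - gap_extend);
    }
  }
  // traceback
  std::string ra, qa;
  int i = n, j = m;
  long mm = M[n * W + m], xx = X[n * W + m], yy = Y[n * W + m];
  int state = (mm >= xx && mm >= yy) ? 0 : (xx >= yy ? 1 : 2);
  long score = std::max(mm, std::max(xx, yy));
  while (i > 0 || j > 0) {
    if (state == 0) {
      // came into M by consuming ref[i-1], qry[j-1]
      long s = (ref[i - 1] == qry[j - 1] && ref[i - 1] != 'N') ? match
                                                               : mismatch;
      ra.push_back(ref[i - 1]);
      qa.push_back(qry[j - 1]);
      long target = M[i * W + j] - s;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[i * W + j] == target) state = 0;
      else if (X[i * W + j] == target) state = 1;
      else state = 2;
    } else if (state == 1) {
      ra.push_back(ref[i - 1]);
      qa.push_back('-');
      long here = X[i * W + j];
      --i;
      if (X[i * W + j] - gap_extend == here) state = 1;
      else if (M[i * W + j] - (gap_open + gap_extend) == here) state = 0;
      else state = 2;
    } else {
      ra.push_back('-');
      qa.push_back(qry[j - 1]);
      long here = Y[i * W + j];
      --j;
      if (Y[i * W + j] - gap_extend == here) state = 2;
      else if (M[i * W + j] - (gap_open + gap_extend) == here) state = 0;
      else state = 1;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());
  return List::create(_["ref"] = ra, _["qry"] = qa, _["score"] = score);
}

// Longest strictly increasing subsequence, O(n log n) patience sorting.
// Returns 1-based indices into x of one LIS (used to chain alignment
// anchors whose reference positions are already sorted).

// [[Rcpp::export]]
IntegerVector lis_indices_cpp(IntegerVector x) {
  const int n = x.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> tails;      // last value of each pile
  std::vector<int> tails_idx;  // index holding that value
  std::vector<int> prev(n, -1);
  tails.reserve(n); tails_idx.reserve(n);
  for (int i = 0; i < n; ++i) {
    // first pile whose tail >= x[i]
    int lo = std::lower_bound(tails.begin(), tails.end(), x[i]) -
             tails.begin();
    if (lo == (int)tails.size()) {
      tails.push_back(x[i]);
      tails_idx.push_back(i);
    } else {
      tails[lo] = x[i];
      tails_idx[lo] = i;
    }
    prev[i] = (lo > 0) ? tails_idx[lo - 1] : -1;
  }
  std::vector<int> out;
  for (int i = tails_idx.back(); i >= 0; i = prev[i]) out.push_back(i + 1);
  std::reverse(out.begin(), out.end());
  return wrap(out);
}
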
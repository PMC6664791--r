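#include <Rcpp.h>
#include <vector>
#include <string>
#include <utility>

using namespace Rcpp;

// Baseline folding engine: maximum-weight nested pairing (Nussinov-style
// dynamic program) with minimum hairpin loop length 3. Pair weights follow
// the usual stability ordering GC > AU > GU; the reported energy is minus
// the total pair weight, so it is <= 0 with at least one pair and 0 for the
// all-unpaired structure. Deterministic: ties resolved by a fixed scan
// order (leave i unpaired, else smallest admissible partner k).

static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return 0;
}

static const int MIN_LOOP = 3;  // min unpaired bases in a hairpin loop

// [[Rcpp::export]]
List nussinov_fold_cpp(std::string seq) {
  const int n = (int)seq.size();
  std::string db(n, '.');
  if (n == 0) return List::create(_["structure"] = db, _["score"] = 0.0);

  // M[i][j]: best weight on seq[i..j], 0-based inclusive
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = MIN_LOOP + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j];  // i unpaired
      for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
        int w = pair_weight(seq[i], seq[k]);
        if (w == 0) continue;
        int cand = w + (k - 1 >= i + 1 ? M[i + 1][k - 1] : 0)
                     + (k + 1 <= j ? M[k + 1][j] : 0);
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }

  // traceback mirroring the fill order exactly
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < MIN_LOOP + 1) continue;
    if (M[i][j] == M[i + 1][j]) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
      int w = pair_weight(seq[i], seq[k]);
      if (w == 0) continue;
      int inner = (k - 1 >= i + 1 ? M[i + 1][k - 1] : 0);
      int outer = (k + 1 <= j ? M[k + 1][j] : 0);
      if (M[i][j] == w + inner + outer) {
        db[i] = '(';
        db[k] = ')';
        if (k - 1 >= i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k + 1 <= j) stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }

  return List::create(_["structure"] = db,
                      _["score"] = -(double)M[0][n - 1]);
}
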
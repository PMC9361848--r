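#include <Rcpp.h>
using namespace Rcpp;

// Legal pairs: Watson-Crick plus GU wobble (standard for plant miRNA hairpins).
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Base-pair maximization (Nussinov) with a minimum hairpin loop size.
// Returns a 1-based pair table; 0 means unpaired. Traceback is deterministic:
// at ties, position i is paired rather than left unpaired, and among equally
// optimal partners the smallest admissible j wins.
// [[Rcpp::export(name = ".nussinov_pairs")]]
IntegerVector nussinov_pairs(std::string seq, int min_loop) {
  const int n = (int) seq.size();
  IntegerVector pt(n, 0);
  if (n < 2) return pt;

  std::vector< std::vector<int> > N(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      int best = N[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int v = 1;
        if (k - i - 1 > 0) v += N[i + 1][k - 1];
        if (k < j)         v += N[k + 1][j];
        if (v > best) best = v;
      }
      N[i][j] = best;
    }
  }

  std::vector< std::pair<int,int> > todo;
  todo.push_back(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    const int i = todo.back().first;
    const int j = todo.back().second;
    todo.pop_back();
    if (i >= j || j - i <= min_loop || N[i][j] == 0) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(seq[i], seq[k])) continue;
      int v = 1;
      if (k - i - 1 > 0) v += N[i + 1][k - 1];
      if (k < j)         v += N[k + 1][j];
      if (v == N[i][j]) {
        pt[i] = k + 1;
        pt[k] = i + 1;
        if (k - i - 1 > 0) todo.push_back(std::make_pair(i + 1, k - 1));
        if (k < j)         todo.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) todo.push_back(std::make_pair(i + 1, j));
  }
  return pt;
}
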
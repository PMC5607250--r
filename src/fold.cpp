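#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Pair scores for Watson-Crick and GU wobble pairs; -1 marks an
// unpairable combination. Sequences are DNA-alphabet internally (U -> T).
static inline int pair_score(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return -1;
}

// Maximum-scoring non-crossing pairing with a stacking bonus.
//
// F[i][j]: best score on the subsequence [i, j].
// P[i][j]: best score on [i, j] given that i pairs with j.
// A pair (i, j) is allowed when the bases are complementary (WC or GU)
// and at least min_loop unpaired bases fit between them. A helix
// continuation (i, j) over (i+1, j-1) earns stack_bonus on top of the
// inner pair's score.
//
// Traceback is deterministic: helix continuation is preferred on ties,
// then the smallest k achieving the optimum in the bifurcation scan.
// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(std::string seq, int min_loop = 3, int stack_bonus = 1) {
  const int n = (int)seq.size();
  const int NEG = -1000000000;
  if (n <= 0) stop("empty sequence");

  std::vector<std::vector<int>> F(n, std::vector<int>(n, 0));
  std::vector<std::vector<int>> P(n, std::vector<int>(n, NEG));

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      // P[i][j]
      int s = pair_score(seq[i], seq[j]);
      if (s > 0 && j - i - 1 >= min_loop) {
        int inner = (i + 1 <= j - 1) ? F[i + 1][j - 1] : 0;
        if (P[i + 1][j - 1] > NEG / 2) {
          int stacked = P[i + 1][j - 1] + stack_bonus;
          if (stacked > inner) inner = stacked;
        }
        P[i][j] = s + inner;
      }
      // F[i][j]
      int best = F[i][j - 1];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (P[k][j] > NEG / 2) {
          int cand = (k > i ? F[i][k - 1] : 0) + P[k][j];
          if (cand > best) best = cand;
        }
      }
      F[i][j] = best;
    }
  }

  // Traceback.
  IntegerVector mate(n, -1);
  std::vector<std::array<int, 3>> stack; // {i, j, state}; state 0 = F, 1 = P
  if (n >= min_loop + 2) stack.push_back({0, n - 1, 0});
  while (!stack.empty()) {
    auto fr = stack.back();
    stack.pop_back();
    int i = fr[0], j = fr[1], st = fr[2];
    if (j - i < min_loop + 1) continue;
    if (st == 0) {
      int target = F[i][j];
      if (target == 0) continue;
      bool done = false;
      // Prefer a pairing decomposition at the smallest k.
      for (int k = i; k <= j - min_loop - 1 && !done; ++k) {
        if (P[k][j] > NEG / 2) {
          int cand = (k > i ? F[i][k - 1] : 0) + P[k][j];
          if (cand == target) {
            if (k > i) stack.push_back({i, k - 1, 0});
            stack.push_back({k, j, 1});
            done = true;
          }
        }
      }
      if (!done) stack.push_back({i, j - 1, 0});
    } else {
      mate[i] = j;
      mate[j] = i;
      int s = pair_score(seq[i], seq[j]);
      int inner = P[i][j] - s;
      if (i + 1 > j - 1) continue;
      bool stacked_ok = P[i + 1][j - 1] > NEG / 2 &&
                        P[i + 1][j - 1] + stack_bonus == inner;
      if (stacked_ok) {
        stack.push_back({i + 1, j - 1, 1});
      } else if (F[i + 1][j - 1] == inner) {
        stack.push_back({i + 1, j - 1, 0});
      }
    }
  }

  int score = (n >= min_loop + 2) ? F[0][n - 1] : 0;
  return List::create(_["score"] = score, _["mate"] = mate);
}
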
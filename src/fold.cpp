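#include <Rcpp.h>
#include <vector>
#include <string>

// Maximum-weight non-crossing base pairing by dynamic programming.
//
// Pair weights (DNA alphabet, U stored as T): G:C = 3, A:T = 2, G:T = 1.
// The reported folding energy is the negated total weight in kcal/mol, so a
// structure with four G:C pairs scores -12. Hairpin loops enclose at least
// 3 unpaired nucleotides (j - i - 1 >= 3 for a pair i:j) and lonely pairs
// are disallowed: every helix contains at least two stacked pairs, so a
// pair (i, j) requires (i+1, j-1) or (i-1, j+1) to be paired as well.

static const int MINLOOP = 3;
static const int NEG = -1000000;

static int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

class FoldDP {
public:
  explicit FoldDP(const std::string& s) : seq(s), n((int)s.size()),
      F(n, std::vector<int>(n, 0)), P(n, std::vector<int>(n, NEG)),
      db(n, '.') {
    run();
    if (n > 0) traceF(0, n - 1);
  }

  int score() const { return n > 0 ? F[0][n - 1] : 0; }
  std::string structure() const { return db; }

private:
  std::string seq;
  int n;
  std::vector<std::vector<int> > F, P;
  std::string db;

  bool pairable(int i, int j) const {
    return i >= 0 && j < n && j - i > MINLOOP &&
           pair_weight(seq[i], seq[j]) > 0;
  }

  void run() {
    for (int span = MINLOOP + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // P[i][j]: best score of [i, j] with (i, j) paired, outer stack
        // partner guaranteed by the caller
        if (pairable(i, j)) {
          int inner = F[i + 1][j - 1];
          if (pairable(i + 1, j - 1) && P[i + 1][j - 1] > inner)
            inner = P[i + 1][j - 1];
          P[i][j] = pair_weight(seq[i], seq[j]) + inner;
        }
        // F[i][j]: best score of [i, j], all helices >= 2 stacked pairs
        int sc = F[i + 1][j];
        for (int k = i + MINLOOP + 3; k <= j; ++k) {
          if (!pairable(i, k) || !pairable(i + 1, k - 1)) continue;
          int cand = pair_weight(seq[i], seq[k]) + P[i + 1][k - 1] +
                     (k < j ? F[k + 1][j] : 0);
          if (cand > sc) sc = cand;
        }
        F[i][j] = sc;
      }
    }
  }

  void traceF(int i, int j) {
    while (i < j && j - i > MINLOOP) {
      if (F[i][j] == F[i + 1][j]) { ++i; continue; }
      bool found = false;
      for (int k = i + MINLOOP + 3; k <= j; ++k) {
        if (!pairable(i, k) || !pairable(i + 1, k - 1)) continue;
        int cand = pair_weight(seq[i], seq[k]) + P[i + 1][k - 1] +
                   (k < j ? F[k + 1][j] : 0);
        if (cand == F[i][j]) {
          db[i] = '('; db[k] = ')';
          traceP(i + 1, k - 1);
          i = k + 1;
          found = true;
          break;
        }
      }
      if (!found) break;  // defensive: recurrence and trace disagree
    }
  }

  void traceP(int a, int b) {
    // (a, b) is paired
    db[a] = '('; db[b] = ')';
    int w = pair_weight(seq[a], seq[b]);
    if (pairable(a + 1, b - 1) && P[a][b] == w + P[a + 1][b - 1]) {
      traceP(a + 1, b - 1);
    } else {
      traceF(a + 1, b - 1);
    }
  }
};

// [[Rcpp::export(name = ".fold_dp")]]
Rcpp::List fold_dp(std::string seq) {
  FoldDP dp(seq);
  return Rcpp::List::create(Rcpp::Named("score") = dp.score(),
                            Rcpp::Named("dot_bracket") = dp.structure());
}
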
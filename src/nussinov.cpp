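#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Base-pair maximization folding (Nussinov-style dynamic program) over the
// DNA alphabet with G:U wobble (G-T) allowed and a minimum hairpin loop of
// `min_loop` unpaired nucleotides.
//
// The primary objective is the number of base pairs (exact maximum). Among
// the typically many structures attaining it, ties are resolved by a
// lexicographic secondary objective: maximize the number of stacked pairs
// (pairs whose immediate inner neighbour is also paired). This keeps helices
// contiguous and makes the returned structure deterministic and biologically
// sensible; a smallest-index tie-break can shred a perfect stem into
// count-equivalent fragments.
//
// Scores are combined as pairs * PAIR_W + stacks with PAIR_W larger than any
// possible stack count, so the pair count is always the true maximum.

static const int PAIR_W = 1024;  // > max stacks for n <= 600

// base codes: A=0, C=1, G=2, T=3, other=4 (never pairs)
static inline int code_of(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4;
  }
}

static const bool PAIR_TAB[5][5] = {
  // A      C      G      T      N
  {false, false, false, true,  false},  // A
  {false, false, true,  false, false},  // C
  {false, true,  false, true,  false},  // G
  {true,  false, true,  false, false},  // T
  {false, false, false, false, false}   // N
};

// [[Rcpp::export(name = ".nussinov_cpp")]]
std::string nussinov_cpp(std::string seq, int min_loop) {
  const int n = (int) seq.size();
  std::string db(n, '.');
  if (n == 0) return db;

  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = code_of(seq[i]);

  // F[i*n+j]: best combined score for seq[i..j] (0-based inclusive).
  // C[i*n+j]: best combined score for seq[i..j] given (i,j) paired
  //           (-1 when i,j cannot pair).
  std::vector<int> F((size_t) n * n, 0), C((size_t) n * n, -1);

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      const size_t ij = (size_t) i * n + j;
      // C[i][j]
      if (PAIR_TAB[code[i]][code[j]]) {
        int inner = 0;
        if (j - i > min_loop + 1) {
          const size_t in_ij = (size_t)(i + 1) * n + (j - 1);
          inner = F[in_ij];
          if (C[in_ij] >= 0 && C[in_ij] + 1 > inner) inner = C[in_ij] + 1;
        }
        C[ij] = PAIR_W + inner;
      }
      // F[i][j]
      int best = F[(size_t)(i + 1) * n + j];  // i unpaired
      const bool *row = PAIR_TAB[code[i]];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!row[code[k]]) continue;
        int cik = C[(size_t) i * n + k];
        int right = (k < j) ? F[(size_t)(k + 1) * n + j] : 0;
        if (cik + right > best) best = cik + right;
      }
      F[ij] = best;
    }
  }

  // Traceback: stack of (i, j, mode); mode 0 = free interval, 1 = (i,j) pair.
  struct Item { int i, j, mode; };
  std::vector<Item> stack;
  stack.push_back(Item{0, n - 1, 0});
  while (!stack.empty()) {
    Item it = stack.back();
    stack.pop_back();
    int i = it.i, j = it.j;
    if (i >= j || j - i <= min_loop) continue;
    if (it.mode == 1) {
      db[i] = '(';
      db[j] = ')';
      if (j - i > min_loop + 1) {
        const size_t in_ij = (size_t)(i + 1) * n + (j - 1);
        int target = C[(size_t) i * n + j] - PAIR_W;
        // prefer continuing the helix when it attains the optimum
        if (C[in_ij] >= 0 && C[in_ij] + 1 == target)
          stack.push_back(Item{i + 1, j - 1, 1});
        else
          stack.push_back(Item{i + 1, j - 1, 0});
      }
      continue;
    }
    int target = F[(size_t) i * n + j];
    if (target == 0) continue;
    bool paired = false;
    const bool *row = PAIR_TAB[code[i]];
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!row[code[k]]) continue;
      int cik = C[(size_t) i * n + k];
      int right = (k < j) ? F[(size_t)(k + 1) * n + j] : 0;
      if (cik + right == target) {
        stack.push_back(Item{i, k, 1});
        if (k < j) stack.push_back(Item{k + 1, j, 0});
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(Item{i + 1, j, 0});
  }
  return db;
}

// Best ungapped antiparallel duplex: the maximum, over alignment offsets, of
// the number of paired positions (Watson-Crick or G:U) between `a` and `b`
// read antiparallel. Used as a cheap miRNA/miRNA* prescreen before folding.
// [[Rcpp::export(name = ".duplex_pairs_cpp")]]
int duplex_pairs_cpp(std::string a, std::string b, int max_offset) {
  const int na = (int) a.size(), nb = (int) b.size();
  std::vector<int> ca(na), cb(nb);
  for (int i = 0; i < na; ++i) ca[i] = code_of(a[i]);
  // reverse b so both run in the same direction; pairing stays antiparallel
  for (int i = 0; i < nb; ++i) cb[i] = code_of(b[nb - 1 - i]);
  int best = 0;
  for (int off = -max_offset; off <= max_offset; ++off) {
    int cnt = 0;
    for (int i = 0; i < na; ++i) {
      int j = i + off;
      if (j < 0 || j >= nb) continue;
      if (PAIR_TAB[ca[i]][cb[j]]) ++cnt;
    }
    if (cnt > best) best = cnt;
  }
  return best;
}
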
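#include <Rcpp.h>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Needleman-Wunsch in two modes (match +1, mismatch -1, gap -2, linear):
//
// * semi-global (`global = false`): end gaps free on both sequences. The
//   alignment endpoint is the maximal score over the last row and last
//   column; ties prefer larger i (bases of `a` consumed), then larger j.
//   Intended for best-hit searches where partial query coverage against a
//   longer reference is legitimate.
// * global (`global = true`): end gaps penalized during optimization, so
//   the alignment must span both sequences; terminal gap-column runs are
//   reported as end gaps and excluded from the match/mismatch/internal-gap
//   counts. Intended for pairwise distances, where free end gaps would let
//   the score-optimal alignment of two unrelated amplicons collapse to a
//   short chance overlap with spuriously low distance.
//
// Traceback prefers diagonal, then up (gap in b), then left (gap in a).
// These tie-breaks are part of the contract: the pure-R oracle in the test
// suite implements the same rules independently, so the two routes must
// agree exactly.

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string a, std::string b, bool return_alignment = false,
                    bool global = false) {
  const int m = (int) a.size();
  const int n = (int) b.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");

  const int GAP = -2;
  std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return (size_t) i * (n + 1) + j; };
  if (global) {
    for (int i = 0; i <= m; ++i) H[at(i, 0)] = GAP * i;
    for (int j = 0; j <= n; ++j) H[at(0, j)] = GAP * j;
  }

  for (int i = 1; i <= m; ++i) {
    const char ai = a[(size_t) i - 1];
    for (int j = 1; j <= n; ++j) {
      const int s = (ai == b[(size_t) j - 1]) ? 1 : -1;
      int best = H[at(i - 1, j - 1)] + s;
      int up = H[at(i - 1, j)] + GAP;
      int left = H[at(i, j - 1)] + GAP;
      if (up > best) best = up;
      if (left > best) best = left;
      H[at(i, j)] = best;
    }
  }

  int ie, je, score;
  if (global) {
    ie = m; je = n; score = H[at(m, n)];
  } else {
    // endpoint: max score over last row/col, ties -> larger i, then larger j
    ie = 0; je = n; score = H[at(0, n)];
    for (int i = 0; i <= m; ++i) {
      int sc = H[at(i, n)];
      if (sc > score || (sc == score && (i > ie || (i == ie && n > je)))) {
        score = sc; ie = i; je = n;
      }
    }
    for (int j = 0; j <= n; ++j) {
      int sc = H[at(m, j)];
      if (sc > score || (sc == score && (m > ie || (m == ie && j > je)))) {
        score = sc; ie = m; je = j;
      }
    }
  }

  // traceback; moves recorded endpoint-first: 0 = diag, 1 = up, 2 = left
  std::vector<unsigned char> moves;
  moves.reserve((size_t) m + n);
  int i = ie, j = je;
  while (i > 0 && j > 0) {
    const int h = H[at(i, j)];
    const int s = (a[(size_t) i - 1] == b[(size_t) j - 1]) ? 1 : -1;
    if (H[at(i - 1, j - 1)] + s == h) {
      moves.push_back(0); --i; --j;
    } else if (H[at(i - 1, j)] + GAP == h) {
      moves.push_back(1); --i;
    } else {
      moves.push_back(2); --j;
    }
  }
  // in global mode, finish along the matrix edge (terminal gap run)
  while (global && i > 0) { moves.push_back(1); --i; }
  while (global && j > 0) { moves.push_back(2); --j; }
  int is = i, js = j;
  std::reverse(moves.begin(), moves.end());

  // strip terminal gap-column runs: free by construction in semi-global
  // mode (there are none), penalized but excluded from the counts in
  // global mode
  size_t lo = 0, hi = moves.size();
  int lead_a = 0, lead_b = 0, trail_a = 0, trail_b = 0;
  while (lo < hi && moves[lo] != 0) {
    if (moves[lo] == 1) ++lead_a; else ++lead_b;
    ++lo;
  }
  while (hi > lo && moves[hi - 1] != 0) {
    if (moves[hi - 1] == 1) ++trail_a; else ++trail_b;
    --hi;
  }

  int matches = 0, mismatches = 0, gaps = 0;
  {
    int ia = is + lead_a, ib = js + lead_b;
    std::string ga, gb;
    for (size_t p = lo; p < hi; ++p) {
      if (moves[p] == 0) {
        const char ca = a[(size_t) ia], cb = b[(size_t) ib];
        if (ca == cb) ++matches; else ++mismatches;
        if (return_alignment) { ga.push_back(ca); gb.push_back(cb); }
        ++ia; ++ib;
      } else if (moves[p] == 1) {
        ++gaps;
        if (return_alignment) { ga.push_back(a[(size_t) ia]); gb.push_back('-'); }
        ++ia;
      } else {
        ++gaps;
        if (return_alignment) { ga.push_back('-'); gb.push_back(b[(size_t) ib]); }
        ++ib;
      }
    }
    const int columns = matches + mismatches + gaps;
    List out = List::create(
      _["score"] = score,
      _["matches"] = matches,
      _["mismatches"] = mismatches,
      _["internal_gaps"] = gaps,
      _["columns"] = columns,
      _["a_start"] = is + lead_a + 1, _["a_end"] = ie - trail_a,
      _["b_start"] = js + lead_b + 1, _["b_end"] = je - trail_b,
      _["end_gap_a_5p"] = is + lead_a, _["end_gap_a_3p"] = m - ie + trail_a,
      _["end_gap_b_5p"] = js + lead_b, _["end_gap_b_3p"] = n - je + trail_b);
    if (return_alignment) {
      out["aligned_a"] = ga;
      out["aligned_b"] = gb;
    }
    return out;
  }
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Sorted multiset of 2-bit packed k-mers (k <= 15); windows containing
// ambiguous bases are skipped.
// [[Rcpp::export(name = ".kmer_profile_cpp")]]
IntegerVector kmer_profile_cpp(std::string s, int k) {
  if (k < 1 || k > 15) stop("k must be in [1, 15]");
  const int n = (int) s.size();
  std::vector<int> out;
  if (n >= k) {
    out.reserve(n - k + 1);
    const int mask = (1 << (2 * k)) - 1;
    int kmer = 0, valid = 0;
    for (int i = 0; i < n; ++i) {
      const int c = base_code(s[(size_t) i]);
      if (c < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | c) & mask;
      if (++valid >= k) out.push_back(kmer);
    }
    std::sort(out.begin(), out.end());
  }
  return wrap(out);
}

// Multiset intersection size of two sorted k-mer profiles.
// [[Rcpp::export(name = ".shared_kmers_cpp")]]
int shared_kmers_cpp(IntegerVector p, IntegerVector q) {
  int i = 0, j = 0, shared = 0;
  const int np = p.size(), nq = q.size();
  while (i < np && j < nq) {
    if (p[i] < q[j]) ++i;
    else if (p[i] > q[j]) ++j;
    else { ++shared; ++i; ++j; }
  }
  return shared;
}
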
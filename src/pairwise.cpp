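#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
#include "seq_utils.h"

using namespace Rcpp;

static const int NEG = -100000000;

// Plain global (Needleman-Wunsch) alignment with affine gaps, terminal
// gaps penalized. Identity = matching columns / total alignment columns,
// so "AAAA" vs "AAAT" is 3/4. Symmetric by construction.
// [[Rcpp::export(name = ".nw_identity_cpp")]]
List nw_identity_cpp(std::string sa, std::string sb,
                     int match = 2, int mismatch = -3,
                     int gap_open = -5, int gap_ext = -2) {
  std::vector<uint8_t> a = encode_seq(sa), b = encode_seq(sb);
  const int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) stop("empty sequence");
  const size_t W = (size_t)(n + 1);
  std::vector<int> M((size_t)(m + 1) * W, NEG), X(M), Y(M);
  // traceback: bits 0-1 = M pred (1 M, 2 X, 3 Y), bit 2 = X pred (0 M,
  // 1 X), bit 3 = Y pred (0 M, 1 Y)
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 0);
  auto at = [W](int i, int j) { return (size_t)i * W + (size_t)j; };

  M[at(0, 0)] = 0;
  for (int i = 1; i <= m; ++i) X[at(i, 0)] = gap_open + i * gap_ext;
  for (int j = 1; j <= n; ++j) Y[at(0, j)] = gap_open + j * gap_ext;

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int s = (a[i - 1] == b[j - 1] && a[i - 1] < 4) ? match : mismatch;
      int bm = M[at(i - 1, j - 1)], bx = X[at(i - 1, j - 1)], by = Y[at(i - 1, j - 1)];
      int best = bm; uint8_t pc = 1;
      if (bx > best) { best = bx; pc = 2; }
      if (by > best) { best = by; pc = 3; }
      M[at(i, j)] = best + s;
      int xo = std::max(M[at(i - 1, j)], Y[at(i - 1, j)]) + gap_open + gap_ext;
      int xe = X[at(i - 1, j)] + gap_ext;
      uint8_t px = 0;
      if (xe > xo) { X[at(i, j)] = xe; px = 1; } else X[at(i, j)] = xo;
      int yo = std::max(M[at(i, j - 1)], X[at(i, j - 1)]) + gap_open + gap_ext;
      int ye = Y[at(i, j - 1)] + gap_ext;
      uint8_t py = 0;
      if (ye > yo) { Y[at(i, j)] = ye; py = 1; } else Y[at(i, j)] = yo;
      tb[at(i, j)] = pc | (px << 2) | (py << 3);
    }
  }

  int bscore = M[at(m, n)]; char bstate = 'M';
  if (X[at(m, n)] > bscore) { bscore = X[at(m, n)]; bstate = 'X'; }
  if (Y[at(m, n)] > bscore) { bscore = Y[at(m, n)]; bstate = 'Y'; }

  long matches = 0, columns = 0;
  int i = m, j = n; char st = bstate;
  while (i > 0 || j > 0) {
    if (i == 0) { ++columns; --j; continue; }
    if (j == 0) { ++columns; --i; continue; }
    uint8_t t = tb[at(i, j)];
    if (st == 'M') {
      ++columns;
      if (a[i - 1] == b[j - 1] && a[i - 1] < 4) ++matches;
      uint8_t pc = t & 3;
      --i; --j;
      st = (pc == 2) ? 'X' : (pc == 3) ? 'Y' : 'M';
    } else if (st == 'X') {
      ++columns;
      st = ((t >> 2) & 1) ? 'X' : 'M';
      --i;
    } else {
      ++columns;
      st = ((t >> 3) & 1) ? 'Y' : 'M';
      --j;
    }
  }
  double identity = columns > 0 ? (double)matches / (double)columns : 0.0;
  return List::create(_["identity"] = identity, _["matches"] = (double)matches,
                      _["columns"] = (double)columns, _["score"] = bscore);
}

LocalAln local_align(const std::vector<uint8_t> &a, const std::vector<uint8_t> &b,
                     int match, int mismatch, int gap_open, int gap_ext,
                     int wildcard) {
  const int m = (int)a.size(), n = (int)b.size();
  LocalAln out;
  if (m == 0 || n == 0) return out;
  const size_t W = (size_t)(n + 1);
  std::vector<int> M((size_t)(m + 1) * W, 0), X(M), Y(M);
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 0);
  auto at = [W](int i, int j) { return (size_t)i * W + (size_t)j; };
  for (int i = 0; i <= m; ++i) { X[at(i, 0)] = NEG; Y[at(i, 0)] = NEG; }
  for (int j = 0; j <= n; ++j) { X[at(0, j)] = NEG; Y[at(0, j)] = NEG; }
  int bi = 0, bj = 0, bscore = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int s = (a[i - 1] == b[j - 1] && (int)a[i - 1] != wildcard) ? match : mismatch;
      int bm = M[at(i - 1, j - 1)], bx = X[at(i - 1, j - 1)], by = Y[at(i - 1, j - 1)];
      int best = 0; uint8_t pc = 0;  // 0 = fresh start
      if (bm > best) { best = bm; pc = 1; }
      if (bx > best) { best = bx; pc = 2; }
      if (by > best) { best = by; pc = 3; }
      int mv = best + s;
      if (mv < 0) { mv = NEG; pc = 0; }  // never keep negative local starts
      M[at(i, j)] = mv;
      int xo = M[at(i - 1, j)] + gap_open + gap_ext;
      int xe = X[at(i - 1, j)] + gap_ext;
      uint8_t px = 0;
      if (xe > xo) { X[at(i, j)] = xe; px = 1; } else X[at(i, j)] = xo;
      int yo = M[at(i, j - 1)] + gap_open + gap_ext;
      int ye = Y[at(i, j - 1)] + gap_ext;
      uint8_t py = 0;
      if (ye > yo) { Y[at(i, j)] = ye; py = 1; } else Y[at(i, j)] = yo;
      tb[at(i, j)] = pc | (px << 2) | (py << 3);
      if (mv > bscore) { bscore = mv; bi = i; bj = j; }
    }
  }
  if (bscore <= 0) return out;
  out.score = bscore; out.aend = bi; out.bend = bj;
  int i = bi, j = bj; char st = 'M';
  while (i > 0 && j > 0) {
    uint8_t t = tb[at(i, j)];
    if (st == 'M') {
      ++out.columns;
      if (a[i - 1] == b[j - 1] && (int)a[i - 1] != wildcard) ++out.matches;
      uint8_t pc = t & 3;
      --i; --j;
      if (pc == 0) break;
      st = (pc == 2) ? 'X' : (pc == 3) ? 'Y' : 'M';
    } else if (st == 'X') {
      ++out.columns; st = ((t >> 2) & 1) ? 'X' : 'M'; --i;
    } else {
      ++out.columns; st = ((t >> 3) & 1) ? 'Y' : 'M'; --j;
    }
  }
  out.astart = i; out.bstart = j;
  return out;
}

// Alphabet-agnostic local alignment (plain character equality, case
// folded): used for peptide-space best-match reports.
// [[Rcpp::export(name = ".sw_generic_cpp")]]
List sw_generic_cpp(std::string sa, std::string sb,
                    int match = 2, int mismatch = -3,
                    int gap_open = -5, int gap_ext = -2) {
  std::vector<uint8_t> a(sa.size()), b(sb.size());
  for (size_t i = 0; i < sa.size(); ++i) a[i] = (uint8_t)toupper(sa[i]);
  for (size_t i = 0; i < sb.size(); ++i) b[i] = (uint8_t)toupper(sb[i]);
  LocalAln r = local_align(a, b, match, mismatch, gap_open, gap_ext, -1);
  double identity = r.columns > 0 ? (double)r.matches / (double)r.columns : 0.0;
  return List::create(_["score"] = r.score,
                      _["astart"] = r.astart, _["aend"] = r.aend,
                      _["bstart"] = r.bstart, _["bend"] = r.bend,
                      _["matches"] = r.matches, _["columns"] = r.columns,
                      _["identity"] = identity);
}

// [[Rcpp::export(name = ".sw_local_cpp")]]
List sw_local_cpp(std::string sa, std::string sb,
                  int match = 2, int mismatch = -3,
                  int gap_open = -5, int gap_ext = -2) {
  std::vector<uint8_t> a = encode_seq(sa), b = encode_seq(sb);
  LocalAln r = local_align(a, b, match, mismatch, gap_open, gap_ext);
  double identity = r.columns > 0 ? (double)r.matches / (double)r.columns : 0.0;
  return List::create(_["score"] = r.score,
                      _["astart"] = r.astart, _["aend"] = r.aend,
                      _["bstart"] = r.bstart, _["bend"] = r.bend,
                      _["matches"] = r.matches, _["columns"] = r.columns,
                      _["identity"] = identity);
}
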
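#include <Rcpp.h>
#include <vector>
#include <deque>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
#include "seq_utils.h"

using namespace Rcpp;

static const int NEG = -100000000;

// Spliced alignment of a CDS against an oriented genomic region.
// States: exon match/mismatch (M), exon gap in region (X, consumes query),
// exon gap in query (Y, consumes region), and a length-independent intron
// state that may only bridge region segments starting GT and ending AG with
// length within [min_intron, max_intron]. Global in the query (every CDS
// base is consumed), local in the region (free start/end).
//
// `cols` optionally restricts the DP to a subset of region base positions
// (0-based); introns may span excluded stretches since their cost does not
// depend on length. An empty `cols` means the full region (unbanded).
// [[Rcpp::export(name = ".spliced_align_cpp")]]
List spliced_align_cpp(std::string cds, std::string region, IntegerVector cols,
                       int match = 5, int mismatch = -4,
                       int gap_open = -12, int gap_ext = -2,
                       int intron_cost = -40,
                       int min_intron = 50, int max_intron = 50000) {
  std::vector<uint8_t> q = encode_seq(cds), r = encode_seq(region);
  const int m = (int)q.size(), n = (int)r.size();
  if (m == 0 || n == 0) stop("empty sequence");

  // DP columns: consumed-base counts; colv[0] == 0 always present
  std::vector<int> colv;
  if (cols.size() == 0) {
    colv.resize(n + 1);
    for (int j = 0; j <= n; ++j) colv[j] = j;
  } else {
    std::vector<int> cc(cols.begin(), cols.end());
    std::sort(cc.begin(), cc.end());
    cc.erase(std::unique(cc.begin(), cc.end()), cc.end());
    colv.push_back(0);
    for (int b : cc) {
      if (b < 0 || b >= n) stop("banding column out of range");
      if (b + 1 != colv.back()) colv.push_back(b + 1);
      else colv.push_back(b + 1);
    }
    colv.erase(std::unique(colv.begin(), colv.end()), colv.end());
  }
  const int nc = (int)colv.size();

  // donor columns: GT begins at region base colv[idx]
  std::vector<int> donor_idx;
  for (int idx = 0; idx < nc; ++idx) {
    int d = colv[idx];
    if (d + 1 < n && r[d] == 2 && r[d + 1] == 3) donor_idx.push_back(idx);
  }

  // traceback: bits 0-2 = M pred (0 start, 1 M, 2 X, 3 Y, 4 intron),
  //            bit 3 = X pred (0 M, 1 X), bit 4 = Y pred (0 M, 1 Y)
  std::vector<uint8_t> tb((size_t)(m + 1) * nc, 0);
  std::unordered_map<int64_t, int> intron_donor;  // (i, idx) -> donor column

  std::vector<int> Mp(nc, NEG), Xp(nc, NEG), Yp(nc, NEG);
  std::vector<int> Mc(nc, NEG), Xc(nc, NEG), Yc(nc, NEG);

  int best = 0, bi = -1, bidx = -1; char bstate = 'M';
  for (int i = 1; i <= m; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Xc.begin(), Xc.end(), NEG);
    std::fill(Yc.begin(), Yc.end(), NEG);
    // sliding-window max over donors of row i-1 (exon must end in M state)
    std::deque<std::pair<int, int>> dq;  // (donor column, value), value decreasing
    size_t dptr = 0;
    for (int idx = 0; idx < nc; ++idx) {
      int j = colv[idx];
      bool adj = idx > 0 && colv[idx - 1] == j - 1;
      // X: consume query base, gap in region (same column)
      {
        int xo = Mp[idx] == NEG ? NEG : Mp[idx] + gap_open + gap_ext;
        int xe = Xp[idx] == NEG ? NEG : Xp[idx] + gap_ext;
        uint8_t px = 0;
        if (xe > xo) { Xc[idx] = xe; px = 1; } else Xc[idx] = xo;
        tb[(size_t)i * nc + idx] |= (px << 3);
      }
      if (j >= 1) {
        // intron close: acceptor AG at bases j-3, j-2; donor row i-1
        int Z = NEG, Zdonor = -1;
        if (i >= 2 && j >= 3 && r[j - 3] == 0 && r[j - 2] == 2) {
          int a = j - 1;  // intron ends before base j-1
          while (dptr < donor_idx.size() && colv[donor_idx[dptr]] <= a - min_intron) {
            int dcol = colv[donor_idx[dptr]];
            int val = Mp[donor_idx[dptr]];
            if (val > NEG / 2) {
              int v = val + intron_cost;
              while (!dq.empty() && dq.back().second <= v) dq.pop_back();
              dq.emplace_back(dcol, v);
            }
            ++dptr;
          }
          while (!dq.empty() && dq.front().first < a - max_intron) dq.pop_front();
          if (!dq.empty()) { Z = dq.front().second; Zdonor = dq.front().first; }
        }
        // M: align cds[i-1] with region[j-1]
        int s = (q[i - 1] == r[j - 1] && q[i - 1] < 4) ? match : mismatch;
        int bestp = NEG; uint8_t pc = 0;
        if (adj) {
          if (Mp[idx - 1] > bestp) { bestp = Mp[idx - 1]; pc = 1; }
          if (Xp[idx - 1] > bestp) { bestp = Xp[idx - 1]; pc = 2; }
          if (Yp[idx - 1] > bestp) { bestp = Yp[idx - 1]; pc = 3; }
        }
        if (i == 1 && 0 > bestp) { bestp = 0; pc = 0; }  // free start in region
        if (Z > bestp) { bestp = Z; pc = 4; }
        if (bestp > NEG / 2) {
          Mc[idx] = bestp + s;
          tb[(size_t)i * nc + idx] |= pc;
          if (pc == 4) intron_donor[(int64_t)i * nc + idx] = Zdonor;
        }
        // Y: consume region base, gap in query (same row)
        if (adj) {
          int yo = Mc[idx - 1] == NEG ? NEG : Mc[idx - 1] + gap_open + gap_ext;
          int ye = Yc[idx - 1] == NEG ? NEG : Yc[idx - 1] + gap_ext;
          uint8_t py = 0;
          if (ye > yo) { Yc[idx] = ye; py = 1; } else Yc[idx] = yo;
          tb[(size_t)i * nc + idx] |= (py << 4);
        }
      }
      if (i == m) {  // free end in region; query fully consumed
        if (Mc[idx] > best) { best = Mc[idx]; bi = i; bidx = idx; bstate = 'M'; }
        if (Xc[idx] > best) { best = Xc[idx]; bi = i; bidx = idx; bstate = 'X'; }
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  if (best <= 0 || bi < 0) {
    return List::create(_["score"] = 0,
                        _["segments"] = IntegerMatrix(0, 4),
                        _["matches"] = 0, _["columns"] = 0,
                        _["identity"] = 0.0);
  }

  // traceback
  struct SegAcc { int qe, re, qs, rs; };
  std::vector<SegAcc> segs;
  int i = bi, idx = bidx; char st = bstate;
  int matches = 0, columns = 0;
  auto open_seg = [&](int qe, int re) { segs.push_back({qe, re, qe, re}); };
  open_seg(i, colv[idx]);
  bool done = false;
  while (!done) {
    uint8_t t = tb[(size_t)i * nc + idx];
    int j = colv[idx];
    if (st == 'M') {
      ++columns;
      if (q[i - 1] == r[j - 1] && q[i - 1] < 4) ++matches;
      uint8_t pc = t & 7;
      segs.back().qs = i - 1; segs.back().rs = j - 1;
      if (pc == 0) { done = true; break; }
      if (pc == 4) {
        int dcol = intron_donor[(int64_t)i * nc + idx];
        // previous exon ends at column dcol, row i-1 in M state
        i -= 1;
        idx = (int)(std::lower_bound(colv.begin(), colv.end(), dcol) - colv.begin());
        st = 'M';
        open_seg(i, dcol);
      } else {
        i -= 1; idx -= 1;
        st = (pc == 1) ? 'M' : (pc == 2) ? 'X' : 'Y';
      }
    } else if (st == 'X') {
      ++columns;
      st = ((t >> 3) & 1) ? 'X' : 'M';
      i -= 1;
      segs.back().qs = i;
      if (i == 0) { done = true; break; }
    } else {
      ++columns;
      st = ((t >> 4) & 1) ? 'Y' : 'M';
      idx -= 1;
      segs.back().rs = colv[idx];
    }
  }
  std::reverse(segs.begin(), segs.end());
  IntegerMatrix sm((int)segs.size(), 4);
  for (int s2 = 0; s2 < (int)segs.size(); ++s2) {
    sm(s2, 0) = segs[s2].qs; sm(s2, 1) = segs[s2].qe;
    sm(s2, 2) = segs[s2].rs; sm(s2, 3) = segs[s2].re;
  }
  colnames(sm) = CharacterVector::create("qstart", "qend", "rstart", "rend");
  double identity = columns > 0 ? (double)matches / columns : 0.0;
  return List::create(_["score"] = best, _["segments"] = sm,
                      _["matches"] = matches, _["columns"] = columns,
                      _["identity"] = identity);
}

// All ATG..stop open reading frames of length >= min_len on both strands;
// nested ORFs sharing a stop report only the longest (first ATG after the
// previous in-frame stop). Coordinates are 0-based half-open on the
// forward strand of the input.
// [[Rcpp::export(name = ".find_orfs_cpp")]]
DataFrame find_orfs_cpp(std::string seq, int min_len) {
  if (min_len < 3) stop("min_len must be >= 3");
  std::vector<int> start, end, frame;
  std::vector<std::string> strand, cds;
  const int L = (int)seq.size();
  for (int s = 0; s < 2; ++s) {
    std::string ss = s == 0 ? seq : revcomp(seq);
    std::vector<uint8_t> e = encode_seq(ss);
    for (int f = 0; f < 3; ++f) {
      int orf_start = -1;
      for (int p = f; p + 3 <= L; p += 3) {
        uint8_t c1 = e[p], c2 = e[p + 1], c3 = e[p + 2];
        bool is_atg = (c1 == 0 && c2 == 3 && c3 == 2);
        bool is_stop = (c1 == 3 && ((c2 == 0 && (c3 == 0 || c3 == 2)) ||
                                    (c2 == 2 && c3 == 0)));
        if (is_stop) {
          if (orf_start >= 0) {
            int len = p + 3 - orf_start;
            if (len >= min_len) {
              int a = orf_start, b = p + 3;
              if (s == 0) { start.push_back(a); end.push_back(b); strand.push_back("+"); }
              else { start.push_back(L - b); end.push_back(L - a); strand.push_back("-"); }
              frame.push_back(f);
              cds.push_back(ss.substr(a, len));
            }
          }
          orf_start = -1;
        } else if (is_atg && orf_start < 0) {
          orf_start = p;
        }
      }
    }
  }
  return DataFrame::create(_["strand"] = strand, _["start"] = start,
                           _["end"] = end, _["frame"] = frame, _["cds"] = cds,
                           _["stringsAsFactors"] = false);
}
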
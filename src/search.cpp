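#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
#include "seq_utils.h"

using namespace Rcpp;

// Sorted flat k-mer index over the forward strand of every contig.
// Minus-strand occurrences are found by querying the reverse complement
// of a k-mer, so they are reported as forward positions of the rc seed.
struct SeedIndex {
  int k = 11;
  std::vector<uint64_t> key;
  std::vector<int32_t> contig;  // 0-based contig index
  std::vector<int32_t> pos;     // 0-based forward position
};

static bool kmer_code(const std::vector<uint8_t> &s, size_t i, int k, uint64_t &code) {
  code = 0;
  for (int j = 0; j < k; ++j) {
    uint8_t c = s[i + j];
    if (c > 3) return false;  // N never indexed
    code = (code << 2) | c;
  }
  return true;
}

static SeedIndex *build_index(const std::vector<std::string> &contigs, int k) {
  SeedIndex *idx = new SeedIndex();
  idx->k = k;
  std::vector<std::tuple<uint64_t, int32_t, int32_t>> entries;
  for (size_t c = 0; c < contigs.size(); ++c) {
    std::vector<uint8_t> e = encode_seq(contigs[c]);
    if ((int)e.size() < k) continue;
    for (size_t i = 0; i + (size_t)k <= e.size(); ++i) {
      uint64_t code;
      if (kmer_code(e, i, k, code))
        entries.emplace_back(code, (int32_t)c, (int32_t)i);
    }
  }
  std::sort(entries.begin(), entries.end());
  idx->key.reserve(entries.size());
  idx->contig.reserve(entries.size());
  idx->pos.reserve(entries.size());
  for (auto &t : entries) {
    idx->key.push_back(std::get<0>(t));
    idx->contig.push_back(std::get<1>(t));
    idx->pos.push_back(std::get<2>(t));
  }
  return idx;
}

// [[Rcpp::export(name = ".seed_index_build_cpp")]]
SEXP seed_index_build_cpp(CharacterVector contigs, int k) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  if (contigs.size() == 0) stop("empty genome");
  std::vector<std::string> cs(contigs.size());
  for (int i = 0; i < contigs.size(); ++i) cs[i] = as<std::string>(contigs[i]);
  XPtr<SeedIndex> p(build_index(cs, k), true);
  return p;
}

// [[Rcpp::export(name = ".seed_index_k_cpp")]]
int seed_index_k_cpp(SEXP ptr) { return XPtr<SeedIndex>(ptr)->k; }

static void lookup(const SeedIndex *idx, uint64_t code,
                   std::vector<std::pair<int32_t, int32_t>> &out) {
  auto lo = std::lower_bound(idx->key.begin(), idx->key.end(), code);
  for (auto it = lo; it != idx->key.end() && *it == code; ++it) {
    size_t i = (size_t)(it - idx->key.begin());
    out.emplace_back(idx->contig[i], idx->pos[i]);
  }
}

// [[Rcpp::export(name = ".seed_index_query_cpp")]]
DataFrame seed_index_query_cpp(SEXP ptr, std::string kmer) {
  XPtr<SeedIndex> idx(ptr);
  if ((int)kmer.size() != idx->k) stop("k-mer length does not match index k");
  std::vector<int> contig, pos;
  std::vector<std::string> strand;
  std::vector<uint8_t> e = encode_seq(kmer);
  uint64_t code;
  std::vector<std::pair<int32_t, int32_t>> hits;
  if (kmer_code(e, 0, idx->k, code)) {
    hits.clear(); lookup(idx.get(), code, hits);
    for (auto &h : hits) { contig.push_back(h.first + 1); pos.push_back(h.second); strand.push_back("+"); }
    std::vector<uint8_t> rc = encode_seq(revcomp(kmer));
    uint64_t rcode;
    kmer_code(rc, 0, idx->k, rcode);
    if (rcode != code) {
      hits.clear(); lookup(idx.get(), rcode, hits);
      for (auto &h : hits) { contig.push_back(h.first + 1); pos.push_back(h.second); strand.push_back("-"); }
    } else {
      // palindromic k-mer: same forward positions on the minus strand
      hits.clear(); lookup(idx.get(), code, hits);
      for (auto &h : hits) { contig.push_back(h.first + 1); pos.push_back(h.second); strand.push_back("-"); }
    }
  }
  return DataFrame::create(_["contig"] = contig, _["pos"] = pos,
                           _["strand"] = strand, _["stringsAsFactors"] = false);
}

struct Seg { int64_t diag; int qs, qe, ts, te; };

struct RawHit {
  int query, contig; char strand;
  int qstart, qend, tstart, tend;
  int score, matches, columns;
};

// Align one clustered seed group with banded-window Smith-Waterman,
// growing the window if the alignment touches its edge.
static bool align_cluster(const std::vector<uint8_t> &q, const std::vector<uint8_t> &t,
                          int qlo, int qhi, int tlo, int thi,
                          int match, int mismatch, int gap_open, int gap_ext,
                          RawHit &hit) {
  int pad = 48;
  for (int round = 0; round < 4; ++round) {
    int qa = std::max(0, qlo - pad), qb = std::min((int)q.size(), qhi + pad);
    int ta = std::max(0, tlo - pad), tb = std::min((int)t.size(), thi + pad);
    std::vector<uint8_t> qa_s(q.begin() + qa, q.begin() + qb);
    std::vector<uint8_t> ta_s(t.begin() + ta, t.begin() + tb);
    LocalAln r = local_align(qa_s, ta_s, match, mismatch, gap_open, gap_ext);
    if (r.score <= 0) return false;
    bool edge = (r.astart == 0 && qa > 0) || (r.aend == (int)qa_s.size() && qb < (int)q.size()) ||
                (r.bstart == 0 && ta > 0) || (r.bend == (int)ta_s.size() && tb < (int)t.size());
    if (edge && round < 3) { pad *= 4; continue; }
    hit.qstart = qa + r.astart; hit.qend = qa + r.aend;
    hit.tstart = ta + r.bstart; hit.tend = ta + r.bend;
    hit.score = r.score; hit.matches = r.matches; hit.columns = r.columns;
    return true;
  }
  return false;
}

// [[Rcpp::export(name = ".search_hits_cpp")]]
DataFrame search_hits_cpp(CharacterVector queries, CharacterVector contigs,
                          int k, int match, int mismatch, int gap_open, int gap_ext,
                          int min_score, double min_identity) {
  std::vector<std::string> cs(contigs.size());
  for (int i = 0; i < contigs.size(); ++i) cs[i] = as<std::string>(contigs[i]);
  SeedIndex *idx = build_index(cs, k);
  std::vector<std::vector<uint8_t>> cenc(cs.size());
  for (size_t i = 0; i < cs.size(); ++i) cenc[i] = encode_seq(cs[i]);

  const int diag_band = 32;     // max diagonal drift merged into one gapped hit
  const int cluster_gap = 40;   // below the minimum intron length, so separate
                                // exons are never fused into one local hit window
  std::vector<RawHit> hits;

  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string qfwd = as<std::string>(queries[qi]);
    int qlen = (int)qfwd.size();
    for (int sidx = 0; sidx < 2; ++sidx) {
      char strand = sidx == 0 ? '+' : '-';
      std::string qs = sidx == 0 ? qfwd : revcomp(qfwd);
      std::vector<uint8_t> qe = encode_seq(qs);
      if ((int)qe.size() < k) continue;
      // seeds grouped per contig: (diag, qpos, tpos)
      std::vector<std::vector<std::tuple<int64_t, int, int>>> seeds(cs.size());
      std::vector<std::pair<int32_t, int32_t>> found;
      for (int i = 0; i + k <= (int)qe.size(); ++i) {
        uint64_t code;
        if (!kmer_code(qe, (size_t)i, k, code)) continue;
        found.clear(); lookup(idx, code, found);
        for (auto &f : found)
          seeds[f.first].emplace_back((int64_t)f.second - i, i, f.second);
      }
      for (size_t ci = 0; ci < cs.size(); ++ci) {
        auto &sv = seeds[ci];
        if (sv.empty()) continue;
        std::sort(sv.begin(), sv.end());
        // collapse seeds into diagonal segments
        std::vector<Seg> segs;
        for (auto &s : sv) {
          int64_t d = std::get<0>(s);
          int qp = std::get<1>(s), tp = std::get<2>(s);
          if (!segs.empty() && segs.back().diag == d && tp <= segs.back().te + 50) {
            segs.back().qe = std::max(segs.back().qe, qp + k);
            segs.back().te = std::max(segs.back().te, tp + k);
          } else {
            segs.push_back({d, qp, qp + k, tp, tp + k});
          }
        }
        // cluster segments: nearby diagonals, nearby target intervals
        std::sort(segs.begin(), segs.end(), [](const Seg &a, const Seg &b) {
          return a.diag != b.diag ? a.diag < b.diag : a.ts < b.ts;
        });
        std::vector<std::vector<Seg>> bands;
        for (auto &s : segs) {
          if (!bands.empty() && s.diag - bands.back().back().diag <= diag_band)
            bands.back().push_back(s);
          else
            bands.push_back({s});
        }
        for (auto &band : bands) {
          std::sort(band.begin(), band.end(), [](const Seg &a, const Seg &b) {
            return a.ts < b.ts;
          });
          size_t i0 = 0;
          while (i0 < band.size()) {
            int qlo = band[i0].qs, qhi = band[i0].qe;
            int tlo = band[i0].ts, thi = band[i0].te;
            size_t i1 = i0 + 1;
            while (i1 < band.size() && band[i1].ts <= thi + cluster_gap) {
              qlo = std::min(qlo, band[i1].qs); qhi = std::max(qhi, band[i1].qe);
              tlo = std::min(tlo, band[i1].ts); thi = std::max(thi, band[i1].te);
              ++i1;
            }
            RawHit h; h.query = qi; h.contig = (int)ci; h.strand = strand;
            if (align_cluster(qe, cenc[ci], qlo, qhi, tlo, thi,
                              match, mismatch, gap_open, gap_ext, h)) {
              double ident = h.columns > 0 ? (double)h.matches / h.columns : 0.0;
              if (h.score >= min_score && ident >= min_identity) {
                if (strand == '-') {  // back to query-forward orientation
                  int a = qlen - h.qend, b2 = qlen - h.qstart;
                  h.qstart = a; h.qend = b2;
                }
                hits.push_back(h);
              }
            }
            i0 = i1;
          }
        }
      }
    }
  }
  delete idx;

  // merge extensions overlapping on both query and target: keep best score
  std::sort(hits.begin(), hits.end(), [](const RawHit &a, const RawHit &b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.query != b.query) return a.query < b.query;
    if (a.contig != b.contig) return a.contig < b.contig;
    if (a.tstart != b.tstart) return a.tstart < b.tstart;
    return a.qstart < b.qstart;
  });
  std::vector<RawHit> kept;
  for (auto &h : hits) {
    bool dup = false;
    for (auto &g : kept) {
      if (g.query != h.query || g.contig != h.contig || g.strand != h.strand) continue;
      int qo = std::min(g.qend, h.qend) - std::max(g.qstart, h.qstart);
      int to = std::min(g.tend, h.tend) - std::max(g.tstart, h.tstart);
      int qmin = std::min(g.qend - g.qstart, h.qend - h.qstart);
      int tmin = std::min(g.tend - g.tstart, h.tend - h.tstart);
      if (qo > qmin / 2 && to > tmin / 2) { dup = true; break; }
    }
    if (!dup) kept.push_back(h);
  }
  std::sort(kept.begin(), kept.end(), [](const RawHit &a, const RawHit &b) {
    if (a.contig != b.contig) return a.contig < b.contig;
    if (a.tstart != b.tstart) return a.tstart < b.tstart;
    if (a.tend != b.tend) return a.tend < b.tend;
    if (a.query != b.query) return a.query < b.query;
    return a.strand < b.strand;
  });

  int nh = (int)kept.size();
  IntegerVector query(nh), contig(nh), qstart(nh), qend(nh), tstart(nh), tend(nh), score(nh);
  NumericVector identity(nh);
  CharacterVector strand(nh);
  for (int i = 0; i < nh; ++i) {
    const RawHit &h = kept[i];
    query[i] = h.query + 1; contig[i] = h.contig + 1;
    strand[i] = h.strand == '+' ? "+" : "-";
    qstart[i] = h.qstart; qend[i] = h.qend;
    tstart[i] = h.tstart; tend[i] = h.tend;
    score[i] = h.score;
    identity[i] = h.columns > 0 ? (double)h.matches / h.columns : 0.0;
  }
  return DataFrame::create(_["query"] = query, _["contig"] = contig,
                           _["strand"] = strand,
                           _["qstart"] = qstart, _["qend"] = qend,
                           _["tstart"] = tstart, _["tend"] = tend,
                           _["identity"] = identity, _["score"] = score,
                           _["stringsAsFactors"] = false);
}
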
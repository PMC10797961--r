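#ifndef TOXANNOT_SEQ_UTILS_H
#define TOXANNOT_SEQ_UTILS_H

#include <string>
#include <vector>
#include <cstdint>

// A=0, C=1, G=2, T=3, anything else (incl. N) = 4
inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return 4;
}

inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'a': return 't';
  case 'C': return 'G'; case 'c': return 'g';
  case 'G': return 'C'; case 'g': return 'c';
  case 'T': return 'A'; case 't': return 'a';
  }
  return 'N';
}

inline std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

inline std::vector<uint8_t> encode_seq(const std::string &s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t)base_code(s[i]);
  return v;
}

struct LocalAln {
  int score = 0;
  // 0-based half-open on the two input strings
  int astart = 0, aend = 0, bstart = 0, bend = 0;
  int matches = 0, columns = 0;
};

// Smith-Waterman with affine gaps; gap of length L costs gap_open + L*gap_ext
// (both passed as negative numbers). N never matches.
// codes equal to `wildcard` never match (pass a negative wildcard to
// disable, e.g. for peptide alphabets)
LocalAln local_align(const std::vector<uint8_t> &a, const std::vector<uint8_t> &b,
                     int match, int mismatch, int gap_open, int gap_ext,
                     int wildcard = 4);

#endif
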
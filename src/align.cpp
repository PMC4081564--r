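// Seed-and-verify search primitives backing the toy aligners.
//
// Contiguous search: pigeonhole seeding (k+1 disjoint seeds tolerate k
// substitutions) over a hashed w-mer index of the target texts, followed by
// full Hamming verification.  Spliced search: exact placement of the read's
// length-a prefix and suffix anchors, pairing anchors whose implied gap lies
// in the allowed intron range, then an O(L) scan for the best two-block split.
// Both work on the forward texts and additionally on the reverse complement
// of each read (strand '-').

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline char complement_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'a': return 't';
    case 'c': return 'g';
    case 'g': return 'c';
    case 't': return 'a';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = complement_base(s[i]);
  return out;
}

// 2-bit packing; returns false when the window contains a non-ACGT base.
static inline bool encode_kmer(const char* s, int w, uint64_t& code) {
  uint64_t c = 0;
  for (int i = 0; i < w; ++i) {
    int b;
    switch (s[i]) {
      case 'A': case 'a': b = 0; break;
      case 'C': case 'c': b = 1; break;
      case 'G': case 'g': b = 2; break;
      case 'T': case 't': b = 3; break;
      default: return false;
    }
    c = (c << 2) | (uint64_t)b;
  }
  code = c;
  return true;
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > KmerIndex;

static KmerIndex build_index(const std::vector<std::string>& texts, int w) {
  KmerIndex idx;
  for (size_t t = 0; t < texts.size(); ++t) {
    const std::string& s = texts[t];
    if ((int)s.size() < w) continue;
    for (int p = 0; p + w <= (int)s.size(); ++p) {
      uint64_t code;
      if (encode_kmer(s.c_str() + p, w, code))
        idx[code].push_back(std::make_pair((int)t, p));
    }
  }
  return idx;
}

static inline int hamming_upto(const std::string& text, int pos,
                               const std::string& read, int kmax) {
  int mm = 0;
  const int L = (int)read.size();
  for (int i = 0; i < L; ++i) {
    if (text[pos + i] != read[i]) {
      if (++mm > kmax) return mm;
    }
  }
  return mm;
}

// All placements of each read (both orientations) on every text with at most
// kmax substitutions.  Returns one row per distinct (read, text, pos, strand).
// [[Rcpp::export]]
DataFrame cpp_contiguous_hits(CharacterVector texts_, CharacterVector reads_,
                              int kmax, int seed_len) {
  std::vector<std::string> texts = as<std::vector<std::string> >(texts_);
  std::vector<std::string> reads = as<std::vector<std::string> >(reads_);
  if (kmax < 0) stop("kmax must be >= 0");
  if (seed_len < 1 || seed_len > 31) stop("seed_len must be in [1, 31]");

  int Lmin = -1;
  for (size_t i = 0; i < reads.size(); ++i) {
    int L = (int)reads[i].size();
    if (Lmin < 0 || L < Lmin) Lmin = L;
  }
  std::vector<int> out_read, out_target, out_pos, out_nm;
  std::vector<std::string> out_strand;
  if (Lmin < 0) {
    return DataFrame::create(_["read"] = out_read, _["target"] = out_target,
                             _["pos"] = out_pos, _["strand"] = out_strand,
                             _["nm"] = out_nm,
                             _["stringsAsFactors"] = false);
  }
  int seg = Lmin / (kmax + 1);
  if (seg < 1) stop("reads too short for the requested mismatch tolerance");
  int w = seed_len < seg ? seed_len : seg;

  KmerIndex idx = build_index(texts, w);

  for (size_t r = 0; r < reads.size(); ++r) {
    const int L = (int)reads[r].size();
    const int step = L / (kmax + 1);
    for (int orient = 0; orient < 2; ++orient) {
      std::string q = orient == 0 ? reads[r] : revcomp(reads[r]);
      std::unordered_set<uint64_t> seen;  // (target << 34) | pos
      for (int s = 0; s <= kmax; ++s) {
        int off = s * step;
        if (off + w > L) break;
        uint64_t code;
        if (!encode_kmer(q.c_str() + off, w, code)) continue;
        KmerIndex::const_iterator it = idx.find(code);
        if (it == idx.end()) continue;
        const std::vector<std::pair<int, int> >& hits = it->second;
        for (size_t h = 0; h < hits.size(); ++h) {
          int t = hits[h].first;
          int start = hits[h].second - off;
          if (start < 0 || start + L > (int)texts[t].size()) continue;
          uint64_t key = ((uint64_t)t << 34) | (uint64_t)(start + 1);
          if (seen.count(key)) continue;
          seen.insert(key);
          int mm = hamming_upto(texts[t], start, q, kmax);
          if (mm <= kmax) {
            out_read.push_back((int)r + 1);
            out_target.push_back(t + 1);
            out_pos.push_back(start);
            out_strand.push_back(orient == 0 ? "+" : "-");
            out_nm.push_back(mm);
          }
        }
      }
    }
  }
  return DataFrame::create(_["read"] = out_read, _["target"] = out_target,
                           _["pos"] = out_pos, _["strand"] = out_strand,
                           _["nm"] = out_nm,
                           _["stringsAsFactors"] = false);
}

// Two-block spliced candidates: the read's length-a prefix and suffix are
// placed exactly; every prefix/suffix pair on one text whose implied gap
// g = q + a - p - L falls inside [intron_min, intron_max] yields an
// M-N-M candidate.  The interior split (left block length in [a, L-a]) is
// chosen to minimise substitutions; ties take the smallest left block.
// [[Rcpp::export]]
DataFrame cpp_spliced_hits(CharacterVector texts_, CharacterVector reads_,
                           int anchor, int intron_min, int intron_max,
                           int kmax) {
  std::vector<std::string> texts = as<std::vector<std::string> >(texts_);
  std::vector<std::string> reads = as<std::vector<std::string> >(reads_);
  if (anchor < 1 || anchor > 31) stop("anchor must be in [1, 31]");
  if (intron_min < 1 || intron_max < intron_min) stop("bad intron range");

  KmerIndex idx = build_index(texts, anchor);

  std::vector<int> out_read, out_target, out_pos, out_nm, out_left, out_intron;
  std::vector<std::string> out_strand;

  for (size_t r = 0; r < reads.size(); ++r) {
    const int L = (int)reads[r].size();
    if (L < 2 * anchor) continue;
    for (int orient = 0; orient < 2; ++orient) {
      std::string q = orient == 0 ? reads[r] : revcomp(reads[r]);
      uint64_t pc, sc;
      if (!encode_kmer(q.c_str(), anchor, pc)) continue;
      if (!encode_kmer(q.c_str() + (L - anchor), anchor, sc)) continue;
      KmerIndex::const_iterator pit = idx.find(pc);
      KmerIndex::const_iterator sit = idx.find(sc);
      if (pit == idx.end() || sit == idx.end()) continue;
      const std::vector<std::pair<int, int> >& pre = pit->second;
      const std::vector<std::pair<int, int> >& suf = sit->second;
      for (size_t i = 0; i < pre.size(); ++i) {
        int t = pre[i].first;
        int p = pre[i].second;
        const std::string& text = texts[t];
        for (size_t j = 0; j < suf.size(); ++j) {
          if (suf[j].first != t) continue;
          int qpos = suf[j].second;
          long g = (long)qpos + anchor - (long)p - L;
          if (g < intron_min || g > intron_max) continue;
          if (p + (long)g + L > (long)text.size()) continue;
          // mmL[i]: substitutions of q[0..i) left-aligned at p;
          // mmR[i]: substitutions of q[i..L) right-aligned before q's end.
          std::vector<int> mmL(L + 1, 0), mmR(L + 1, 0);
          for (int x = 0; x < L; ++x)
            mmL[x + 1] = mmL[x] + (text[p + x] != q[x] ? 1 : 0);
          for (int x = L - 1; x >= 0; --x)
            mmR[x] = mmR[x + 1] + (text[p + g + x] != q[x] ? 1 : 0);
          int best_bl = -1, best_nm = kmax + 1;
          for (int bl = anchor; bl <= L - anchor; ++bl) {
            int nm = mmL[bl] + mmR[bl];
            if (nm < best_nm) { best_nm = nm; best_bl = bl; }
          }
          if (best_bl < 0 || best_nm > kmax) continue;
          out_read.push_back((int)r + 1);
          out_target.push_back(t + 1);
          out_pos.push_back(p);
          out_strand.push_back(orient == 0 ? "+" : "-");
          out_nm.push_back(best_nm);
          out_left.push_back(best_bl);
          out_intron.push_back((int)g);
        }
      }
    }
  }
  return DataFrame::create(_["read"] = out_read, _["target"] = out_target,
                           _["pos"] = out_pos, _["strand"] = out_strand,
                           _["nm"] = out_nm, _["left_len"] = out_left,
                           _["intron"] = out_intron,
                           _["stringsAsFactors"] = false);
}

// Hamming distance between equal-length strings (test/oracle helper).
// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) stop("length mismatch");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i]) ++d;
  return d;
}
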
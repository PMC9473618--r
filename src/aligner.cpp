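// Minimal deterministic seed-and-extend read assigner.
//
// Candidate locations are enumerated by exact k-mer seeding (tiled seed
// offsets, both strands), scored by ungapped full-length extension
// (+1 match / -2 mismatch), and the single best location is reported as the
// primary record. Ties are broken by (reference name, start, strand)
// lexicographic order; references are expected pre-sorted by name.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
  }
  return 'N';
}

static std::string reverse_complement(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = complement(r[i]);
  return r;
}

// Encode the k-mer starting at s[pos]; returns false if it contains a
// non-ACGT character.
static inline bool encode_kmer(const std::string& s, size_t pos, int k,
                               uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[pos + i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

struct Candidate {
  int ref;
  int pos;
  int strand;  // 0 = '+', 1 = '-'
  bool operator<(const Candidate& o) const {
    if (ref != o.ref) return ref < o.ref;
    if (pos != o.pos) return pos < o.pos;
    return strand < o.strand;
  }
  bool operator==(const Candidate& o) const {
    return ref == o.ref && pos == o.pos && strand == o.strand;
  }
};

// [[Rcpp::export]]
List cpp_align(CharacterVector reads, CharacterVector ref_seqs, int k,
               int max_mismatches, double max_mismatch_frac, int margin) {
  if (k < 1 || k > 31) stop("seed length k must be in [1, 31]");
  int n_ref = ref_seqs.size();
  std::vector<std::string> refs(n_ref);
  for (int i = 0; i < n_ref; ++i) refs[i] = as<std::string>(ref_seqs[i]);

  // k-mer index over all references: kmer -> packed (ref, pos)
  std::unordered_map<uint64_t, std::vector<uint64_t> > index;
  size_t total_len = 0;
  for (int r = 0; r < n_ref; ++r) total_len += refs[r].size();
  index.reserve(total_len);
  for (int r = 0; r < n_ref; ++r) {
    const std::string& s = refs[r];
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + (size_t)k <= s.size(); ++p) {
      uint64_t key;
      if (!encode_kmer(s, p, k, key)) continue;
      index[key].push_back(((uint64_t)r << 32) | (uint64_t)p);
    }
  }

  int n_reads = reads.size();
  std::vector<int> o_read, o_ref, o_start, o_end, o_score, o_nco, o_mm;
  std::vector<int> o_strand, o_unique;
  int n_skipped = 0, n_unmapped = 0;

  std::vector<Candidate> cands;
  std::vector<int> offsets;

  for (int ri = 0; ri < n_reads; ++ri) {
    std::string read = as<std::string>(reads[ri]);
    int len = (int)read.size();
    if (len < k) { ++n_skipped; continue; }

    // tiled seed offsets: 0, k, 2k, ..., plus the final full window
    offsets.clear();
    for (int o = 0; o + k <= len; o += k) offsets.push_back(o);
    if (offsets.empty() || offsets.back() != len - k)
      offsets.push_back(len - k);

    std::string rc = reverse_complement(read);
    cands.clear();
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = (strand == 0) ? read : rc;
      for (size_t oi = 0; oi < offsets.size(); ++oi) {
        int o = offsets[oi];
        uint64_t key;
        if (!encode_kmer(q, o, k, key)) continue;
        std::unordered_map<uint64_t, std::vector<uint64_t> >::const_iterator
            it = index.find(key);
        if (it == index.end()) continue;
        const std::vector<uint64_t>& hits = it->second;
        for (size_t h = 0; h < hits.size(); ++h) {
          int r = (int)(hits[h] >> 32);
          long p = (long)(hits[h] & 0xffffffffULL) - o;
          if (p < 0 || p + len > (long)refs[r].size()) continue;
          Candidate c; c.ref = r; c.pos = (int)p; c.strand = strand;
          cands.push_back(c);
        }
      }
    }
    if (cands.empty()) { ++n_unmapped; continue; }
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

    int best = INT32_MIN, second = INT32_MIN, n_co = 0;
    Candidate bc = cands[0];
    int best_matches = 0;
    for (size_t ci = 0; ci < cands.size(); ++ci) {
      const Candidate& c = cands[ci];
      const std::string& q = (c.strand == 0) ? read : rc;
      const char* rseq = refs[c.ref].data() + c.pos;
      int matches = 0;
      for (int j = 0; j < len; ++j) if (q[j] == rseq[j]) ++matches;
      int score = matches - 2 * (len - matches);
      if (score > best) {
        second = best; best = score; bc = c; n_co = 1; best_matches = matches;
      } else if (score == best) {
        ++n_co;
        if (score > second) second = score;
      } else if (score > second) {
        second = score;
      }
    }

    int mm = len - best_matches;
    int mm_cap = max_mismatches < 0 ? len : max_mismatches;
    int frac_cap = (int)(max_mismatch_frac * len);
    if (frac_cap < mm_cap) mm_cap = frac_cap;
    if (mm > mm_cap) { ++n_unmapped; continue; }

    bool uniq = (n_co == 1) && (second == INT32_MIN || best - second > margin);
    o_read.push_back(ri + 1);
    o_ref.push_back(bc.ref + 1);
    o_start.push_back(bc.pos);
    o_end.push_back(bc.pos + len);
    o_strand.push_back(bc.strand);
    o_score.push_back(best);
    o_nco.push_back(n_co);
    o_mm.push_back(mm);
    o_unique.push_back(uniq ? 1 : 0);
  }

  return List::create(
      _["read_idx"] = wrap(o_read), _["ref_idx"] = wrap(o_ref),
      _["start"] = wrap(o_start), _["end"] = wrap(o_end),
      _["strand"] = wrap(o_strand), _["score"] = wrap(o_score),
      _["n_cooptimal"] = wrap(o_nco), _["mismatches"] = wrap(o_mm),
      _["is_unique"] = wrap(o_unique),
      _["n_skipped"] = n_skipped, _["n_unmapped"] = n_unmapped);
}
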
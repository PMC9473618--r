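// Tandem simple-repeat unit detection and canonicalization.
//
// A read is called tandem-repetitive when some unit of length k <= k_max has
// >= min_copies consecutive exact copies covering >= min_fraction of the
// read. Among qualifying runs the one with maximal covered length wins;
// ties go to the smaller k, then to the lexicographically smaller canonical
// unit. The canonical form of a unit is the lexicographic minimum over all
// rotations of the unit and of its reverse complement, so e.g. GA, AG, TC
// and CT tandems collapse onto one record ("AG").

#include <Rcpp.h>
#include <string>
#include <cstring>

using namespace Rcpp;

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
  }
  return 'N';
}

static std::string canonical_one(const std::string& u) {
  int k = (int)u.size();
  std::string rc(u.rbegin(), u.rend());
  for (int i = 0; i < k; ++i) rc[i] = complement(rc[i]);
  std::string best = u;
  std::string rot;
  for (int r = 0; r < k; ++r) {
    rot = u.substr(r) + u.substr(0, r);
    if (rot < best) best = rot;
    rot = rc.substr(r) + rc.substr(0, r);
    if (rot < best) best = rot;
  }
  return best;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical_unit(CharacterVector units) {
  int n = units.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (CharacterVector::is_na(units[i])) { out[i] = NA_STRING; continue; }
    out[i] = canonical_one(as<std::string>(units[i]));
  }
  return out;
}

// [[Rcpp::export]]
List cpp_detect_tandem(CharacterVector reads, int k_max, int min_copies,
                       double min_fraction) {
  int n = reads.size();
  CharacterVector out_unit(n);
  IntegerVector out_copies(n);

  for (int ri = 0; ri < n; ++ri) {
    out_unit[ri] = NA_STRING;
    out_copies[ri] = NA_INTEGER;
    if (CharacterVector::is_na(reads[ri])) continue;
    std::string s = as<std::string>(reads[ri]);
    int len = (int)s.size();
    const char* p = s.data();

    int best_cov = -1, best_k = 0, best_copies = 0;
    std::string best_canon;

    int kk_max = k_max;
    if (min_copies > 0 && len / min_copies < kk_max) kk_max = len / min_copies;
    for (int k = 1; k <= kk_max; ++k) {
      for (int st = 0; st + k * min_copies <= len; ++st) {
        // skip run starts that are interior to a longer run of the same
        // period (the start one base earlier dominates in coverage)
        if (st > 0 && st - 1 + k < len && p[st - 1] == p[st - 1 + k]) continue;
        int c = 1;
        while (st + (c + 1) * k <= len &&
               std::memcmp(p + st + c * k, p + st, k) == 0)
          ++c;
        if (c < min_copies) continue;
        int cov = c * k;
        if ((double)cov < min_fraction * len) continue;
        if (cov < best_cov) continue;
        if (cov == best_cov && k > best_k) continue;
        std::string canon = canonical_one(s.substr(st, k));
        if (cov == best_cov && k == best_k && canon >= best_canon) continue;
        best_cov = cov; best_k = k; best_copies = c; best_canon = canon;
      }
    }
    if (best_cov >= 0) {
      out_unit[ri] = best_canon;
      out_copies[ri] = best_copies;
    }
  }
  return List::create(_["unit"] = out_unit, _["copies"] = out_copies);
}
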
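#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Minimal exact-seed + ungapped full-length extension aligner.
// A read maps at a reference position if the whole read aligns without gaps
// with at most max_mm mismatches. Candidate positions come from exact seed
// matches at up to three offsets (start / middle / end of the read), on both
// strands. Unique best location -> MAPQ 42; tied best -> MAPQ 0.

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': case 'a': r[i] = 'T'; break;
      case 'C': case 'c': r[i] = 'G'; break;
      case 'G': case 'g': r[i] = 'C'; break;
      case 'T': case 't': r[i] = 'A'; break;
      default: r[i] = 'N';
    }
  }
  return r;
}

static inline int mismatches(const std::string& ref, size_t pos,
                             const std::string& read, int cap) {
  int mm = 0;
  const size_t n = read.size();
  for (size_t k = 0; k < n; ++k) {
    if (ref[pos + k] != read[k]) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
List align_reads_cpp(CharacterVector reads, CharacterVector refs,
                     int seed_len, double max_mismatch_frac) {
  const int nref = refs.size();
  std::vector<std::string> R(nref);
  for (int i = 0; i < nref; ++i) R[i] = as<std::string>(refs[i]);

  // k-mer index over forward strands of all references
  std::unordered_map<uint64_t, std::vector<uint64_t> > index;
  const uint64_t mask = (seed_len >= 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
  for (int r = 0; r < nref; ++r) {
    const std::string& s = R[r];
    if ((int)s.size() < seed_len) continue;
    uint64_t h = 0;
    int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      const int b = base2bit(s[i]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++run >= seed_len) {
        const uint64_t pos = i + 1 - seed_len;
        index[h].push_back(((uint64_t)r << 40) | pos);
      }
    }
  }

  const int n = reads.size();
  IntegerVector out_ref(n, NA_INTEGER), out_pos(n, NA_INTEGER),
      out_mapq(n, NA_INTEGER), out_nmis(n, NA_INTEGER);
  LogicalVector out_mapped(n);
  CharacterVector out_strand(n);

  std::vector<uint64_t> seen; // (ref<<41)|(pos<<1)|strand for dedupe
  for (int q = 0; q < n; ++q) {
    const std::string fwd = as<std::string>(reads[q]);
    const int len = fwd.size();
    const int cap = (int)std::floor(max_mismatch_frac * len + 1e-9);
    int best_mm = cap + 1, best_ref = -1, best_pos = -1, best_strand = 0,
        nbest = 0;
    if (len >= seed_len) {
      const std::string rev = revcomp(fwd);
      seen.clear();
      int offs[3] = {0, (len - seed_len) / 2, len - seed_len};
      for (int strand = 0; strand < 2; ++strand) {
        const std::string& rd = (strand == 0) ? fwd : rev;
        for (int oi = 0; oi < 3; ++oi) {
          const int off = offs[oi];
          if (oi > 0 && off == offs[oi - 1]) continue;
          uint64_t h = 0;
          bool valid = true;
          for (int k = 0; k < seed_len; ++k) {
            const int b = base2bit(rd[off + k]);
            if (b < 0) { valid = false; break; }
            h = (h << 2) | (uint64_t)b;
          }
          if (!valid) continue;
          auto it = index.find(h & mask);
          if (it == index.end()) continue;
          const std::vector<uint64_t>& cands = it->second;
          for (size_t c = 0; c < cands.size(); ++c) {
            const int r = (int)(cands[c] >> 40);
            const int64_t p = (int64_t)(cands[c] & ((1ULL << 40) - 1)) - off;
            if (p < 0 || p + len > (int64_t)R[r].size()) continue;
            const uint64_t key =
                ((uint64_t)r << 41) | ((uint64_t)p << 1) | strand;
            bool dup = false;
            for (size_t z = 0; z < seen.size(); ++z)
              if (seen[z] == key) { dup = true; break; }
            if (dup) continue;
            seen.push_back(key);
            const int mm = mismatches(R[r], (size_t)p, rd, cap);
            if (mm > cap) continue;
            if (mm < best_mm) {
              best_mm = mm;
              best_ref = r;
              best_pos = (int)p;
              best_strand = strand;
              nbest = 1;
            } else if (mm == best_mm) {
              ++nbest;
            }
          }
        }
      }
    }
    if (best_ref >= 0) {
      out_mapped[q] = true;
      out_ref[q] = best_ref + 1;
      out_pos[q] = best_pos;
      out_mapq[q] = (nbest == 1) ? 42 : 0;
      out_nmis[q] = best_mm;
      out_strand[q] = (best_strand == 0) ? "+" : "-";
    } else {
      out_mapped[q] = false;
      out_strand[q] = NA_STRING;
    }
  }
  return List::create(_["ref"] = out_ref, _["pos"] = out_pos,
                      _["mapq"] = out_mapq, _["nmis"] = out_nmis,
                      _["strand"] = out_strand, _["mapped"] = out_mapped);
}
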
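#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// Canonical k-mer counting with 2-bit encoding (k <= 31).  Windows
// containing any non-ACGT character are skipped; each window is counted
// under the lexicographic minimum of itself and its reverse complement.
// Returns the depth -> distinct-kmer-count histogram as a named vector.
// [[Rcpp::export(name = ".count_kmers_cpp")]]
NumericVector count_kmers_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::unordered_map<uint64_t, uint32_t> tab;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *p = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rev = 0;
    int run = 0;  // valid bases accumulated in current window
    for (; *p; ++p) {
      int code;
      switch (*p) {
        case 'A': case 'a': code = 0; break;
        case 'C': case 'c': code = 1; break;
        case 'G': case 'g': code = 2; break;
        case 'T': case 't': code = 3; break;
        default: code = -1;
      }
      if (code < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)code) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - code) << shift);
      if (++run >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++tab[canon];
      }
    }
  }

  // histogram: depth -> number of distinct canonical k-mers
  std::unordered_map<uint32_t, double> histo;
  for (auto &kv : tab) ++histo[kv.second];
  std::vector<uint32_t> depths;
  depths.reserve(histo.size());
  for (auto &kv : histo) depths.push_back(kv.first);
  std::sort(depths.begin(), depths.end());
  NumericVector out(depths.size());
  CharacterVector nm(depths.size());
  for (size_t i = 0; i < depths.size(); ++i) {
    out[i] = histo[depths[i]];
    nm[i] = std::to_string(depths[i]);
  }
  out.names() = nm;
  return out;
}
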
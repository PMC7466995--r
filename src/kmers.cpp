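#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <map>
#include <cstdint>
using namespace Rcpp;

// 2-bit base encoding; anything non-ACGT (case-insensitive) is invalid and
// breaks every k-mer window that overlaps it.
static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Rolling canonical k-mer scan over one sequence. Maintains the forward
// 2-bit encoding and the reverse complement simultaneously; emits the
// lexicographic (= numeric under this encoding) minimum of the two for every
// window of k consecutive valid bases. Calls f(key) once per emitted window.
template <typename F>
static inline void scan_canonical(const char* s, int n, int k, F f) {
  uint64_t fwd = 0, rev = 0;
  const uint64_t mask = (1ULL << (2 * k)) - 1;  // k <= 31 so 2k <= 62
  const int shift = 2 * (k - 1);
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++valid >= k) f(fwd < rev ? fwd : rev);
  }
}

// Count canonical k-mers across a set of sequences and return the
// multiplicity histogram (Jellyfish "histo" semantics): for each multiplicity
// i the number of distinct canonical k-mers seen exactly i times.
// [[Rcpp::export]]
List kmer_histogram_cpp(CharacterVector seqs, int k) {
  if (k < 3 || k > 31) stop("k must be between 3 and 31");
  if (k % 2 == 0) stop("k must be odd");
  std::unordered_map<uint64_t, uint32_t> tab;
  tab.reserve(1 << 20);
  double n_windows = 0, n_possible = 0;
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    const char* s = CHAR(STRING_ELT(seqs, j));
    int n = LENGTH(STRING_ELT(seqs, j));
    if (n >= k) n_possible += n - k + 1;
    scan_canonical(s, n, k, [&](uint64_t key) {
      ++tab[key];
      n_windows += 1.0;
    });
  }
  std::map<uint32_t, double> hist;
  for (const auto& kv : tab) hist[kv.second] += 1.0;
  IntegerVector mult(hist.size());
  NumericVector cnt(hist.size());
  R_xlen_t i = 0;
  for (const auto& kv : hist) { mult[i] = kv.first; cnt[i] = kv.second; ++i; }
  return List::create(_["multiplicity"] = mult, _["count"] = cnt,
                      _["n_windows"] = n_windows,
                      _["n_skipped"] = n_possible - n_windows);
}

// For each read, the number of its k-mer windows whose canonical k-mer also
// occurs in the reference sequences. Basis of the alignment-free
// mitochondrial screen.
// [[Rcpp::export]]
IntegerVector shared_kmer_counts_cpp(CharacterVector reads,
                                     CharacterVector refs, int k) {
  if (k < 3 || k > 31) stop("k must be between 3 and 31");
  if (k % 2 == 0) stop("k must be odd");
  std::unordered_set<uint64_t> ref_set;
  ref_set.reserve(1 << 16);
  for (R_xlen_t j = 0; j < refs.size(); ++j) {
    const char* s = CHAR(STRING_ELT(refs, j));
    int n = LENGTH(STRING_ELT(refs, j));
    scan_canonical(s, n, k, [&](uint64_t key) { ref_set.insert(key); });
  }
  IntegerVector out(reads.size());
  for (R_xlen_t j = 0; j < reads.size(); ++j) {
    const char* s = CHAR(STRING_ELT(reads, j));
    int n = LENGTH(STRING_ELT(reads, j));
    int shared = 0;
    scan_canonical(s, n, k, [&](uint64_t key) {
      if (ref_set.count(key)) ++shared;
    });
    out[j] = shared;
  }
  return out;
}
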
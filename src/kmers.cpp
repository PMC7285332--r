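#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int code2(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static std::string decode_kmer(uint64_t v, int k) {
  static const char b[4] = {'A', 'C', 'G', 'T'};
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = b[v & 3];
    v >>= 2;
  }
  return s;
}

// Rolling canonical k-mer scan: for each position with a valid (ACGT-only)
// k-mer, call f(canonical_code). Canonical = min(forward, reverse
// complement) on the 2-bit encoding, which equals lexicographic order on
// the decoded strings.
template <class F>
static void scan_canonical(const std::string& s, int k, F f) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int rcshift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  const int n = (int) s.size();
  for (int i = 0; i < n; ++i) {
    int c = code2(s[i]);
    if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t) c) & mask;
    rev = (rev >> 2) | (((uint64_t)(3 - c)) << rcshift);
    if (++valid >= k) f(std::min(fwd, rev));
  }
}

// Canonical k-mer occurrence counts over a set of reads.
// Overlapping occurrences all count; k-mers containing N are skipped.
// Returns list(kmers = character, counts = integer), kmers sorted
// lexicographically for determinism.
// [[Rcpp::export]]
List kmer_count_cpp(CharacterVector seqs, int k) {
  if (k < 3 || k > 31) stop("k must be in [3, 31]");
  std::unordered_map<uint64_t, int> counts;
  for (int r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    scan_canonical(s, k, [&](uint64_t v) { ++counts[v]; });
  }
  std::vector<uint64_t> keys;
  keys.reserve(counts.size());
  for (std::unordered_map<uint64_t, int>::const_iterator it = counts.begin();
       it != counts.end(); ++it)
    keys.push_back(it->first);
  std::sort(keys.begin(), keys.end());
  CharacterVector km(keys.size());
  IntegerVector ct(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    km[i] = decode_kmer(keys[i], k);
    ct[i] = counts[keys[i]];
  }
  return List::create(_["kmers"] = km, _["counts"] = ct);
}

// Median copy number of each read's canonical k-mers under a k-mer count
// table. Even-sized multisets take the mean of the two central values.
// Reads with no countable k-mer (too short, or all k-mers contain N)
// get NA. K-mers absent from the table count as 0 copies.
// [[Rcpp::export]]
NumericVector median_copy_batch_cpp(CharacterVector seqs,
                                    CharacterVector kmers,
                                    IntegerVector counts, int k) {
  if (k < 3 || k > 31) stop("k must be in [3, 31]");
  std::unordered_map<uint64_t, int> table;
  table.reserve(kmers.size() * 2);
  for (int i = 0; i < kmers.size(); ++i) {
    std::string km = as<std::string>(kmers[i]);
    if ((int) km.size() != k) stop("k-mer table entry of wrong length");
    uint64_t fwd = 0, rev = 0;
    const int rcshift = 2 * (k - 1);
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = code2(km[j]);
      if (c < 0) { ok = false; break; }
      fwd = (fwd << 2) | (uint64_t) c;
      rev = (rev >> 2) | (((uint64_t)(3 - c)) << rcshift);
    }
    if (ok) table[std::min(fwd, rev)] = counts[i];
  }
  NumericVector out(seqs.size());
  std::vector<int> copies;
  for (int r = 0; r < seqs.size(); ++r) {
    copies.clear();
    std::string s = as<std::string>(seqs[r]);
    scan_canonical(s, k, [&](uint64_t v) {
      std::unordered_map<uint64_t, int>::const_iterator it = table.find(v);
      copies.push_back(it == table.end() ? 0 : it->second);
    });
    if (copies.empty()) {
      out[r] = NA_REAL;
    } else {
      std::sort(copies.begin(), copies.end());
      const size_t n = copies.size();
      out[r] = (n % 2 == 1)
        ? (double) copies[n / 2]
        : (copies[n / 2 - 1] + copies[n / 2]) / 2.0;
    }
  }
  return out;
}

// Fraction of a read's canonical k-mers whose copy number is below a
// threshold (the unmodified Stacks kmer_filter criterion). NA when the
// read has no countable k-mer.
// [[Rcpp::export]]
NumericVector low_copy_fraction_batch_cpp(CharacterVector seqs,
                                          CharacterVector kmers,
                                          IntegerVector counts, int k,
                                          int min_copy) {
  if (k < 3 || k > 31) stop("k must be in [3, 31]");
  std::unordered_map<uint64_t, int> table;
  table.reserve(kmers.size() * 2);
  for (int i = 0; i < kmers.size(); ++i) {
    std::string km = as<std::string>(kmers[i]);
    uint64_t fwd = 0, rev = 0;
    const int rcshift = 2 * (k - 1);
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int c = code2(km[j]);
      if (c < 0) { ok = false; break; }
      fwd = (fwd << 2) | (uint64_t) c;
      rev = (rev >> 2) | (((uint64_t)(3 - c)) << rcshift);
    }
    if (ok) table[std::min(fwd, rev)] = counts[i];
  }
  NumericVector out(seqs.size());
  for (int r = 0; r < seqs.size(); ++r) {
    long total = 0, low = 0;
    std::string s = as<std::string>(seqs[r]);
    scan_canonical(s, k, [&](uint64_t v) {
      std::unordered_map<uint64_t, int>::const_iterator it = table.find(v);
      int c = (it == table.end()) ? 0 : it->second;
      ++total;
      if (c < min_copy) ++low;
    });
    out[r] = (total == 0) ? NA_REAL : (double) low / (double) total;
  }
  return out;
}
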
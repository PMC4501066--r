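#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoding A=0, C=1, G=2, T=3 packed big-endian (first base most
// significant), so numeric order on codes equals lexicographic order on the
// strings. Codes are returned as doubles; exact for k <= 26 (4^26 < 2^53).

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  if (k < 2 || k > 26)
    stop("k must be between 2 and 26");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift_hi = 2 * (k - 1);
  int max_len = 0;

  std::vector<uint64_t> windows;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *p = CHAR(STRING_ELT(seqs, s));
    int len = LENGTH(STRING_ELT(seqs, s));
    if (len > max_len) max_len = len;
    uint64_t fwd = 0, rev = 0;
    int valid = 0;  // consecutive valid bases ending at current position
    for (int i = 0; i < len; ++i) {
      int b = base_code(p[i]);
      if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift_hi);
      if (++valid >= k)
        windows.push_back(fwd < rev ? fwd : rev);
    }
  }
  if (max_len < k && seqs.size() > 0)
    stop("k (%d) exceeds the length of every input sequence", k);

  double n_windows = (double)windows.size();
  std::sort(windows.begin(), windows.end());
  // run-length encode the sorted windows into distinct k-mers + counts
  R_xlen_t n_distinct = 0;
  for (size_t i = 0; i < windows.size(); ++i)
    if (i == 0 || windows[i] != windows[i - 1]) ++n_distinct;
  NumericVector kmers(n_distinct);
  IntegerVector counts(n_distinct);
  R_xlen_t j = -1;
  for (size_t i = 0; i < windows.size(); ++i) {
    if (i == 0 || windows[i] != windows[i - 1]) {
      kmers[++j] = (double)windows[i];
      counts[j] = 1;
    } else {
      ++counts[j];
    }
  }
  return List::create(_["kmers"] = kmers, _["counts"] = counts,
                      _["n_windows"] = n_windows);
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmers(NumericVector codes, int k) {
  static const char bases[] = "ACGT";
  R_xlen_t n = codes.size();
  CharacterVector out(n);
  std::vector<char> buf(k + 1, '\0');
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t code = (uint64_t)codes[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = bases[code & 3ULL];
      code >>= 2;
    }
    out[i] = std::string(buf.data(), k);
  }
  return out;
}

// Canonical code of each input string; NA for strings with non-ACGT symbols.
// [[Rcpp::export]]
NumericVector cpp_encode_canonical(CharacterVector kmers, int k) {
  R_xlen_t n = kmers.size();
  NumericVector out(n);
  const int shift_hi = 2 * (k - 1);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (STRING_ELT(kmers, i) == NA_STRING || LENGTH(STRING_ELT(kmers, i)) != k) {
      out[i] = NA_REAL;
      continue;
    }
    const char *p = CHAR(STRING_ELT(kmers, i));
    uint64_t fwd = 0, rev = 0;
    bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = base_code(p[j]);
      if (b < 0) { ok = false; break; }
      fwd = (fwd << 2) | (uint64_t)b;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift_hi);
    }
    out[i] = ok ? (double)(fwd < rev ? fwd : rev) : NA_REAL;
  }
  return out;
}

// Size of the intersection of two sorted, duplicate-free code vectors.
// [[Rcpp::export]]
double cpp_intersect_size(NumericVector a, NumericVector b) {
  const double *pa = REAL(a), *pb = REAL(b);
  R_xlen_t na = a.size(), nb = b.size();
  R_xlen_t i = 0, j = 0, n = 0;
  while (i < na && j < nb) {
    if (pa[i] < pb[j]) ++i;
    else if (pa[i] > pb[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return (double)n;
}

// Flip each base independently with probability E to one of the other three
// bases (uniformly). Uses R's RNG so results are seed-reproducible.
// [[Rcpp::export]]
CharacterVector cpp_add_read_errors(CharacterVector reads, double E) {
  static const char bases[] = "ACGT";
  R_xlen_t n = reads.size();
  CharacterVector out(n);
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *p = CHAR(STRING_ELT(reads, i));
    int len = LENGTH(STRING_ELT(reads, i));
    buf.assign(p, len);
    for (int j = 0; j < len; ++j) {
      if (unif_rand() < E) {
        int b = base_code(buf[j]);
        if (b < 0) continue;
        int alt = (int)(unif_rand() * 3.0);
        if (alt > 2) alt = 2;
        buf[j] = bases[(b + 1 + alt) & 3];
      }
    }
    out[i] = buf;
  }
  return out;
}
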
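#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3. This ordering makes the numeric order
// of encoded k-mers agree with lexicographic order on the strings, so the
// canonical (strand-folded) k-mer is simply the numeric minimum of the
// forward and reverse-complement encodings. k up to 63 fits in 128 bits.
typedef unsigned __int128 kmer_t;

struct KmerHash {
  size_t operator()(const kmer_t &x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    lo *= 0x9E3779B97F4A7C15ULL;
    lo ^= lo >> 32;
    return (size_t)(lo ^ (hi * 0xC2B2AE3D27D4EB4FULL));
  }
};

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static std::string decode_kmer(kmer_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; i--) {
    s[i] = BITS2BASE[(int)(x & 3)];
    x >>= 2;
  }
  return s;
}

static bool encode_kmer(const char *s, int k, kmer_t &out) {
  kmer_t x = 0;
  for (int i = 0; i < k; i++) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    x = (x << 2) | (kmer_t)b;
  }
  out = x;
  return true;
}

// Scan one sequence, calling f(canonical_kmer, start_position) for every
// valid window. Rolling update; windows touching a non-ACGT base are skipped.
template <typename F>
static void scan_kmers(const char *s, int n, int k, F f) {
  if (n < k) return;
  kmer_t fwd = 0, rev = 0;
  const kmer_t mask = (k >= 64) ? ~(kmer_t)0 : (((kmer_t)1 << (2 * k)) - 1);
  const int revshift = 2 * (k - 1);
  int run = 0; // valid bases accumulated
  for (int i = 0; i < n; i++) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (kmer_t)b) & mask;
    rev = (rev >> 2) | ((kmer_t)(3 - b) << revshift);
    if (++run >= k) {
      kmer_t canon = fwd < rev ? fwd : rev;
      f(canon, i - k + 1);
    }
  }
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  std::unordered_map<kmer_t, int, KmerHash> counts;
  for (R_xlen_t j = 0; j < seqs.size(); j++) {
    const char *s = CHAR(STRING_ELT(seqs, j));
    int n = LENGTH(STRING_ELT(seqs, j));
    scan_kmers(s, n, k, [&](kmer_t canon, int) { counts[canon]++; });
  }
  R_xlen_t m = counts.size();
  CharacterVector kmer(m);
  IntegerVector count(m);
  R_xlen_t i = 0;
  for (auto &kv : counts) {
    kmer[i] = decode_kmer(kv.first, k);
    count[i] = kv.second;
    i++;
  }
  return List::create(_["kmer"] = kmer, _["count"] = count);
}

// Fraction of each read's bases covered by at least one occurrence of a
// flagged (canonical) k-mer. Non-ACGT positions never match a window but do
// count in the denominator.
// [[Rcpp::export]]
NumericVector cpp_flagged_fraction(CharacterVector seqs, CharacterVector flagged, int k) {
  std::unordered_set<kmer_t, KmerHash> flag;
  flag.reserve(flagged.size() * 2 + 8);
  for (R_xlen_t i = 0; i < flagged.size(); i++) {
    const char *s = CHAR(STRING_ELT(flagged, i));
    if ((int)LENGTH(STRING_ELT(flagged, i)) != k)
      stop("flagged k-mer of wrong length");
    kmer_t x;
    if (!encode_kmer(s, k, x)) stop("flagged k-mer with non-ACGT character");
    flag.insert(x);
  }
  R_xlen_t nr = seqs.size();
  NumericVector frac(nr);
  std::vector<int> covered;
  for (R_xlen_t j = 0; j < nr; j++) {
    const char *s = CHAR(STRING_ELT(seqs, j));
    int n = LENGTH(STRING_ELT(seqs, j));
    if (n == 0) { frac[j] = 0.0; continue; }
    covered.assign(n, 0);
    bool any = false;
    scan_kmers(s, n, k, [&](kmer_t canon, int pos) {
      if (flag.count(canon)) {
        any = true;
        for (int p = pos; p < pos + k; p++) covered[p] = 1;
      }
    });
    if (!any) { frac[j] = 0.0; continue; }
    int tot = 0;
    for (int p = 0; p < n; p++) tot += covered[p];
    frac[j] = (double)tot / (double)n;
  }
  return frac;
}
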
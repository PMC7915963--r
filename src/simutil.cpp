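#include <Rcpp.h>
#include <string>

using namespace Rcpp;

// Per-base substitution errors at a fixed rate, using R's RNG so that
// results are reproducible under set.seed(). Each hit base is replaced by
// one of the three other bases uniformly; non-ACGT characters are left alone.

static const char *ALPHA = "ACGT";

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
CharacterVector cpp_mutate_bases(CharacterVector seqs, double rate) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  RNGScope scope;
  for (R_xlen_t j = 0; j < n; j++) {
    std::string s = as<std::string>(seqs[j]);
    for (size_t i = 0; i < s.size(); i++) {
      if (unif_rand() < rate) {
        int b = base_idx(s[i]);
        if (b < 0) continue;
        int shift = 1 + (int)(unif_rand() * 3.0);
        if (shift > 3) shift = 3;
        s[i] = ALPHA[(b + shift) % 4];
      }
    }
    out[j] = s;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t j = 0; j < n; j++) {
    std::string s = as<std::string>(seqs[j]);
    std::string r(s.rbegin(), s.rend());
    for (auto &c : r) {
      switch (c) {
        case 'A': c = 'T'; break; case 'T': c = 'A'; break;
        case 'C': c = 'G'; break; case 'G': c = 'C'; break;
        case 'a': c = 't'; break; case 't': c = 'a'; break;
        case 'c': c = 'g'; break; case 'g': c = 'c'; break;
        default: break;
      }
    }
    out[j] = r;
  }
  return out;
}
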
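#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Seed-and-verify read mapper. Contig seeds (exact seed_length-mers, forward
// strand) are indexed in a hash table; each read is tried on both strands
// using non-overlapping seeds, candidate placements are verified by direct
// mismatch counting (N counts as a mismatch), and all placements tied at the
// minimum mismatch count (<= max_mismatches) are reported.

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static bool encode64(const char *s, int k, uint64_t &out) {
  uint64_t x = 0;
  for (int i = 0; i < k; i++) {
    int b = base2bits(s[i]);
    if (b < 0) return false;
    x = (x << 2) | (uint64_t)b;
  }
  out = x;
  return true;
}

static std::string revcomp(const std::string &s) {
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
  return r;
}

struct Hit { int contig; int pos; }; // pos 0-based on contig forward strand

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector contigs,
                   int seed_length, int max_mismatches) {
  if (seed_length < 1 || seed_length > 31) stop("seed_length must be in [1, 31]");
  int nc = contigs.size();
  std::vector<std::string> ctg(nc);
  for (int c = 0; c < nc; c++) ctg[c] = as<std::string>(contigs[c]);

  // index: seed k-mer -> packed (contig, position)
  std::unordered_map<uint64_t, std::vector<int64_t> > index;
  for (int c = 0; c < nc; c++) {
    const std::string &s = ctg[c];
    int n = (int)s.size();
    for (int p = 0; p + seed_length <= n; p++) {
      uint64_t key;
      if (encode64(s.c_str() + p, seed_length, key))
        index[key].push_back(((int64_t)c << 32) | (uint32_t)p);
    }
  }

  std::vector<int> out_read, out_contig, out_start, out_mm, out_nbest;
  std::vector<int> out_strand; // 1 = forward, -1 = reverse
  R_xlen_t nr = reads.size();

  std::vector<Hit> cand;
  for (R_xlen_t r = 0; r < nr; r++) {
    std::string fwd = as<std::string>(reads[r]);
    int len = (int)fwd.size();
    if (len < seed_length) continue; // unmapped: too short to seed
    std::string rev = revcomp(fwd);
    int best_mm = max_mismatches + 1;
    std::vector<int> best_contig, best_start, best_strand;
    for (int strand = 0; strand < 2; strand++) {
      const std::string &q = strand == 0 ? fwd : rev;
      cand.clear();
      // non-overlapping seeds plus one flush with the read end
      std::vector<int> offs;
      for (int o = 0; o + seed_length <= len; o += seed_length) offs.push_back(o);
      if (offs.empty() || offs.back() != len - seed_length)
        offs.push_back(len - seed_length);
      for (int o : offs) {
        uint64_t key;
        if (!encode64(q.c_str() + o, seed_length, key)) continue;
        auto it = index.find(key);
        if (it == index.end()) continue;
        for (int64_t packed : it->second) {
          int c = (int)(packed >> 32);
          int p = (int)(packed & 0xFFFFFFFF);
          int start = p - o;
          if (start < 0 || start + len > (int)ctg[c].size()) continue;
          cand.push_back({c, start});
        }
      }
      std::sort(cand.begin(), cand.end(), [](const Hit &a, const Hit &b) {
        return a.contig < b.contig || (a.contig == b.contig && a.pos < b.pos);
      });
      cand.erase(std::unique(cand.begin(), cand.end(), [](const Hit &a, const Hit &b) {
        return a.contig == b.contig && a.pos == b.pos;
      }), cand.end());
      for (const Hit &h : cand) {
        const char *cs = ctg[h.contig].c_str() + h.pos;
        int mm = 0;
        for (int i = 0; i < len && mm <= best_mm; i++)
          if (cs[i] != q[i]) mm++;
        if (mm > max_mismatches || mm > best_mm) continue;
        if (mm < best_mm) {
          best_mm = mm;
          best_contig.clear(); best_start.clear(); best_strand.clear();
        }
        best_contig.push_back(h.contig);
        best_start.push_back(h.pos);
        best_strand.push_back(strand == 0 ? 1 : -1);
      }
    }
    int nb = (int)best_contig.size();
    for (int i = 0; i < nb; i++) {
      out_read.push_back((int)r + 1);
      out_contig.push_back(best_contig[i] + 1);
      out_start.push_back(best_start[i]);
      out_strand.push_back(best_strand[i]);
      out_mm.push_back(best_mm);
      out_nbest.push_back(nb);
    }
  }
  return List::create(
    _["read"] = wrap(out_read), _["contig"] = wrap(out_contig),
    _["start"] = wrap(out_start), _["strand"] = wrap(out_strand),
    _["mismatches"] = wrap(out_mm), _["n_best"] = wrap(out_nbest));
}
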
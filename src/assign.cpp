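// Builtin paired-end read assigner for dense oligo libraries.
//
// Oligos in a dense-tiling pool differ from neighbors by only a few
// nucleotides at each end, but reads are end-anchored (forward read =
// oligo 5' end, reverse read = oligo 3' end), so the pair identifies its
// source uniquely. Assignment is seed-and-score: exact k-mer seeds at
// fixed template offsets nominate candidate oligos, which are then scored
// by a banded, start-anchored edit distance on both mates. The "effort"
// setting controls how many seed slots are probed and whether an
// exhaustive rescan is performed when seeding fails, mirroring the
// seed-extension effort knob of end-to-end short-read aligners.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static const int INF = 1 << 28;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static bool pack_kmer(const std::string& s, size_t pos, int k, uint64_t& out) {
  if (pos + k > s.size()) return false;
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2bits(s[pos + i]);
    if (b < 0) return false;
    v = (v << 2) | (uint64_t)b;
  }
  out = v;
  return true;
}

// Banded edit distance: read fully consumed (start-anchored), template end
// free (min over last DP row). Band limits |j - i|; result capped at cap.
static int banded_dist(const std::string& r, const std::string& t,
                       int band, int cap) {
  const int n = (int)r.size();
  const int m = std::min((int)t.size(), n + band);
  const int W = 2 * band + 1;
  std::vector<int> prev(W), cur(W);
  for (int d = 0; d < W; ++d) {
    int j = d - band;
    prev[d] = (j >= 0 && j <= m) ? j : INF;
  }
  for (int i = 1; i <= n; ++i) {
    int rowmin = INF;
    for (int d = 0; d < W; ++d) {
      int j = i + d - band;
      if (j < 0 || j > m) { cur[d] = INF; continue; }
      int best = INF;
      if (j == 0) {
        best = i;                               // read prefix vs empty template
      } else {
        int v = prev[d];                        // diagonal (i-1, j-1)
        if (v < INF) best = v + (r[i - 1] == t[j - 1] ? 0 : 1);
        if (d > 0 && cur[d - 1] < INF)          // gap in read: consume template
          best = std::min(best, cur[d - 1] + 1);
      }
      if (d + 1 < W && prev[d + 1] < INF)       // gap in template: consume read
        best = std::min(best, prev[d + 1] + 1);
      cur[d] = best;
      if (best < rowmin) rowmin = best;
    }
    if (rowmin > cap) return cap + 1;           // early abandon
    std::swap(prev, cur);
  }
  int res = INF;
  for (int d = 0; d < W; ++d) {
    int j = n + d - band;
    if (j >= 0 && j <= m) res = std::min(res, prev[d]);
  }
  return std::min(res, cap + 1);
}

typedef std::unordered_map<uint64_t, std::vector<int> > SeedIndex;

static void index_templates(const std::vector<std::string>& tpl,
                            const std::vector<int>& seed_pos, int k,
                            SeedIndex& idx) {
  for (int o = 0; o < (int)tpl.size(); ++o) {
    for (size_t s = 0; s < seed_pos.size(); ++s) {
      uint64_t key;
      if (pack_kmer(tpl[o], seed_pos[s], k, key)) {
        idx[((uint64_t)s << 40) | key].push_back(o);
      }
    }
  }
}

// [[Rcpp::export]]
List assign_reads_cpp(CharacterVector fwd_reads, CharacterVector rev_reads,
                      CharacterVector fwd_tpl, CharacterVector rev_tpl,
                      int seed_k, int n_seed_fwd, int n_seed_rev,
                      bool exhaustive_fallback, int band, int max_dist) {
  const int n_read = fwd_reads.size();
  const int n_oligo = fwd_tpl.size();
  std::vector<std::string> ft(n_oligo), rt(n_oligo);
  for (int i = 0; i < n_oligo; ++i) {
    ft[i] = as<std::string>(fwd_tpl[i]);
    rt[i] = as<std::string>(rev_tpl[i]);
  }
  // seed slots at fixed template offsets 0, k, 2k, ...
  std::vector<int> fpos, rpos;
  for (int i = 0; i < n_seed_fwd; ++i) fpos.push_back(i * seed_k);
  for (int i = 0; i < n_seed_rev; ++i) rpos.push_back(i * seed_k);
  SeedIndex fidx, ridx;
  index_templates(ft, fpos, seed_k, fidx);
  index_templates(rt, rpos, seed_k, ridx);

  IntegerVector assignment(n_read, NA_INTEGER);
  IntegerVector best_dist(n_read, NA_INTEGER);
  IntegerVector margin(n_read, NA_INTEGER);

  std::vector<int> seen(n_oligo, -1);
  std::vector<int> cand;
  cand.reserve(64);

  for (int r = 0; r < n_read; ++r) {
    std::string fr = as<std::string>(fwd_reads[r]);
    std::string rr = as<std::string>(rev_reads[r]);
    cand.clear();
    uint64_t key;
    for (size_t s = 0; s < fpos.size(); ++s) {
      if (!pack_kmer(fr, fpos[s], seed_k, key)) continue;
      SeedIndex::const_iterator it = fidx.find(((uint64_t)s << 40) | key);
      if (it == fidx.end()) continue;
      for (size_t j = 0; j < it->second.size(); ++j) {
        int o = it->second[j];
        if (seen[o] != r) { seen[o] = r; cand.push_back(o); }
      }
    }
    for (size_t s = 0; s < rpos.size(); ++s) {
      if (!pack_kmer(rr, rpos[s], seed_k, key)) continue;
      SeedIndex::const_iterator it = ridx.find(((uint64_t)s << 40) | key);
      if (it == ridx.end()) continue;
      for (size_t j = 0; j < it->second.size(); ++j) {
        int o = it->second[j];
        if (seen[o] != r) { seen[o] = r; cand.push_back(o); }
      }
    }
    int best = INF, second = INF, best_o = -1;
    for (size_t c = 0; c < cand.size(); ++c) {
      int o = cand[c];
      int d = banded_dist(fr, ft[o], band, max_dist);
      if (d > max_dist) d = INF;
      else {
        int d2 = banded_dist(rr, rt[o], band, max_dist);
        d = (d2 > max_dist) ? INF : d + d2;
      }
      if (d < best) { second = best; best = d; best_o = o; }
      else if (d < second) second = d;
    }
    // high effort: rescan everything when seeding found nothing usable
    if (exhaustive_fallback && (best_o < 0 || best > max_dist)) {
      best = INF; second = INF; best_o = -1;
      for (int o = 0; o < n_oligo; ++o) {
        int d = banded_dist(fr, ft[o], band, max_dist);
        if (d <= max_dist) d += banded_dist(rr, rt[o], band, max_dist);
        if (d < best) { second = best; best = d; best_o = o; }
        else if (d < second) second = d;
      }
    }
    if (best_o >= 0 && best < INF && best < second) {
      assignment[r] = best_o + 1;             // ties -> unassigned
      best_dist[r] = best;
      margin[r] = (second >= INF) ? NA_INTEGER : (second - best);
    }
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["assignment"] = assignment,
                      _["best_dist"] = best_dist,
                      _["margin"] = margin);
}
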
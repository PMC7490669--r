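// Seed-and-extend read aligner used for competitive placement of short
// reads on the wild-type / mutant scaffold pair.
//
// - exact k-mer seeds on every read offset, voted per diagonal;
// - diagonal clusters (gap <= band) extended by banded affine-gap local
//   DP (Gotoh) with free terminal soft clips;
// - deterministic tie-breaks: higher score, then lower reference start,
//   then smaller left clip, forward strand preferred;
// - placements aligning fewer than min_anchor read bases are unmapped.
//
// The band is wide enough (set by the R wrapper to cover the expected
// indel length) that a single pass spans both copies of the duplicated
// segment and the full-length gap path between them.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

namespace {

const int NEG_INF = -100000000;

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return 4;
  }
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

std::string revcomp_str(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (char& c : out) c = comp_base(c);
  return out;
}

struct SeedIndex {
  int k;
  std::unordered_map<uint32_t, std::vector<int>> pos;  // kmer -> 0-based starts

  void build(const std::string& ref, int k_) {
    k = k_;
    pos.clear();
    const int m = (int)ref.size();
    if (m < k) return;
    uint32_t key = 0, mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
    int run = 0;  // valid bases accumulated
    for (int j = 0; j < m; ++j) {
      int c = base_code(ref[j]);
      if (c > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t)c) & mask;
      if (++run >= k) pos[key].push_back(j - k + 1);
    }
  }
};

struct SitePick {
  char base;
  int dist;  // min aligned read bases between the site base and either
             // end of the aligned segment
  int qpos;  // 0-based offset of the base in the aligned-orientation read
};

struct Placement {
  bool mapped = false;
  int score = NEG_INF;
  int ref_start = 0;   // 1-based
  int ref_end = 0;     // 1-based inclusive
  int left_clip = 0, right_clip = 0;
  int n_aligned = 0;   // read bases aligned to reference (M columns)
  int strand = 1;      // +1 forward, -1 reverse-complement
  std::string cigar;
  std::vector<SitePick> sites;
};

bool better_than(const Placement& a, const Placement& b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.ref_start != b.ref_start) return a.ref_start < b.ref_start;
  if (a.left_clip != b.left_clip) return a.left_clip < b.left_clip;
  return false;
}

void append_op(std::string& cig, int len, char op) {
  if (len > 0) { cig += std::to_string(len); cig += op; }
}

// exact full-length match at diagonal d (read i <-> ref i+d)
bool exact_at(const std::string& read, const std::string& ref, int d) {
  const int n = (int)read.size(), m = (int)ref.size();
  if (d < 0 || d + n > m) return false;
  return ref.compare(d, n, read) == 0;
}

Placement perfect_placement(const std::string& read, int d, int match,
                            const IntegerVector& sites) {
  const int n = (int)read.size();
  Placement p;
  p.mapped = true;
  p.score = n * match;
  p.ref_start = d + 1;
  p.ref_end = d + n;
  p.n_aligned = n;
  p.cigar = std::to_string(n) + "M";
  p.sites.assign(sites.size(), {'\0', -1, -1});
  for (int s = 0; s < sites.size(); ++s) {
    int j0 = sites[s] - 1;          // 0-based ref position
    int i = j0 - d;                 // read offset
    if (i >= 0 && i < n) p.sites[s] = {read[i], std::min(i, n - 1 - i), i};
  }
  return p;
}

// Banded local affine-gap alignment around diagonal `d`, half-width W.
Placement banded_extend(const std::string& read, const std::string& ref,
                        int d, int W, int match, int mismatch, int gap_open,
                        int gap_ext, const IntegerVector& sites) {
  const int n = (int)read.size(), m = (int)ref.size();
  const int width = 2 * W + 1;
  std::vector<int> H((size_t)n * width, NEG_INF), E((size_t)n * width, NEG_INF),
      F((size_t)n * width, NEG_INF);
  // traceback: bits 0-2 H-source (0 fresh M, 1 cont M, 2 E, 3 F, 4 zero),
  // bit 3: E extends E, bit 4: F extends F
  std::vector<uint8_t> TB((size_t)n * width, 4);

  int best = 0, best_i = -1, best_b = -1;
  for (int i = 0; i < n; ++i) {
    const int jlo = i + d - W;
    const uint8_t xc = (uint8_t)read[i];
    const size_t row = (size_t)i * width, prow = row - width;
    for (int b = 0; b < width; ++b) {
      const int j = jlo + b;
      if (j < 0 || j >= m) continue;
      int e = NEG_INF, f = NEG_INF;
      uint8_t tb = 0;
      if (b > 0 && H[row + b - 1] > NEG_INF / 2) {
        const int open_e = H[row + b - 1] + gap_open;
        const int ext_e = (E[row + b - 1] > NEG_INF / 2)
                              ? E[row + b - 1] + gap_ext : NEG_INF;
        if (ext_e > open_e) { e = ext_e; tb |= 8; } else e = open_e;
      }
      if (i > 0 && b < width - 1) {
        const int hup = H[prow + b + 1];
        const int open_f = (hup > NEG_INF / 2) ? hup + gap_open : NEG_INF;
        const int ext_f = (F[prow + b + 1] > NEG_INF / 2)
                              ? F[prow + b + 1] + gap_ext : NEG_INF;
        if (ext_f > open_f) { f = ext_f; tb |= 16; } else f = open_f;
      }
      const int sub = (xc == (uint8_t)ref[j]) ? match : mismatch;
      int hd = 0;
      uint8_t src = 0;  // fresh local start
      if (i > 0 && H[prow + b] > 0) { hd = H[prow + b]; src = 1; }
      int h = hd + sub;
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      if (h <= 0) { h = 0; src = 4; }
      E[row + b] = e;
      F[row + b] = f;
      H[row + b] = h;
      TB[row + b] = (uint8_t)(src | (tb & 24));
      if (h > best) { best = h; best_i = i; best_b = b; }
    }
  }

  Placement p;
  p.sites.assign(sites.size(), {'\0', -1, -1});
  if (best_i < 0 || best <= 0) return p;

  // traceback
  int i = best_i, b = best_b;
  std::vector<std::pair<char, int>> ops;  // reversed (op, len)
  std::vector<std::pair<int, int>> mcols;  // (read i, ref j) of M columns
  int state = 0;  // 0 = H, 1 = E, 2 = F
  int i_first = best_i, j_first = best_i + d - W + best_b;
  const int j_last = j_first;
  auto push = [&ops](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.emplace_back(op, 1);
  };
  for (;;) {
    const size_t idx = (size_t)i * width + b;
    if (state == 0) {
      const uint8_t src = TB[idx] & 7;
      if (src == 4) break;  // zero cell: alignment starts after this
      if (src == 0 || src == 1) {
        push('M');
        mcols.emplace_back(i, i + d - W + b);
        i_first = i;
        j_first = i + d - W + b;
        if (src == 0 || i == 0) break;
        --i;  // diagonal: b unchanged
      } else if (src == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {  // E: deletion, consume ref
      push('D');
      const bool from_e = (TB[idx] & 8) != 0;
      --b;
      if (!from_e) state = 0;
    } else {  // F: insertion, consume read
      push('I');
      const bool from_f = (TB[idx] & 16) != 0;
      if (i == 0) break;
      --i; ++b;
      if (!from_f) state = 0;
    }
  }

  p.mapped = true;
  p.score = best;
  p.ref_start = j_first + 1;
  p.ref_end = j_last + 1;
  p.left_clip = i_first;
  p.right_clip = n - 1 - best_i;
  std::string cig;
  append_op(cig, p.left_clip, 'S');
  for (auto it = ops.rbegin(); it != ops.rend(); ++it)
    append_op(cig, it->second, it->first);
  append_op(cig, p.right_clip, 'S');
  p.cigar = cig;
  int naligned = 0;
  for (auto& o : ops) if (o.first == 'M') naligned += o.second;
  p.n_aligned = naligned;
  for (int s = 0; s < sites.size(); ++s) {
    const int j0 = sites[s] - 1;
    for (auto& mc : mcols) {
      if (mc.second == j0) {
        p.sites[s] = {read[mc.first],
                      std::min(mc.first - i_first, best_i - mc.first),
                      mc.first};
        break;
      }
    }
  }
  return p;
}

struct Cluster { int diag; int votes; };

std::vector<Cluster> seed_clusters(const std::string& read,
                                   const SeedIndex& idx, int band) {
  const int n = (int)read.size(), k = idx.k;
  std::unordered_map<int, int> votes;
  if (n >= k) {
    uint32_t key = 0, mask = (k >= 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = base_code(read[i]);
      if (c > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t)c) & mask;
      if (++run < k) continue;
      auto it = idx.pos.find(key);
      if (it == idx.pos.end()) continue;
      const int qpos = i - k + 1;
      for (int p : it->second) votes[p - qpos]++;
    }
  }
  std::vector<std::pair<int, int>> dv(votes.begin(), votes.end());
  std::sort(dv.begin(), dv.end());
  std::vector<Cluster> out;
  size_t i = 0;
  while (i < dv.size()) {
    int best_d = dv[i].first, best_v = dv[i].second, tot = dv[i].second;
    size_t j = i + 1;
    while (j < dv.size() && dv[j].first - dv[j - 1].first <= band) {
      tot += dv[j].second;
      if (dv[j].second > best_v) { best_v = dv[j].second; best_d = dv[j].first; }
      ++j;
    }
    out.push_back({best_d, tot});
    i = j;
  }
  std::sort(out.begin(), out.end(), [](const Cluster& a, const Cluster& b) {
    if (a.votes != b.votes) return a.votes > b.votes;
    return a.diag < b.diag;
  });
  return out;
}

Placement align_one_strand(const std::string& read, const std::string& ref,
                           const SeedIndex& idx, int band, int match,
                           int mismatch, int gap_open, int gap_ext,
                           const IntegerVector& sites, int max_clusters) {
  const int n = (int)read.size();
  Placement best;
  std::vector<Cluster> cl = seed_clusters(read, idx, band);
  const int ncl = std::min((int)cl.size(), max_clusters);
  for (int c = 0; c < ncl; ++c) {
    Placement p;
    if (cl[c].votes == n - idx.k + 1 && exact_at(read, ref, cl[c].diag)) {
      p = perfect_placement(read, cl[c].diag, match, sites);
    } else {
      p = banded_extend(read, ref, cl[c].diag, band, match, mismatch,
                        gap_open, gap_ext, sites);
    }
    if (p.mapped && (!best.mapped || better_than(p, best))) best = p;
    if (best.mapped && best.score == n * match) break;
  }
  return best;
}

}  // namespace

// [[Rcpp::export]]
List cpp_align_batch(CharacterVector reads, std::string ref, int k,
                     int match, int mismatch, int gap_open, int gap_ext,
                     int band, int min_anchor, IntegerVector sites,
                     bool try_revcomp, int max_clusters) {
  if (k < 8) stop("seed length k must be at least 8");
  if ((int)ref.size() < k) stop("reference shorter than the seed length");
  SeedIndex idx;
  idx.build(ref, k);

  const int nr = reads.size(), ns = sites.size();
  LogicalVector mapped(nr);
  IntegerVector score(nr, NA_INTEGER), start(nr, NA_INTEGER),
      end(nr, NA_INTEGER), lclip(nr, NA_INTEGER), rclip(nr, NA_INTEGER),
      naln(nr, NA_INTEGER), strand(nr, NA_INTEGER);
  CharacterVector cigar(nr, NA_STRING);
  CharacterMatrix site_base(nr, ns);
  IntegerMatrix site_dist(nr, ns), site_qpos(nr, ns);
  std::fill(site_base.begin(), site_base.end(), NA_STRING);
  std::fill(site_dist.begin(), site_dist.end(), NA_INTEGER);
  std::fill(site_qpos.begin(), site_qpos.end(), NA_INTEGER);

  for (int r = 0; r < nr; ++r) {
    const std::string rd = as<std::string>(reads[r]);
    const int n = (int)rd.size();
    Placement best = align_one_strand(rd, ref, idx, band, match, mismatch,
                                      gap_open, gap_ext, sites, max_clusters);
    if (try_revcomp && !(best.mapped && best.score == n * match)) {
      const std::string rc = revcomp_str(rd);
      Placement prc = align_one_strand(rc, ref, idx, band, match, mismatch,
                                       gap_open, gap_ext, sites, max_clusters);
      prc.strand = -1;
      if (prc.mapped && (!best.mapped || prc.score > best.score)) best = prc;
    }
    if (!best.mapped || best.n_aligned < min_anchor) continue;
    mapped[r] = true;
    score[r] = best.score;
    start[r] = best.ref_start;
    end[r] = best.ref_end;
    lclip[r] = best.left_clip;
    rclip[r] = best.right_clip;
    naln[r] = best.n_aligned;
    strand[r] = best.strand;
    cigar[r] = best.cigar;
    for (int s = 0; s < ns; ++s) {
      if (best.sites[s].base != '\0') {
        site_base(r, s) = std::string(1, best.sites[s].base);
        site_dist(r, s) = best.sites[s].dist;
        site_qpos(r, s) = best.sites[s].qpos;
      }
    }
  }
  return List::create(
      _["mapped"] = mapped, _["score"] = score, _["start"] = start,
      _["end"] = end, _["left_clip"] = lclip, _["right_clip"] = rclip,
      _["n_aligned"] = naln, _["strand"] = strand, _["cigar"] = cigar,
      _["site_base"] = site_base, _["site_dist"] = site_dist,
      _["site_qpos"] = site_qpos);
}

// Exhaustive full-matrix local affine-gap alignment score (no banding,
// no seeding).  Kept as a slow independent reference path; the heuristic
// aligner is checked against it and against external implementations.
// [[Rcpp::export]]
int cpp_align_full_score(std::string read, std::string ref, int match,
                         int mismatch, int gap_open, int gap_ext) {
  const int n = (int)read.size(), m = (int)ref.size();
  std::vector<int> Hprev(m + 1, 0), H(m + 1, 0), Eprev(m + 1, NEG_INF),
      E(m + 1, NEG_INF), F(m + 1, NEG_INF);
  int best = 0;
  std::vector<int> Fcur(m + 1, NEG_INF);
  for (int i = 1; i <= n; ++i) {
    H[0] = 0;
    int e = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      e = std::max(H[j - 1] + gap_open, e + gap_ext);
      Fcur[j] = std::max(Hprev[j] + gap_open, Fcur[j] + gap_ext);
      const int sub = (read[i - 1] == ref[j - 1]) ? match : mismatch;
      int h = std::max(0, Hprev[j - 1] + sub);
      h = std::max(h, std::max(e, Fcur[j]));
      H[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, H);
  }
  return best;
}
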
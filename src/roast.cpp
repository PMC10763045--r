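// Core sequence kernels: k-mer seeded ungapped read alignment with
// soft-clipping, word-seeded overlap search, anchored column consensus,
// greedy overlap-layout assembly, and IUPAC-aware string utilities.
//
// All alignment here is ungapped (single diagonal).  Soft-clips absorb any
// read tail that cannot be extended; gapped hits are never produced, which
// matches the default behaviour of the pipeline (gapped overlap hits are
// ignored).

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>
#include <unordered_map>
#include <array>

using namespace Rcpp;

// ---- IUPAC machinery -------------------------------------------------------

// bitmask per base: A=1 C=2 G=4 T=8
static unsigned char IUPAC_MASK[256];
static char MASK_CHAR[16];
static bool tables_ready = false;

static void init_tables() {
  if (tables_ready) return;
  for (int i = 0; i < 256; ++i) IUPAC_MASK[i] = 0;
  auto set = [](char c, unsigned char m) {
    IUPAC_MASK[(unsigned char)c] = m;
    IUPAC_MASK[(unsigned char)tolower(c)] = m;
  };
  set('A', 1); set('C', 2); set('G', 4); set('T', 8); set('U', 8);
  set('M', 3); set('R', 5); set('W', 9); set('S', 6); set('Y', 10); set('K', 12);
  set('V', 7); set('H', 11); set('D', 13); set('B', 14); set('N', 15);
  const char *mc = "?ACMGRSVTWYHKDBN";
  for (int i = 1; i < 16; ++i) MASK_CHAR[i] = mc[i];
  MASK_CHAR[0] = 'N';
  tables_ready = true;
}

static inline bool compat(char a, char b) {
  return (IUPAC_MASK[(unsigned char)a] & IUPAC_MASK[(unsigned char)b]) != 0;
}

static inline char comp_base(char c) {
  unsigned char m = IUPAC_MASK[(unsigned char)c];
  unsigned char r = ((m & 1) ? 8 : 0) | ((m & 2) ? 4 : 0) |
                    ((m & 4) ? 2 : 0) | ((m & 8) ? 1 : 0);
  return r ? MASK_CHAR[r] : 'N';
}

static std::string revcomp_str(const std::string &s) {
  init_tables();
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp_str(s); }

// [[Rcpp::export]]
int cpp_match_count(std::string a, std::string b, int a_from, int b_from, int len) {
  // number of IUPAC-compatible positions comparing a[a_from+i] vs b[b_from+i]
  init_tables();
  int n = 0;
  for (int i = 0; i < len; ++i) {
    int ai = a_from + i, bi = b_from + i;
    if (ai < 0 || bi < 0 || ai >= (int)a.size() || bi >= (int)b.size()) break;
    if (compat(a[ai], b[bi])) ++n;
  }
  return n;
}

// [[Rcpp::export]]
bool cpp_iupac_eq(std::string a, std::string b) {
  init_tables();
  if (a.size() != b.size()) return false;
  for (size_t i = 0; i < a.size(); ++i) if (!compat(a[i], b[i])) return false;
  return true;
}

// [[Rcpp::export]]
int cpp_find_exact(std::string hay, std::string needle) {
  size_t p = hay.find(needle);
  return p == std::string::npos ? -1 : (int)p;
}

// ---- k-mer index -----------------------------------------------------------

struct SeedHit { int32_t contig; int32_t pos; };

struct KmerIndex {
  int k;
  // sorted (key -> hits) flattened
  std::vector<uint64_t> keys;
  std::vector<uint32_t> starts;       // offset into hits for each distinct key
  std::vector<SeedHit> hits;
  std::vector<const char*> seqs;
  std::vector<int> lens;
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

static void build_index(KmerIndex &idx, const std::vector<std::string> &contigs, int k) {
  idx.k = k;
  std::vector<std::pair<uint64_t, SeedHit>> tmp;
  size_t total = 0;
  for (auto &s : contigs) total += s.size();
  tmp.reserve(total);
  for (size_t ci = 0; ci < contigs.size(); ++ci) {
    const std::string &s = contigs[ci];
    if ((int)s.size() < k) continue;
    uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int valid = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++valid >= k)
        tmp.push_back({key, {(int32_t)ci, (int32_t)(i - k + 1)}});
    }
  }
  std::sort(tmp.begin(), tmp.end(),
            [](const std::pair<uint64_t, SeedHit> &a, const std::pair<uint64_t, SeedHit> &b) {
              if (a.first != b.first) return a.first < b.first;
              if (a.second.contig != b.second.contig) return a.second.contig < b.second.contig;
              return a.second.pos < b.second.pos;
            });
  idx.keys.clear(); idx.starts.clear(); idx.hits.clear();
  idx.hits.reserve(tmp.size());
  for (size_t i = 0; i < tmp.size(); ++i) {
    if (i == 0 || tmp[i].first != tmp[i - 1].first) {
      idx.keys.push_back(tmp[i].first);
      idx.starts.push_back((uint32_t)idx.hits.size());
    }
    idx.hits.push_back(tmp[i].second);
  }
  idx.starts.push_back((uint32_t)idx.hits.size());
}

static inline std::pair<uint32_t, uint32_t> index_lookup(const KmerIndex &idx, uint64_t key) {
  auto it = std::lower_bound(idx.keys.begin(), idx.keys.end(), key);
  if (it == idx.keys.end() || *it != key) return {0, 0};
  size_t j = it - idx.keys.begin();
  return {idx.starts[j], idx.starts[j + 1]};
}

// ---- diagonal extension ----------------------------------------------------

struct Placement {
  int contig;       // index
  int rs, re;       // reference span [rs, re] inclusive
  int qs, qe;       // query span on the oriented read, inclusive
  int score;
  int matches;
  int strand;       // +1 / -1 (orientation of the read)
};

// Ungapped X-drop extension of read `q` against contig `r` anchored so that
// q[qpos] pairs with r[rpos]; seed of length k is exact.
static Placement extend_diag(const char *q, int qlen, const char *r, int rlen,
                             int qpos, int rpos, int k, int xdrop,
                             int match_sc, int mismatch_sc) {
  Placement p;
  p.qs = qpos; p.qe = qpos + k - 1;
  p.rs = rpos; p.re = rpos + k - 1;
  p.score = k * match_sc;
  p.matches = k;
  // right extension
  {
    int cur = 0, best = 0, bq = p.qe, br = p.re, m = 0, bm = 0;
    int qi = p.qe + 1, ri = p.re + 1;
    while (qi < qlen && ri < rlen) {
      if (compat(q[qi], r[ri])) { cur += match_sc; ++m; }
      else cur += mismatch_sc;
      if (cur > best) { best = cur; bq = qi; br = ri; bm = m; }
      if (cur < best - xdrop) break;
      ++qi; ++ri;
    }
    p.qe = bq; p.re = br; p.score += best; p.matches += bm;
  }
  // left extension
  {
    int cur = 0, best = 0, bq = p.qs, br = p.rs, m = 0, bm = 0;
    int qi = p.qs - 1, ri = p.rs - 1;
    while (qi >= 0 && ri >= 0) {
      if (compat(q[qi], r[ri])) { cur += match_sc; ++m; }
      else cur += mismatch_sc;
      if (cur > best) { best = cur; bq = qi; br = ri; bm = m; }
      if (cur < best - xdrop) break;
      --qi; --ri;
    }
    p.qs = bq; p.rs = br; p.score += best; p.matches += bm;
  }
  return p;
}

// collect candidate placements of an oriented sequence against the index
static void candidate_placements(const KmerIndex &idx, const std::string &oseq,
                                 int strand, int stride, int max_occ,
                                 int max_cand, int xdrop,
                                 std::vector<Placement> &out) {
  int k = idx.k;
  int qlen = (int)oseq.size();
  if (qlen < k) return;
  // seed positions: stride, plus the final k-mer
  std::vector<int> qpos_list;
  for (int i = 0; i + k <= qlen; i += stride) qpos_list.push_back(i);
  if (qpos_list.empty() || qpos_list.back() != qlen - k) qpos_list.push_back(qlen - k);

  // gather (contig, diag) -> seed count and anchor
  struct Cand { int contig; int diag; int qpos; int rpos; int count; };
  std::unordered_map<uint64_t, Cand> cands;
  cands.reserve(64);
  for (int qpos : qpos_list) {
    uint64_t key = 0; bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = base2bits(oseq[qpos + j]);
      if (b < 0) { ok = false; break; }
      key = (key << 2) | (uint64_t)b;
    }
    if (!ok) continue;
    auto range = index_lookup(idx, key);
    if (range.second - range.first == 0) continue;
    if ((int)(range.second - range.first) > max_occ) continue;  // repeat word
    for (uint32_t h = range.first; h < range.second; ++h) {
      const SeedHit &sh = idx.hits[h];
      int diag = sh.pos - qpos;
      uint64_t ckey = ((uint64_t)(uint32_t)sh.contig << 32) ^ (uint32_t)(diag + (1 << 30));
      auto it = cands.find(ckey);
      if (it == cands.end())
        cands[ckey] = {sh.contig, diag, qpos, sh.pos, 1};
      else
        it->second.count++;
    }
  }
  if (cands.empty()) return;
  std::vector<Cand> cv;
  cv.reserve(cands.size());
  for (auto &kv : cands) cv.push_back(kv.second);
  std::sort(cv.begin(), cv.end(), [](const Cand &a, const Cand &b) {
    if (a.count != b.count) return a.count > b.count;
    if (a.contig != b.contig) return a.contig < b.contig;
    return a.diag < b.diag;
  });
  int ncand = std::min((int)cv.size(), max_cand);
  for (int i = 0; i < ncand; ++i) {
    const Cand &c = cv[i];
    Placement p = extend_diag(oseq.c_str(), qlen, idx.seqs[c.contig], idx.lens[c.contig],
                              c.qpos, c.rpos, k, xdrop, 1, -2);
    p.contig = c.contig;
    p.strand = strand;
    out.push_back(p);
  }
}

static bool placement_lt(const Placement &a, const Placement &b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.contig != b.contig) return a.contig < b.contig;
  if (a.rs != b.rs) return a.rs < b.rs;
  return a.strand > b.strand;
}

// ---- read alignment --------------------------------------------------------

// [[Rcpp::export]]
List cpp_align_reads(CharacterVector contigs, CharacterVector reads,
                     int k = 15, int stride = 6, int xdrop = 12,
                     int min_score = 20, int max_occ = 200, int max_cand = 12,
                     int mapq_cap = 60, double mapq_scale = 40.0) {
  init_tables();
  int nc = contigs.size(), nr = reads.size();
  std::vector<std::string> cs(nc);
  for (int i = 0; i < nc; ++i) cs[i] = as<std::string>(contigs[i]);
  KmerIndex idx;
  build_index(idx, cs, k);
  idx.seqs.resize(nc); idx.lens.resize(nc);
  for (int i = 0; i < nc; ++i) { idx.seqs[i] = cs[i].c_str(); idx.lens[i] = (int)cs[i].size(); }

  IntegerVector contig_out(nr, NA_INTEGER), start(nr, NA_INTEGER), mlen(nr, NA_INTEGER),
      lclip(nr, NA_INTEGER), rclip(nr, NA_INTEGER), strand(nr, NA_INTEGER),
      mapq(nr, NA_INTEGER), score(nr, NA_INTEGER), nmatch(nr, NA_INTEGER);

  std::vector<Placement> pls;
  for (int i = 0; i < nr; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rev = revcomp_str(fwd);
    pls.clear();
    candidate_placements(idx, fwd, +1, stride, max_occ, max_cand, xdrop, pls);
    candidate_placements(idx, rev, -1, stride, max_occ, max_cand, xdrop, pls);
    if (pls.empty()) continue;
    std::sort(pls.begin(), pls.end(), placement_lt);
    // dedupe near-identical placements (same contig, close start, same strand)
    std::vector<Placement> uniq;
    for (auto &p : pls) {
      bool dup = false;
      for (auto &u : uniq)
        if (u.contig == p.contig && u.strand == p.strand && std::abs(u.rs - p.rs) <= 5) { dup = true; break; }
      if (!dup) uniq.push_back(p);
    }
    const Placement &best = uniq[0];
    if (best.score < min_score) continue;
    int second = (uniq.size() > 1) ? uniq[1].score : 0;
    int q;
    if (second <= 0) q = mapq_cap;
    else {
      q = (int)std::lround(mapq_scale * (1.0 - (double)second / (double)best.score));
      if (q < 0) q = 0;
      if (q > mapq_cap) q = mapq_cap;
    }
    int qlen = (int)fwd.size();
    contig_out[i] = best.contig + 1;
    start[i] = best.rs;
    mlen[i] = best.re - best.rs + 1;
    lclip[i] = best.qs;
    rclip[i] = qlen - 1 - best.qe;
    strand[i] = best.strand;
    mapq[i] = q;
    score[i] = best.score;
    nmatch[i] = best.matches;
  }
  return List::create(_["contig"] = contig_out, _["start"] = start, _["mlen"] = mlen,
                      _["lclip"] = lclip, _["rclip"] = rclip, _["strand"] = strand,
                      _["mapq"] = mapq, _["score"] = score, _["matches"] = nmatch);
}

// ---- overlap search (blast-like, ungapped) ---------------------------------

// [[Rcpp::export]]
DataFrame cpp_overlap_hits(CharacterVector queries, CharacterVector subjects,
                           int word = 11, int xdrop = 20, int max_occ = 400,
                           int max_cand = 32, int max_hits = 20,
                           bool both_strands = true) {
  init_tables();
  int ns = subjects.size(), nq = queries.size();
  std::vector<std::string> ss(ns);
  for (int i = 0; i < ns; ++i) ss[i] = as<std::string>(subjects[i]);
  KmerIndex idx;
  build_index(idx, ss, word);
  idx.seqs.resize(ns); idx.lens.resize(ns);
  for (int i = 0; i < ns; ++i) { idx.seqs[i] = ss[i].c_str(); idx.lens[i] = (int)ss[i].size(); }

  std::vector<int> o_query, o_subj, o_qs, o_qe, o_ss, o_se, o_strand, o_matches, o_len;
  for (int qi = 0; qi < nq; ++qi) {
    std::string q = as<std::string>(queries[qi]);
    int qlen = (int)q.size();
    int stride = qlen > 400 ? 4 : 1;
    std::vector<Placement> pls;
    candidate_placements(idx, q, +1, stride, max_occ, max_cand, xdrop, pls);
    if (both_strands) {
      std::string qr = revcomp_str(q);
      candidate_placements(idx, qr, -1, stride, max_occ, max_cand, xdrop, pls);
    }
    std::sort(pls.begin(), pls.end(), placement_lt);
    std::vector<Placement> uniq;
    for (auto &p : pls) {
      bool dup = false;
      for (auto &u : uniq)
        if (u.contig == p.contig && u.strand == p.strand &&
            !(p.re < u.rs || p.rs > u.re)) { dup = true; break; }
      if (!dup) uniq.push_back(p);
      if ((int)uniq.size() >= max_hits) break;
    }
    for (auto &p : uniq) {
      int pqs = p.qs, pqe = p.qe;
      if (p.strand < 0) { pqs = qlen - 1 - p.qe; pqe = qlen - 1 - p.qs; }
      o_query.push_back(qi + 1);
      o_subj.push_back(p.contig + 1);
      o_qs.push_back(pqs); o_qe.push_back(pqe);
      o_ss.push_back(p.rs); o_se.push_back(p.re);
      o_strand.push_back(p.strand);
      o_matches.push_back(p.matches);
      o_len.push_back(p.re - p.rs + 1);
    }
  }
  return DataFrame::create(_["query"] = o_query, _["subject"] = o_subj,
                           _["qs"] = o_qs, _["qe"] = o_qe,
                           _["ss"] = o_ss, _["se"] = o_se,
                           _["strand"] = o_strand, _["matches"] = o_matches,
                           _["length"] = o_len);
}

// Extend a pairing of a[a_next + dir*i] vs b[b_next + dir*i] while the running
// identity from the anchor stays >= min_id percent; returns the maximal
// extension length and its match count.
// [[Rcpp::export]]
IntegerVector cpp_extend_identity(std::string a, std::string b,
                                  int a_next, int b_next, int dir,
                                  double min_id = 90.0) {
  init_tables();
  int m = 0, best = 0, best_m = 0;
  int i = 0;
  while (true) {
    int ai = a_next + dir * i, bi = b_next + dir * i;
    if (ai < 0 || bi < 0 || ai >= (int)a.size() || bi >= (int)b.size()) break;
    if (compat(a[ai], b[bi])) ++m;
    ++i;
    if (100.0 * m / i >= min_id) { best = i; best_m = m; }
  }
  return IntegerVector::create(best, best_m);
}

// ---- anchored column consensus --------------------------------------------

// fragments[i] occupies columns offsets[i] .. offsets[i] + len - 1 relative
// to a common origin (typically the clip point at column 0).
// [[Rcpp::export]]
List cpp_consensus(CharacterVector fragments, IntegerVector offsets) {
  init_tables();
  int n = fragments.size();
  if (n == 0) stop("no fragments");
  int lo = INT32_MAX, hi = INT32_MIN;
  std::vector<std::string> fr(n);
  for (int i = 0; i < n; ++i) {
    fr[i] = as<std::string>(fragments[i]);
    lo = std::min(lo, offsets[i]);
    hi = std::max(hi, offsets[i] + (int)fr[i].size());
  }
  int w = hi - lo;
  std::vector<std::array<int, 4>> counts(w, {0, 0, 0, 0});
  for (int i = 0; i < n; ++i) {
    int off = offsets[i] - lo;
    for (size_t j = 0; j < fr[i].size(); ++j) {
      int b = base2bits(fr[i][j]);
      if (b >= 0) counts[off + j][b]++;
    }
  }
  std::string cons(w, 'N');
  IntegerVector depth(w);
  for (int c = 0; c < w; ++c) {
    int mx = 0, tot = 0;
    for (int b = 0; b < 4; ++b) { mx = std::max(mx, counts[c][b]); tot += counts[c][b]; }
    depth[c] = tot;
    if (mx == 0) { cons[c] = 'N'; continue; }
    unsigned char mask = 0;
    for (int b = 0; b < 4; ++b) if (counts[c][b] == mx) mask |= (1 << b);
    cons[c] = MASK_CHAR[mask];
  }
  return List::create(_["seq"] = cons, _["depth"] = depth, _["origin"] = lo);
}

// ---- greedy overlap-layout assembly ----------------------------------------

struct Layout {
  std::vector<std::string> seqs;
  std::vector<int> offs;
  std::string cons;
  std::vector<int> depth;
};

static void layout_consensus(Layout &L) {
  int lo = INT32_MAX, hi = INT32_MIN;
  for (size_t i = 0; i < L.seqs.size(); ++i) {
    lo = std::min(lo, L.offs[i]);
    hi = std::max(hi, L.offs[i] + (int)L.seqs[i].size());
  }
  int w = hi - lo;
  std::vector<std::array<int, 4>> counts(w, {0, 0, 0, 0});
  for (size_t i = 0; i < L.seqs.size(); ++i) {
    int off = L.offs[i] - lo;
    for (size_t j = 0; j < L.seqs[i].size(); ++j) {
      int b = base2bits(L.seqs[i][j]);
      if (b >= 0) counts[off + j][b]++;
    }
  }
  for (size_t i = 0; i < L.seqs.size(); ++i) L.offs[i] -= lo;
  L.cons.assign(w, 'N');
  L.depth.assign(w, 0);
  for (int c = 0; c < w; ++c) {
    int mx = 0, tot = 0;
    for (int b = 0; b < 4; ++b) { mx = std::max(mx, counts[c][b]); tot += counts[c][b]; }
    L.depth[c] = tot;
    if (mx == 0) continue;
    unsigned char mask = 0;
    for (int b = 0; b < 4; ++b) if (counts[c][b] == mx) mask |= (1 << b);
    L.cons[c] = MASK_CHAR[mask];
  }
}

// longest suffix(a)-prefix(b) ungapped overlap with identity >= min_id.
// Candidate overlap lengths are anchored by shared 12-mers so the scan is
// linear in sequence length rather than quadratic in overlap length.
static int best_sp_overlap(const std::string &a, const std::string &b,
                           int min_ov, double min_id, int &matches_out) {
  const int k = 12;
  int la = (int)a.size(), lb = (int)b.size();
  matches_out = 0;
  if (la < min_ov || lb < min_ov) return 0;
  int kk = std::min(k, min_ov);
  uint64_t mask = (1ULL << (2 * kk)) - 1;
  std::unordered_map<uint64_t, std::vector<int>> bpos;
  {
    uint64_t key = 0; int valid = 0;
    for (int i = 0; i < lb; ++i) {
      int bb = base2bits(b[i]);
      if (bb < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)bb) & mask;
      if (++valid >= kk) {
        auto &v = bpos[key];
        if ((int)v.size() < 50) v.push_back(i - kk + 1);
      }
    }
  }
  std::vector<char> seen(la + 1, 0);  // candidate diag = offset of b within a
  std::vector<int> diags;
  {
    uint64_t key = 0; int valid = 0;
    for (int i = 0; i < la; ++i) {
      int bb = base2bits(a[i]);
      if (bb < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)bb) & mask;
      if (++valid >= kk) {
        auto it = bpos.find(key);
        if (it == bpos.end()) continue;
        int apos = i - kk + 1;
        for (int bp : it->second) {
          int diag = apos - bp;
          if (diag < 0 || diag > la - min_ov) continue;
          if (!seen[diag]) { seen[diag] = 1; diags.push_back(diag); }
        }
      }
    }
  }
  std::sort(diags.begin(), diags.end());  // smallest diag = longest overlap
  for (int diag : diags) {
    int L = std::min(la - diag, lb);
    if (L < min_ov) continue;
    int m = 0;
    for (int i = 0; i < L; ++i) if (compat(a[diag + i], b[i])) ++m;
    if (100.0 * m / L >= min_id) { matches_out = m; return L; }
  }
  return 0;
}

static void flip_layout(Layout &L) {
  int w = 0;
  for (size_t i = 0; i < L.seqs.size(); ++i)
    w = std::max(w, L.offs[i] + (int)L.seqs[i].size());
  for (size_t i = 0; i < L.seqs.size(); ++i) {
    int newoff = w - (L.offs[i] + (int)L.seqs[i].size());
    L.seqs[i] = revcomp_str(L.seqs[i]);
    L.offs[i] = newoff;
  }
  layout_consensus(L);
}

// [[Rcpp::export]]
List cpp_greedy_assemble(CharacterVector seqs, int min_ov = 16,
                         double min_id = 95.0, bool both_strands = false) {
  init_tables();
  int n = seqs.size();
  std::vector<Layout> cl(n);
  for (int i = 0; i < n; ++i) {
    cl[i].seqs.push_back(as<std::string>(seqs[i]));
    cl[i].offs.push_back(0);
    layout_consensus(cl[i]);
  }
  std::vector<bool> alive(n, true);
  while (true) {
    int bi = -1, bj = -1, bL = 0, bM = 0, bMode = 0;
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      for (int j = 0; j < n; ++j) {
        if (i == j || !alive[j]) continue;
        int m = 0;
        int L = best_sp_overlap(cl[i].cons, cl[j].cons, min_ov, min_id, m);
        if (L > bL || (L == bL && m > bM)) { bL = L; bM = m; bi = i; bj = j; bMode = 0; }
        if (both_strands && i < j) {
          std::string rc = revcomp_str(cl[j].cons);
          int m2 = 0;
          int L2 = best_sp_overlap(cl[i].cons, rc, min_ov, min_id, m2);
          if (L2 > bL || (L2 == bL && m2 > bM)) { bL = L2; bM = m2; bi = i; bj = j; bMode = 1; }
          int m3 = 0;
          int L3 = best_sp_overlap(rc, cl[i].cons, min_ov, min_id, m3);
          if (L3 > bL || (L3 == bL && m3 > bM)) { bL = L3; bM = m3; bi = i; bj = j; bMode = 2; }
        }
      }
    }
    if (bL < min_ov || bi < 0) break;
    Layout &A = cl[bi];
    Layout B = cl[bj];
    if (bMode == 1) flip_layout(B);          // suffix(A) ~ prefix(rc(B))
    if (bMode == 2) { flip_layout(B); std::swap(A, B); }  // suffix(rc(B)) ~ prefix(A)
    int shift = (int)A.cons.size() - bL;
    for (size_t t = 0; t < B.seqs.size(); ++t) {
      A.seqs.push_back(B.seqs[t]);
      A.offs.push_back(B.offs[t] + shift);
    }
    layout_consensus(A);
    cl[bi] = A;
    alive[bj] = false;
  }
  std::vector<int> order;
  for (int i = 0; i < n; ++i) if (alive[i]) order.push_back(i);
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (cl[a].cons.size() != cl[b].cons.size()) return cl[a].cons.size() > cl[b].cons.size();
    return a < b;
  });
  List out(order.size());
  for (size_t i = 0; i < order.size(); ++i) {
    Layout &L = cl[order[i]];
    out[i] = List::create(_["seq"] = L.cons, _["depth"] = wrap(L.depth),
                          _["n_seqs"] = (int)L.seqs.size());
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_sp_overlap(std::string a, std::string b, int min_ov = 10,
                             double min_id = 90.0) {
  init_tables();
  int m = 0;
  int L = best_sp_overlap(a, b, min_ov, min_id, m);
  return IntegerVector::create(L, m);
}

// ---- misc ------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_coverage(IntegerVector starts, IntegerVector mlens, int clen) {
  // starts are 0-based; depth[i] = number of intervals covering base i
  std::vector<int> d(clen + 1, 0);
  int n = starts.size();
  for (int i = 0; i < n; ++i) {
    int s = starts[i], e = s + mlens[i];
    if (s < 0) s = 0;
    if (e > clen) e = clen;
    if (s >= e) continue;
    d[s] += 1; d[e] -= 1;
  }
  IntegerVector out(clen);
  int cur = 0;
  for (int i = 0; i < clen; ++i) { cur += d[i]; out[i] = cur; }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_apply_substitutions(CharacterVector seqs, IntegerVector idx,
                                        IntegerVector pos, CharacterVector base) {
  // idx, pos are 1-based; randomness is drawn by the caller
  CharacterVector out = clone(seqs);
  int n = idx.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(out[idx[i] - 1]);
    s[pos[i] - 1] = as<std::string>(base[i])[0];
    out[idx[i] - 1] = s;
  }
  return out;
}
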
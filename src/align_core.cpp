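// Alignment primitives: pigeonhole-seeded k-mismatch end-to-end mapper
// (Hamming, both strands, -m style hit-count suppression handled in R),
// Phred quality trimming, and a seeded local aligner whose score/length
// ratio stands in for a BLAT score ratio.

#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// A=0 C=1 G=2 T=3, anything else (incl. N) = 4; code 4 never matches.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static inline int comp_code(int c) { return c < 4 ? 3 - c : 4; }

struct TargetPack {
  std::vector<uint8_t> code;     // concatenated target codes
  std::vector<size_t> start;     // start offset of each target in `code`
  std::vector<size_t> end;       // one past end
  size_t n_targets() const { return start.size(); }
  // target containing global position g (assumes g valid)
  int target_of(size_t g) const {
    int lo = 0, hi = (int)start.size() - 1;
    while (lo < hi) { int mid = (lo + hi + 1) / 2; if (start[mid] <= g) lo = mid; else hi = mid - 1; }
    return lo;
  }
};

static TargetPack pack_targets(const CharacterVector& seqs) {
  TargetPack tp;
  size_t total = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) total += LENGTH(STRING_ELT(seqs, i));
  tp.code.reserve(total);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t n = LENGTH(STRING_ELT(seqs, i));
    tp.start.push_back(tp.code.size());
    for (size_t j = 0; j < n; ++j) tp.code.push_back((uint8_t)base_code(s[j]));
    tp.end.push_back(tp.code.size());
  }
  return tp;
}

// Exact s-mer index over the packed targets (counting-sort layout).
// Positions whose window contains a non-ACGT code or crosses a target
// boundary are not indexed.
struct SeedIndex {
  int s;
  std::vector<uint32_t> off;   // 4^s + 1 prefix offsets
  std::vector<uint32_t> pos;   // global positions grouped by hash
};

static SeedIndex build_seed_index(const TargetPack& tp, int s) {
  SeedIndex idx;
  idx.s = s;
  const size_t nbins = (size_t)1 << (2 * s);
  idx.off.assign(nbins + 1, 0);
  std::vector<std::pair<uint32_t, uint32_t> > entries;  // (hash, pos)
  const uint32_t mask = (s == 16) ? 0xFFFFFFFFu : (((uint32_t)1 << (2 * s)) - 1);
  for (size_t t = 0; t < tp.n_targets(); ++t) {
    size_t a = tp.start[t], b = tp.end[t];
    if (b - a < (size_t)s) continue;
    uint32_t h = 0;
    int clean = 0;  // number of consecutive clean (ACGT) codes ending here
    for (size_t g = a; g < b; ++g) {
      int c = tp.code[g];
      if (c >= 4) { clean = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t)c) & mask;
      ++clean;
      if (clean >= s) entries.push_back(std::make_pair(h, (uint32_t)(g - s + 1)));
    }
  }
  for (size_t i = 0; i < entries.size(); ++i) idx.off[entries[i].first + 1]++;
  for (size_t b = 1; b <= nbins; ++b) idx.off[b] += idx.off[b - 1];
  idx.pos.resize(entries.size());
  std::vector<uint32_t> cur(idx.off.begin(), idx.off.end() - 1);
  for (size_t i = 0; i < entries.size(); ++i) idx.pos[cur[entries[i].first]++] = entries[i].second;
  return idx;
}

struct RawHit { int target; int pos; int strand; int mm; };  // strand: 0='+', 1='-'

static bool hit_less(const RawHit& a, const RawHit& b) {
  if (a.mm != b.mm) return a.mm < b.mm;
  if (a.target != b.target) return a.target < b.target;
  if (a.pos != b.pos) return a.pos < b.pos;
  return a.strand < b.strand;
}

// Verify query codes q against target pack at global start g; returns
// mismatch count or max_mm+1 on early abort / out of bounds.
static int verify_at(const TargetPack& tp, const std::vector<uint8_t>& q,
                     size_t g, int max_mm) {
  size_t qlen = q.size();
  int t = tp.target_of(g);
  if (g + qlen > tp.end[t]) return max_mm + 1;
  int mm = 0;
  const uint8_t* tc = &tp.code[g];
  for (size_t i = 0; i < qlen; ++i) {
    uint8_t a = q[i], b = tc[i];
    if (a != b || a >= 4) { if (++mm > max_mm) return mm; }
  }
  return mm;
}

// Enumerate all hits of q (one strand) via pigeonhole seeding.
static void scan_strand(const TargetPack& tp, const SeedIndex& idx,
                        const std::vector<uint8_t>& q, int max_mm, int strand,
                        std::vector<RawHit>& out) {
  const int s = idx.s;
  const int qlen = (int)q.size();
  const int nseed = max_mm + 1;
  const uint32_t mask = (s == 16) ? 0xFFFFFFFFu : (((uint32_t)1 << (2 * s)) - 1);
  std::vector<size_t> cand;
  for (int i = 0; i < nseed; ++i) {
    int off = (nseed == 1) ? 0 : (int)std::lround((double)i * (qlen - s) / (nseed - 1));
    uint32_t h = 0;
    bool ok = true;
    for (int j = 0; j < s; ++j) {
      int c = q[off + j];
      if (c >= 4) { ok = false; break; }
      h = ((h << 2) | (uint32_t)c) & mask;
    }
    if (!ok) continue;
    for (uint32_t k = idx.off[h]; k < idx.off[h + 1]; ++k) {
      int64_t g = (int64_t)idx.pos[k] - off;
      if (g >= 0) cand.push_back((size_t)g);
    }
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  for (size_t i = 0; i < cand.size(); ++i) {
    int mm = verify_at(tp, q, cand[i], max_mm);
    if (mm <= max_mm) {
      int t = tp.target_of(cand[i]);
      RawHit h;
      h.target = t; h.pos = (int)(cand[i] - tp.start[t]); h.strand = strand; h.mm = mm;
      out.push_back(h);
    }
  }
}

// [[Rcpp::export]]
List cpp_map_batch(CharacterVector target_seqs, CharacterVector queries,
                   int max_mm, int max_hits_report) {
  if (max_mm < 0) stop("max_mm must be >= 0");
  TargetPack tp = pack_targets(target_seqs);
  // seed length from the shortest query and the mismatch budget
  int min_q = INT_MAX;
  for (R_xlen_t i = 0; i < queries.size(); ++i)
    min_q = std::min(min_q, (int)LENGTH(STRING_ELT(queries, i)));
  if (queries.size() == 0) min_q = 0;
  int s = std::min(12, min_q / (max_mm + 1));
  if (queries.size() > 0 && s < 4)
    stop("queries too short for the mismatch budget (need length >= 4*(max_mm+1))");
  SeedIndex idx = build_seed_index(tp, std::max(s, 4));

  R_xlen_t nq = queries.size();
  IntegerVector n_total(nq), n_best(nq), best_target(nq), best_pos(nq),
    best_strand(nq), best_mm(nq);
  std::vector<int> hq, ht, hp, hs, hm;

  std::vector<uint8_t> qf, qr;
  std::vector<RawHit> hits;
  for (R_xlen_t i = 0; i < nq; ++i) {
    const char* qs = CHAR(STRING_ELT(queries, i));
    int qlen = LENGTH(STRING_ELT(queries, i));
    qf.assign(qlen, 0); qr.assign(qlen, 0);
    for (int j = 0; j < qlen; ++j) qf[j] = (uint8_t)base_code(qs[j]);
    for (int j = 0; j < qlen; ++j) qr[j] = (uint8_t)comp_code(qf[qlen - 1 - j]);
    hits.clear();
    scan_strand(tp, idx, qf, max_mm, 0, hits);
    scan_strand(tp, idx, qr, max_mm, 1, hits);
    std::sort(hits.begin(), hits.end(), hit_less);
    n_total[i] = (int)hits.size();
    if (hits.empty()) {
      n_best[i] = 0; best_target[i] = NA_INTEGER; best_pos[i] = NA_INTEGER;
      best_strand[i] = NA_INTEGER; best_mm[i] = NA_INTEGER;
    } else {
      int bm = hits[0].mm, nb = 0;
      for (size_t k = 0; k < hits.size(); ++k) if (hits[k].mm == bm) ++nb;
      n_best[i] = nb;
      best_target[i] = hits[0].target + 1;
      best_pos[i] = hits[0].pos;
      best_strand[i] = hits[0].strand;
      best_mm[i] = bm;
      int keep = std::min((int)hits.size(), max_hits_report);
      for (int k = 0; k < keep; ++k) {
        hq.push_back((int)i + 1); ht.push_back(hits[k].target + 1);
        hp.push_back(hits[k].pos); hs.push_back(hits[k].strand); hm.push_back(hits[k].mm);
      }
    }
  }
  return List::create(
    _["n_total"] = n_total, _["n_best"] = n_best,
    _["best_target"] = best_target, _["best_pos"] = best_pos,
    _["best_strand"] = best_strand, _["best_mm"] = best_mm,
    _["hit_query"] = wrap(hq), _["hit_target"] = wrap(ht),
    _["hit_pos"] = wrap(hp), _["hit_strand"] = wrap(hs), _["hit_mm"] = wrap(hm));
}

// Leading/trailing Phred trim + mean-quality gate. Returns 1-based keep
// bounds per read; end = 0 marks a discarded read.
// [[Rcpp::export]]
List cpp_quality_trim(CharacterVector quals, int lead, int trail, double avg_min) {
  R_xlen_t n = quals.size();
  IntegerVector from(n), to(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* q = CHAR(STRING_ELT(quals, i));
    int len = LENGTH(STRING_ELT(quals, i));
    int a = 0, b = len;
    while (a < b && (q[a] - 33) < lead) ++a;
    while (b > a && (q[b - 1] - 33) < trail) --b;
    if (a >= b) { from[i] = 1; to[i] = 0; continue; }
    double tot = 0;
    for (int j = a; j < b; ++j) tot += q[j] - 33;
    if (tot / (b - a) < avg_min) { from[i] = 1; to[i] = 0; continue; }
    from[i] = a + 1; to[i] = b;
  }
  return List::create(_["from"] = from, _["to"] = to);
}

// Local alignment (affine gaps) of query codes vs a target window; returns
// best score. match +1, mismatch -1, gap of length g costs open + g*ext.
static int sw_window(const std::vector<uint8_t>& q, const uint8_t* t, size_t wlen,
                     int ma, int mi, int go, int ge) {
  const size_t qlen = q.size();
  std::vector<int> H(wlen + 1, 0), E(wlen + 1, INT_MIN / 4);
  int best = 0;
  for (size_t i = 1; i <= qlen; ++i) {
    int diag = 0;          // H[i-1][j-1]
    int F = INT_MIN / 4;   // gap in target row state
    uint8_t qc = q[i - 1];
    for (size_t j = 1; j <= wlen; ++j) {
      int sub = (qc < 4 && qc == t[j - 1]) ? ma : mi;
      E[j] = std::max(E[j] - ge, H[j] - go - ge);
      F = std::max(F - ge, H[j - 1] - go - ge);
      int h = diag + sub;
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Best local-alignment score of each query anywhere in the targets, either
// strand, divided by query length. Seeded: exact seed_len-mer hits nominate
// windows (padded by the query length) that are merged and aligned in full;
// exhaustive = TRUE aligns against every complete target instead.
// [[Rcpp::export]]
NumericVector cpp_local_ratio(CharacterVector target_seqs, CharacterVector queries,
                              int seed_len, bool exhaustive,
                              int match, int mismatch, int gap_open, int gap_ext) {
  TargetPack tp = pack_targets(target_seqs);
  SeedIndex idx;
  if (!exhaustive) idx = build_seed_index(tp, seed_len);
  R_xlen_t nq = queries.size();
  NumericVector out(nq);
  std::vector<uint8_t> qf, qr;
  const uint32_t mask = (seed_len == 16) ? 0xFFFFFFFFu : (((uint32_t)1 << (2 * seed_len)) - 1);
  for (R_xlen_t i = 0; i < nq; ++i) {
    const char* qs = CHAR(STRING_ELT(queries, i));
    int qlen = LENGTH(STRING_ELT(queries, i));
    if (qlen == 0) { out[i] = 0.0; continue; }
    qf.assign(qlen, 0); qr.assign(qlen, 0);
    for (int j = 0; j < qlen; ++j) qf[j] = (uint8_t)base_code(qs[j]);
    for (int j = 0; j < qlen; ++j) qr[j] = (uint8_t)comp_code(qf[qlen - 1 - j]);
    int best = 0;
    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<uint8_t>& q = strand == 0 ? qf : qr;
      if (exhaustive) {
        for (size_t t = 0; t < tp.n_targets(); ++t) {
          size_t wlen = tp.end[t] - tp.start[t];
          if (wlen == 0) continue;
          best = std::max(best, sw_window(q, &tp.code[tp.start[t]], wlen,
                                          match, mismatch, gap_open, gap_ext));
        }
      } else {
        // windows around seed hits, per target, merged
        std::vector<std::pair<int64_t, int64_t> > win;
        uint32_t h = 0; int clean = 0;
        for (int j = 0; j < qlen; ++j) {
          int c = q[j];
          if (c >= 4) { clean = 0; h = 0; continue; }
          h = ((h << 2) | (uint32_t)c) & mask;
          if (++clean < seed_len) continue;
          for (uint32_t k = idx.off[h]; k < idx.off[h + 1]; ++k) {
            int64_t g = (int64_t)idx.pos[k];
            int t = tp.target_of((size_t)g);
            int64_t lo = std::max((int64_t)tp.start[t], g - (j + 1) - 8);
            int64_t hi = std::min((int64_t)tp.end[t], g + seed_len + (qlen - j) + 8);
            win.push_back(std::make_pair(lo, hi));
          }
        }
        std::sort(win.begin(), win.end());
        size_t w = 0;
        while (w < win.size()) {
          int64_t lo = win[w].first, hi = win[w].second;
          while (w + 1 < win.size() && win[w + 1].first <= hi) {
            hi = std::max(hi, win[w + 1].second); ++w;
          }
          ++w;
          best = std::max(best, sw_window(q, &tp.code[lo], (size_t)(hi - lo),
                                          match, mismatch, gap_open, gap_ext));
          if (best == qlen * match) break;  // perfect, cannot improve
        }
      }
      if (best == qlen * match) break;
    }
    out[i] = (double)best / (double)qlen;
  }
  return out;
}
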
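// Alignment engine: affine-gap Smith-Waterman with traceback, a k-mer
// seed index over the combined reference, a paired-end seed-and-extend
// mapper, and a pileup tally.  Coordinates are 0-based half-open
// throughout; conversion to 1-based formats happens on the R side.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// ---------------------------------------------------------------------------
// Smith-Waterman, affine gaps.  A gap of length L costs gap_open +
// L * gap_extend (the open penalty is charged in addition to the first
// extension).  Tie-break among maximal cells: smaller target start,
// then shorter target span, then shorter query span.

struct SWPlacement {
  int score, qstart, qend, tstart, tend;
  std::string cigar;
};

// traceback state codes for the H matrix
enum { FROM_NONE = 0, FROM_DIAG = 1, FROM_E = 2, FROM_F = 3 };

static void sw_fill(const std::string& q, const std::string& t,
                    int match, int mismatch, int gap_open, int gap_extend,
                    std::vector<int>& H, std::vector<int>& E, std::vector<int>& F,
                    std::vector<uint8_t>& Hfrom, std::vector<uint8_t>& Efrom,
                    std::vector<uint8_t>& Ffrom, int& best) {
  const int m = (int)q.size(), n = (int)t.size();
  const int W = n + 1;
  H.assign((size_t)(m + 1) * W, 0);
  E.assign((size_t)(m + 1) * W, INT_MIN / 4);
  F.assign((size_t)(m + 1) * W, INT_MIN / 4);
  Hfrom.assign((size_t)(m + 1) * W, FROM_NONE);
  Efrom.assign((size_t)(m + 1) * W, 0); // 0: opened from H, 1: extended from E
  Ffrom.assign((size_t)(m + 1) * W, 0);
  best = 0;
  for (int i = 1; i <= m; ++i) {
    const char qc = q[(size_t)i - 1];
    for (int j = 1; j <= n; ++j) {
      const size_t idx = (size_t)i * W + j;
      // E: gap in query (consumes target)
      int e_open = H[idx - 1] - gap_open - gap_extend;
      int e_ext  = E[idx - 1] - gap_extend;
      if (e_open >= e_ext) { E[idx] = e_open; Efrom[idx] = 0; }
      else                 { E[idx] = e_ext;  Efrom[idx] = 1; }
      // F: gap in target (consumes query)
      int f_open = H[idx - W] - gap_open - gap_extend;
      int f_ext  = F[idx - W] - gap_extend;
      if (f_open >= f_ext) { F[idx] = f_open; Ffrom[idx] = 0; }
      else                 { F[idx] = f_ext;  Ffrom[idx] = 1; }
      int s = (base_code(qc) >= 0 && base_code(qc) == base_code(t[(size_t)j - 1]))
                ? match : -mismatch;
      int diag = H[idx - W - 1] + s;
      int h = 0; uint8_t from = FROM_NONE;
      if (diag > h) { h = diag; from = FROM_DIAG; }
      if (E[idx] > h) { h = E[idx]; from = FROM_E; }
      if (F[idx] > h) { h = F[idx]; from = FROM_F; }
      H[idx] = h; Hfrom[idx] = from;
      if (h > best) best = h;
    }
  }
}

static SWPlacement sw_traceback(const std::string& q, const std::string& t,
                                int i, int j,
                                const std::vector<int>& H,
                                const std::vector<uint8_t>& Hfrom,
                                const std::vector<uint8_t>& Efrom,
                                const std::vector<uint8_t>& Ffrom) {
  const int n = (int)t.size();
  const int W = n + 1;
  SWPlacement p;
  p.score = H[(size_t)i * W + j];
  p.qend = i; p.tend = j;
  std::vector<std::pair<char, int>> ops; // reversed
  auto push = [&ops](char op) {
    if (!ops.empty() && ops.back().first == op) ops.back().second++;
    else ops.emplace_back(op, 1);
  };
  while (i > 0 && j > 0) {
    const size_t idx = (size_t)i * W + j;
    uint8_t from = Hfrom[idx];
    if (from == FROM_NONE) break;
    if (from == FROM_DIAG) { push('M'); --i; --j; }
    else if (from == FROM_E) {
      // walk the E chain: each step consumes one target base
      while (true) {
        push('D');
        uint8_t ef = Efrom[(size_t)i * W + j];
        --j;
        if (ef == 0) break;
      }
    } else { // FROM_F
      while (true) {
        push('I');
        uint8_t ff = Ffrom[(size_t)i * W + j];
        --i;
        if (ff == 0) break;
      }
    }
  }
  p.qstart = i; p.tstart = j;
  std::string cig;
  const int m = (int)q.size();
  if (p.qstart > 0) cig += std::to_string(p.qstart) + "S";
  for (auto it = ops.rbegin(); it != ops.rend(); ++it)
    cig += std::to_string(it->second) + it->first;
  if (p.qend < m) cig += std::to_string(m - p.qend) + "S";
  p.cigar = cig;
  return p;
}

// collect all maximal cells, traceback each, order placements by the
// tie-break rule; returns at most max_hits placements (all same score)
static std::vector<SWPlacement> sw_align(const std::string& q, const std::string& t,
                                         int match, int mismatch,
                                         int gap_open, int gap_extend,
                                         int max_hits) {
  std::vector<int> H, E, F;
  std::vector<uint8_t> Hfrom, Efrom, Ffrom;
  int best = 0;
  sw_fill(q, t, match, mismatch, gap_open, gap_extend, H, E, F, Hfrom, Efrom, Ffrom, best);
  std::vector<SWPlacement> out;
  if (best <= 0) {
    SWPlacement p; p.score = 0; p.qstart = p.qend = p.tstart = p.tend = 0;
    p.cigar = "";
    out.push_back(p);
    return out;
  }
  const int m = (int)q.size(), n = (int)t.size();
  const int W = n + 1;
  std::vector<SWPlacement> hits;
  for (int i = 1; i <= m; ++i)
    for (int j = 1; j <= n; ++j)
      if (H[(size_t)i * W + j] == best)
        hits.push_back(sw_traceback(q, t, i, j, H, Hfrom, Efrom, Ffrom));
  std::stable_sort(hits.begin(), hits.end(),
                   [](const SWPlacement& a, const SWPlacement& b) {
                     if (a.tstart != b.tstart) return a.tstart < b.tstart;
                     int la = a.tend - a.tstart, lb = b.tend - b.tstart;
                     if (la != lb) return la < lb;
                     return (a.qend - a.qstart) < (b.qend - b.qstart);
                   });
  // drop placements that end inside an already-kept placement's span
  // (co-terminal sub-optimal tracebacks of the same local alignment)
  for (const auto& h : hits) {
    bool dup = false;
    for (const auto& k : out)
      if (h.tstart == k.tstart && h.tend == k.tend && h.qstart == k.qstart) { dup = true; break; }
    if (!dup) out.push_back(h);
    if ((int)out.size() >= max_hits) break;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_smith_waterman(std::string query, std::string target,
                        int match, int mismatch, int gap_open, int gap_extend,
                        int max_hits = 1) {
  std::vector<SWPlacement> hits =
    sw_align(query, target, match, mismatch, gap_open, gap_extend, max_hits);
  int nh = (int)hits.size();
  IntegerVector qs(nh), qe(nh), ts(nh), te(nh), sc(nh);
  CharacterVector cig(nh);
  for (int i = 0; i < nh; ++i) {
    sc[i] = hits[i].score;
    qs[i] = hits[i].qstart; qe[i] = hits[i].qend;
    ts[i] = hits[i].tstart; te[i] = hits[i].tend;
    cig[i] = hits[i].cigar;
  }
  return List::create(_["score"] = sc, _["query_start"] = qs, _["query_end"] = qe,
                      _["target_start"] = ts, _["target_end"] = te,
                      _["cigar"] = cig);
}

// ---------------------------------------------------------------------------
// k-mer index

struct KmerIndex {
  int k;
  std::vector<std::string> seqs;
  std::vector<std::string> names;
  std::unordered_map<uint64_t, std::vector<uint64_t>> map; // contig<<40 | pos
};

static bool encode_kmer(const char* s, int k, uint64_t& key) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  key = v;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, int k) {
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  CharacterVector nm = seqs.names();
  for (int c = 0; c < seqs.size(); ++c) {
    idx->seqs.push_back(as<std::string>(seqs[c]));
    idx->names.push_back(nm.size() ? as<std::string>(nm[c]) : std::to_string(c + 1));
  }
  for (size_t c = 0; c < idx->seqs.size(); ++c) {
    const std::string& s = idx->seqs[c];
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + k <= s.size(); ++p) {
      uint64_t key;
      if (!encode_kmer(s.c_str() + p, k, key)) continue;
      idx->map[key].push_back(((uint64_t)c << 40) | (uint64_t)p);
    }
  }
  XPtr<KmerIndex> ptr(idx, true);
  ptr.attr("class") = "kmer_index";
  ptr.attr("k") = k;
  ptr.attr("contigs") = nm;
  return ptr;
}

// [[Rcpp::export]]
DataFrame cpp_kmer_lookup(SEXP xp, std::string kmer) {
  XPtr<KmerIndex> idx(xp);
  uint64_t key;
  std::vector<std::string> contig;
  std::vector<int> pos;
  if ((int)kmer.size() == idx->k && encode_kmer(kmer.c_str(), idx->k, key)) {
    auto it = idx->map.find(key);
    if (it != idx->map.end())
      for (uint64_t v : it->second) {
        contig.push_back(idx->names[(size_t)(v >> 40)]);
        pos.push_back((int)(v & 0xFFFFFFFFFFULL));
      }
  }
  return DataFrame::create(_["contig"] = contig, _["pos"] = pos,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// paired-end mapper

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
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

struct Candidate {
  int contig;
  int start;      // proposed 0-based alignment start on contig (of full read)
  bool fwd;       // read used as-is (true) or reverse-complemented (false)
  int score;
  int pos;        // final alignment start after SW (ref coordinate)
  std::string cigar;
};

// gapless score of read at [start, start+len) on contig; clipped ends score 0
static int gapless_score(const std::string& ref, const std::string& read,
                         int start, int match, int mismatch, int& mismatches,
                         int& ov_start, int& ov_end) {
  int len = (int)read.size();
  ov_start = std::max(0, -start);
  ov_end = std::min(len, (int)ref.size() - start);
  mismatches = 0;
  if (ov_end <= ov_start) return 0;
  int sc = 0;
  for (int i = ov_start; i < ov_end; ++i) {
    if (base_code(read[(size_t)i]) >= 0 &&
        base_code(read[(size_t)i]) == base_code(ref[(size_t)(start + i)])) sc += match;
    else { sc -= mismatch; ++mismatches; }
  }
  return sc;
}

static void collect_candidates(const KmerIndex& idx, const std::string& read, bool fwd,
                               std::vector<Candidate>& cands) {
  const int k = idx.k;
  const int len = (int)read.size();
  if (len < k) return;
  int offs[3] = {0, (len - k) / 2, len - k};
  std::vector<uint64_t> seen;
  for (int o = 0; o < 3; ++o) {
    uint64_t key;
    if (!encode_kmer(read.c_str() + offs[o], k, key)) continue;
    auto it = idx.map.find(key);
    if (it == idx.map.end()) continue;
    if (it->second.size() > 64) continue; // hyper-repetitive seed
    for (uint64_t v : it->second) {
      int contig = (int)(v >> 40);
      int pos = (int)(v & 0xFFFFFFFFFFULL);
      int start = pos - offs[o];
      uint64_t tag = ((uint64_t)contig << 41) | ((uint64_t)(start + (1 << 20)) << 1) | (fwd ? 1 : 0);
      if (std::find(seen.begin(), seen.end(), tag) != seen.end()) continue;
      seen.push_back(tag);
      Candidate c; c.contig = contig; c.start = start; c.fwd = fwd;
      c.score = 0; c.pos = start; c.cigar = "";
      cands.push_back(c);
    }
  }
}

// reusable DP buffers so the SW fallback does not reallocate per read
struct SWBuffers {
  std::vector<int> H, E, F;
  std::vector<uint8_t> Hf, Ef, Ff;
};

static SWPlacement sw_align_buffered(const std::string& q, const std::string& t,
                                     int match, int mismatch,
                                     int gap_open, int gap_extend,
                                     SWBuffers& buf) {
  int best = 0;
  sw_fill(q, t, match, mismatch, gap_open, gap_extend,
          buf.H, buf.E, buf.F, buf.Hf, buf.Ef, buf.Ff, best);
  SWPlacement p;
  if (best <= 0) {
    p.score = 0; p.qstart = p.qend = p.tstart = p.tend = 0; p.cigar = "";
    return p;
  }
  const int m = (int)q.size(), n = (int)t.size();
  const int W = n + 1;
  // deterministic single best cell: smallest target end, then query end
  int bi = 0, bj = 0;
  for (int j = 1; j <= n && bj == 0; ++j)
    for (int i = 1; i <= m; ++i)
      if (buf.H[(size_t)i * W + j] == best) { bi = i; bj = j; break; }
  return sw_traceback(q, t, bi, bj, buf.H, buf.Hf, buf.Ef, buf.Ff);
}

// gapless score pass; returns false when the candidate needs the SW path
// (partial overlap with the contig end)
static bool gapless_candidate(const KmerIndex& idx, const std::string& oriented,
                              Candidate& c, int match, int mismatch, int& mm) {
  const std::string& ref = idx.seqs[(size_t)c.contig];
  int ov_s, ov_e;
  int gs = gapless_score(ref, oriented, c.start, match, mismatch, mm, ov_s, ov_e);
  int len = (int)oriented.size();
  if (!(ov_s == 0 && ov_e == len)) { mm = INT_MAX / 4; return false; }
  c.score = gs;
  c.pos = c.start;
  c.cigar = std::to_string(len) + "M";
  return true;
}

static void sw_rescore(const KmerIndex& idx, const std::string& oriented,
                       Candidate& c, int match, int mismatch,
                       int gap_open, int gap_extend, int pad, SWBuffers& buf) {
  const std::string& ref = idx.seqs[(size_t)c.contig];
  int len = (int)oriented.size();
  int ws = std::max(0, c.start - pad);
  int we = std::min((int)ref.size(), c.start + len + pad);
  if (we <= ws) { c.score = 0; c.cigar = ""; return; }
  SWPlacement p = sw_align_buffered(oriented,
                                    ref.substr((size_t)ws, (size_t)(we - ws)),
                                    match, mismatch, gap_open, gap_extend, buf);
  if (p.score <= 0) { c.score = 0; c.cigar = ""; return; }
  c.score = p.score;
  c.pos = ws + p.tstart;
  c.cigar = p.cigar;
}

// score candidates: gapless throughout unless no candidate reaches the
// gapless mismatch budget (then the read likely carries an indel or spans
// a junction, and every candidate is re-scored by local alignment)
static void score_candidates(const KmerIndex& idx, const std::string& fwd,
                             const std::string& rev, std::vector<Candidate>& cands,
                             int match, int mismatch, int gap_open,
                             int gap_extend, int max_mm_gapless, int pad,
                             SWBuffers& buf) {
  int best_mm = INT_MAX / 4;
  std::vector<int> mms(cands.size());
  for (size_t i = 0; i < cands.size(); ++i) {
    const std::string& oriented = cands[i].fwd ? fwd : rev;
    gapless_candidate(idx, oriented, cands[i], match, mismatch, mms[i]);
    if (mms[i] < best_mm) best_mm = mms[i];
  }
  if (best_mm <= max_mm_gapless) {
    // fix up partial-overlap candidates only
    for (size_t i = 0; i < cands.size(); ++i)
      if (mms[i] >= INT_MAX / 4)
        sw_rescore(idx, cands[i].fwd ? fwd : rev, cands[i], match, mismatch,
                   gap_open, gap_extend, pad, buf);
    return;
  }
  // indel/junction path: re-score by local alignment, cheapest-first and
  // only the few most promising candidates (the others are strictly worse
  // already under the gapless bound)
  std::vector<size_t> ord(cands.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&mms](size_t a, size_t b) { return mms[a] < mms[b]; });
  size_t limit = std::min<size_t>(3, ord.size());
  for (size_t r = 0; r < ord.size(); ++r) {
    size_t i = ord[r];
    if (r < limit)
      sw_rescore(idx, cands[i].fwd ? fwd : rev, cands[i], match, mismatch,
                 gap_open, gap_extend, pad, buf);
    // beyond the limit the gapless score stands
  }
}

struct PairCombo { int a, b, score; };

// [[Rcpp::export]]
List cpp_map_read_pairs(SEXP xp, CharacterVector r1, CharacterVector r2,
                        int match, int mismatch, int gap_open, int gap_extend,
                        int outer, int outer_slack, int max_mm_gapless,
                        int mapq_scale, int mapq_cap, int pad) {
  XPtr<KmerIndex> idxp(xp);
  const KmerIndex& idx = *idxp;
  int n = r1.size();
  std::vector<int> out_contig, out_pos, out_mapq, out_score, out_second, out_pair, out_mate;
  std::vector<std::string> out_cigar, out_seq;
  std::vector<bool> out_fwd, out_proper;
  SWBuffers swbuf;
  RNGScope rng;

  for (int i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(r1[i]);
    std::string s2 = as<std::string>(r2[i]);
    std::string s1r = revcomp(s1), s2r = revcomp(s2);
    std::vector<Candidate> c1, c2;
    collect_candidates(idx, s1, true, c1);
    collect_candidates(idx, s1r, false, c1);
    collect_candidates(idx, s2, true, c2);
    collect_candidates(idx, s2r, false, c2);
    score_candidates(idx, s1, s1r, c1, match, mismatch, gap_open, gap_extend,
                     max_mm_gapless, pad, swbuf);
    score_candidates(idx, s2, s2r, c2, match, mismatch, gap_open, gap_extend,
                     max_mm_gapless, pad, swbuf);

    // enumerate proper combos: same contig, opposite orientation, insert ok
    std::vector<PairCombo> combos;
    for (int a = 0; a < (int)c1.size(); ++a)
      for (int b = 0; b < (int)c2.size(); ++b) {
        if (c1[a].contig != c2[b].contig) continue;
        if (c1[a].fwd == c2[b].fwd) continue;
        if (c1[a].score <= 0 || c2[b].score <= 0) continue;
        const Candidate& fw = c1[a].fwd ? c1[a] : c2[b];
        const Candidate& rv = c1[a].fwd ? c2[b] : c1[a];
        int insert = (rv.start + (int)(c1[a].fwd ? s2 : s1).size()) - fw.start;
        if (fw.start > rv.start) continue;
        if (std::abs(insert - outer) > outer_slack) continue;
        combos.push_back({a, b, c1[a].score + c2[b].score});
      }

    int best = -1, second = -1; // scores
    std::vector<int> best_idx;
    for (int c = 0; c < (int)combos.size(); ++c) {
      if (combos[c].score > best) { second = best; best = combos[c].score; best_idx.clear(); best_idx.push_back(c); }
      else if (combos[c].score == best) best_idx.push_back(c);
      else if (combos[c].score > second) second = combos[c].score;
    }

    auto emit = [&](const Candidate& c, int mate, const std::string& fseq,
                    const std::string& rseq, int mq, int sc, int sec, bool proper) {
      out_pair.push_back(i + 1);
      out_mate.push_back(mate);
      out_contig.push_back(c.contig + 1);
      out_pos.push_back(c.pos);
      out_fwd.push_back(c.fwd);
      out_cigar.push_back(c.cigar);
      out_mapq.push_back(mq);
      out_score.push_back(sc);
      out_second.push_back(sec);
      out_seq.push_back(c.fwd ? fseq : rseq);
      out_proper.push_back(proper);
    };

    if (best >= 0) {
      int ci, mapq;
      if ((int)best_idx.size() > 1) {
        int r = (int)std::floor(unif_rand() * best_idx.size());
        if (r >= (int)best_idx.size()) r = (int)best_idx.size() - 1;
        ci = best_idx[(size_t)r];
        mapq = 0;
      } else {
        ci = best_idx[0];
        mapq = (second < 0) ? mapq_cap
                            : std::min(mapq_cap, mapq_scale * (best - second));
      }
      const PairCombo& pc = combos[ci];
      emit(c1[pc.a], 1, s1, s1r, mapq, best, second < 0 ? NA_INTEGER : second, true);
      emit(c2[pc.b], 2, s2, s2r, mapq, best, second < 0 ? NA_INTEGER : second, true);
    } else {
      // no proper pair: place each mate at its own best candidate
      for (int mate = 1; mate <= 2; ++mate) {
        std::vector<Candidate>& cc = (mate == 1) ? c1 : c2;
        const std::string& fs = (mate == 1) ? s1 : s2;
        const std::string& rs = (mate == 1) ? s1r : s2r;
        int b = -1, sec = -1;
        std::vector<int> bi;
        for (int c = 0; c < (int)cc.size(); ++c) {
          if (cc[c].score <= 0) continue;
          if (cc[c].score > b) { sec = b; b = cc[c].score; bi.clear(); bi.push_back(c); }
          else if (cc[c].score == b) bi.push_back(c);
          else if (cc[c].score > sec) sec = cc[c].score;
        }
        if (b < 0) {
          out_pair.push_back(i + 1); out_mate.push_back(mate);
          out_contig.push_back(NA_INTEGER); out_pos.push_back(NA_INTEGER);
          out_fwd.push_back(true); out_cigar.push_back("");
          out_mapq.push_back(NA_INTEGER); out_score.push_back(NA_INTEGER);
          out_second.push_back(NA_INTEGER); out_seq.push_back(fs);
          out_proper.push_back(false);
          continue;
        }
        int pick = bi[0], mq;
        if ((int)bi.size() > 1) {
          int r = (int)std::floor(unif_rand() * bi.size());
          if (r >= (int)bi.size()) r = (int)bi.size() - 1;
          pick = bi[r]; mq = 0;
        } else {
          mq = (sec < 0) ? mapq_cap : std::min(mapq_cap, mapq_scale * (b - sec));
        }
        emit(cc[pick], mate, fs, rs, mq, b, sec < 0 ? NA_INTEGER : sec, false);
      }
    }
  }

  int N = (int)out_pair.size();
  IntegerVector pair_id(N), mate(N), contig(N), pos(N), mapq(N), score(N), second_best(N);
  CharacterVector cigar(N), seq(N), strand(N);
  LogicalVector proper(N);
  for (int i = 0; i < N; ++i) {
    pair_id[i] = out_pair[i]; mate[i] = out_mate[i];
    contig[i] = out_contig[i]; pos[i] = out_pos[i];
    mapq[i] = out_mapq[i]; score[i] = out_score[i]; second_best[i] = out_second[i];
    cigar[i] = out_cigar[i]; seq[i] = out_seq[i];
    strand[i] = out_fwd[i] ? "+" : "-";
    proper[i] = out_proper[i];
  }
  return List::create(_["pair_id"] = pair_id, _["mate"] = mate,
                      _["contig_idx"] = contig, _["pos"] = pos,
                      _["strand"] = strand, _["cigar"] = cigar,
                      _["mapq"] = mapq, _["score"] = score,
                      _["second_score"] = second_best, _["seq"] = seq,
                      _["proper_pair"] = proper);
}

// ---------------------------------------------------------------------------
// pileup tally over one contig region

// [[Rcpp::export]]
List cpp_pileup(std::string ref, IntegerVector pos, CharacterVector cigar,
                CharacterVector seq, IntegerVector mapq, CharacterVector qual,
                int region_start, int region_end, int min_bq, int min_mq) {
  const int L = region_end - region_start;
  if (L < 0) stop("empty region");
  IntegerMatrix counts(4, L);       // A,C,G,T
  IntegerVector depth(L), lowbq(L), lowmq(L);
  std::map<std::pair<int, std::string>, int> indels;
  bool have_qual = qual.size() == seq.size();

  for (int r = 0; r < pos.size(); ++r) {
    if (pos[r] == NA_INTEGER) continue;
    std::string cg = as<std::string>(cigar[r]);
    if (cg.empty()) continue;
    int mq = mapq[r] == NA_INTEGER ? 0 : mapq[r];
    bool mq_fail = mq < min_mq;
    std::string sq = as<std::string>(seq[r]);
    std::string ql = have_qual ? as<std::string>(qual[r]) : std::string();
    int rp = pos[r], qp = 0;
    int last_pos = -1, last_base = -1; // last M-base tallied (for indel anchors)
    size_t ci = 0;
    while (ci < cg.size()) {
      int len = 0;
      while (ci < cg.size() && isdigit(cg[ci])) { len = len * 10 + (cg[ci] - '0'); ++ci; }
      char op = cg[ci++]; // cppcheck-suppress (cigar validated upstream)
      if (op == 'S' || op == 'H') { if (op == 'S') qp += len; continue; }
      if (op == 'M' || op == '=' || op == 'X') {
        for (int x = 0; x < len; ++x, ++rp, ++qp) {
          if (rp < region_start || rp >= region_end) continue;
          int o = rp - region_start;
          if (mq_fail) { lowmq[o]++; continue; }
          int bq = have_qual && qp < (int)ql.size() ? (int)ql[(size_t)qp] - 33 : 93;
          if (bq < min_bq) { lowbq[o]++; continue; }
          int b = qp < (int)sq.size() ? base_code(sq[(size_t)qp]) : -1;
          if (b < 0) continue;
          counts(b, o)++;
          depth[o]++;
          last_pos = rp; last_base = b;
        }
      } else if (op == 'D' || op == 'N') {
        int anchor = rp - 1;
        if (op == 'D' && !mq_fail && anchor >= region_start && anchor < region_end &&
            last_pos == anchor && last_base >= 0) {
          // the read's vote at the anchor becomes the deletion allele
          counts(last_base, anchor - region_start)--;
          indels[{anchor, "-" + std::to_string(len)}]++;
        }
        rp += len;
      } else if (op == 'I') {
        int anchor = rp - 1;
        std::string ins = sq.substr((size_t)qp, (size_t)len);
        if (!mq_fail && anchor >= region_start && anchor < region_end &&
            last_pos == anchor && last_base >= 0) {
          counts(last_base, anchor - region_start)--;
          indels[{anchor, "+" + ins}]++;
        }
        qp += len;
      }
    }
  }

  int ni = (int)indels.size();
  IntegerVector ipos(ni), icount(ni);
  CharacterVector iallele(ni);
  int t = 0;
  for (auto& kv : indels) {
    ipos[t] = kv.first.first; iallele[t] = kv.first.second; icount[t] = kv.second; ++t;
  }
  return List::create(_["depth"] = depth, _["counts"] = counts,
                      _["lowbq"] = lowbq, _["lowmq"] = lowmq,
                      _["indel_pos"] = ipos, _["indel_allele"] = iallele,
                      _["indel_count"] = icount);
}

// per-base coverage from reference spans (start, end half-open), one contig
// [[Rcpp::export]]
IntegerVector cpp_span_coverage(IntegerVector start, IntegerVector end,
                                int region_start, int region_end) {
  int L = region_end - region_start;
  IntegerVector cov(L);
  std::vector<int> diff((size_t)L + 1, 0);
  for (int i = 0; i < start.size(); ++i) {
    int s = std::max(start[i], region_start) - region_start;
    int e = std::min(end[i], region_end) - region_start;
    if (e <= s) continue;
    diff[(size_t)s]++; diff[(size_t)e]--;
  }
  int acc = 0;
  for (int i = 0; i < L; ++i) { acc += diff[(size_t)i]; cov[i] = acc; }
  return cov;
}
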
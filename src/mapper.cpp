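// Seed-and-extend read mapping against a set of target contigs (the linear
// backbone plus alternate-allele contigs of a variation graph). Deterministic:
// no randomness, ties broken by lowest approximate reference position.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static inline int base2i(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  }
  return 'N';
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
  return r;
}

// ---------------------------------------------------------------------------
// banded local alignment with affine gaps and traceback
// ---------------------------------------------------------------------------

struct AlnRes {
  bool ok = false;
  int score = 0;
  int tstart = 0;      // 0-based start on the window
  int qstart = 0;      // 0-based start on the query (leading soft clip)
  int qend = 0;        // 0-based exclusive end on query
  int nm = 0;          // mismatches + gap bases within the aligned segment
  int clip = 0;        // total soft-clipped query bases
  std::string cigar;   // S/M/I/D ops, M covers match and mismatch
};

static const int NEG = -100000000;

// Query q vs window t; the stored band coordinate d = (j - i) encodes the
// target-minus-query offset, restricted to [0, 2*band]: the window is
// expected to start ~band bases left of the query origin, so the band is
// centred on that placement with +/- band of drift.
static AlnRes band_align(const std::string& q, const std::string& t,
                         int band, int mat, int mis, int gapo, int gape) {
  const int m = (int)q.size(), w = (int)t.size();
  const int B = 2 * band + 1;
  if (m == 0 || w == 0) return AlnRes();
  // reused scratch buffers (single-threaded R session)
  static std::vector<int> H, E, F;
  static std::vector<uint8_t> tb;
  const size_t need = (size_t)(m + 1) * B;
  if (H.size() < need) { H.resize(need); E.resize(need); F.resize(need); tb.resize(need); }
  std::fill(H.begin(), H.begin() + need, 0);
  std::fill(E.begin(), E.begin() + need, NEG);
  std::fill(F.begin(), F.begin() + need, NEG);
  std::fill(tb.begin(), tb.begin() + need, 0);
  // tb: 2 bits H source (0 stop, 1 diag, 2 E, 3 F), bit2 E-extends, bit3 F-extends
  int best = 0, bi = 0, bd = 0;
  for (int i = 1; i <= m; ++i) {
    const int qi = q[i - 1];
    for (int d = 0; d < B; ++d) {
      const int j = i + d;  // 1-based window column (offset d in [0, 2*band])
      const int idx = i * B + d;
      if (j < 1 || j > w) { H[idx] = 0; E[idx] = NEG; F[idx] = NEG; continue; }
      // E: gap consuming window (D op): from (i, j-1) -> same row, d-1
      int e = NEG, eext = 0;
      if (d > 0) {
        int ho = H[i * B + d - 1] - gapo - gape;
        int eo = E[i * B + d - 1] - gape;
        if (eo > ho) { e = eo; eext = 1; } else e = ho;
      }
      // F: gap consuming query (I op): from (i-1, j) -> prev row, d+1
      int f = NEG, fext = 0;
      if (d < B - 1) {
        int ho = H[(i - 1) * B + d + 1] - gapo - gape;
        int fo = F[(i - 1) * B + d + 1] - gape;
        if (fo > ho) { f = fo; fext = 1; } else f = ho;
      }
      // diag: from (i-1, j-1) -> prev row, same d
      int s = (qi == t[j - 1]) ? mat : -mis;
      int dg = H[(i - 1) * B + d] + s;
      int h = 0; uint8_t src = 0;
      if (dg > h) { h = dg; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      H[idx] = h; E[idx] = e; F[idx] = f;
      tb[idx] = src | (eext << 2) | (fext << 3);
      if (h > best || (h == best && (i > bi))) {
        if (h > best) { best = h; bi = i; bd = d; }
      }
    }
  }
  AlnRes r;
  if (best <= 0) return r;
  r.ok = true; r.score = best;
  // traceback
  std::vector<std::pair<char, int> > ops;  // reversed
  int i = bi, d = bd;
  int state = 0;  // 0 = in H, 1 = in E, 2 = in F
  r.qend = bi;
  int nm = 0;
  while (i > 0) {
    const int idx = i * B + d;
    if (state == 0) {
      uint8_t src = tb[idx] & 3;
      if (src == 0) break;
      if (src == 1) {
        const int j = i + d;
        if (q[i - 1] != t[j - 1]) ++nm;
        if (!ops.empty() && ops.back().first == 'M') ops.back().second++;
        else ops.push_back(std::make_pair('M', 1));
        --i;  // d unchanged
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) {  // E, consume window (D)
      if (!ops.empty() && ops.back().first == 'D') ops.back().second++;
      else ops.push_back(std::make_pair('D', 1));
      ++nm;
      int ext = (tb[idx] >> 2) & 1;
      d -= 1;
      if (!ext) state = 0;
    } else {  // F, consume query (I)
      if (!ops.empty() && ops.back().first == 'I') ops.back().second++;
      else ops.push_back(std::make_pair('I', 1));
      ++nm;
      int ext = (tb[idx] >> 3) & 1;
      --i; d += 1;
      if (!ext) state = 0;
    }
    if (d < 0 || d >= B) break;  // fell off band (should not happen)
  }
  r.qstart = i;
  r.tstart = i + d;  // 0-based window start: the stop cell precedes the segment
  r.nm = nm;
  r.clip = r.qstart + (m - r.qend);
  std::string cg;
  if (r.qstart > 0) cg += std::to_string(r.qstart) + "S";
  for (int kk = (int)ops.size() - 1; kk >= 0; --kk)
    cg += std::to_string(ops[kk].second) + ops[kk].first;
  if (m - r.qend > 0) cg += std::to_string(m - r.qend) + "S";
  r.cigar = cg;
  return r;
}

// [[Rcpp::export]]
List cpp_align(std::string query, std::string target, int band = 32,
               int match = 1, int mismatch = 4, int gap_open = 6,
               int gap_ext = 1) {
  // widen the window so the band covers the whole target
  AlnRes r = band_align(query, target, band, match, mismatch, gap_open, gap_ext);
  return List::create(_["ok"] = r.ok, _["score"] = r.score,
                      _["tstart"] = r.tstart, _["qstart"] = r.qstart,
                      _["nm"] = r.nm, _["clip"] = r.clip,
                      _["cigar"] = r.cigar);
}

// ---------------------------------------------------------------------------
// k-mer index + mapping
// ---------------------------------------------------------------------------

struct Cand {
  int contig = -1;
  int strand = 0;      // +1 / -1 (read strand relative to contig forward)
  int anchor = 0;      // approximate contig start of the alignment
  int votes = 0;
  bool extended = false;
  AlnRes aln;
  long refpos = -1;    // approximate reference position (for locus dedup)
  int tpos = 0;        // exact contig position of first aligned base
};

typedef std::unordered_map<uint64_t, std::vector<uint64_t> > KIndex;

static void index_contig(KIndex& idx, const std::string& s, int ci, int k) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t kmer = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2i(s[i]);
    if (b < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      uint64_t key = kmer;
      idx[key].push_back(((uint64_t)ci << 32) | (uint64_t)(i - k + 1));
    }
  }
}

static bool encode_kmer(const std::string& s, int off, int k, uint64_t& out) {
  uint64_t kmer = 0;
  for (int i = 0; i < k; ++i) {
    int b = base2i(s[off + i]);
    if (b < 0) return false;
    kmer = (kmer << 2) | (uint64_t)b;
  }
  out = kmer;
  return true;
}

// gather candidate loci for one oriented read sequence; a cluster's votes
// are the number of distinct seed offsets supporting it, so self-similar
// (low-complexity) targets cannot out-vote a genuine locus
struct SeedHit { int contig; int64_t diag; int off; };

static void gather(const KIndex& idx, const std::string& s, int strand, int k,
                   int stride, int occ_cap, std::vector<Cand>& out) {
  const int m = (int)s.size();
  if (m < k) return;
  std::vector<SeedHit> hits;
  for (int off = 0; off <= m - k; off += stride) {
    int o = off;
    if (off + stride > m - k && off != m - k) o = m - k;  // ensure last seed
    uint64_t key;
    if (encode_kmer(s, o, k, key)) {
      KIndex::const_iterator it = idx.find(key);
      if (it != idx.end() && (int)it->second.size() <= occ_cap) {
        const std::vector<uint64_t>& v = it->second;
        for (size_t h = 0; h < v.size(); ++h) {
          SeedHit sh;
          sh.contig = (int)(v[h] >> 32);
          sh.diag = (int64_t)(int)(v[h] & 0xffffffffULL) - o;
          sh.off = o;
          hits.push_back(sh);
        }
      }
    }
    if (o == m - k) break;
  }
  if (hits.empty()) return;
  std::sort(hits.begin(), hits.end(), [](const SeedHit& a, const SeedHit& b) {
    if (a.contig != b.contig) return a.contig < b.contig;
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.off < b.off;
  });
  // cluster adjacent diagonals (within 8) on the same contig; the anchor is
  // the modal diagonal of the cluster (a cluster midpoint is easily dragged
  // away from the true diagonal by self-similar runs inside the read)
  size_t i = 0;
  while (i < hits.size()) {
    int ci = hits[i].contig;
    int64_t last = hits[i].diag;
    uint32_t offmask = 0;  // seed offsets are off/stride < 32
    offmask |= 1u << std::min(31, hits[i].off / std::max(1, stride));
    int64_t mode_diag = hits[i].diag, cur_diag = hits[i].diag;
    int mode_n = 1, cur_n = 1;
    size_t j = i + 1;
    while (j < hits.size() && hits[j].contig == ci) {
      if (hits[j].diag - last <= 8) {
        last = hits[j].diag;
        offmask |= 1u << std::min(31, hits[j].off / std::max(1, stride));
        if (hits[j].diag == cur_diag) ++cur_n;
        else { cur_diag = hits[j].diag; cur_n = 1; }
        if (cur_n > mode_n) { mode_n = cur_n; mode_diag = cur_diag; }
        ++j;
      } else break;
    }
    Cand c;
    c.contig = ci; c.strand = strand;
    c.anchor = (int)mode_diag;
    c.votes = __builtin_popcount(offmask);
    out.push_back(c);
    i = j;
  }
}

struct MapCfg {
  int k, stride, occ_cap, max_cand, match, mismatch, gap_open, gap_ext, band;
  int dedup_slop, unpaired_pen;
  double frag_mean, frag_sd;
};

// extend + dedup candidate list for one read; returns sorted by score desc,
// ties by refpos asc
static std::vector<Cand> map_one(const KIndex& idx,
                                 const std::vector<std::string>& contigs,
                                 const IntegerVector& offsets,
                                 const std::string& read, const MapCfg& cfg) {
  std::vector<Cand> cands;
  std::string rc = revcomp(read);
  gather(idx, read, +1, cfg.k, cfg.stride, cfg.occ_cap, cands);
  gather(idx, rc, -1, cfg.k, cfg.stride, cfg.occ_cap, cands);
  if (cands.empty()) return cands;
  std::stable_sort(cands.begin(), cands.end(),
                   [](const Cand& a, const Cand& b) { return a.votes > b.votes; });
  const int m = (int)read.size();
  // group candidates by approximate surjected locus; extend at most two
  // candidates per locus (different allele-combination contigs of the same
  // site) and prune loci with far fewer seed votes than the best locus
  const int best_votes = cands[0].votes;
  std::vector<long> grp_ref; std::vector<int> grp_strand, grp_n;
  std::vector<Cand> ext;
  int n_groups = 0, n_ext = 0;
  for (size_t i = 0; i < cands.size() && n_ext < 2 * cfg.max_cand; ++i) {
    Cand c = cands[i];
    long est = (long)offsets[c.contig] + c.anchor;
    int gi = -1;
    for (int g = 0; g < n_groups; ++g)
      if (grp_strand[g] == c.strand && std::labs(grp_ref[g] - est) <= 60) {
        gi = g; break;
      }
    if (gi >= 0 && grp_n[gi] >= 2) continue;
    if (gi < 0) {
      if (n_groups >= cfg.max_cand) continue;
      if (n_groups >= 2 && 4 * c.votes < best_votes) continue;
      grp_ref.push_back(est); grp_strand.push_back(c.strand);
      grp_n.push_back(0);
      gi = n_groups++;
    }
    const std::string& t = contigs[c.contig];
    int astart = c.anchor - cfg.band;
    int alen = m + 2 * cfg.band;
    if (astart < 0) astart = 0;
    if (astart >= (int)t.size()) continue;
    if (astart + alen > (int)t.size()) alen = (int)t.size() - astart;
    const std::string& q = (c.strand > 0) ? read : rc;
    AlnRes r;
    // exact-match fast path on the consensus diagonal
    if (c.anchor >= 0 && c.anchor + m <= (int)t.size() &&
        t.compare(c.anchor, m, q) == 0) {
      r.ok = true; r.score = m * cfg.match; r.tstart = c.anchor - astart;
      r.qstart = 0; r.qend = m; r.nm = 0; r.clip = 0;
      r.cigar = std::to_string(m) + "M";
    } else {
      std::string win = t.substr(astart, alen);
      r = band_align(q, win, cfg.band, cfg.match, cfg.mismatch,
                     cfg.gap_open, cfg.gap_ext);
    }
    if (!r.ok) continue;
    grp_n[gi]++; n_ext++;
    c.aln = r;
    c.extended = true;
    c.tpos = astart + r.tstart;
    c.refpos = (long)offsets[c.contig] + c.tpos;
    ext.push_back(c);
  }
  if (ext.empty()) return ext;
  std::stable_sort(ext.begin(), ext.end(), [](const Cand& a, const Cand& b) {
    if (a.aln.score != b.aln.score) return a.aln.score > b.aln.score;
    if (a.refpos != b.refpos) return a.refpos < b.refpos;
    return a.contig < b.contig;
  });
  // dedup by surjected locus (approximate refpos within slop, same strand)
  std::vector<Cand> kept;
  for (size_t i = 0; i < ext.size(); ++i) {
    bool dup = false;
    for (size_t j = 0; j < kept.size(); ++j) {
      if (kept[j].strand == ext[i].strand &&
          std::labs(kept[j].refpos - ext[i].refpos) <= cfg.dedup_slop) {
        dup = true; break;
      }
    }
    if (!dup) kept.push_back(ext[i]);
  }
  return kept;
}

struct OutRow {
  int mapped = 0, contig = NA_INTEGER, tpos = NA_INTEGER, strand = NA_INTEGER;
  int score = NA_INTEGER, mq = NA_INTEGER, nm = NA_INTEGER, clip = NA_INTEGER;
  int nsec = NA_INTEGER;
  std::string cigar = "";
};

static void fill_row(OutRow& o, const Cand& c, int mq) {
  o.mapped = 1; o.contig = c.contig + 1; o.tpos = c.tpos;
  o.strand = c.strand; o.score = c.aln.score; o.mq = mq;
  o.nm = c.aln.nm; o.clip = c.aln.clip; o.cigar = c.aln.cigar;
}

static int mq_single(const std::vector<Cand>& cs) {
  if (cs.size() < 2) return 60;
  int d = cs[0].aln.score - cs[1].aln.score;
  if (d <= 0) return 0;
  int mq = 6 * d;
  return mq > 60 ? 60 : mq;
}

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector contigs, IntegerVector contig_offsets,
                   CharacterVector reads1, CharacterVector reads2,
                   int k = 21, int stride = 10, int occ_cap = 255,
                   int max_cand = 8, int match = 1, int mismatch = 4,
                   int gap_open = 6, int gap_ext = 1, int band = 12,
                   double frag_mean = 500.0, double frag_sd = 50.0,
                   int dedup_slop = 50, int unpaired_pen = 40) {
  MapCfg cfg;
  cfg.k = k; cfg.stride = stride; cfg.occ_cap = occ_cap; cfg.max_cand = max_cand;
  cfg.match = match; cfg.mismatch = mismatch; cfg.gap_open = gap_open;
  cfg.gap_ext = gap_ext; cfg.band = band; cfg.dedup_slop = dedup_slop;
  cfg.unpaired_pen = unpaired_pen; cfg.frag_mean = frag_mean; cfg.frag_sd = frag_sd;

  const int nc = contigs.size();
  std::vector<std::string> tgt(nc);
  for (int i = 0; i < nc; ++i) tgt[i] = as<std::string>(contigs[i]);
  KIndex idx;
  for (int i = 0; i < nc; ++i) index_contig(idx, tgt[i], i, k);

  const bool paired = reads2.size() > 0;
  const int n1 = reads1.size();
  const int ntot = paired ? 2 * n1 : n1;
  std::vector<OutRow> out(ntot);

  for (int r = 0; r < n1; ++r) {
    std::string q1 = as<std::string>(reads1[r]);
    std::vector<Cand> c1 = map_one(idx, tgt, contig_offsets, q1, cfg);
    if (!paired) {
      if (!c1.empty()) fill_row(out[r], c1[0], mq_single(c1));
      if (!c1.empty()) out[r].nsec = (int)c1.size() - 1;
      continue;
    }
    std::string q2 = as<std::string>(reads2[r]);
    std::vector<Cand> c2 = map_one(idx, tgt, contig_offsets, q2, cfg);
    OutRow& o1 = out[r];
    OutRow& o2 = out[n1 + r];
    if (c1.empty() && c2.empty()) continue;
    if (c2.empty()) {
      fill_row(o1, c1[0], mq_single(c1));
      o1.nsec = (int)c1.size() - 1;
      continue;
    }
    if (c1.empty()) {
      fill_row(o2, c2[0], mq_single(c2));
      o2.nsec = (int)c2.size() - 1;
      continue;
    }
    // joint scoring with fragment-length prior
    const int m1 = (int)q1.size(), m2 = (int)q2.size();
    int nA = (int)c1.size(), nB = (int)c2.size();
    double bestS = -1e18;
    int bi = -1, bj = -1;
    std::vector<double> S(nA * nB);
    for (int i = 0; i < nA; ++i) {
      for (int j = 0; j < nB; ++j) {
        const Cand& a = c1[i];
        const Cand& b = c2[j];
        double pen = unpaired_pen;
        if (a.strand != b.strand) {
          const Cand& fwd = (a.strand > 0) ? a : b;
          const Cand& rev = (a.strand > 0) ? b : a;
          int mrev = (a.strand > 0) ? ((&rev == &b) ? m2 : m1) : m1;
          long d = (rev.refpos + mrev) - fwd.refpos;
          if (d > 0 && std::abs((double)d - frag_mean) < 10.0 * frag_sd) {
            double z = ((double)d - frag_mean) / frag_sd;
            pen = 0.5 * z * z;
            if (pen > unpaired_pen) pen = unpaired_pen;
          }
        }
        double s = (double)a.aln.score + (double)b.aln.score - pen;
        S[i * nB + j] = s;
        if (s > bestS + 1e-9) { bestS = s; bi = i; bj = j; }
      }
    }
    const Cand& A = c1[bi];
    const Cand& B = c2[bj];
    // per-mate runner-up: best pair score where this mate's locus differs
    double run1 = -1e18, run2 = -1e18;
    for (int i = 0; i < nA; ++i) {
      for (int j = 0; j < nB; ++j) {
        double s = S[i * nB + j];
        bool diff1 = (c1[i].strand != A.strand) ||
                     (std::labs(c1[i].refpos - A.refpos) > cfg.dedup_slop);
        bool diff2 = (c2[j].strand != B.strand) ||
                     (std::labs(c2[j].refpos - B.refpos) > cfg.dedup_slop);
        if (diff1 && s > run1) run1 = s;
        if (diff2 && s > run2) run2 = s;
      }
    }
    auto pair_mq = [&](double runner) {
      if (runner < -1e17) return 60;
      double d = bestS - runner;
      if (d <= 1e-9) return 0;
      int mq = (int)std::floor(6.0 * d);
      return mq > 60 ? 60 : mq;
    };
    fill_row(o1, A, pair_mq(run1));
    fill_row(o2, B, pair_mq(run2));
    o1.nsec = nA - 1;
    o2.nsec = nB - 1;
  }

  IntegerVector mapped(ntot), contig(ntot), tpos(ntot), strand(ntot),
      score(ntot), mq(ntot), nm(ntot), clip(ntot), nsec(ntot);
  CharacterVector cigar(ntot);
  for (int i = 0; i < ntot; ++i) {
    mapped[i] = out[i].mapped; contig[i] = out[i].contig;
    tpos[i] = out[i].tpos; strand[i] = out[i].strand;
    score[i] = out[i].score; mq[i] = out[i].mq; nm[i] = out[i].nm;
    clip[i] = out[i].clip; nsec[i] = out[i].nsec;
    cigar[i] = out[i].cigar;
  }
  return List::create(_["mapped"] = mapped, _["contig"] = contig,
                      _["tpos"] = tpos, _["strand"] = strand,
                      _["score"] = score, _["mq"] = mq, _["nm"] = nm,
                      _["soft_clip"] = clip, _["n_secondary"] = nsec,
                      _["cigar"] = cigar);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}
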
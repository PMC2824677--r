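// Core kernels: banded alignment, k-mer hashing, seed-and-extend overlap
// detection and read-to-genome mapping.  Scoring is match +1, mismatch -2,
// gap -3 per base (linear); all R-facing coordinates here are 0-based
// half-open and converted at the R layer.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

static const int SC_MATCH = 1;
static const int SC_MISMATCH = -2;
static const int SC_GAP = -3;
static const int NEG_INF = -1000000000;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static const char BIT2BASE[4] = {'A', 'C', 'G', 'T'};

static inline uint64_t revcomp_kmer(uint64_t km, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (km & 3ULL));
    km >>= 2;
  }
  return rc;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

// Enumerate valid (no non-ACGT base) k-mer windows of a sequence; calls
// fn(pos, fwd_kmer, canonical_kmer, is_fwd_canonical).
template <typename F>
static void for_each_kmer(const std::string& s, int k, F fn) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t fwd = 0, rc = 0;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) {
      valid = 0;
      fwd = 0;
      rc = 0;
      continue;
    }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
    if (++valid >= k) {
      bool fwd_can = fwd <= rc;
      fn(i - k + 1, fwd, fwd_can ? fwd : rc, fwd_can);
    }
  }
}

// ---------------------------------------------------------------------------
// k-mer frequency model
// ---------------------------------------------------------------------------

typedef std::unordered_map<uint64_t, int32_t> KmerMap;

// [[Rcpp::export]]
SEXP cpp_kmer_build(CharacterVector seqs, int k) {
  KmerMap* map = new KmerMap();
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    for_each_kmer(seq, k, [&](int, uint64_t, uint64_t canon, bool) {
      (*map)[canon] += 1;
    });
  }
  XPtr<KmerMap> ptr(map, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_kmer_summary(SEXP ptr_) {
  XPtr<KmerMap> ptr(ptr_);
  double total = 0;
  double n_singleton = 0;
  for (const auto& kv : *ptr) {
    total += kv.second;
    if (kv.second == 1) n_singleton += 1;
  }
  double nd = (double)ptr->size();
  return List::create(_["n_distinct"] = nd, _["total"] = total,
                      _["n_singleton"] = n_singleton,
                      _["mean_count"] = nd > 0 ? total / nd : NA_REAL);
}

// [[Rcpp::export]]
DataFrame cpp_kmer_dump(SEXP ptr_, int k) {
  XPtr<KmerMap> ptr(ptr_);
  const size_t n = ptr->size();
  CharacterVector kmers(n);
  IntegerVector counts(n);
  size_t i = 0;
  for (const auto& kv : *ptr) {
    std::string s(k, 'A');
    uint64_t km = kv.first;
    for (int j = k - 1; j >= 0; --j) {
      s[j] = BIT2BASE[km & 3ULL];
      km >>= 2;
    }
    kmers[i] = s;
    counts[i] = kv.second;
    ++i;
  }
  return DataFrame::create(_["kmer"] = kmers, _["count"] = counts,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
IntegerVector cpp_kmer_counts_of(SEXP ptr_, CharacterVector kmers, int k) {
  XPtr<KmerMap> ptr(ptr_);
  IntegerVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != k) {
      out[i] = NA_INTEGER;
      continue;
    }
    uint64_t km = 0;
    bool ok = true;
    for (char c : s) {
      int b = base2bit(c);
      if (b < 0) { ok = false; break; }
      km = (km << 2) | (uint64_t)b;
    }
    if (!ok) {
      out[i] = NA_INTEGER;
      continue;
    }
    uint64_t canon = std::min(km, revcomp_kmer(km, k));
    auto it = ptr->find(canon);
    out[i] = (it == ptr->end()) ? 0 : it->second;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_kmer_window_counts(SEXP ptr_, CharacterVector seqs, int k) {
  XPtr<KmerMap> ptr(ptr_);
  List out(seqs.size());
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    std::vector<int> counts;
    for_each_kmer(seq, k, [&](int, uint64_t, uint64_t canon, bool) {
      auto it = ptr->find(canon);
      counts.push_back(it == ptr->end() ? 0 : it->second);
    });
    out[s] = wrap(counts);
  }
  return out;
}

// Per-candidate k-mer statistics over both reads' overlap substrings.
// Columns: q1, q2, q3 (normalised, nearest-rank lower), pct_overrepresented,
// n_singleton, n_kmers.  Rows with no countable k-mer are all-NA.
// [[Rcpp::export]]
NumericMatrix cpp_overlap_kmer_stats(SEXP ptr_, CharacterVector subA,
                                     CharacterVector subB, int k,
                                     double expected_coverage,
                                     double mean_frequency) {
  XPtr<KmerMap> ptr(ptr_);
  const R_xlen_t n = subA.size();
  NumericMatrix out(n, 6);
  colnames(out) = CharacterVector::create("kmer_q1", "kmer_q2", "kmer_q3",
                                          "pct_overrepresented",
                                          "n_singleton_kmers", "n_kmers");
  std::vector<int> counts;
  const double thresh = 1.5 * mean_frequency;
  for (R_xlen_t i = 0; i < n; ++i) {
    counts.clear();
    for (int side = 0; side < 2; ++side) {
      std::string seq = as<std::string>(side == 0 ? subA[i] : subB[i]);
      for_each_kmer(seq, k, [&](int, uint64_t, uint64_t canon, bool) {
        auto it = ptr->find(canon);
        counts.push_back(it == ptr->end() ? 0 : it->second);
      });
    }
    const int m = (int)counts.size();
    if (m == 0) {
      for (int j = 0; j < 6; ++j) out(i, j) = NA_REAL;
      continue;
    }
    std::sort(counts.begin(), counts.end());
    auto qidx = [m](double p) {
      int idx = (int)std::ceil(p * m);
      if (idx < 1) idx = 1;
      if (idx > m) idx = m;
      return idx - 1;
    };
    double q1 = counts[qidx(0.25)] / expected_coverage;
    double q2 = counts[qidx(0.50)] / expected_coverage;
    double q3 = counts[qidx(0.75)] / expected_coverage;
    int n_over = 0, n_single = 0;
    for (int c : counts) {
      if (c / expected_coverage > thresh) ++n_over;
      if (c == 1) ++n_single;
    }
    out(i, 0) = q1;
    out(i, 1) = q2;
    out(i, 2) = q3;
    out(i, 3) = (double)n_over / m;
    out(i, 4) = n_single;
    out(i, 5) = m;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Banded pairwise alignment
// ---------------------------------------------------------------------------

enum AlnMode { MODE_GLOBAL = 0, MODE_OVERLAP = 1, MODE_FITTING = 2 };

struct AlnResult {
  int score = NEG_INF;
  int matches = 0, mismatches = 0, gap_events = 0, gap_bases = 0, columns = 0;
  int i0 = 0, j0 = 0, i1 = 0, j1 = 0;
  bool band_edge = false;
  bool ok = false;
};

// s1 indexed by i (rows), s2 by j (cols); band: |j - i - center| <= w.
static AlnResult banded_align(const std::string& s1, const std::string& s2,
                              int center, int w, int mode) {
  const int m = (int)s1.size(), n = (int)s2.size();
  const int width = 2 * w + 1;
  AlnResult res;
  std::vector<int> prev(width, NEG_INF), cur(width, NEG_INF);
  std::vector<signed char> tb((size_t)(m + 1) * width, 0);
  auto jlo = [&](int i) { return std::max(0, i + center - w); };
  auto jhi = [&](int i) { return std::min(n, i + center + w); };
  auto tcol = [&](int i, int j) { return j - (i + center - w); };

  // row 0 (its band slice may be empty when the offset is large; paths
  // then start at a free first-column cell instead)
  {
    int lo = jlo(0), hi = jhi(0);
    for (int j = lo; j <= hi; ++j) {
      int t = tcol(0, j);
      if (mode == MODE_GLOBAL)
        prev[t] = SC_GAP * j;
      else
        prev[t] = 0;  // free leading gap in s2 (start at (0, j))
    }
  }
  int best = NEG_INF, best_i = -1, best_j = -1;
  if (mode != MODE_GLOBAL) {
    // path may end on row 0 only degenerately; ignore (columns filter later)
  }
  for (int i = 1; i <= m; ++i) {
    int lo = jlo(i), hi = jhi(i);
    std::fill(cur.begin(), cur.end(), NEG_INF);
    if (lo > hi) { prev.swap(cur); continue; }
    for (int j = lo; j <= hi; ++j) {
      int t = tcol(i, j);
      int sc = NEG_INF;
      signed char dir = 0;
      if (j == 0) {
        // first column
        if (mode == MODE_OVERLAP) {
          sc = 0;
          dir = 0;
        } else {
          sc = SC_GAP * i;
          dir = 4;  // implicit run of up-moves; traceback stops via dir 4
        }
      }
      // diagonal from (i-1, j-1): same t in prev
      if (j >= 1) {
        int pd = prev[t];  // tcol(i-1, j-1) == tcol(i, j)
        if (pd > NEG_INF / 2) {
          int s = pd + (s1[i - 1] == s2[j - 1] ? SC_MATCH : SC_MISMATCH);
          if (s > sc) { sc = s; dir = 1; }
        }
      }
      // up from (i-1, j): tcol(i-1, j) = t + 1
      if (t + 1 < width) {
        int pu = prev[t + 1];
        if (pu > NEG_INF / 2) {
          int s = pu + SC_GAP;
          if (s > sc) { sc = s; dir = 2; }
        }
      }
      // left from (i, j-1): tcol(i, j-1) = t - 1
      if (t - 1 >= 0) {
        int pl = cur[t - 1];
        if (pl > NEG_INF / 2) {
          int s = pl + SC_GAP;
          if (s > sc) { sc = s; dir = 3; }
        }
      }
      cur[t] = sc;
      tb[(size_t)i * width + t] = dir;
      bool at_end = false;
      if (mode == MODE_GLOBAL) at_end = (i == m && j == n);
      else if (mode == MODE_FITTING) at_end = (i == m);
      else at_end = (i == m || j == n);
      if (at_end && sc > best) {
        best = sc;
        best_i = i;
        best_j = j;
      }
    }
    prev.swap(cur);
  }
  if (best_i < 0) return res;
  // traceback
  int i = best_i, j = best_j;
  int matches = 0, mismatches = 0, gap_events = 0, gap_bases = 0, columns = 0;
  signed char last_gap = 0;
  bool touched = false;
  while (true) {
    if (i == 0) break;
    int t = tcol(i, j);
    if (t == 0 || t == width - 1) {
      // on the band boundary (unless clamped by sequence ends)
      if (j > 0 && j < n) touched = true;
    }
    signed char dir = tb[(size_t)i * width + t];
    if (dir == 0) break;
    if (dir == 4) {
      // leading gap in s1's partner: i up-moves to (0, j)
      gap_bases += i;
      gap_events += 1;
      columns += i;
      i = 0;
      break;
    }
    if (dir == 1) {
      if (s1[i - 1] == s2[j - 1]) ++matches; else ++mismatches;
      --i; --j;
      ++columns;
      last_gap = 0;
    } else if (dir == 2) {
      ++gap_bases;
      if (last_gap != 2) ++gap_events;
      last_gap = 2;
      --i;
      ++columns;
    } else {
      ++gap_bases;
      if (last_gap != 3) ++gap_events;
      last_gap = 3;
      --j;
      ++columns;
    }
  }
  res.score = best;
  res.matches = matches;
  res.mismatches = mismatches;
  res.gap_events = gap_events;
  res.gap_bases = gap_bases;
  res.columns = columns;
  res.i0 = i;
  res.j0 = j;
  res.i1 = best_i;
  res.j1 = best_j;
  res.band_edge = touched;
  res.ok = true;
  return res;
}

// Retry with doubled band until the optimum no longer touches the band edge.
static AlnResult align_retry(const std::string& s1, const std::string& s2,
                             int center, int w, int mode) {
  const int m = (int)s1.size(), n = (int)s2.size();
  const int wmax = m + n + 2;
  AlnResult res;
  while (true) {
    res = banded_align(s1, s2, center, w, mode);
    if (res.ok && !res.band_edge) return res;
    if (w >= wmax) return res;
    w = std::min(2 * w, wmax);
  }
}

static List aln_to_list(const AlnResult& r) {
  return List::create(
      _["score"] = r.score, _["matches"] = r.matches,
      _["mismatches"] = r.mismatches, _["gap_events"] = r.gap_events,
      _["gap_bases"] = r.gap_bases, _["columns"] = r.columns, _["i0"] = r.i0,
      _["j0"] = r.j0, _["i1"] = r.i1, _["j1"] = r.j1, _["ok"] = r.ok);
}

// Global alignment of two (sub)sequences.
// [[Rcpp::export]]
List cpp_align_global(std::string a, std::string b, int band) {
  int center = ((int)b.size() - (int)a.size()) / 2;
  AlnResult r = align_retry(a, b, center, std::max(band, std::abs(center) + 4),
                            MODE_GLOBAL);
  return aln_to_list(r);
}

// Ends-free (dovetail/containment) alignment of full reads at a seed offset.
// offset = start of b in a's frame (may be negative).
// [[Rcpp::export]]
List cpp_align_overlap(std::string a, std::string b, int offset, int band) {
  AlnResult r = align_retry(a, b, -offset, band, MODE_OVERLAP);
  return aln_to_list(r);
}

// ---------------------------------------------------------------------------
// Overlap candidate detection
// ---------------------------------------------------------------------------

struct SeedOcc {
  int32_t read;
  int32_t pos;
  uint8_t fwd_canon;
};

// [[Rcpp::export]]
List cpp_find_overlaps(CharacterVector reads, int seed_k, int min_olap,
                       double max_error, int band, int max_bucket) {
  const int nreads = (int)reads.size();
  std::vector<std::string> seq(nreads), seq_rc(nreads);
  for (int i = 0; i < nreads; ++i) {
    seq[i] = as<std::string>(reads[i]);
    seq_rc[i] = revcomp_str(seq[i]);
  }
  // seed index
  std::unordered_map<uint64_t, std::vector<SeedOcc>> index;
  index.reserve(1 << 20);
  for (int r = 0; r < nreads; ++r) {
    for_each_kmer(seq[r], seed_k,
                  [&](int pos, uint64_t, uint64_t canon, bool fwd_can) {
                    index[canon].push_back(
                        {(int32_t)r, (int32_t)pos, (uint8_t)(fwd_can ? 1 : 0)});
                  });
  }
  // pair -> offsets (A = smaller read index, forward; B oriented)
  std::unordered_map<uint64_t, std::vector<int32_t>> pair_offsets;
  pair_offsets.reserve(1 << 18);
  for (const auto& kv : index) {
    const auto& occ = kv.second;
    const int sz = (int)occ.size();
    if (sz < 2 || sz > max_bucket) continue;
    for (int x = 0; x < sz; ++x) {
      for (int y = x + 1; y < sz; ++y) {
        const SeedOcc &o1 = occ[x], &o2 = occ[y];
        if (o1.read == o2.read) continue;
        const SeedOcc& a = (o1.read < o2.read) ? o1 : o2;
        const SeedOcc& b = (o1.read < o2.read) ? o2 : o1;
        int orient = (a.fwd_canon == b.fwd_canon) ? 0 : 1;
        int offset;
        if (orient == 0) {
          offset = a.pos - b.pos;
        } else {
          int bpos_rc = (int)seq[b.read].size() - seed_k - b.pos;
          offset = a.pos - bpos_rc;
        }
        uint64_t key =
            (((uint64_t)a.read * (uint64_t)nreads + (uint64_t)b.read) << 1) |
            (uint64_t)orient;
        pair_offsets[key].push_back(offset);
      }
    }
  }
  // evaluate candidates
  std::vector<int> out_a, out_b, out_orient, out_ah, out_bh, out_len, out_match,
      out_mm, out_ge, out_gb, out_score;
  const int cluster_gap = std::max(band, 4);
  std::vector<uint64_t> keys;
  keys.reserve(pair_offsets.size());
  for (const auto& kv : pair_offsets) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  for (uint64_t key : keys) {
    std::vector<int32_t>& offs = pair_offsets[key];
    int orient = (int)(key & 1ULL);
    uint64_t pk = key >> 1;
    int ai = (int)(pk / (uint64_t)nreads);
    int bi = (int)(pk % (uint64_t)nreads);
    const std::string& A = seq[ai];
    const std::string& B = (orient == 0) ? seq[bi] : seq_rc[bi];
    std::sort(offs.begin(), offs.end());
    AlnResult best;
    int best_ah = 0, best_bh = 0;
    bool have = false;
    size_t s = 0;
    while (s < offs.size()) {
      size_t e = s + 1;
      while (e < offs.size() && offs[e] - offs[e - 1] <= cluster_gap) ++e;
      // modal offset of the cluster
      int mode_off = offs[s], mode_n = 0;
      size_t t = s;
      while (t < e) {
        size_t u = t + 1;
        while (u < e && offs[u] == offs[t]) ++u;
        if ((int)(u - t) > mode_n) {
          mode_n = (int)(u - t);
          mode_off = offs[t];
        }
        t = u;
      }
      s = e;
      // implied overlap length must be able to reach min_olap
      int implied = std::min((int)A.size(), mode_off + (int)B.size()) -
                    std::max(mode_off, 0);
      if (implied < min_olap - band) continue;
      AlnResult r = align_retry(A, B, -mode_off, band, MODE_OVERLAP);
      if (!r.ok || r.columns < min_olap) continue;
      if ((double)(r.mismatches + r.gap_bases) >
          max_error * (double)r.columns + 1e-9)
        continue;
      int ah = r.i0 - r.j0;
      int bh = ((int)B.size() - r.j1) - ((int)A.size() - r.i1);
      bool better = false;
      if (!have) better = true;
      else if (r.score != best.score) better = r.score > best.score;
      else if (std::abs(ah) != std::abs(best_ah))
        better = std::abs(ah) < std::abs(best_ah);
      else better = r.gap_events < best.gap_events;
      if (better) {
        best = r;
        best_ah = ah;
        best_bh = bh;
        have = true;
      }
    }
    if (have) {
      out_a.push_back(ai + 1);
      out_b.push_back(bi + 1);
      out_orient.push_back(orient);
      out_ah.push_back(best_ah);
      out_bh.push_back(best_bh);
      out_len.push_back(best.columns);
      out_match.push_back(best.matches);
      out_mm.push_back(best.mismatches);
      out_ge.push_back(best.gap_events);
      out_gb.push_back(best.gap_bases);
      out_score.push_back(best.score);
    }
  }
  return List::create(
      _["readA"] = out_a, _["readB"] = out_b, _["orient"] = out_orient,
      _["a_hang"] = out_ah, _["b_hang"] = out_bh, _["overlap_length"] = out_len,
      _["matches"] = out_match, _["mismatches"] = out_mm,
      _["gap_events"] = out_ge, _["gap_bases"] = out_gb,
      _["score"] = out_score);
}

// ---------------------------------------------------------------------------
// Read-to-genome mapping (seed + banded fitting alignment)
// ---------------------------------------------------------------------------

struct Hit {
  int read;
  int start, end;  // 0-based half-open, genome forward frame
  int strand;      // 0 = '+', 1 = '-'
  int matches, columns;
};

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, std::string genome, int mersize,
                        double min_identity, double min_coverage, int band,
                        int max_clusters, int max_bucket) {
  const int GL = (int)genome.size();
  // genome seed index: canonical kmer -> (pos, strand of canonical match)
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, uint8_t>>> gindex;
  gindex.reserve(1 << 20);
  for_each_kmer(genome, mersize,
                [&](int pos, uint64_t, uint64_t canon, bool fwd_can) {
                  gindex[canon].push_back(
                      {(int32_t)pos, (uint8_t)(fwd_can ? 1 : 0)});
                });
  std::vector<Hit> hits;
  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    const int LR = (int)rd.size();
    if (LR == 0) continue;
    std::string rd_rc = revcomp_str(rd);
    // diag votes per strand
    std::vector<std::pair<int, int>> diags[2];  // (diag, 1) entries
    for_each_kmer(rd, mersize,
                  [&](int pos, uint64_t, uint64_t canon, bool fwd_can) {
                    auto it = gindex.find(canon);
                    if (it == gindex.end()) return;
                    if ((int)it->second.size() > max_bucket) return;
                    for (const auto& g : it->second) {
                      int strand = (g.second == (uint8_t)(fwd_can ? 1 : 0)) ? 0 : 1;
                      int p = (strand == 0) ? pos : (LR - mersize - pos);
                      diags[strand].push_back({(int)g.first - p, 1});
                    }
                  });
    for (int strand = 0; strand < 2; ++strand) {
      auto& dv = diags[strand];
      if (dv.empty()) continue;
      std::sort(dv.begin(), dv.end());
      // cluster by diagonal
      struct Cluster { int diag; int votes; };
      std::vector<Cluster> clusters;
      size_t s = 0;
      while (s < dv.size()) {
        size_t e = s + 1;
        while (e < dv.size() && dv[e].first - dv[e - 1].first <= band) ++e;
        // modal diag
        int mode_d = dv[s].first, mode_n = 0;
        size_t t = s;
        while (t < e) {
          size_t u = t + 1;
          while (u < e && dv[u].first == dv[t].first) ++u;
          if ((int)(u - t) > mode_n) {
            mode_n = (int)(u - t);
            mode_d = dv[t].first;
          }
          t = u;
        }
        clusters.push_back({mode_d, (int)(e - s)});
        s = e;
      }
      std::sort(clusters.begin(), clusters.end(),
                [](const Cluster& a, const Cluster& b) {
                  return a.votes > b.votes;
                });
      if ((int)clusters.size() > max_clusters) clusters.resize(max_clusters);
      const std::string& query = (strand == 0) ? rd : rd_rc;
      for (const auto& cl : clusters) {
        int gw_start = std::max(0, cl.diag - band);
        int gw_end = std::min(GL, cl.diag + LR + band);
        if (gw_end - gw_start < mersize) continue;
        std::string window = genome.substr(gw_start, gw_end - gw_start);
        int center = cl.diag - gw_start;
        AlnResult r = align_retry(query, window, center, band, MODE_FITTING);
        if (!r.ok || r.columns == 0) continue;
        double identity = (double)r.matches / (double)r.columns;
        double coverage = (double)(r.i1 - r.i0) / (double)LR;
        if (identity + 1e-12 < min_identity || coverage + 1e-12 < min_coverage)
          continue;
        hits.push_back({(int)ri + 1, gw_start + r.j0, gw_start + r.j1, strand,
                        r.matches, r.columns});
      }
    }
  }
  // dedup: same read/strand, heavily-overlapping intervals keep best matches
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    if (a.read != b.read) return a.read < b.read;
    if (a.strand != b.strand) return a.strand < b.strand;
    if (a.matches != b.matches) return a.matches > b.matches;
    return a.start < b.start;
  });
  std::vector<Hit> kept;
  for (const auto& h : hits) {
    bool dup = false;
    for (auto it = kept.rbegin(); it != kept.rend(); ++it) {
      if (it->read != h.read || it->strand != h.strand) break;
      int inter = std::min(it->end, h.end) - std::max(it->start, h.start);
      int shorter = std::min(it->end - it->start, h.end - h.start);
      if (shorter > 0 && inter * 2 > shorter) {
        dup = true;
        break;
      }
    }
    if (!dup) kept.push_back(h);
  }
  const size_t n = kept.size();
  IntegerVector read(n), start(n), end(n), matches(n), columns(n);
  CharacterVector strand(n);
  NumericVector identity(n), coverage(n);
  for (size_t i = 0; i < n; ++i) {
    const Hit& h = kept[i];
    read[i] = h.read;
    start[i] = h.start;
    end[i] = h.end;
    strand[i] = h.strand == 0 ? "+" : "-";
    matches[i] = h.matches;
    columns[i] = h.columns;
    identity[i] = (double)h.matches / (double)h.columns;
    coverage[i] = 1.0;
  }
  return DataFrame::create(_["read"] = read, _["start"] = start,
                           _["end"] = end, _["strand"] = strand,
                           _["matches"] = matches, _["columns"] = columns,
                           _["identity"] = identity, _["coverage"] = coverage,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Layout consensus: realign reads to a spliced draft and vote per column
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
std::string cpp_consensus(std::string draft, CharacterVector reads,
                          IntegerVector offsets, int band) {
  const int DL = (int)draft.size();
  // votes[5] per column: A C G T + deletion
  std::vector<std::array<int, 5>> votes(DL, {0, 0, 0, 0, 0});
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    const int LR = (int)rd.size();
    int off = offsets[r];
    int w0 = std::max(0, off - band);
    int w1 = std::min(DL, off + LR + band);
    if (w1 - w0 < 1) continue;
    std::string window = draft.substr(w0, w1 - w0);
    AlnResult res = align_retry(rd, window, off - w0, band, MODE_FITTING);
    if (!res.ok) continue;
    // second pass traceback to vote
    // (re-run alignment tracking the path explicitly)
    // reuse banded_align internals via a simple re-trace: align again with
    // same parameters and walk the traceback recording column moves.
    // To avoid duplicating code, we redo the DP here inline.
    const std::string& s1 = rd;
    const std::string& s2 = window;
    const int m = (int)s1.size(), n = (int)s2.size();
    int center = off - w0;
    int w = band;
    // grow band as align_retry would have
    while (true) {
      AlnResult probe = banded_align(s1, s2, center, w, MODE_FITTING);
      if (probe.ok && !probe.band_edge) break;
      if (w >= m + n + 2) break;
      w = std::min(2 * w, m + n + 2);
    }
    const int width = 2 * w + 1;
    std::vector<int> prev(width, NEG_INF), cur(width, NEG_INF);
    std::vector<signed char> tb((size_t)(m + 1) * width, 0);
    auto jlo = [&](int i) { return std::max(0, i + center - w); };
    auto jhi = [&](int i) { return std::min(n, i + center + w); };
    auto tcolf = [&](int i, int j) { return j - (i + center - w); };
    {
      int lo = jlo(0), hi = jhi(0);
      for (int j = lo; j <= hi; ++j) prev[tcolf(0, j)] = 0;
    }
    int best = NEG_INF, bi = -1, bj = -1;
    for (int i = 1; i <= m; ++i) {
      int lo = jlo(i), hi = jhi(i);
      std::fill(cur.begin(), cur.end(), NEG_INF);
      if (lo > hi) { prev.swap(cur); continue; }
      for (int j = lo; j <= hi; ++j) {
        int t = tcolf(i, j);
        int sc = NEG_INF;
        signed char dir = 0;
        if (j == 0) { sc = SC_GAP * i; dir = 4; }
        if (j >= 1) {
          int pd = prev[t];
          if (pd > NEG_INF / 2) {
            int s = pd + (s1[i - 1] == s2[j - 1] ? SC_MATCH : SC_MISMATCH);
            if (s > sc) { sc = s; dir = 1; }
          }
        }
        if (t + 1 < width) {
          int pu = prev[t + 1];
          if (pu > NEG_INF / 2) {
            int s = pu + SC_GAP;
            if (s > sc) { sc = s; dir = 2; }
          }
        }
        if (t - 1 >= 0) {
          int pl = cur[t - 1];
          if (pl > NEG_INF / 2) {
            int s = pl + SC_GAP;
            if (s > sc) { sc = s; dir = 3; }
          }
        }
        cur[t] = sc;
        tb[(size_t)i * width + t] = dir;
        if (i == m && sc > best) { best = sc; bi = i; bj = j; }
      }
      prev.swap(cur);
    }
    if (bi < 0) continue;
    int i = bi, j = bj;
    while (i > 0) {
      signed char dir = tb[(size_t)i * width + tcolf(i, j)];
      if (dir == 0 || dir == 4) break;
      if (dir == 1) {
        int col = w0 + j - 1;
        int b = base2bit(s1[i - 1]);
        if (b >= 0 && col >= 0 && col < DL) votes[col][b] += 1;
        --i; --j;
      } else if (dir == 2) {
        --i;  // insertion in read: no draft column
      } else {
        int col = w0 + j - 1;
        if (col >= 0 && col < DL) votes[col][4] += 1;  // deletion vote
        --j;
      }
    }
  }
  std::string out;
  out.reserve(DL);
  for (int c = 0; c < DL; ++c) {
    const auto& v = votes[c];
    int tot = v[0] + v[1] + v[2] + v[3];
    if (v[4] > tot) continue;  // majority deletes this column
    if (tot == 0) { out.push_back(draft[c]); continue; }
    int bestb = 0;
    for (int b = 1; b < 4; ++b)
      if (v[b] > v[bestb]) bestb = b;
    out.push_back(BIT2BASE[bestb]);
  }
  return out;
}
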
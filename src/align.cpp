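// Edit-distance alignment kernels shared by the panel aligner, the read
// mapper, the repeat profiler and the pair merger. All costs are unit
// (match 0, mismatch 1, indel 1); traceback preference is diagonal, then
// read-gap, then reference-gap, which makes every result deterministic.
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <climits>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    out[i] = revcomp_str(as<std::string>(x[i]));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Banded global alignment (Needleman-Wunsch, unit costs). The band is wide
// enough for any length difference so a path always exists; alignments whose
// optimum leaves the band are still valid, just capped at the band edge.
// ---------------------------------------------------------------------------

struct GlobalAln { std::string a_aln, b_aln; int edits; };

static GlobalAln global_banded(const std::string& a, const std::string& b, int band) {
  const int m = (int)a.size(), n = (int)b.size();
  const int d = n - m;
  const int lo = std::min(0, d) - band;
  const int hi = std::max(0, d) + band;
  const int W = hi - lo + 1;
  const int INF = INT_MAX / 4;
  std::vector<int> D((size_t)(m + 1) * W, INF);
  std::vector<uint8_t> T((size_t)(m + 1) * W, 0); // 1 diag, 2 up (gap in b), 3 left (gap in a)
  auto idx = [&](int i, int j) { return (size_t)i * W + (size_t)(j - i - lo); };
  auto valid = [&](int i, int j) {
    int o = j - i; return j >= 0 && j <= n && o >= lo && o <= hi;
  };
  for (int j = 0; j <= n && valid(0, j); ++j) { D[idx(0, j)] = j; T[idx(0, j)] = 3; }
  T[idx(0, 0)] = 0;
  for (int i = 1; i <= m; ++i) {
    const int jlo = std::max(0, i + lo), jhi = std::min(n, i + hi);
    for (int j = jlo; j <= jhi; ++j) {
      int best = INF; uint8_t tb = 0;
      if (j > 0 && valid(i - 1, j - 1) && D[idx(i - 1, j - 1)] < INF) {
        int v = D[idx(i - 1, j - 1)] + (a[i - 1] != b[j - 1] ? 1 : 0);
        if (v < best) { best = v; tb = 1; }
      }
      if (valid(i - 1, j) && D[idx(i - 1, j)] < INF) {
        int v = D[idx(i - 1, j)] + 1;
        if (v < best) { best = v; tb = 2; }
      }
      if (j > 0 && valid(i, j - 1) && D[idx(i, j - 1)] < INF) {
        int v = D[idx(i, j - 1)] + 1;
        if (v < best) { best = v; tb = 3; }
      }
      D[idx(i, j)] = best; T[idx(i, j)] = tb;
    }
  }
  GlobalAln res;
  res.edits = D[idx(m, n)];
  std::string ra, rb;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    uint8_t tb = T[idx(i, j)];
    if (tb == 1)      { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j; }
    else if (tb == 2) { ra.push_back(a[i - 1]); rb.push_back('-');     --i; }
    else              { ra.push_back('-');      rb.push_back(b[j - 1]); --j; }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  res.a_aln = ra; res.b_aln = rb;
  return res;
}

// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b, int band) {
  GlobalAln g = global_banded(a, b, band);
  return List::create(_["a_aln"] = g.a_aln, _["b_aln"] = g.b_aln,
                      _["edits"] = g.edits);
}

// Batched gap closure between collinear anchor matches: pair i aligned with
// band 2*|len difference| + extra.
// [[Rcpp::export]]
List cpp_align_segment_pairs(CharacterVector a_segs, CharacterVector b_segs, int extra) {
  R_xlen_t n = a_segs.size();
  CharacterVector a_aln(n), b_aln(n);
  IntegerVector edits(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string a = as<std::string>(a_segs[i]);
    std::string b = as<std::string>(b_segs[i]);
    if (a.empty() && b.empty()) { a_aln[i] = ""; b_aln[i] = ""; edits[i] = 0; continue; }
    int band = 2 * std::abs((int)a.size() - (int)b.size()) + extra;
    GlobalAln g = global_banded(a, b, band);
    a_aln[i] = g.a_aln; b_aln[i] = g.b_aln; edits[i] = g.edits;
  }
  return List::create(_["a_aln"] = a_aln, _["b_aln"] = b_aln, _["edits"] = edits);
}

// ---------------------------------------------------------------------------
// Semi-global alignment: the read is aligned end-to-end, reference end gaps
// are free. Full dynamic programming over the supplied reference window.
// ---------------------------------------------------------------------------

struct SemiAln { int start0, end0, edits, nm; std::string cigar; };

// Edits are minimised first; among co-optimal paths the gap count is
// minimised (lexicographic DP). Terminal mismatches therefore stay aligned
// instead of drifting into co-optimal indels, which matters when the
// mismatch IS the signal (terminal deamination).
static SemiAln semiglobal(const std::string& q, const std::string& r) {
  const int m = (int)q.size(), n = (int)r.size();
  std::vector<int> D((size_t)(m + 1) * (n + 1));
  std::vector<int> G((size_t)(m + 1) * (n + 1));
  std::vector<uint8_t> T((size_t)(m + 1) * (n + 1), 0);
  auto id = [&](int i, int j) { return (size_t)i * (n + 1) + j; };
  for (int j = 0; j <= n; ++j) { D[id(0, j)] = 0; G[id(0, j)] = 0; T[id(0, j)] = 0; }
  for (int i = 1; i <= m; ++i) {
    D[id(i, 0)] = i; G[id(i, 0)] = i; T[id(i, 0)] = 2;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int bd = D[id(i - 1, j - 1)] + (q[i - 1] != r[j - 1] ? 1 : 0);
      int bg = G[id(i - 1, j - 1)];
      uint8_t tb = 1;
      int vd = D[id(i - 1, j)] + 1, vg = G[id(i - 1, j)] + 1;
      if (vd < bd || (vd == bd && vg < bg)) { bd = vd; bg = vg; tb = 2; }
      vd = D[id(i, j - 1)] + 1; vg = G[id(i, j - 1)] + 1;
      if (vd < bd || (vd == bd && vg < bg)) { bd = vd; bg = vg; tb = 3; }
      D[id(i, j)] = bd; G[id(i, j)] = bg; T[id(i, j)] = tb;
    }
  }
  int bj = 0, bv = INT_MAX, bgaps = INT_MAX;
  for (int j = 0; j <= n; ++j) {
    int v = D[id(m, j)], g = G[id(m, j)];
    if (v < bv || (v == bv && g < bgaps)) { bv = v; bgaps = g; bj = j; }
  }
  // traceback
  std::vector<std::pair<char, int> > runs;
  auto push_op = [&](char op) {
    if (!runs.empty() && runs.back().first == op) runs.back().second++;
    else runs.push_back(std::make_pair(op, 1));
  };
  int i = m, j = bj, nm = 0;
  while (i > 0) {
    uint8_t tb = T[id(i, j)];
    if (tb == 1)      { if (q[i - 1] != r[j - 1]) ++nm; push_op('M'); --i; --j; }
    else if (tb == 2) { push_op('I'); --i; }
    else              { push_op('D'); --j; }
  }
  std::string cig;
  for (int k = (int)runs.size() - 1; k >= 0; --k)
    cig += std::to_string(runs[k].second) + runs[k].first;
  SemiAln res; res.start0 = j; res.end0 = bj; res.edits = bv; res.nm = nm; res.cigar = cig;
  return res;
}

// [[Rcpp::export]]
List cpp_semiglobal(std::string read, std::string ref) {
  if (read.empty() || ref.empty())
    stop("semiglobal alignment needs non-empty read and reference");
  double cells = (double)(read.size() + 1) * (double)(ref.size() + 1);
  if (cells > 8e7) stop("semiglobal window too large (%d x %d)",
                        (int)read.size(), (int)ref.size());
  SemiAln s = semiglobal(read, ref);
  return List::create(_["start"] = s.start0 + 1, _["end"] = s.end0,
                      _["edits"] = s.edits, _["nm"] = s.nm,
                      _["cigar"] = s.cigar);
}

// ---------------------------------------------------------------------------
// Seeded read mapping against a single reference: exact k-mer seeds vote on
// diagonals, candidate windows are resolved by semi-global DP, both strands
// are tried, ties between distinct loci flag the read as ambiguous.
// ---------------------------------------------------------------------------

static bool encode_kmer(const std::string& s, int pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    uint64_t c;
    switch (s[pos + i]) {
    case 'A': c = 0; break; case 'C': c = 1; break;
    case 'G': c = 2; break; case 'T': c = 3; break;
    default: return false;
    }
    v = (v << 2) | c;
  }
  out = v;
  return true;
}

struct Candidate { int strand, start, end, edits, nm; std::string cigar; };

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, std::string ref, int seedk, int pad,
                   int max_candidates) {
  const int n = (int)ref.size();
  if (seedk < 8 || seedk > 31) stop("seedk must be in [8, 31]");
  std::unordered_map<uint64_t, std::vector<int> > index;
  if (n >= seedk) {
    index.reserve((size_t)n * 2);
    for (int p = 0; p + seedk <= n; ++p) {
      uint64_t v;
      if (encode_kmer(ref, p, seedk, v)) index[v].push_back(p);
    }
  }
  R_xlen_t nr = reads.size();
  LogicalVector mapped(nr), ambiguous(nr);
  IntegerVector start(nr), end(nr), edits(nr), nm(nr);
  CharacterVector strand(nr), cigar(nr), seq_aln(nr);
  for (R_xlen_t ri = 0; ri < nr; ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    int len = (int)fwd.size();
    mapped[ri] = false; ambiguous[ri] = false;
    start[ri] = NA_INTEGER; end[ri] = NA_INTEGER;
    edits[ri] = NA_INTEGER; nm[ri] = NA_INTEGER;
    strand[ri] = NA_STRING; cigar[ri] = NA_STRING; seq_aln[ri] = NA_STRING;
    if (len < seedk || n < seedk) continue;
    std::string rc = revcomp_str(fwd);
    std::vector<Candidate> cands;
    for (int st = 0; st < 2; ++st) {
      const std::string& q = (st == 0) ? fwd : rc;
      int step = std::max(1, (len - seedk) / 7);
      std::vector<int> diags;
      for (int p = 0; p + seedk <= len; p += step) {
        uint64_t v;
        if (!encode_kmer(q, p, seedk, v)) continue;
        auto it = index.find(v);
        if (it == index.end()) continue;
        if (it->second.size() > 64) continue; // highly repetitive seed
        for (int rp : it->second) diags.push_back(rp - p);
      }
      { // ensure terminal seed is tried too
        int p = len - seedk;
        uint64_t v;
        if (p > 0 && encode_kmer(q, p, seedk, v)) {
          auto it = index.find(v);
          if (it != index.end() && it->second.size() <= 64)
            for (int rp : it->second) diags.push_back(rp - p);
        }
      }
      if (diags.empty()) continue;
      std::sort(diags.begin(), diags.end());
      // cluster diagonals within pad
      struct Clu { int dmin, dmax, votes; };
      std::vector<Clu> clus;
      for (size_t t = 0; t < diags.size(); ++t) {
        if (!clus.empty() && diags[t] - clus.back().dmax <= pad &&
            diags[t] - clus.back().dmin <= pad) {
          clus.back().dmax = diags[t]; clus.back().votes++;
        } else {
          Clu c; c.dmin = diags[t]; c.dmax = diags[t]; c.votes = 1;
          clus.push_back(c);
        }
      }
      std::stable_sort(clus.begin(), clus.end(),
                       [](const Clu& a, const Clu& b) { return a.votes > b.votes; });
      int ncand = std::min((int)clus.size(), max_candidates);
      for (int ci = 0; ci < ncand; ++ci) {
        int ws = std::max(0, clus[ci].dmin - pad);
        int we = std::min(n, clus[ci].dmax + len + pad);
        if (we - ws < seedk) continue;
        SemiAln s = semiglobal(q, ref.substr(ws, we - ws));
        Candidate c;
        c.strand = st; c.start = ws + s.start0; c.end = ws + s.end0;
        c.edits = s.edits; c.nm = s.nm; c.cigar = s.cigar;
        cands.push_back(c);
      }
    }
    if (cands.empty()) continue;
    // dedupe identical loci, keep best score per locus
    std::sort(cands.begin(), cands.end(), [](const Candidate& a, const Candidate& b) {
      if (a.strand != b.strand) return a.strand < b.strand;
      if (a.start != b.start) return a.start < b.start;
      return a.edits < b.edits;
    });
    std::vector<Candidate> uniq;
    for (auto& c : cands) {
      if (!uniq.empty() && uniq.back().strand == c.strand && uniq.back().start == c.start)
        continue;
      uniq.push_back(c);
    }
    int best = 0;
    for (int t = 1; t < (int)uniq.size(); ++t)
      if (uniq[t].edits < uniq[best].edits) best = t;
    bool amb = false;
    for (int t = 0; t < (int)uniq.size(); ++t)
      if (t != best && uniq[t].edits == uniq[best].edits) amb = true;
    const Candidate& c = uniq[best];
    mapped[ri] = true; ambiguous[ri] = amb;
    start[ri] = c.start + 1; end[ri] = c.end;
    edits[ri] = c.edits; nm[ri] = c.nm;
    strand[ri] = (c.strand == 0) ? "+" : "-";
    cigar[ri] = c.cigar;
    seq_aln[ri] = (c.strand == 0) ? fwd : rc;
  }
  return List::create(_["mapped"] = mapped, _["strand"] = strand,
                      _["start"] = start, _["end"] = end, _["edits"] = edits,
                      _["nm"] = nm, _["cigar"] = cigar,
                      _["ambiguous"] = ambiguous, _["seq_aln"] = seq_aln);
}

// ---------------------------------------------------------------------------
// Paired-end merging. Adapter read-through is trimmed by exact adapter match
// (full adapter anywhere, or an adapter prefix of >= 5 bp flush with the read
// end); overlaps are then scanned longest-first in the standard orientation
// and, failing that, in read-through orientation. Mate 1 wins base conflicts
// (qualities are flat in this data model).
// ---------------------------------------------------------------------------

static std::string trim_adapter(const std::string& s, const std::string& ad, bool& trimmed) {
  trimmed = false;
  size_t pos = s.find(ad);
  if (pos != std::string::npos) { trimmed = true; return s.substr(0, pos); }
  int L = (int)s.size(), A = (int)ad.size();
  int maxl = std::min(L, A - 1);
  for (int l = maxl; l >= 5; --l) {
    if (s.compare(L - l, l, ad, 0, l) == 0) { trimmed = true; return s.substr(0, L - l); }
  }
  return s;
}

static int count_mismatch(const std::string& a, int ai, const std::string& b, int bi, int len) {
  int mm = 0;
  for (int i = 0; i < len; ++i) if (a[ai + i] != b[bi + i]) ++mm;
  return mm;
}

// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector m1, CharacterVector m2, std::string adapter,
                     int min_overlap, double max_mismatch_frac) {
  if (m1.size() != m2.size()) stop("mate vectors differ in length");
  if ((int)adapter.size() < 5) stop("adapter must be at least 5 bp");
  R_xlen_t np = m1.size();
  CharacterVector status(np), merged(np);
  IntegerVector overlap(np);
  for (R_xlen_t i = 0; i < np; ++i) {
    std::string r1 = as<std::string>(m1[i]);
    std::string r2 = as<std::string>(m2[i]);
    bool t1f, t2f;
    std::string t1 = trim_adapter(r1, adapter, t1f);
    std::string t2 = trim_adapter(r2, adapter, t2f);
    if (t1f && t2f && (t1.empty() || t2.empty())) {
      status[i] = "empty"; merged[i] = NA_STRING; overlap[i] = 0;
      continue;
    }
    std::string rc2 = revcomp_str(t2);
    int L1 = (int)t1.size(), L2 = (int)rc2.size();
    std::string out; int ov = 0;
    bool ok = false;
    // both adapters seen: definite read-through, insert = trimmed length
    if (t1f && t2f && L1 == L2 &&
        count_mismatch(t1, 0, rc2, 0, L1) <= max_mismatch_frac * L1) {
      out = t1; ov = L1; ok = true;
    }
    // standard orientation: suffix of mate 1 over prefix of rc(mate 2)
    if (!ok)
    for (int o = std::min(L1, L2); o >= min_overlap; --o) {
      if (count_mismatch(t1, L1 - o, rc2, 0, o) <= max_mismatch_frac * o) {
        out = t1 + rc2.substr(o); ov = o; ok = true; break;
      }
    }
    // read-through orientation: prefix of mate 1 over suffix of rc(mate 2)
    if (!ok) {
      for (int o = std::min(L1, L2); o >= min_overlap; --o) {
        if (count_mismatch(t1, 0, rc2, L2 - o, o) <= max_mismatch_frac * o) {
          out = t1.substr(0, o); ov = o; ok = true; break;
        }
      }
    }
    if (ok) { status[i] = "merged"; merged[i] = out; overlap[i] = ov; }
    else    { status[i] = "unmerged"; merged[i] = NA_STRING; overlap[i] = 0; }
  }
  return List::create(_["status"] = status, _["merged"] = merged,
                      _["overlap"] = overlap);
}
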
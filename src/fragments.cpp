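#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Sequences are passed as integer vectors with codes A=0, C=1, G=2, T=3,
// anything else (N, gaps) = -1. A -1 never matches and never seeds a k-mer.

static inline bool valid_kmer(const int* s, int k) {
  for (int i = 0; i < k; ++i) if (s[i] < 0) return false;
  return true;
}

static inline uint64_t encode_kmer(const int* s, int k) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) v = (v << 2) | (uint64_t)s[i];
  return v;
}

// Ungapped match count between q[qs..qs+len) and r[rs..rs+len).
static inline int match_count(const int* q, int qs, const int* r, int rs, int len) {
  int m = 0;
  for (int i = 0; i < len; ++i) {
    int a = q[qs + i], b = r[rs + i];
    if (a >= 0 && a == b) ++m;
  }
  return m;
}

// Ungapped X-drop extension from an anchoring seed: extend left and right
// from [anchor, anchor+k) scoring +1 per match, -2 per mismatch, stopping
// when the running score falls `xdrop` below its maximum. Reports the match
// count and span of the maximal-scoring extension, so positions past a
// breakpoint (e.g. an accessory-gene indel) are excluded instead of
// matching at random ~25%.
struct Extension { int matches; int span; };

static Extension xdrop_extend(const int* q, int qs, const int* r, int rs,
                              int len, int anchor, int k, int xdrop) {
  int matches = k;                         // the seed itself is an exact match
  int right = anchor + k - 1, left = anchor;
  int score = 0, best = 0, run = 0;
  for (int i = anchor + k; i < len; ++i) {
    int a = q[qs + i], b = r[rs + i];
    bool hit = (a >= 0 && a == b);
    score += hit ? 1 : -2;
    run += hit ? 1 : 0;
    if (score > best) { best = score; matches += run; run = 0; right = i; }
    else if (best - score > xdrop) break;
  }
  score = 0; best = 0; run = 0;
  for (int i = anchor - 1; i >= 0; --i) {
    int a = q[qs + i], b = r[rs + i];
    bool hit = (a >= 0 && a == b);
    score += hit ? 1 : -2;
    run += hit ? 1 : 0;
    if (score > best) { best = score; matches += run; run = 0; left = i; }
    else if (best - score > xdrop) break;
  }
  Extension e; e.matches = matches; e.span = right - left + 1;
  return e;
}

// Map each query fragment to its best ungapped location on the reference by
// exact k-mer seeding (seeds every `seed_step` bp along the fragment) followed
// by full-fragment ungapped extension of the top-voted candidate offsets.
// frag_starts are 0-based; every fragment has length frag_len and must lie
// within the query. ref_bounds is a 2-column matrix of 0-based half-open
// contig intervals on the reference: candidate placements must not cross
// contig boundaries. Returns a matrix with columns (ref_start, identity_pct,
// aligned_fraction); ref_start = -1 when no candidate placement was found.
// [[Rcpp::export(name = ".map_fragments_cpp")]]
NumericMatrix map_fragments_cpp(IntegerVector query, IntegerVector reference,
                                IntegerVector frag_starts, int frag_len,
                                int k, int seed_step,
                                IntegerMatrix ref_bounds,
                                int max_candidates = 8) {
  const int* q = INTEGER(query);
  const int* r = INTEGER(reference);
  const int rlen = reference.size();
  const int nf = frag_starts.size();

  // index all reference k-mers (within contig bounds)
  std::unordered_multimap<uint64_t, int> index;
  index.reserve(rlen > k ? rlen : 1);
  for (int c = 0; c < ref_bounds.nrow(); ++c) {
    int lo = ref_bounds(c, 0), hi = ref_bounds(c, 1);
    for (int p = lo; p + k <= hi; ++p) {
      if (valid_kmer(r + p, k)) index.emplace(encode_kmer(r + p, k), p);
    }
  }

  NumericMatrix out(nf, 3);
  // per candidate offset: vote count and the query offset of its first seed
  std::unordered_map<int, std::pair<int, int> > votes;
  for (int f = 0; f < nf; ++f) {
    const int qs = frag_starts[f];
    votes.clear();
    for (int off = 0; off + k <= frag_len; off += seed_step) {
      if (!valid_kmer(q + qs + off, k)) continue;
      uint64_t key = encode_kmer(q + qs + off, k);
      auto range = index.equal_range(key);
      for (auto it = range.first; it != range.second; ++it) {
        int cand = it->second - off;
        auto ins = votes.emplace(cand, std::make_pair(0, off));
        ins.first->second.first += 1;
      }
    }
    // rank candidates by votes (ties: smaller start)
    std::vector<std::pair<int, std::pair<int, int> > > cands(votes.begin(), votes.end());
    std::sort(cands.begin(), cands.end(),
              [](const std::pair<int, std::pair<int, int> >& a,
                 const std::pair<int, std::pair<int, int> >& b) {
                if (a.second.first != b.second.first) return a.second.first > b.second.first;
                return a.first < b.first;
              });
    int best_start = -1;
    double best_id = -1.0, best_cov = 0.0;
    int best_m = -1;
    int tried = 0;
    for (size_t ci = 0; ci < cands.size() && tried < max_candidates; ++ci) {
      int cand = cands[ci].first;
      if (cand < 0 || cand + frag_len > rlen) continue;
      // must lie within a single reference contig
      bool ok = false;
      for (int c = 0; c < ref_bounds.nrow(); ++c) {
        if (cand >= ref_bounds(c, 0) && cand + frag_len <= ref_bounds(c, 1)) { ok = true; break; }
      }
      if (!ok) continue;
      ++tried;
      Extension e = xdrop_extend(q, qs, r + cand, 0, frag_len,
                                 cands[ci].second.second, k, 20);
      double id = 100.0 * e.matches / e.span;
      double cov = (double)e.span / frag_len;
      // best mapping = most matched bases; identity reported over the
      // aligned extension, coverage = extension span / fragment length
      if (e.matches > best_m || (e.matches == best_m && (best_start < 0 || cand < best_start))) {
        best_m = e.matches; best_id = id; best_cov = cov; best_start = cand;
      }
    }
    out(f, 0) = best_start;
    out(f, 1) = best_start < 0 ? NA_REAL : best_id;
    out(f, 2) = best_start < 0 ? NA_REAL : best_cov;
  }
  return out;
}

// Percent identity of two equal-role sequences compared position by position
// over their common length (ungapped).
// [[Rcpp::export(name = ".hamming_identity_cpp")]]
double hamming_identity_cpp(IntegerVector a, IntegerVector b) {
  int len = std::min(a.size(), b.size());
  if (len == 0) return NA_REAL;
  int m = match_count(INTEGER(a), 0, INTEGER(b), 0, len);
  return 100.0 * m / len;
}

// Pairwise percent identity between two gene sets: matches counted over the
// shared prefix, denominator = longer gene (length differences penalised).
// [[Rcpp::export(name = ".gene_identity_cpp")]]
NumericMatrix gene_identity_cpp(List genes_a, List genes_b) {
  int na = genes_a.size(), nb = genes_b.size();
  NumericMatrix out(na, nb);
  std::vector<IntegerVector> av(na), bv(nb);
  for (int i = 0; i < na; ++i) av[i] = genes_a[i];
  for (int j = 0; j < nb; ++j) bv[j] = genes_b[j];
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      int la = av[i].size(), lb = bv[j].size();
      int len = std::min(la, lb);
      int denom = std::max(la, lb);
      if (denom == 0) { out(i, j) = NA_REAL; continue; }
      int m = match_count(INTEGER(av[i]), 0, INTEGER(bv[j]), 0, len);
      out(i, j) = 100.0 * m / denom;
    }
  }
  return out;
}
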
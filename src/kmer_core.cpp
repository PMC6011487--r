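#include <Rcpp.h>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// Canonical kmer = lexicographic min of the window and its reverse complement.
// Windows containing any non-ACGT character are skipped.

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 0;
  }
}

static inline bool base_ok(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Writes the canonical form of seq[pos, pos+k) into out.
// Returns false if the window contains a non-ACGT base.
static bool canonical_window(const std::string& seq, size_t pos, int k,
                             std::string& out) {
  std::string fwd(seq, pos, k);
  std::string rc(k, 'N');
  for (int i = 0; i < k; ++i) {
    char c = fwd[i];
    if (!base_ok(c)) return false;
    rc[k - 1 - i] = complement(c);
  }
  out = (fwd <= rc) ? fwd : rc;
  return true;
}

// [[Rcpp::export]]
CharacterVector cpp_kmerize(std::string seq, int k) {
  if (k < 1) stop("k must be >= 1");
  std::vector<std::string> res;
  if ((int)seq.size() >= k) {
    std::string can;
    for (size_t pos = 0; pos + k <= seq.size(); ++pos) {
      if (canonical_window(seq, pos, k, can)) res.push_back(can);
    }
  }
  return wrap(res);
}

struct KIndex {
  int k;
  // canonical kmer -> 1-based contig-end index, or -1 for multimapped
  std::unordered_map<std::string, int> table;
  long long n_stored = 0;
  long long n_multi = 0;
  long long n_nonacgt = 0;
  int n_ends = 0;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector end_seqs, int k) {
  if (k < 1) stop("k must be >= 1");
  XPtr<KIndex> xp(new KIndex, true);
  xp->k = k;
  xp->n_ends = end_seqs.size();
  std::string can;
  for (int e = 0; e < end_seqs.size(); ++e) {
    std::string seq = as<std::string>(end_seqs[e]);
    if ((int)seq.size() < k) continue;
    for (size_t pos = 0; pos + k <= seq.size(); ++pos) {
      if (!canonical_window(seq, pos, k, can)) {
        xp->n_nonacgt++;
        continue;
      }
      auto it = xp->table.find(can);
      if (it == xp->table.end()) {
        xp->table.emplace(can, e + 1);
      } else if (it->second != e + 1 && it->second != -1) {
        // seen in a different end: cross-end ambiguity, drop from table
        it->second = -1;
        xp->n_multi++;
      }
      // same end again (within-end repeat) or already multimapped: no-op
    }
  }
  for (auto& kv : xp->table)
    if (kv.second > 0) xp->n_stored++;
  return xp;
}

// [[Rcpp::export]]
List cpp_index_stats(SEXP xpsexp) {
  XPtr<KIndex> xp(xpsexp);
  return List::create(
    _["k"] = xp->k,
    _["n_ends"] = xp->n_ends,
    _["n_kmers_stored"] = (double)xp->n_stored,
    _["n_kmers_dropped_multimapped"] = (double)xp->n_multi,
    _["n_kmers_dropped_nonACGT"] = (double)xp->n_nonacgt);
}

// Look up canonical kmers: 1-based end index, -1 if multimapped, NA if absent.
// [[Rcpp::export]]
IntegerVector cpp_index_lookup(SEXP xpsexp, CharacterVector kmers) {
  XPtr<KIndex> xp(xpsexp);
  IntegerVector out(kmers.size(), NA_INTEGER);
  for (int i = 0; i < kmers.size(); ++i) {
    std::string km = as<std::string>(kmers[i]);
    auto it = xp->table.find(km);
    if (it != xp->table.end()) out[i] = it->second;
  }
  return out;
}

// Per-read hit profile over contig ends, used by score_read()/map_read().
// denom = number of distinct valid canonical kmers in the read (all of them,
// including those that are multimapped in the index).
// [[Rcpp::export]]
List cpp_read_hits(SEXP xpsexp, std::string read) {
  XPtr<KIndex> xp(xpsexp);
  const int k = xp->k;
  std::unordered_set<std::string> seen;
  std::unordered_map<int, int> hits;
  std::string can;
  if ((int)read.size() >= k) {
    for (size_t pos = 0; pos + k <= read.size(); ++pos) {
      if (!canonical_window(read, pos, k, can)) continue;
      if (!seen.insert(can).second) continue;  // multiset-collapsed
      auto it = xp->table.find(can);
      if (it != xp->table.end() && it->second > 0) hits[it->second]++;
    }
  }
  std::vector<int> ends, counts;
  for (auto& kv : hits) {
    ends.push_back(kv.first);
    counts.push_back(kv.second);
  }
  return List::create(_["denom"] = (int)seen.size(), _["end"] = wrap(ends),
                      _["hits"] = wrap(counts));
}

// Vectorised best-end mapping: for each read return the index of the single
// best-scoring contig end with score >= j_min, or NA when there is no
// candidate, the best score falls below j_min, or the best score is tied.
// [[Rcpp::export]]
IntegerVector cpp_map_reads(SEXP xpsexp, CharacterVector reads, double j_min) {
  XPtr<KIndex> xp(xpsexp);
  const int k = xp->k;
  IntegerVector out(reads.size(), NA_INTEGER);
  std::unordered_set<std::string> seen;
  std::unordered_map<int, int> hits;
  std::string can;
  for (int r = 0; r < reads.size(); ++r) {
    std::string read = as<std::string>(reads[r]);
    seen.clear();
    hits.clear();
    if ((int)read.size() >= k) {
      for (size_t pos = 0; pos + k <= read.size(); ++pos) {
        if (!canonical_window(read, pos, k, can)) continue;
        if (!seen.insert(can).second) continue;
        auto it = xp->table.find(can);
        if (it != xp->table.end() && it->second > 0) hits[it->second]++;
      }
    }
    int denom = (int)seen.size();
    if (denom == 0 || hits.empty()) continue;
    int best_end = 0, best = -1;
    bool tie = false;
    for (auto& kv : hits) {
      if (kv.second > best) {
        best = kv.second;
        best_end = kv.first;
        tie = false;
      } else if (kv.second == best) {
        tie = true;
      }
    }
    if (tie) continue;
    double score = (double)best / (double)denom;
    if (score >= j_min) out[r] = best_end;
  }
  return out;
}
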
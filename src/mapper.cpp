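// Deterministic seed-and-extend short-read mapper.
//
// Candidate loci come from exact k-mer seed matches on both strands;
// each candidate is scored by ungapped full-length extension and the
// best hit is reported when its identity reaches min_identity. Ties are
// broken in favour of the forward strand, then the lowest start
// coordinate. At most max_candidates candidate loci (lowest start
// coordinates) are evaluated per read, which keeps the mapper
// deterministic on repeat-rich references.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <set>
#include <cstdint>

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

static inline char comp_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

typedef std::unordered_map<uint64_t, std::vector<int32_t> > KmerIndex;

// Index every k-mer of the genome (forward strand only); k-mers that
// contain a non-ACGT character are skipped.
static void build_index(const std::string& genome, int k, KmerIndex& index) {
  const int64_t n = (int64_t) genome.size();
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t code = 0;
  int valid = 0;
  for (int64_t i = 0; i < n; ++i) {
    int b = base_code(genome[(size_t) i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t) b) & mask;
    ++valid;
    if (valid >= k) index[code].push_back((int32_t) (i - k + 1));
  }
}

// Collect deduplicated candidate start positions for one oriented read.
static void collect_candidates(const std::string& oriented, int k,
                               const KmerIndex& index, int64_t glen,
                               std::set<int32_t>& starts) {
  const int len = (int) oriented.size();
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t code = 0;
  int valid = 0;
  for (int i = 0; i < len; ++i) {
    int b = base_code(oriented[(size_t) i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t) b) & mask;
    ++valid;
    if (valid < k) continue;
    int j = i - k + 1;  // k-mer offset within the read
    KmerIndex::const_iterator it = index.find(code);
    if (it == index.end()) continue;
    const std::vector<int32_t>& pos = it->second;
    for (size_t m = 0; m < pos.size(); ++m) {
      int64_t cand = (int64_t) pos[m] - (int64_t) j;
      if (cand >= 0 && cand + len <= glen) starts.insert((int32_t) cand);
    }
  }
}

static int count_mismatches(const std::string& oriented,
                            const std::string& genome, int32_t start) {
  int mm = 0;
  const int len = (int) oriented.size();
  for (int i = 0; i < len; ++i)
    if (oriented[(size_t) i] != genome[(size_t) (start + i)]) ++mm;
  return mm;
}

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, std::string genome, int k,
                        double min_identity, int max_candidates) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  const int n = reads.size();
  const int64_t glen = (int64_t) genome.size();

  KmerIndex index;
  build_index(genome, k, index);

  LogicalVector hit(n), short_read(n);
  IntegerVector start(n), mismatches(n), aligned_length(n);
  CharacterVector strand(n);
  NumericVector identity(n);

  for (int r = 0; r < n; ++r) {
    hit[r] = false; short_read[r] = false;
    start[r] = NA_INTEGER; mismatches[r] = NA_INTEGER;
    aligned_length[r] = NA_INTEGER;
    strand[r] = NA_STRING; identity[r] = NA_REAL;

    std::string fwd = as<std::string>(reads[r]);
    const int len = (int) fwd.size();
    if (len < k) { short_read[r] = true; continue; }
    if ((int64_t) len > glen) continue;

    std::string rev(len, 'N');
    for (int i = 0; i < len; ++i) rev[(size_t) (len - 1 - i)] = comp_base(fwd[(size_t) i]);

    std::set<int32_t> fwd_starts, rev_starts;
    collect_candidates(fwd, k, index, glen, fwd_starts);
    collect_candidates(rev, k, index, glen, rev_starts);

    // Merge to (start, strand) pairs ordered by start, '+' before '-';
    // keep the first max_candidates.
    std::vector<std::pair<int32_t, int> > cands;
    cands.reserve(fwd_starts.size() + rev_starts.size());
    for (std::set<int32_t>::const_iterator it = fwd_starts.begin(); it != fwd_starts.end(); ++it)
      cands.push_back(std::make_pair(*it, 0));
    for (std::set<int32_t>::const_iterator it = rev_starts.begin(); it != rev_starts.end(); ++it)
      cands.push_back(std::make_pair(*it, 1));
    std::sort(cands.begin(), cands.end());
    if ((int) cands.size() > max_candidates) cands.resize((size_t) max_candidates);

    int best_mm = -1, best_strand = -1;
    int32_t best_start = -1;
    for (size_t c = 0; c < cands.size(); ++c) {
      const std::string& oriented = cands[c].second == 0 ? fwd : rev;
      int mm = count_mismatches(oriented, genome, cands[c].first);
      bool better = false;
      if (best_mm < 0 || mm < best_mm) better = true;
      else if (mm == best_mm) {
        if (cands[c].second < best_strand) better = true;
        else if (cands[c].second == best_strand && cands[c].first < best_start) better = true;
      }
      if (better) { best_mm = mm; best_strand = cands[c].second; best_start = cands[c].first; }
    }

    if (best_mm < 0) continue;
    double ident = 1.0 - (double) best_mm / (double) len;
    if (ident < min_identity) continue;
    hit[r] = true;
    start[r] = best_start;
    strand[r] = best_strand == 0 ? "+" : "-";
    mismatches[r] = best_mm;
    aligned_length[r] = len;
    identity[r] = ident;
  }

  return DataFrame::create(
    _["hit"] = hit, _["start"] = start, _["strand"] = strand,
    _["aligned_length"] = aligned_length, _["mismatches"] = mismatches,
    _["identity"] = identity, _["short_read"] = short_read,
    _["stringsAsFactors"] = false);
}
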
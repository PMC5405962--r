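#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// 2-bit base encoding; -1 for anything outside {A,C,G,T}
static inline int encodeBase(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char complementBase(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

// [[Rcpp::export]]
List cpp_build_index(std::string ref, int k) {
  const int L = (int) ref.size();
  const int n = L - k + 1;
  if (n < 1) stop("reference shorter than seed length");
  // rolling 2-bit code for every k-mer start; positions with non-ACGT are skipped
  std::vector<std::pair<uint64_t, int> > keyed;
  keyed.reserve(n);
  uint64_t code = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int valid = 0; // run length of valid bases ending at i
  for (int i = 0; i < L; ++i) {
    int b = encodeBase(ref[i]);
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t) b) & mask;
    ++valid;
    if (valid >= k) keyed.push_back(std::make_pair(code, i - k + 2)); // 1-based start
  }
  std::sort(keyed.begin(), keyed.end());
  const int m = (int) keyed.size();
  std::vector<double> codes;
  std::vector<int> starts, positions(m);
  for (int i = 0; i < m; ++i) {
    if (i == 0 || keyed[i].first != keyed[i - 1].first) {
      codes.push_back((double) keyed[i].first);
      starts.push_back(i);
    }
    positions[i] = keyed[i].second;
  }
  starts.push_back(m);
  return List::create(_["codes"] = NumericVector(codes.begin(), codes.end()),
                      _["starts"] = IntegerVector(starts.begin(), starts.end()),
                      _["positions"] = IntegerVector(positions.begin(), positions.end()));
}

static inline bool kmerCode(const std::string &s, int from, int k, uint64_t &code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    int b = encodeBase(s[from + i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t) b;
  }
  return true;
}

// positions (1-based) whose k-mer equals `code`
static void lookup(const NumericVector &codes, const IntegerVector &starts,
                   const IntegerVector &positions, uint64_t code,
                   std::vector<int> &out) {
  double target = (double) code;
  int lo = 0, hi = codes.size() - 1;
  while (lo <= hi) {
    int mid = (lo + hi) / 2;
    if (codes[mid] < target) lo = mid + 1;
    else if (codes[mid] > target) hi = mid - 1;
    else {
      for (int i = starts[mid]; i < starts[mid + 1]; ++i) out.push_back(positions[i]);
      return;
    }
  }
}

// [[Rcpp::export]]
IntegerVector cpp_seed_hits(std::string kmer, NumericVector codes,
                            IntegerVector starts, IntegerVector positions) {
  uint64_t code;
  if (!kmerCode(kmer, 0, (int) kmer.size(), code)) return IntegerVector(0);
  std::vector<int> out;
  lookup(codes, starts, positions, code, out);
  std::sort(out.begin(), out.end());
  return IntegerVector(out.begin(), out.end());
}

struct Placement { int pos; int strand; int mm; }; // strand: 0 = '+', 1 = '-'

// Hamming distance with early exit once > cap
static inline int hamming(const std::string &ref, int pos0, const std::string &read, int cap) {
  int mm = 0;
  const int n = (int) read.size();
  for (int i = 0; i < n; ++i) {
    if (ref[pos0 + i] != read[i]) { if (++mm > cap) return mm; }
  }
  return mm;
}

// Seed-and-extend placement of one oriented sequence; appends placements with
// mismatches <= max_mismatch. Seeds are the three disjoint k-mers at offsets
// 0, k and 2k of the oriented read (pigeonhole for max_mismatch = 2).
static void placeOriented(const std::string &ref, const std::string &oriented,
                          const NumericVector &codes, const IntegerVector &starts,
                          const IntegerVector &positions, int k, int max_mismatch,
                          int strand, std::vector<Placement> &placements) {
  const int L = (int) ref.size();
  const int rl = (int) oriented.size();
  std::vector<int> cand;
  for (int s = 0; s < 3; ++s) {
    int off = s * k;
    uint64_t code;
    if (!kmerCode(oriented, off, k, code)) continue;
    std::vector<int> hits;
    lookup(codes, starts, positions, code, hits);
    for (size_t h = 0; h < hits.size(); ++h) {
      int p = hits[h] - off; // candidate leftmost 1-based position
      if (p >= 1 && p + rl - 1 <= L) cand.push_back(p);
    }
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  for (size_t i = 0; i < cand.size(); ++i) {
    int mm = hamming(ref, cand[i] - 1, oriented, max_mismatch);
    if (mm <= max_mismatch) {
      Placement pl; pl.pos = cand[i]; pl.strand = strand; pl.mm = mm;
      placements.push_back(pl);
    }
  }
}

// status codes: 1 aligned, 2 suppressed, 3 orphan
// [[Rcpp::export]]
List cpp_align_reads(std::string ref, CharacterVector reads, NumericVector codes,
                     IntegerVector starts, IntegerVector positions, int k,
                     int max_mismatch) {
  const int n = reads.size();
  IntegerVector status(n), pos(n, NA_INTEGER), mism(n, NA_INTEGER);
  CharacterVector strand(n, NA_STRING);
  for (int r = 0; r < n; ++r) {
    std::string read = as<std::string>(reads[r]);
    bool ok = true;
    for (size_t i = 0; i < read.size(); ++i) {
      read[i] = (char) toupper(read[i]);
      if (encodeBase(read[i]) < 0) { ok = false; break; }
    }
    if (!ok || (int) read.size() < 3 * k) { status[r] = 3; continue; }
    std::string rc(read.rbegin(), read.rend());
    for (size_t i = 0; i < rc.size(); ++i) rc[i] = complementBase(rc[i]);
    std::vector<Placement> placements;
    placeOriented(ref, read, codes, starts, positions, k, max_mismatch, 0, placements);
    placeOriented(ref, rc, codes, starts, positions, k, max_mismatch, 1, placements);
    if (placements.empty()) { status[r] = 3; continue; }
    int best = max_mismatch + 1;
    for (size_t i = 0; i < placements.size(); ++i) best = std::min(best, placements[i].mm);
    int nbest = 0, ibest = -1;
    for (size_t i = 0; i < placements.size(); ++i)
      if (placements[i].mm == best) { ++nbest; ibest = (int) i; }
    if (nbest == 1) {
      status[r] = 1;
      pos[r] = placements[ibest].pos;
      strand[r] = placements[ibest].strand == 0 ? "+" : "-";
      mism[r] = best;
    } else {
      status[r] = 2;
    }
  }
  return List::create(_["status"] = status, _["position"] = pos,
                      _["strand"] = strand, _["mismatches"] = mism);
}

// Base counts per reference position from aligned reads. Reads on '-' are
// reverse-complemented into reference orientation before tallying.
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(int genome_length, CharacterVector reads,
                         IntegerVector pos, CharacterVector strand) {
  IntegerMatrix counts(4, genome_length);
  const int n = reads.size();
  for (int r = 0; r < n; ++r) {
    std::string read = as<std::string>(reads[r]);
    if (strand[r] == "-") {
      std::string rc(read.rbegin(), read.rend());
      for (size_t i = 0; i < rc.size(); ++i) rc[i] = complementBase(rc[i]);
      read = rc;
    }
    int p0 = pos[r] - 1;
    if (p0 < 0 || p0 + (int) read.size() > genome_length)
      stop("alignment position out of genome bounds");
    for (size_t i = 0; i < read.size(); ++i) {
      int b = encodeBase(read[i]);
      if (b >= 0) counts(b, p0 + (int) i) += 1;
    }
  }
  return counts;
}
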
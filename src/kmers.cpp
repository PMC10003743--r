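#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>

using namespace Rcpp;

static inline char complement_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 0;
  }
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static const char CODE_BASE[4] = {'A', 'C', 'G', 'T'};

// Fast path for k <= 31: rolling 2-bit encoding of the window and its
// reverse complement; canonical = the numerically smaller encoding
// (2-bit codes are in lexicographic base order, so this is the
// lexicographic minimum).
static IntegerVector count_kmers_u64(CharacterVector seqs, int k) {
  std::unordered_map<uint64_t, int> counts;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    SEXP el = STRING_ELT(seqs, s);
    if (el == NA_STRING) continue;
    const char *str = CHAR(el);
    int n = LENGTH(el);
    if (n < k) continue;
    uint64_t fwd = 0, rev = 0;
    int run = 0;  // length of current valid run
    for (int i = 0; i < n; ++i) {
      int c = base_code(str[i]);
      if (c < 0) { run = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++run >= k) ++counts[fwd < rev ? fwd : rev];
    }
  }

  IntegerVector out(counts.size());
  CharacterVector nm(counts.size());
  std::string buf(k, 'A');
  R_xlen_t i = 0;
  for (const auto &kv : counts) {
    uint64_t v = kv.first;
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = CODE_BASE[v & 3ULL];
      v >>= 2;
    }
    nm[i] = buf;
    out[i] = kv.second;
    ++i;
  }
  out.attr("names") = nm;
  return out;
}

// Generic string path for 31 < k <= 63.
static IntegerVector count_kmers_str(CharacterVector seqs, int k) {
  std::unordered_map<std::string, int> counts;
  std::string fwd(k, 'A'), rev(k, 'A');

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    SEXP el = STRING_ELT(seqs, s);
    if (el == NA_STRING) continue;
    const char *str = CHAR(el);
    int n = LENGTH(el);
    if (n < k) continue;
    int last_bad = -1;
    for (int i = 0; i < k - 1; ++i)
      if (base_code(str[i]) < 0) last_bad = i;
    for (int start = 0; start + k <= n; ++start) {
      int end = start + k - 1;
      if (base_code(str[end]) < 0) last_bad = end;
      if (last_bad >= start) continue;
      bool use_rev = false;
      for (int j = 0; j < k; ++j) {
        char a = str[start + j];
        char b = complement_base(str[end - j]);
        if (a != b) { use_rev = b < a; break; }
      }
      if (use_rev) {
        for (int j = 0; j < k; ++j) rev[j] = complement_base(str[end - j]);
        ++counts[rev];
      } else {
        fwd.assign(str + start, k);
        ++counts[fwd];
      }
    }
  }

  IntegerVector out(counts.size());
  CharacterVector nm(counts.size());
  R_xlen_t i = 0;
  for (const auto &kv : counts) {
    nm[i] = kv.first;
    out[i] = kv.second;
    ++i;
  }
  out.attr("names") = nm;
  return out;
}

// Exact canonical k-mer counting over DNA strings (upper-case A/C/G/T/N).
// Windows containing any non-ACGT character are skipped. Canonical form =
// lexicographic min(k-mer, reverse complement).
// [[Rcpp::export]]
IntegerVector count_canonical_kmers_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 63) stop("k must be between 1 and 63");
  if (k <= 31) return count_kmers_u64(seqs, k);
  return count_kmers_str(seqs, k);
}

static void fill_u64_map(CharacterVector seqs, int k,
                         std::unordered_map<uint64_t, int> &counts) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    SEXP el = STRING_ELT(seqs, s);
    if (el == NA_STRING) continue;
    const char *str = CHAR(el);
    int n = LENGTH(el);
    if (n < k) continue;
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = base_code(str[i]);
      if (c < 0) { run = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++run >= k) ++counts[fwd < rev ? fwd : rev];
    }
  }
}

static CharacterVector decode_specific(
    const std::unordered_map<uint64_t, int> &self,
    const std::unordered_map<uint64_t, int> &other,
    int k, int min_count) {
  std::vector<uint64_t> keep;
  for (const auto &kv : self)
    if (kv.second >= min_count && other.find(kv.first) == other.end())
      keep.push_back(kv.first);
  CharacterVector out(keep.size());
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < (R_xlen_t)keep.size(); ++i) {
    uint64_t v = keep[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = CODE_BASE[v & 3ULL];
      v >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// Fused one-sample-per-sex path: canonical k-mer counting of both genomes
// and extraction of the sex-specific sets without materializing the full
// spectra in R. k must be <= 31.
// [[Rcpp::export]]
List sex_specific_genomes_cpp(CharacterVector male_seqs,
                              CharacterVector female_seqs,
                              int k, int min_count) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, int> mc, fc;
  fill_u64_map(male_seqs, k, mc);
  fill_u64_map(female_seqs, k, fc);
  return List::create(
    _["male_specific"] = decode_specific(mc, fc, k, min_count),
    _["female_specific"] = decode_specific(fc, mc, k, min_count));
}
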
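#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// splitmix64: the documented generator driving the substring-space shuffle.
static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Unbiased draw in [0, bound) by rejection, so the permutation is uniform.
static inline uint64_t bounded_draw(uint64_t &state, uint64_t bound) {
  uint64_t threshold = (-bound) % bound;
  for (;;) {
    uint64_t r = splitmix64(state);
    if (r >= threshold) return r % bound;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_generate_perm(int s, double seed) {
  R_xlen_t n = (R_xlen_t)1 << (2 * s);
  IntegerVector perm(n);
  for (R_xlen_t i = 0; i < n; ++i) perm[i] = (int)i;
  uint64_t state = (uint64_t)seed;
  for (R_xlen_t i = n - 1; i > 0; --i) {
    R_xlen_t j = (R_xlen_t)bounded_draw(state, (uint64_t)(i + 1));
    int tmp = perm[i];
    perm[i] = perm[j];
    perm[j] = tmp;
  }
  return perm;
}

static inline uint64_t fnv1a_update(uint64_t h, uint8_t b) {
  h ^= b;
  h *= 1099511628211ULL;
  return h;
}

static RawVector fnv_to_raw(uint64_t h) {
  RawVector out(8);
  for (int i = 0; i < 8; ++i) out[i] = (Rbyte)((h >> (8 * i)) & 0xFF);
  return out;
}

// [[Rcpp::export]]
RawVector cpp_fnv1a(RawVector bytes) {
  uint64_t h = 14695981039346656037ULL;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) h = fnv1a_update(h, (uint8_t)bytes[i]);
  return fnv_to_raw(h);
}

// FNV-1a over the little-endian 4-byte encoding of each value: equals
// cpp_fnv1a() applied to the shuffle-file body without materializing it.
// [[Rcpp::export]]
RawVector cpp_fnv1a_u32(IntegerVector values) {
  uint64_t h = 14695981039346656037ULL;
  for (R_xlen_t i = 0; i < values.size(); ++i) {
    uint32_t v = (uint32_t)values[i];
    for (int b = 0; b < 4; ++b) h = fnv1a_update(h, (uint8_t)((v >> (8 * b)) & 0xFF));
  }
  return fnv_to_raw(h);
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline uint64_t kmer_mask(int k) {
  return (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
}

// Scan sequences, canonicalize every valid window, filter through the
// selected subspace and collect the invertible hashes of kept k-mers.
// [[Rcpp::export]]
List cpp_sketch_sequences(CharacterVector seqs, int k, int s, int L,
                          IntegerVector perm) {
  const uint64_t kmask = kmer_mask(k);
  const int fl = (k - s) / 2;          // left flank, left-biased for odd k-s
  const int fr = (k - s) - fl;         // right flank
  const uint64_t smask = (1ULL << (2 * s)) - 1;
  const int rank_bits = 2 * s - 4 * L;
  const uint64_t sub_size = 1ULL << rank_bits;
  const uint64_t frmask = (fr == 0) ? 0ULL : ((1ULL << (2 * fr)) - 1);

  std::unordered_set<uint64_t> distinct;
  std::unordered_set<uint64_t> sketch;
  double total = 0;

  for (R_xlen_t si = 0; si < seqs.size(); ++si) {
    const char *p = CHAR(STRING_ELT(seqs, si));
    R_xlen_t len = LENGTH(STRING_ELT(seqs, si));
    uint64_t fwd = 0, rc = 0;
    int run = 0;
    for (R_xlen_t i = 0; i < len; ++i) {
      int c = base_code(p[i]);
      if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & kmask;
      rc = (rc >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++run >= k) {
        ++total;
        uint64_t canon = std::min(fwd, rc & kmask);
        distinct.insert(canon);
        uint64_t center = (canon >> (2 * fr)) & smask;
        uint64_t rank = (uint64_t)(uint32_t)perm[(R_xlen_t)center];
        if (rank < sub_size) {
          uint64_t left = canon >> (2 * (fr + s));
          uint64_t right = canon & frmask;
          uint64_t hash = (((left << (2 * fr)) | right) << rank_bits) | rank;
          sketch.insert(hash);
        }
      }
    }
  }

  std::vector<uint64_t> v(sketch.begin(), sketch.end());
  std::sort(v.begin(), v.end());
  NumericVector hashes(v.size());
  for (size_t i = 0; i < v.size(); ++i) hashes[i] = (double)v[i];
  return List::create(_["hashes"] = hashes,
                      _["total_kmers"] = total,
                      _["distinct_kmers"] = (double)distinct.size());
}

// Canonical code of every valid window, in window order.
// [[Rcpp::export]]
NumericVector cpp_extract_kmers(std::string seq, int k) {
  const uint64_t kmask = kmer_mask(k);
  std::vector<double> out;
  uint64_t fwd = 0, rc = 0;
  int run = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & kmask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++run >= k) out.push_back((double)std::min(fwd, rc & kmask));
  }
  return NumericVector(out.begin(), out.end());
}

static inline uint64_t revcomp_code(uint64_t code, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3 - (code & 3));
    code >>= 2;
  }
  return rc;
}

// [[Rcpp::export]]
NumericVector cpp_canonicalize(NumericVector codes, int k) {
  NumericVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t c = (uint64_t)codes[i];
    out[i] = (double)std::min(c, revcomp_code(c, k));
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_revcomp(NumericVector codes, int k) {
  NumericVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    out[i] = (double)revcomp_code((uint64_t)codes[i], k);
  return out;
}

// Invertible hash of canonical codes; NA for k-mers outside the selected
// subspace (REJECT).
// [[Rcpp::export]]
NumericVector cpp_encode_hash(NumericVector codes, int k, int s, int L,
                              IntegerVector perm) {
  const int fl = (k - s) / 2;
  const int fr = (k - s) - fl;
  const uint64_t smask = (1ULL << (2 * s)) - 1;
  const int rank_bits = 2 * s - 4 * L;
  const uint64_t sub_size = 1ULL << rank_bits;
  const uint64_t frmask = (fr == 0) ? 0ULL : ((1ULL << (2 * fr)) - 1);
  NumericVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t code = (uint64_t)codes[i];
    uint64_t center = (code >> (2 * fr)) & smask;
    uint64_t rank = (uint64_t)(uint32_t)perm[(R_xlen_t)center];
    if (rank >= sub_size) {
      out[i] = NA_REAL;
    } else {
      uint64_t left = code >> (2 * (fr + s));
      uint64_t right = code & frmask;
      out[i] = (double)((((left << (2 * fr)) | right) << rank_bits) | rank);
    }
  }
  return out;
}

// Exact inverse of cpp_encode_hash on its image: rebuild the canonical code
// from flank bits and the within-subspace rank.
// [[Rcpp::export]]
NumericVector cpp_decode_hash(NumericVector hashes, int k, int s, int L,
                              IntegerVector perm) {
  const int fl = (k - s) / 2;
  const int fr = (k - s) - fl;
  const int rank_bits = 2 * s - 4 * L;
  const uint64_t sub_size = 1ULL << rank_bits;
  const uint64_t frmask = (fr == 0) ? 0ULL : ((1ULL << (2 * fr)) - 1);
  const int hash_bits = 2 * k - 4 * L;
  const uint64_t hmax = 1ULL << hash_bits;

  std::vector<uint32_t> inv(sub_size);
  for (R_xlen_t x = 0; x < perm.size(); ++x) {
    uint32_t r = (uint32_t)perm[x];
    if (r < sub_size) inv[r] = (uint32_t)x;
  }

  NumericVector out(hashes.size());
  for (R_xlen_t i = 0; i < hashes.size(); ++i) {
    uint64_t h = (uint64_t)hashes[i];
    if (hashes[i] < 0 || h >= hmax)
      stop("invalid hash: value %.0f outside [0, 2^%d)", hashes[i], hash_bits);
    uint64_t rank = h & (sub_size - 1);
    uint64_t flank = h >> rank_bits;
    uint64_t left = flank >> (2 * fr);
    uint64_t right = flank & frmask;
    uint64_t center = (uint64_t)inv[rank];
    out[i] = (double)((left << (2 * (fr + s))) | (center << (2 * fr)) | right);
  }
  return out;
}

// Little-endian fixed-width packing of hash values for the sketch archive.
// [[Rcpp::export]]
RawVector cpp_pack_values(NumericVector values, int width) {
  RawVector out(values.size() * (R_xlen_t)width);
  R_xlen_t pos = 0;
  for (R_xlen_t i = 0; i < values.size(); ++i) {
    uint64_t v = (uint64_t)values[i];
    for (int b = 0; b < width; ++b) out[pos++] = (Rbyte)((v >> (8 * b)) & 0xFF);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_unpack_values(RawVector bytes, int width) {
  if (bytes.size() % width != 0) stop("byte payload is not a multiple of the record width");
  R_xlen_t n = bytes.size() / width;
  NumericVector out(n);
  R_xlen_t pos = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t v = 0;
    for (int b = 0; b < width; ++b) v |= ((uint64_t)(uint8_t)bytes[pos++]) << (8 * b);
    out[i] = (double)v;
  }
  return out;
}
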
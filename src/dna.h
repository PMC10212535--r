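#ifndef KAMQ_DNA_H
#define KAMQ_DNA_H

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>

// 2-bit DNA codes: A=0, C=1, G=2, T=3 (case-insensitive); -1 for anything else.
static inline int dna_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char code_char(int code) {
  static const char chars[4] = {'A', 'C', 'G', 'T'};
  return chars[code & 3];
}

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Seed-free, platform-stable hash of a 2-bit code sequence: FNV-1a over the
// codes, length folded in, then a splitmix64 finalizer for mixing.
static inline uint64_t hash_codes(const uint8_t *codes, size_t len) {
  uint64_t h = 0xcbf29ce484222325ULL;
  for (size_t i = 0; i < len; ++i) {
    h ^= (uint64_t)codes[i];
    h *= 0x100000001b3ULL;
  }
  return splitmix64(h ^ (uint64_t)len);
}

// b-bit counters packed little-endian-by-bit into a byte array; b in 1..8 so a
// counter spans at most two bytes.
static inline uint32_t slot_get(const uint8_t *p, uint64_t i, int b) {
  uint64_t bit = i * (uint64_t)b;
  uint64_t byte = bit >> 3;
  int off = (int)(bit & 7);
  uint32_t v = (uint32_t)p[byte] >> off;
  if (off + b > 8) v |= (uint32_t)p[byte + 1] << (8 - off);
  return v & ((1u << b) - 1u);
}

static inline void slot_set(uint8_t *p, uint64_t i, int b, uint32_t value) {
  uint64_t bit = i * (uint64_t)b;
  uint64_t byte = bit >> 3;
  int off = (int)(bit & 7);
  uint32_t mask = (1u << b) - 1u;
  value &= mask;
  p[byte] = (uint8_t)((p[byte] & ~(mask << off)) | (value << off));
  if (off + b > 8) {
    int hi = off + b - 8;  // bits spilling into the next byte
    uint32_t himask = (1u << hi) - 1u;
    p[byte + 1] = (uint8_t)((p[byte + 1] & ~himask) | (value >> (8 - off)));
  }
}

// Encode a word into codes; returns false (and the offending position in
// *bad_at) when a non-ACGT character is present.
static inline bool encode_word(const char *w, size_t len, std::vector<uint8_t> &codes,
                               size_t *bad_at) {
  codes.resize(len);
  for (size_t i = 0; i < len; ++i) {
    int c = dna_code(w[i]);
    if (c < 0) { if (bad_at) *bad_at = i; return false; }
    codes[i] = (uint8_t)c;
  }
  return true;
}

// Lexicographically smaller of a code sequence and its reverse complement,
// written into out (A<C<G<T coincides with 0<1<2<3).
static inline void canonical_codes(const std::vector<uint8_t> &codes,
                                   std::vector<uint8_t> &out) {
  size_t n = codes.size();
  out.resize(n);
  // compare codes with its reverse complement without materializing it
  int cmp = 0;  // -1: forward smaller, 1: rc smaller
  for (size_t i = 0; i < n; ++i) {
    uint8_t f = codes[i];
    uint8_t r = (uint8_t)(3 - codes[n - 1 - i]);
    if (f != r) { cmp = (f < r) ? -1 : 1; break; }
  }
  if (cmp <= 0) {
    out = codes;
  } else {
    for (size_t i = 0; i < n; ++i) out[i] = (uint8_t)(3 - codes[n - 1 - i]);
  }
}

#endif
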
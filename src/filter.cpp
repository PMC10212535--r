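#include <Rcpp.h>
#include "dna.h"
using namespace Rcpp;

static uint64_t word_slot(const char *w, size_t len, uint64_t nb_slots,
                          std::vector<uint8_t> &scratch) {
  size_t bad = 0;
  if (!encode_word(w, len, scratch, &bad))
    stop("non-ACGT character '%s' at position %d in word '%s'",
         std::string(1, w[bad]).c_str(), (int)(bad + 1), std::string(w, len).c_str());
  return hash_codes(scratch.data(), len) % nb_slots;
}

// [[Rcpp::export]]
NumericVector cpp_hash_smer(CharacterVector words, double nb_slots) {
  uint64_t m = (uint64_t)nb_slots;
  if (m < 1) stop("nb_slots must be >= 1");
  R_xlen_t n = words.size();
  NumericVector out(n);
  std::vector<uint8_t> scratch;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *w = CHAR(STRING_ELT(words, i));
    out[i] = (double)word_slot(w, strlen(w), m, scratch);
  }
  return out;
}

// Saturating max-insert; mutates the raw slot array in place (the R wrapper
// owns the vector inside an environment, so no other binding is affected).
// [[Rcpp::export]]
void cpp_cf_insert_max(RawVector slots, double nb_slots, int b,
                       CharacterVector words, IntegerVector values) {
  uint64_t m = (uint64_t)nb_slots;
  uint32_t cap = (1u << b) - 1u;
  uint8_t *p = RAW(slots);
  R_xlen_t n = words.size();
  if (values.size() != n) stop("words and values must have the same length");
  std::vector<uint8_t> scratch;
  for (R_xlen_t i = 0; i < n; ++i) {
    int val = values[i];
    if (val == NA_INTEGER || val < 0) stop("values must be non-negative");
    const char *w = CHAR(STRING_ELT(words, i));
    uint64_t slot = word_slot(w, strlen(w), m, scratch);
    uint32_t v = std::min((uint32_t)val, cap);
    if (v > slot_get(p, slot, b)) slot_set(p, slot, b, v);
  }
}

// [[Rcpp::export]]
IntegerVector cpp_cf_lookup(RawVector slots, double nb_slots, int b,
                            CharacterVector words) {
  uint64_t m = (uint64_t)nb_slots;
  const uint8_t *p = RAW(slots);
  R_xlen_t n = words.size();
  IntegerVector out(n);
  std::vector<uint8_t> scratch;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *w = CHAR(STRING_ELT(words, i));
    out[i] = (int)slot_get(p, word_slot(w, strlen(w), m, scratch), b);
  }
  return out;
}

// FNV-1a over the payload bytes, reported as 16 hex characters; used as the
// integrity checksum of serialized filters.
// [[Rcpp::export]]
std::string cpp_checksum(RawVector bytes) {
  uint64_t h = 0xcbf29ce484222325ULL;
  const uint8_t *p = RAW(bytes);
  R_xlen_t n = bytes.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    h ^= (uint64_t)p[i];
    h *= 0x100000001b3ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}

// [[Rcpp::export]]
double cpp_count_nonzero_slots(RawVector slots, double nb_slots, int b) {
  uint64_t m = (uint64_t)nb_slots;
  const uint8_t *p = RAW(slots);
  double cnt = 0;
  for (uint64_t i = 0; i < m; ++i)
    if (slot_get(p, i, b) > 0) cnt += 1;
  return cnt;
}
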
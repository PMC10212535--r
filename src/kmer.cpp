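#include <Rcpp.h>
#include "dna.h"
using namespace Rcpp;

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector words) {
  R_xlen_t n = words.size();
  CharacterVector out(n);
  std::vector<uint8_t> codes;
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *w = CHAR(STRING_ELT(words, i));
    size_t len = strlen(w), bad = 0;
    if (!encode_word(w, len, codes, &bad))
      stop("non-ACGT character at position %d in '%s'", (int)(bad + 1), w);
    buf.resize(len);
    for (size_t j = 0; j < len; ++j) buf[j] = code_char(3 - codes[len - 1 - j]);
    out[i] = buf;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector words) {
  R_xlen_t n = words.size();
  CharacterVector out(n);
  std::vector<uint8_t> codes, canon;
  std::string buf;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *w = CHAR(STRING_ELT(words, i));
    size_t len = strlen(w), bad = 0;
    if (!encode_word(w, len, codes, &bad))
      stop("non-ACGT character at position %d in '%s'", (int)(bad + 1), w);
    canonical_codes(codes, canon);
    buf.resize(len);
    for (size_t j = 0; j < len; ++j) buf[j] = code_char(canon[j]);
    out[i] = buf;
  }
  return out;
}

// Encode a sequence; codes[j] = -1 marks a non-ACGT character.
static void encode_seq(const char *seq, size_t L, std::vector<int> &codes) {
  codes.resize(L);
  for (size_t j = 0; j < L; ++j) codes[j] = dna_code(seq[j]);
}

// [[Rcpp::export]]
List cpp_enumerate_smers(std::string seq, int s, bool canonicalize) {
  if (s < 1) stop("s must be >= 1");
  size_t L = seq.size();
  R_xlen_t n = (L >= (size_t)s) ? (R_xlen_t)(L - s + 1) : 0;
  CharacterVector smers(n);
  LogicalVector valid(n);
  std::vector<int> codes;
  encode_seq(seq.c_str(), L, codes);
  std::vector<uint8_t> win, canon;
  std::string buf((size_t)s, 'A');
  for (R_xlen_t i = 0; i < n; ++i) {
    bool ok = true;
    for (int j = 0; j < s; ++j) if (codes[i + j] < 0) { ok = false; break; }
    valid[i] = ok;
    if (ok) {
      win.resize(s);
      for (int j = 0; j < s; ++j) win[j] = (uint8_t)codes[i + j];
      if (canonicalize) { canonical_codes(win, canon); win = canon; }
      for (int j = 0; j < s; ++j) buf[j] = code_char(win[j]);
      smers[i] = buf;
    } else {
      // keep the raw (uppercased) substring so positions stay aligned
      for (int j = 0; j < s; ++j)
        buf[j] = codes[i + j] >= 0 ? code_char(codes[i + j]) : (char)toupper(seq[i + j]);
      smers[i] = buf;
    }
  }
  return List::create(_["smers"] = smers, _["valid"] = valid);
}

static uint32_t lookup_window(const uint8_t *p, uint64_t m, int b,
                              const std::vector<int> &codes, R_xlen_t at, int s,
                              bool canonicalize, std::vector<uint8_t> &win,
                              std::vector<uint8_t> &canon) {
  for (int j = 0; j < s; ++j)
    if (codes[at + j] < 0) return 0;  // window with non-ACGT: treated as absent
  win.resize(s);
  for (int j = 0; j < s; ++j) win[j] = (uint8_t)codes[at + j];
  const uint8_t *key = win.data();
  if (canonicalize) { canonical_codes(win, canon); key = canon.data(); }
  return slot_get(p, hash_codes(key, (size_t)s) % m, b);
}

// [[Rcpp::export]]
IntegerVector cpp_query_responses(RawVector slots, double nb_slots, int b,
                                  std::string seq, int s, bool canonicalize) {
  uint64_t m = (uint64_t)nb_slots;
  const uint8_t *p = RAW(slots);
  size_t L = seq.size();
  R_xlen_t n = (L >= (size_t)s) ? (R_xlen_t)(L - s + 1) : 0;
  IntegerVector out(n);
  std::vector<int> codes;
  encode_seq(seq.c_str(), L, codes);
  std::vector<uint8_t> win, canon;
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (int)lookup_window(p, m, b, codes, i, s, canonicalize, win, canon);
  return out;
}

template <typename T>
static void fixed_window_min_buf(T *v, R_xlen_t n, R_xlen_t W) {
  T run = v[0];
  R_xlen_t block_start = 0;
  for (R_xlen_t t = 0; t < n; ++t) {
    R_xlen_t o = t - block_start;
    run = (o == 0) ? v[t] : std::min(run, v[t]);
    R_xlen_t i = t - W + 1;
    if (i >= 0) v[i] = (o == W - 1) ? run : std::min(run, v[i]);
    if (o == W - 1 || t == n - 1) {
      for (R_xlen_t u = t - 1; u >= block_start; --u) v[u] = std::min(v[u], v[u + 1]);
      block_start = t + 1;
    }
  }
}

// Per-k-mer minimum of stored s-mer responses along a sequence.  The
// unoptimized path looks up every s-mer then takes sliding-window minima.
// The optimized path exploits absence: an s-mer response of 0 zeroes every
// window spanning it, so those windows are emitted without inspection and
// s-mer lookups beyond the last window are never performed.  Both paths
// return bit-identical results; the number of filter probes actually made is
// attached as attribute "lookups".
// [[Rcpp::export]]
IntegerVector cpp_query_ranks(RawVector slots, double nb_slots, int b,
                              std::string seq, int s, int W, bool canonicalize,
                              bool optimize) {
  uint64_t m = (uint64_t)nb_slots;
  const uint8_t *p = RAW(slots);
  size_t L = seq.size();
  R_xlen_t n_resp = (L >= (size_t)s) ? (R_xlen_t)(L - s + 1) : 0;
  R_xlen_t n_out = n_resp - W + 1;
  if (n_out < 0) n_out = 0;
  IntegerVector out(n_out);
  std::vector<int> codes;
  encode_seq(seq.c_str(), L, codes);
  std::vector<uint8_t> win, canon;
  double lookups = 0;

  if (n_out == 0) { out.attr("lookups") = 0.0; return out; }

  if (!optimize) {
    std::vector<int> resp(n_resp);
    for (R_xlen_t q = 0; q < n_resp; ++q) {
      resp[q] = (int)lookup_window(p, m, b, codes, q, s, canonicalize, win, canon);
      lookups += 1;
    }
    fixed_window_min_buf(resp.data(), n_resp, (R_xlen_t)W);
    for (R_xlen_t i = 0; i < n_out; ++i) out[i] = resp[i];
    out.attr("lookups") = lookups;
    return out;
  }

  // memoized lazy responses: -1 = not probed yet
  std::vector<int> resp(n_resp, -1);
  std::vector<int> seg;
  R_xlen_t pos = 0;
  while (pos < n_out) {
    // probe the current window, stopping at the first absent s-mer
    R_xlen_t zero = -1;
    for (R_xlen_t q = pos; q < pos + W; ++q) {
      if (resp[q] < 0) {
        resp[q] = (int)lookup_window(p, m, b, codes, q, s, canonicalize, win, canon);
        lookups += 1;
      }
      if (resp[q] == 0) { zero = q; break; }
    }
    if (zero >= 0) {
      // all windows spanning `zero` are absent
      R_xlen_t last = std::min(zero, n_out - 1);
      for (R_xlen_t q = pos; q <= last; ++q) out[q] = 0;
      pos = zero + 1;
      continue;
    }
    // extend the zero-free run as far as it goes
    R_xlen_t e = pos + W;
    while (e < n_resp) {
      if (resp[e] < 0) {
        resp[e] = (int)lookup_window(p, m, b, codes, e, s, canonicalize, win, canon);
        lookups += 1;
      }
      if (resp[e] == 0) break;
      ++e;
    }
    // windows fully inside [pos, e) are zero-free: sliding minima on the run
    seg.assign(resp.begin() + pos, resp.begin() + e);
    fixed_window_min_buf(seg.data(), (R_xlen_t)seg.size(), (R_xlen_t)W);
    R_xlen_t run_out = (R_xlen_t)seg.size() - W + 1;
    for (R_xlen_t q = 0; q < run_out && pos + q < n_out; ++q) out[pos + q] = seg[q];
    pos += run_out;  // window at pos+run_out (if any) spans the 0 at e
  }
  out.attr("lookups") = lookups;
  return out;
}

// Assemble DNA words from 2-bit codes drawn in R (keeps all randomness under
// R's RNG); codes are 0..3, length(codes) must be a multiple of len.
// [[Rcpp::export]]
CharacterVector cpp_codes_to_dna(IntegerVector codes, int len) {
  if (len < 1) stop("len must be >= 1");
  if (codes.size() % len != 0) stop("length(codes) must be a multiple of len");
  R_xlen_t n = codes.size() / len;
  CharacterVector out(n);
  std::string buf((size_t)len, 'A');
  for (R_xlen_t i = 0; i < n; ++i) {
    for (int j = 0; j < len; ++j) {
      int c = codes[i * len + j];
      if (c < 0 || c > 3) stop("codes must be in 0..3");
      buf[j] = code_char(c);
    }
    out[i] = buf;
  }
  return out;
}
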
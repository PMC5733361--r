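#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// xorshift128 step (Marsaglia-style 128-bit xorshift, period 2^128 - 1).
// State words are carried between R and C++ as doubles holding exact
// 32-bit unsigned values (doubles represent integers < 2^53 exactly).
static inline uint32_t xs_step(uint32_t s[4]) {
  uint32_t t = s[0] ^ (s[0] << 11);
  t ^= t >> 8;
  s[0] = s[1];
  s[1] = s[2];
  s[2] = s[3];
  s[3] = (s[3] ^ (s[3] >> 19)) ^ t;
  return s[3];
}

// [[Rcpp::export(name = ".xs128_fill")]]
List xs128_fill(NumericVector state, double n) {
  if (state.size() != 4) stop("state must have 4 words");
  uint32_t s[4];
  for (int i = 0; i < 4; ++i) s[i] = (uint32_t)state[i];
  R_xlen_t nn = (R_xlen_t)n;
  NumericVector out(nn);
  for (R_xlen_t i = 0; i < nn; ++i) out[i] = (double)xs_step(s);
  NumericVector ns(4);
  for (int i = 0; i < 4; ++i) ns[i] = (double)s[i];
  return List::create(_["words"] = out, _["state"] = ns);
}

// [[Rcpp::export(name = ".xs128_skip")]]
NumericVector xs128_skip(NumericVector state, double n) {
  if (state.size() != 4) stop("state must have 4 words");
  uint32_t s[4];
  for (int i = 0; i < 4; ++i) s[i] = (uint32_t)state[i];
  R_xlen_t nn = (R_xlen_t)n;
  for (R_xlen_t i = 0; i < nn; ++i) xs_step(s);
  NumericVector ns(4);
  for (int i = 0; i < 4; ++i) ns[i] = (double)s[i];
  return ns;
}

// CRC-32 (IEEE 802.3, as used by PNG chunks), table-driven.
static uint32_t crc_table[256];
static bool crc_table_ready = false;

static void crc_init() {
  for (uint32_t k = 0; k < 256; ++k) {
    uint32_t c = k;
    for (int j = 0; j < 8; ++j)
      c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
    crc_table[k] = c;
  }
  crc_table_ready = true;
}

// [[Rcpp::export(name = ".crc32")]]
double crc32_raw(RawVector data) {
  if (!crc_table_ready) crc_init();
  uint32_t c = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    c = crc_table[(c ^ data[i]) & 0xFFu] ^ (c >> 8);
  return (double)(c ^ 0xFFFFFFFFu);
}
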
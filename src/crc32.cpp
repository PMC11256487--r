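#include <Rcpp.h>
#include <stdint.h>

// CRC-32 (IEEE 802.3 polynomial, reflected), as used by the ZIP container.

static uint32_t crc_table[256];
static bool crc_table_ready = false;

static void init_crc_table() {
  for (uint32_t i = 0; i < 256; ++i) {
    uint32_t c = i;
    for (int k = 0; k < 8; ++k)
      c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
    crc_table[i] = c;
  }
  crc_table_ready = true;
}

// [[Rcpp::export(name = ".crc32_raw")]]
double crc32_raw(Rcpp::RawVector data) {
  if (!crc_table_ready) init_crc_table();
  uint32_t c = 0xFFFFFFFFu;
  const R_xlen_t n = data.size();
  for (R_xlen_t i = 0; i < n; ++i)
    c = crc_table[(c ^ data[i]) & 0xFFu] ^ (c >> 8);
  return static_cast<double>(c ^ 0xFFFFFFFFu);
}
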
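#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Packed deltas live in 32-bit words, LSB-first: stream bit b is bit (b % 32)
// of word b / 32.  Every field is at most 32 bits wide, so a read or write
// touches at most two words.

static inline uint64_t width_mask(int width) {
  return (width >= 32) ? 0xFFFFFFFFULL : ((1ULL << width) - 1ULL);
}

static inline uint32_t get_bits(const uint32_t *w, uint64_t off, int width) {
  if (width == 0) return 0;
  uint64_t wi = off >> 5;
  int b = (int)(off & 31);
  uint64_t v = (uint64_t)w[wi] >> b;
  if (b + width > 32) v |= (uint64_t)w[wi + 1] << (32 - b);
  return (uint32_t)(v & width_mask(width));
}

static inline void put_bits(uint32_t *w, uint64_t off, int width, uint32_t val) {
  if (width == 0) return;
  uint64_t wi = off >> 5;
  int b = (int)(off & 31);
  uint64_t mask = width_mask(width) << b;
  uint64_t v = ((uint64_t)val << b) & mask;
  w[wi] = (uint32_t)(((uint64_t)w[wi] & ~mask) | v);
  if (b + width > 32) {
    uint64_t himask = mask >> 32;
    w[wi + 1] = (uint32_t)(((uint64_t)w[wi + 1] & ~himask) | (v >> 32));
  }
}

static inline int bits_for_range(uint32_t range) {
  // ceil(log2(range + 1)) in integer arithmetic
  int b = 0;
  while (range) { b++; range >>= 1; }
  return b;
}

// ---- bitstream primitives -------------------------------------------------

// [[Rcpp::export(name = ".bs_read")]]
double bs_read(IntegerVector words, double bit_offset, int width) {
  return (double)get_bits((const uint32_t *)INTEGER(words),
                          (uint64_t)bit_offset, width);
}

// [[Rcpp::export(name = ".bs_write")]]
IntegerVector bs_write(IntegerVector words, double bit_offset, int width,
                       double value) {
  IntegerVector out = clone(words);
  put_bits((uint32_t *)INTEGER(out), (uint64_t)bit_offset, width,
           (uint32_t)value);
  return out;
}

// [[Rcpp::export(name = ".bs_read_many")]]
NumericVector bs_read_many(IntegerVector words, NumericVector offsets,
                           IntegerVector widths) {
  R_xlen_t k = offsets.size();
  NumericVector out(k);
  const uint32_t *w = (const uint32_t *)INTEGER(words);
  for (R_xlen_t i = 0; i < k; i++)
    out[i] = (double)get_bits(w, (uint64_t)offsets[i], widths[i]);
  return out;
}

// [[Rcpp::export(name = ".bs_pack")]]
List bs_pack(NumericVector values, int width) {
  R_xlen_t k = values.size();
  uint64_t nbits = (uint64_t)width * (uint64_t)k;
  R_xlen_t nwords = (R_xlen_t)((nbits + 31) / 32);
  IntegerVector words(nwords); // zero-initialised
  uint32_t *w = (uint32_t *)INTEGER(words);
  for (R_xlen_t i = 0; i < k; i++)
    put_bits(w, (uint64_t)i * width, width, (uint32_t)values[i]);
  return List::create(_["words"] = words, _["bit_length"] = (double)nbits);
}

// ---- codec ----------------------------------------------------------------

// data has R dim (n, Z, Y, X): the time series of voxel (z, y, x) is the
// contiguous run starting at n * (z + Z*(y + Y*x)).  Voxels are linearised
// j = (z*Y + y)*X + x (x fastest) for the C/B/O/D arrays.

static inline R_xlen_t series_base(R_xlen_t j, int n, int Z, int Y, int X) {
  R_xlen_t x = j % X, y = (j / X) % Y, z = j / ((R_xlen_t)X * Y);
  return (R_xlen_t)n * (z + (R_xlen_t)Z * (y + (R_xlen_t)Y * x));
}

// [[Rcpp::export(name = ".codec_compress")]]
List codec_compress(IntegerVector data, int n, int Z, int Y, int X) {
  R_xlen_t m = (R_xlen_t)Z * Y * X;
  IntegerVector C(m), B(m);
  NumericVector O(m);
  uint64_t total = 0;
  for (R_xlen_t j = 0; j < m; j++) {
    R_xlen_t base = series_base(j, n, Z, Y, X);
    int lo = data[base], hi = data[base];
    for (int t = 1; t < n; t++) {
      int v = data[base + t];
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    C[j] = lo;
    B[j] = bits_for_range((uint32_t)(hi - lo));
    O[j] = (double)total;
    total += (uint64_t)n * B[j];
  }
  IntegerVector words((R_xlen_t)((total + 31) / 32));
  uint32_t *w = (uint32_t *)INTEGER(words);
  for (R_xlen_t j = 0; j < m; j++) {
    int width = B[j];
    if (width == 0) continue;
    R_xlen_t base = series_base(j, n, Z, Y, X);
    uint64_t off = (uint64_t)O[j];
    int c = C[j];
    for (int t = 0; t < n; t++)
      put_bits(w, off + (uint64_t)t * width, width,
               (uint32_t)(data[base + t] - c));
  }
  return List::create(_["C"] = C, _["B"] = B, _["O"] = O, _["words"] = words,
                      _["bit_length"] = (double)total);
}

// [[Rcpp::export(name = ".codec_decompress")]]
IntegerVector codec_decompress(IntegerVector C, IntegerVector B,
                               NumericVector O, IntegerVector words, int n,
                               int Z, int Y, int X) {
  R_xlen_t m = (R_xlen_t)Z * Y * X;
  IntegerVector data((R_xlen_t)n * m);
  const uint32_t *w = (const uint32_t *)INTEGER(words);
  for (R_xlen_t j = 0; j < m; j++) {
    R_xlen_t base = series_base(j, n, Z, Y, X);
    int width = B[j], c = C[j];
    uint64_t off = (uint64_t)O[j];
    if (width == 0) {
      for (int t = 0; t < n; t++) data[base + t] = c;
    } else {
      for (int t = 0; t < n; t++)
        data[base + t] = c + (int)get_bits(w, off + (uint64_t)t * width, width);
    }
  }
  return data;
}

// [[Rcpp::export(name = ".codec_read_voxel")]]
int codec_read_voxel(IntegerVector C, IntegerVector B, NumericVector O,
                     IntegerVector words, int n, double j0, int t0) {
  R_xlen_t j = (R_xlen_t)j0;
  int width = B[j];
  if (width == 0) return C[j];
  const uint32_t *w = (const uint32_t *)INTEGER(words);
  return C[j] + (int)get_bits(w, (uint64_t)O[j] + (uint64_t)t0 * width, width);
}

// [[Rcpp::export(name = ".codec_read_timeseries")]]
IntegerVector codec_read_timeseries(IntegerVector C, IntegerVector B,
                                    NumericVector O, IntegerVector words,
                                    int n, double j0) {
  R_xlen_t j = (R_xlen_t)j0;
  IntegerVector out(n);
  int width = B[j], c = C[j];
  if (width == 0) {
    std::fill(out.begin(), out.end(), c);
    return out;
  }
  const uint32_t *w = (const uint32_t *)INTEGER(words);
  uint64_t off = (uint64_t)O[j];
  for (int t = 0; t < n; t++)
    out[t] = c + (int)get_bits(w, off + (uint64_t)t * width, width);
  return out;
}

// ---- compressed-domain double-threshold mask ------------------------------

// reduction: 0 = per_timestep (mask over n*m), 1 = all_timesteps,
// 2 = any_timestep (mask over m).  A voxel whose bound interval
// [C, C + 2^B - 1] lies entirely inside or entirely outside [lo, hi] is
// resolved without reading a single delta bit.

// [[Rcpp::export(name = ".codec_mask")]]
List codec_mask(IntegerVector C, IntegerVector B, NumericVector O,
                IntegerVector words, int n, int Z, int Y, int X, int lo,
                int hi, int reduction) {
  R_xlen_t m = (R_xlen_t)Z * Y * X;
  const uint32_t *w = (const uint32_t *)INTEGER(words);
  LogicalVector mask(reduction == 0 ? (R_xlen_t)n * m : m);
  double pruned = 0, delta_reads = 0;
  for (R_xlen_t j = 0; j < m; j++) {
    int width = B[j], c = C[j];
    int vmax = c + (int)((width >= 31) ? (uint32_t)INT32_MAX
                                       : ((1u << width) - 1u));
    bool all_in = (c >= lo) && (vmax <= hi);
    bool all_out = (vmax < lo) || (c > hi);
    // voxel index for reduced masks: dim (Z, Y, X), z fastest
    R_xlen_t x = j % X, y = (j / X) % Y, z = j / ((R_xlen_t)X * Y);
    R_xlen_t vox = z + (R_xlen_t)Z * (y + (R_xlen_t)Y * x);
    R_xlen_t base = (R_xlen_t)n * vox; // per-timestep layout (n, Z, Y, X)
    if (all_in || all_out) {
      pruned += 1;
      if (reduction == 0) {
        for (int t = 0; t < n; t++) mask[base + t] = all_in;
      } else {
        mask[vox] = all_in;
      }
      continue;
    }
    uint64_t off = (uint64_t)O[j];
    bool all = true, any = false;
    for (int t = 0; t < n; t++) {
      int v = c + (int)get_bits(w, off + (uint64_t)t * width, width);
      delta_reads += 1;
      bool in = (v >= lo) && (v <= hi);
      if (reduction == 0) mask[base + t] = in;
      all = all && in;
      any = any || in;
    }
    if (reduction == 1) mask[vox] = all;
    if (reduction == 2) mask[vox] = any;
  }
  return List::create(_["mask"] = mask, _["voxels_pruned"] = pruned,
                      _["delta_reads"] = delta_reads);
}

// ---- CRC-32 (IEEE 802.3 polynomial) for the container checksum ------------

// [[Rcpp::export(name = ".crc32")]]
double crc32_raw(RawVector bytes) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; i++) {
      uint32_t c = i;
      for (int k = 0; k < 8; k++)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < bytes.size(); i++)
    crc = table[(crc ^ bytes[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
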
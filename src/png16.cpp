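#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <vector>
using namespace Rcpp;

// Minimal 16-bit grayscale PNG writer.  The CRAN `png` package reads 16-bit
// PNGs but only writes 8-bit ones, which would destroy millimeter depth
// resolution, so depth frames are encoded here directly: one IHDR (bit depth
// 16, color type 0), one zlib-compressed IDAT with filter type 0 scanlines,
// one IEND.  Samples are big-endian per the PNG specification.

static void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

static void write_chunk(FILE* f, const char type[4],
                        const std::vector<unsigned char>& data) {
  std::vector<unsigned char> hdr;
  put_u32(hdr, (uint32_t)data.size());
  fwrite(hdr.data(), 1, 4, f);
  fwrite(type, 1, 4, f);
  if (!data.empty()) fwrite(data.data(), 1, data.size(), f);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, (const Bytef*)type, 4);
  if (!data.empty()) crc = crc32(crc, data.data(), (uInt)data.size());
  std::vector<unsigned char> tail;
  put_u32(tail, (uint32_t)crc);
  fwrite(tail.data(), 1, 4, f);
}

// depth: integer matrix (rows = image rows), values in [0, 65535]
// [[Rcpp::export(name = ".write_png16")]]
void write_png16(std::string path, const IntegerMatrix& depth) {
  int nr = depth.nrow(), nc = depth.ncol();
  std::vector<unsigned char> raw;
  raw.reserve((size_t)nr * (2 * nc + 1));
  for (int i = 0; i < nr; ++i) {
    raw.push_back(0);  // filter type: none
    for (int j = 0; j < nc; ++j) {
      int v = depth(i, j);
      if (v == NA_INTEGER) v = 0;
      if (v < 0 || v > 65535)
        stop("depth value %d out of 16-bit PNG range [0, 65535]", v);
      raw.push_back((v >> 8) & 0xff);
      raw.push_back(v & 0xff);
    }
  }
  uLongf bound = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(bound);
  if (compress2(comp.data(), &bound, raw.data(), (uLong)raw.size(),
                Z_DEFAULT_COMPRESSION) != Z_OK)
    stop("zlib compression failed");
  comp.resize(bound);

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  fwrite(sig, 1, 8, f);
  std::vector<unsigned char> ihdr;
  put_u32(ihdr, (uint32_t)nc);  // width
  put_u32(ihdr, (uint32_t)nr);  // height
  ihdr.push_back(16);  // bit depth
  ihdr.push_back(0);   // color type: grayscale
  ihdr.push_back(0);   // compression
  ihdr.push_back(0);   // filter
  ihdr.push_back(0);   // interlace
  write_chunk(f, "IHDR", ihdr);
  write_chunk(f, "IDAT", comp);
  write_chunk(f, "IEND", std::vector<unsigned char>());
  std::fclose(f);
}
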
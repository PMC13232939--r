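// Bit-level codec core: two-bit / four-bit base packing into little-endian
// 64-bit words, fixed-size (BQ) and variable-size (VBQ) record
// serialization, ZSTD block compression, and uniform-random read synthesis.
//
// Conventions (fixed for the on-disk formats):
//   codes: A=0, C=1, G=2, T=3; four-bit additionally N=8.
//   base i of a sequence occupies bits [i*bits, (i+1)*bits) of word i/B,
//   least-significant-first, with B = 64/bits bases per word; words are
//   serialized little-endian, so the byte stream is position-monotone and
//   packing can operate directly on bytes.
//   Trailing pad bits of the final word are always zero.

#include <Rcpp.h>
#include <zstd.h>
#include <cstdint>
#include <cstring>
#include <string>

using namespace Rcpp;

static inline int base_code(unsigned char c, int bits) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  case 'N': case 'n': return bits == 4 ? 8 : -1;
  default: return -1;
  }
}

static inline char code_base(int code, int bits, R_xlen_t pos) {
  static const char acgt[4] = {'A', 'C', 'G', 'T'};
  if (code >= 0 && code < 4) return acgt[code];
  if (bits == 4 && code == 8) return 'N';
  stop("corrupt %d-bit payload: code %d at base %td has no table entry",
       bits, code, (ptrdiff_t)(pos + 1));
  return 'X'; // unreached
}

static inline void check_bits(int bits) {
  if (bits != 2 && bits != 4) stop("encoding must be 2 or 4 bits per base");
}

// bytes occupied by n bases after padding to whole 64-bit words
static inline uint64_t padded_bytes(uint64_t n_bases, int bits) {
  uint64_t B = 64 / bits;                  // bases per word
  return 8 * ((n_bases + B - 1) / B);
}

// pack seq[0..n) into dst (dst must be zeroed, padded_bytes long);
// returns index of first invalid base or -1
static ptrdiff_t pack_into(uint8_t *dst, const char *seq, R_xlen_t n, int bits) {
  const int per_byte = 8 / bits;
  for (R_xlen_t i = 0; i < n; ++i) {
    int code = base_code((unsigned char)seq[i], bits);
    if (code < 0) return (ptrdiff_t)i;
    dst[i / per_byte] |= (uint8_t)(code << ((i % per_byte) * bits));
  }
  return -1;
}

static void unpack_into(char *dst, const uint8_t *src, R_xlen_t n, int bits) {
  const int per_byte = 8 / bits;
  const int mask = (1 << bits) - 1;
  for (R_xlen_t i = 0; i < n; ++i) {
    int code = (src[i / per_byte] >> ((i % per_byte) * bits)) & mask;
    dst[i] = code_base(code, bits, i);
  }
}

static inline void put_u64(uint8_t *p, uint64_t v) {
  for (int i = 0; i < 8; ++i) p[i] = (uint8_t)(v >> (8 * i));
}

static inline uint64_t get_u64(const uint8_t *p) {
  uint64_t v = 0;
  for (int i = 0; i < 8; ++i) v |= (uint64_t)p[i] << (8 * i);
  return v;
}

static inline void put_u16(uint8_t *p, uint16_t v) {
  p[0] = (uint8_t)v;
  p[1] = (uint8_t)(v >> 8);
}

static inline uint16_t get_u16(const uint8_t *p) {
  return (uint16_t)p[0] | ((uint16_t)p[1] << 8);
}

// ---------------------------------------------------------------- encoding

// [[Rcpp::export(".cpp_pack")]]
RawVector cpp_pack(std::string seq, int bits) {
  check_bits(bits);
  R_xlen_t n = (R_xlen_t)seq.size();
  RawVector out(padded_bytes(n, bits));
  std::memset(RAW(out), 0, out.size());
  ptrdiff_t bad = pack_into(RAW(out), seq.data(), n, bits);
  if (bad >= 0)
    stop("invalid nucleotide '%c' at position %td for %d-bit encoding",
         seq[bad], bad + 1, bits);
  return out;
}

// [[Rcpp::export(".cpp_unpack")]]
CharacterVector cpp_unpack(RawVector buf, double n_bases, int bits) {
  check_bits(bits);
  R_xlen_t n = (R_xlen_t)n_bases;
  if (n < 0) stop("n_bases must be non-negative");
  if ((uint64_t)buf.size() < padded_bytes(n, bits))
    stop("packed buffer too short: %td bytes for %td bases",
         (ptrdiff_t)buf.size(), (ptrdiff_t)n);
  std::string s((size_t)n, '\0');
  unpack_into(&s[0], RAW(buf), n, bits);
  return CharacterVector::create(String(s));
}

// ------------------------------------------------------------ BQ records

// Fixed-size record blob: for each record, optional 8-byte flag, then
// padded primary words, then padded extended words.
// [[Rcpp::export(".cpp_pack_records")]]
RawVector cpp_pack_records(CharacterVector primary,
                           Nullable<CharacterVector> extended,
                           Nullable<NumericVector> flags,
                           int slen, int xlen, int bits, bool flag_enabled) {
  check_bits(bits);
  R_xlen_t n = primary.size();
  bool paired = xlen > 0;
  uint64_t pbytes = padded_bytes(slen, bits);
  uint64_t xbytes = paired ? padded_bytes(xlen, bits) : 0;
  uint64_t fbytes = flag_enabled ? 8 : 0;
  uint64_t rec = fbytes + pbytes + xbytes;

  CharacterVector ext;
  if (paired) {
    if (extended.isNull()) stop("extended sequences required when xlen > 0");
    ext = extended.get();
    if (ext.size() != n) stop("primary/extended record count mismatch");
  }
  NumericVector flg;
  if (flag_enabled && flags.isNotNull()) {
    flg = flags.get();
    if (flg.size() != n) stop("flag vector length mismatch");
  }

  RawVector out((R_xlen_t)(rec * n));
  std::memset(RAW(out), 0, out.size());
  uint8_t *p = RAW(out);

  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP sp = STRING_ELT(primary, i);
    if (LENGTH(sp) != slen)
      stop("record %td: primary length %d does not match slen %d "
           "(use VBQ for variable-length records)",
           (ptrdiff_t)(i + 1), LENGTH(sp), slen);
    uint8_t *r = p + (uint64_t)i * rec;
    if (flag_enabled)
      put_u64(r, flg.size() ? (uint64_t)flg[i] : 0);
    ptrdiff_t bad = pack_into(r + fbytes, CHAR(sp), slen, bits);
    if (bad >= 0)
      stop("record %td: invalid nucleotide '%c' at position %td",
           (ptrdiff_t)(i + 1), CHAR(sp)[bad], bad + 1);
    if (paired) {
      SEXP sx = STRING_ELT(ext, i);
      if (LENGTH(sx) != xlen)
        stop("record %td: extended length %d does not match xlen %d "
             "(use VBQ for variable-length records)",
             (ptrdiff_t)(i + 1), LENGTH(sx), xlen);
      bad = pack_into(r + fbytes + pbytes, CHAR(sx), xlen, bits);
      if (bad >= 0)
        stop("record %td: invalid nucleotide '%c' at extended position %td",
             (ptrdiff_t)(i + 1), CHAR(sx)[bad], bad + 1);
    }
  }
  return out;
}

// [[Rcpp::export(".cpp_unpack_records")]]
List cpp_unpack_records(RawVector blob, double n_records,
                        int slen, int xlen, int bits, bool flag_enabled) {
  check_bits(bits);
  R_xlen_t n = (R_xlen_t)n_records;
  bool paired = xlen > 0;
  uint64_t pbytes = padded_bytes(slen, bits);
  uint64_t xbytes = paired ? padded_bytes(xlen, bits) : 0;
  uint64_t fbytes = flag_enabled ? 8 : 0;
  uint64_t rec = fbytes + pbytes + xbytes;
  if ((uint64_t)blob.size() != rec * (uint64_t)n)
    stop("record blob size %td is not %td records of %td bytes",
         (ptrdiff_t)blob.size(), (ptrdiff_t)n, (ptrdiff_t)rec);

  CharacterVector primary(n);
  CharacterVector ext(paired ? n : 0);
  NumericVector flg(flag_enabled ? n : 0);
  std::string pb((size_t)slen, '\0'), xb((size_t)(paired ? xlen : 0), '\0');
  const uint8_t *p = RAW(blob);

  for (R_xlen_t i = 0; i < n; ++i) {
    const uint8_t *r = p + (uint64_t)i * rec;
    if (flag_enabled) flg[i] = (double)get_u64(r);
    unpack_into(&pb[0], r + fbytes, slen, bits);
    SET_STRING_ELT(primary, i, Rf_mkCharLen(pb.data(), slen));
    if (paired) {
      unpack_into(&xb[0], r + fbytes + pbytes, xlen, bits);
      SET_STRING_ELT(ext, i, Rf_mkCharLen(xb.data(), xlen));
    }
  }
  return List::create(
      _["primary"] = primary,
      _["extended"] = paired ? (SEXP)ext : R_NilValue,
      _["flag"] = flag_enabled ? (SEXP)flg : R_NilValue);
}

// ------------------------------------------------------------ VBQ records

// Variable-size record wire layout (all integers little-endian):
//   [flag u64]? [slen u64] [xlen u64]? [primary words] [extended words]?
//   [qual_primary slen bytes]? [qual_extended xlen bytes]?
//   [u16 len + header_primary]? [u16 len + header_extended]?
// Optional fields are governed by the file-level feature flags.

static uint64_t vbq_rec_bytes(uint64_t sl, uint64_t xl, int bits, bool paired,
                              bool has_q, bool has_h, bool has_f,
                              uint64_t hl, uint64_t ehl) {
  uint64_t sz = (has_f ? 8 : 0) + 8 + (paired ? 8 : 0);
  sz += padded_bytes(sl, bits) + (paired ? padded_bytes(xl, bits) : 0);
  if (has_q) sz += sl + (paired ? xl : 0);
  if (has_h) sz += 2 + hl + (paired ? 2 + ehl : 0);
  return sz;
}

// [[Rcpp::export(".cpp_vbq_serialize")]]
RawVector cpp_vbq_serialize(CharacterVector primary,
                            Nullable<CharacterVector> extended,
                            Nullable<CharacterVector> qual_primary,
                            Nullable<CharacterVector> qual_extended,
                            Nullable<CharacterVector> header_primary,
                            Nullable<CharacterVector> header_extended,
                            Nullable<NumericVector> flags,
                            int bits, bool paired, bool has_quality,
                            bool has_headers, bool has_flags) {
  check_bits(bits);
  R_xlen_t n = primary.size();
  CharacterVector ext, qp, qx, hp, hx;
  NumericVector flg;
  if (paired) ext = extended.get();
  if (has_quality) {
    qp = qual_primary.get();
    if (paired) qx = qual_extended.get();
  }
  if (has_headers) {
    hp = header_primary.get();
    if (paired) hx = header_extended.get();
  }
  if (has_flags && flags.isNotNull()) flg = flags.get();

  uint64_t total = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t sl = LENGTH(STRING_ELT(primary, i));
    uint64_t xl = paired ? LENGTH(STRING_ELT(ext, i)) : 0;
    uint64_t hl = has_headers ? LENGTH(STRING_ELT(hp, i)) : 0;
    uint64_t ehl = (has_headers && paired) ? LENGTH(STRING_ELT(hx, i)) : 0;
    if (hl > 65535 || ehl > 65535)
      stop("record %td: sequence header exceeds 65535 bytes", (ptrdiff_t)(i + 1));
    total += vbq_rec_bytes(sl, xl, bits, paired, has_quality, has_headers,
                           has_flags, hl, ehl);
  }

  RawVector out((R_xlen_t)total);
  std::memset(RAW(out), 0, out.size());
  uint8_t *p = RAW(out);

  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP sp = STRING_ELT(primary, i);
    uint64_t sl = LENGTH(sp);
    SEXP sx = paired ? STRING_ELT(ext, i) : R_NilValue;
    uint64_t xl = paired ? LENGTH(sx) : 0;

    if (has_flags) { put_u64(p, flg.size() ? (uint64_t)flg[i] : 0); p += 8; }
    put_u64(p, sl); p += 8;
    if (paired) { put_u64(p, xl); p += 8; }

    ptrdiff_t bad = pack_into(p, CHAR(sp), sl, bits);
    if (bad >= 0)
      stop("record %td: invalid nucleotide '%c' at position %td",
           (ptrdiff_t)(i + 1), CHAR(sp)[bad], bad + 1);
    p += padded_bytes(sl, bits);
    if (paired) {
      bad = pack_into(p, CHAR(sx), xl, bits);
      if (bad >= 0)
        stop("record %td: invalid nucleotide '%c' at extended position %td",
             (ptrdiff_t)(i + 1), CHAR(sx)[bad], bad + 1);
      p += padded_bytes(xl, bits);
    }
    if (has_quality) {
      SEXP q = STRING_ELT(qp, i);
      if ((uint64_t)LENGTH(q) != sl)
        stop("record %td: quality length %d != sequence length %td",
             (ptrdiff_t)(i + 1), LENGTH(q), (ptrdiff_t)sl);
      std::memcpy(p, CHAR(q), sl); p += sl;
      if (paired) {
        SEXP qe = STRING_ELT(qx, i);
        if ((uint64_t)LENGTH(qe) != xl)
          stop("record %td: extended quality length %d != %td",
               (ptrdiff_t)(i + 1), LENGTH(qe), (ptrdiff_t)xl);
        std::memcpy(p, CHAR(qe), xl); p += xl;
      }
    }
    if (has_headers) {
      SEXP h = STRING_ELT(hp, i);
      put_u16(p, (uint16_t)LENGTH(h)); p += 2;
      std::memcpy(p, CHAR(h), LENGTH(h)); p += LENGTH(h);
      if (paired) {
        SEXP he = STRING_ELT(hx, i);
        put_u16(p, (uint16_t)LENGTH(he)); p += 2;
        std::memcpy(p, CHAR(he), LENGTH(he)); p += LENGTH(he);
      }
    }
  }
  return out;
}

// [[Rcpp::export(".cpp_vbq_parse")]]
List cpp_vbq_parse(RawVector payload, double n_records, int bits, bool paired,
                   bool has_quality, bool has_headers, bool has_flags) {
  check_bits(bits);
  R_xlen_t n = (R_xlen_t)n_records;
  const uint8_t *p = RAW(payload);
  const uint8_t *end = p + payload.size();

  CharacterVector primary(n);
  CharacterVector ext(paired ? n : 0);
  CharacterVector qp(has_quality ? n : 0);
  CharacterVector qx((has_quality && paired) ? n : 0);
  CharacterVector hp(has_headers ? n : 0);
  CharacterVector hx((has_headers && paired) ? n : 0);
  NumericVector flg(has_flags ? n : 0);
  std::string buf;

  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t need = (has_flags ? 8 : 0) + 8 + (paired ? 8 : 0);
    if ((uint64_t)(end - p) < need)
      stop("block corruption: record %td header truncated", (ptrdiff_t)(i + 1));
    if (has_flags) { flg[i] = (double)get_u64(p); p += 8; }
    uint64_t sl = get_u64(p); p += 8;
    uint64_t xl = 0;
    if (paired) { xl = get_u64(p); p += 8; }

    uint64_t body = padded_bytes(sl, bits) + (paired ? padded_bytes(xl, bits) : 0);
    if (has_quality) body += sl + (paired ? xl : 0);
    if ((uint64_t)(end - p) < body)
      stop("block corruption: record %td body truncated", (ptrdiff_t)(i + 1));

    buf.resize(sl);
    unpack_into(&buf[0], p, sl, bits);
    SET_STRING_ELT(primary, i, Rf_mkCharLen(buf.data(), sl));
    p += padded_bytes(sl, bits);
    if (paired) {
      buf.resize(xl);
      unpack_into(&buf[0], p, xl, bits);
      SET_STRING_ELT(ext, i, Rf_mkCharLen(buf.data(), xl));
      p += padded_bytes(xl, bits);
    }
    if (has_quality) {
      SET_STRING_ELT(qp, i, Rf_mkCharLen((const char *)p, sl)); p += sl;
      if (paired) {
        SET_STRING_ELT(qx, i, Rf_mkCharLen((const char *)p, xl)); p += xl;
      }
    }
    if (has_headers) {
      if (end - p < 2) stop("block corruption: record %td header field truncated",
                            (ptrdiff_t)(i + 1));
      uint16_t hl = get_u16(p); p += 2;
      if ((uint64_t)(end - p) < hl)
        stop("block corruption: record %td header field truncated",
             (ptrdiff_t)(i + 1));
      SET_STRING_ELT(hp, i, Rf_mkCharLen((const char *)p, hl)); p += hl;
      if (paired) {
        if (end - p < 2) stop("block corruption: record %td header field truncated",
                              (ptrdiff_t)(i + 1));
        uint16_t ehl = get_u16(p); p += 2;
        if ((uint64_t)(end - p) < ehl)
          stop("block corruption: record %td header field truncated",
               (ptrdiff_t)(i + 1));
        SET_STRING_ELT(hx, i, Rf_mkCharLen((const char *)p, ehl)); p += ehl;
      }
    }
  }
  if (p != end)
    stop("block corruption: %td trailing bytes after %td records",
         (ptrdiff_t)(end - p), (ptrdiff_t)n);

  return List::create(
      _["primary"] = primary,
      _["extended"] = paired ? (SEXP)ext : R_NilValue,
      _["qual_primary"] = has_quality ? (SEXP)qp : R_NilValue,
      _["qual_extended"] = (has_quality && paired) ? (SEXP)qx : R_NilValue,
      _["header_primary"] = has_headers ? (SEXP)hp : R_NilValue,
      _["header_extended"] = (has_headers && paired) ? (SEXP)hx : R_NilValue,
      _["flag"] = has_flags ? (SEXP)flg : R_NilValue);
}

// ---------------------------------------------------------------- ZSTD

// [[Rcpp::export(".cpp_zstd_compress")]]
RawVector cpp_zstd_compress(RawVector x, int level) {
  size_t bound = ZSTD_compressBound(x.size());
  std::vector<uint8_t> tmp(bound);
  size_t sz = ZSTD_compress(tmp.data(), bound, RAW(x), x.size(), level);
  if (ZSTD_isError(sz)) stop("zstd compression failed: %s", ZSTD_getErrorName(sz));
  RawVector out((R_xlen_t)sz);
  std::memcpy(RAW(out), tmp.data(), sz);
  return out;
}

// [[Rcpp::export(".cpp_zstd_decompress")]]
RawVector cpp_zstd_decompress(RawVector x) {
  unsigned long long raw = ZSTD_getFrameContentSize(RAW(x), x.size());
  if (raw == ZSTD_CONTENTSIZE_ERROR || raw == ZSTD_CONTENTSIZE_UNKNOWN)
    stop("not a valid zstd frame with known content size");
  RawVector out((R_xlen_t)raw);
  size_t sz = ZSTD_decompress(RAW(out), raw, RAW(x), x.size());
  if (ZSTD_isError(sz)) stop("zstd decompression failed: %s", ZSTD_getErrorName(sz));
  if (sz != raw) stop("zstd frame decompressed to unexpected size");
  return out;
}

// ------------------------------------------------------------- generator

// Uniform i.i.d. bases over {A,C,G,T} drawn from R's RNG stream, so
// set.seed() governs reproducibility and chunked generation continues the
// same stream. Draw order: record by record, primary bases then (for pairs)
// extended bases.

static inline char rand_base() {
  static const char acgt[4] = {'A', 'C', 'G', 'T'};
  int c = (int)(4.0 * unif_rand());
  return acgt[c > 3 ? 3 : c];
}

// [[Rcpp::export(".cpp_random_seqs")]]
CharacterVector cpp_random_seqs(int n, int len) {
  CharacterVector out(n);
  std::string buf((size_t)len, 'A');
  GetRNGstate();
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < len; ++j) buf[j] = rand_base();
    SET_STRING_ELT(out, i, Rf_mkCharLen(buf.data(), len));
  }
  PutRNGstate();
  return out;
}

// [[Rcpp::export(".cpp_random_pairs")]]
List cpp_random_pairs(int n, int len1, int len2) {
  CharacterVector r1(n), r2(n);
  std::string b1((size_t)len1, 'A'), b2((size_t)len2, 'A');
  GetRNGstate();
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < len1; ++j) b1[j] = rand_base();
    SET_STRING_ELT(r1, i, Rf_mkCharLen(b1.data(), len1));
    for (int j = 0; j < len2; ++j) b2[j] = rand_base();
    SET_STRING_ELT(r2, i, Rf_mkCharLen(b2.data(), len2));
  }
  PutRNGstate();
  return List::create(_["primary"] = r1, _["extended"] = r2);
}
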
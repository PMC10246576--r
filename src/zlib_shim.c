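/* Thin wrappers over zlib for the BGZF codec: CRC32 and raw (headerless)
 * deflate/inflate.  BGZF blocks are gzip members whose payload is a raw
 * deflate stream; R's memCompress/memDecompress only expose zlib-wrapped
 * streams, so these three entry points are required. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <zlib.h>
#include <string.h>

SEXP pg_crc32(SEXP data)
{
    uLong crc = crc32(0L, Z_NULL, 0);
    crc = crc32(crc, (const Bytef *) RAW(data), (uInt) XLENGTH(data));
    return ScalarReal((double) crc);
}

SEXP pg_deflate_raw(SEXP data, SEXP level)
{
    z_stream s;
    int ret;
    memset(&s, 0, sizeof(s));
    /* windowBits = -15: raw deflate, no zlib/gzip wrapper */
    ret = deflateInit2(&s, asInteger(level), Z_DEFLATED, -15, 8,
                       Z_DEFAULT_STRATEGY);
    if (ret != Z_OK)
        error("deflateInit2 failed (%d)", ret);
    uLong bound = deflateBound(&s, (uLong) XLENGTH(data));
    SEXP buf = PROTECT(allocVector(RAWSXP, (R_xlen_t) bound));
    s.next_in = (Bytef *) RAW(data);
    s.avail_in = (uInt) XLENGTH(data);
    s.next_out = RAW(buf);
    s.avail_out = (uInt) bound;
    ret = deflate(&s, Z_FINISH);
    if (ret != Z_STREAM_END) {
        deflateEnd(&s);
        UNPROTECT(1);
        error("deflate failed (%d)", ret);
    }
    R_xlen_t n = (R_xlen_t) s.total_out;
    deflateEnd(&s);
    SEXP out = PROTECT(allocVector(RAWSXP, n));
    memcpy(RAW(out), RAW(buf), (size_t) n);
    UNPROTECT(2);
    return out;
}

SEXP pg_inflate_raw(SEXP data, SEXP isize)
{
    z_stream s;
    int ret;
    R_xlen_t n = (R_xlen_t) asReal(isize);
    if (n < 0)
        error("negative uncompressed size");
    memset(&s, 0, sizeof(s));
    ret = inflateInit2(&s, -15);
    if (ret != Z_OK)
        error("inflateInit2 failed (%d)", ret);
    SEXP out = PROTECT(allocVector(RAWSXP, n));
    s.next_in = (Bytef *) RAW(data);
    s.avail_in = (uInt) XLENGTH(data);
    s.next_out = RAW(out);
    s.avail_out = (uInt) n;
    ret = inflate(&s, Z_FINISH);
    if (ret != Z_STREAM_END || (R_xlen_t) s.total_out != n) {
        inflateEnd(&s);
        UNPROTECT(1);
        error("corrupt deflate payload (inflate returned %d)", ret);
    }
    inflateEnd(&s);
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef call_entries[] = {
    {"pg_crc32",       (DL_FUNC) &pg_crc32,       1},
    {"pg_deflate_raw", (DL_FUNC) &pg_deflate_raw, 2},
    {"pg_inflate_raw", (DL_FUNC) &pg_inflate_raw, 2},
    {NULL, NULL, 0}
};

void R_init_gintervals(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
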
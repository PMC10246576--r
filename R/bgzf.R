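# ---- little-endian byte helpers over raw vectors -------------------------
# Coordinates and sizes are carried as doubles (exact below 2^53); unsigned
# 32-bit fields (CRC32, ISIZE) do not fit in R's signed integers.

r_u8 <- function(r, i) as.integer(r[i])

r_u16 <- function(r, i) as.integer(r[i]) + 256L * as.integer(r[i + 1L])

r_u32 <- function(r, i) sum(as.numeric(r[i:(i + 3L)]) * 256^(0:3))

r_i32 <- function(r, i) readBin(r[i:(i + 3L)], "integer", size = 4L,
                                endian = "little")

r_f32 <- function(r, i) readBin(r[i:(i + 3L)], "double", size = 4L,
                                endian = "little")

w_u8 <- function(x) as.raw(x)

w_u16 <- function(x) as.raw(c(x %% 256, x %/% 256))

w_u32 <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

w_i32 <- function(x) {
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

w_f32 <- function(x) {
  writeBin(as.numeric(x), raw(), size = 4L, endian = "little")
}

#' CRC-32 checksum
#'
#' The IEEE CRC-32 used by gzip and BGZF, computed in C via zlib.
#'
#' @param data a raw vector.
#' @return The checksum as a double in `[0, 2^32)`.
#' @export
crc32 <- function(data) .Call("pg_crc32", data, PACKAGE = "gintervals")

# The canonical 28-byte BGZF end-of-file marker: an empty block.
bgzf_eof_block <- as.raw(c(
  0x1f, 0x8b, 0x08, 0x04, 0x00, 0x00, 0x00, 0x00, 0x00, 0xff, 0x06, 0x00,
  0x42, 0x43, 0x02, 0x00, 0x1b, 0x00, 0x03, 0x00, 0x00, 0x00, 0x00, 0x00,
  0x00, 0x00, 0x00, 0x00
))

# Uncompressed bytes per block on write: the conventional maximum that
# leaves room for the fixed 26 bytes of header/trailer within 2^16.
BGZF_CHUNK <- 65280L

bgzf_one_block <- function(chunk, level) {
  cdata <- .Call("pg_deflate_raw", chunk, as.integer(level), PACKAGE = "gintervals")
  total <- 18L + length(cdata) + 8L
  if (total > 65536L) {
    pg_stop("bgzf_error", "deflated block exceeds 65536 bytes")
  }
  c(as.raw(c(0x1f, 0x8b, 0x08, 0x04)),      # magic, CM=deflate, FLG=FEXTRA
    as.raw(c(0x00, 0x00, 0x00, 0x00)),      # MTIME
    as.raw(c(0x00, 0xff)),                  # XFL, OS=unknown
    w_u16(6),                               # XLEN
    as.raw(c(0x42, 0x43)), w_u16(2),        # BC subfield
    w_u16(total - 1L),                      # BSIZE
    cdata,
    w_u32(crc32(chunk)),
    w_u32(length(chunk)))
}

#' BGZF: blocked gzip compression
#'
#' Splits the payload into chunks of at most 65280 bytes, deflates each
#' into an independent gzip member carrying the BGZF `BC` extra subfield,
#' and terminates the stream with the canonical 28-byte end-of-file block.
#' The result is decompressible by any ordinary gzip reader.
#'
#' @param payload a raw vector (may be empty).
#' @param level zlib compression level 0-9.
#' @return The compressed stream as a raw vector.
#' @examples
#' length(bgzf_compress(raw(0)))  # the EOF marker alone: 28 bytes
#' @export
bgzf_compress <- function(payload, level = 6L) {
  stopifnot(is.raw(payload))
  n <- length(payload)
  if (n == 0L) return(bgzf_eof_block)
  starts <- seq(1L, n, by = BGZF_CHUNK)
  blocks <- lapply(starts, function(s) {
    bgzf_one_block(payload[s:min(s + BGZF_CHUNK - 1L, n)], level)
  })
  c(do.call(c, blocks), bgzf_eof_block)
}

#' BGZF: decompression with a block index
#'
#' Walks the stream member by member, validating the gzip magic, the
#' presence of the `BC` subfield, and (by default) each block's CRC-32 and
#' ISIZE.  The returned index maps each block's compressed offset to its
#' uncompressed offset so virtual offsets can be resolved.
#'
#' @param x raw vector or path to a BGZF file.
#' @param check_crc validate each block's CRC-32 (default TRUE).
#' @param on_missing_eof `"warn"` (default), `"error"` or `"ignore"` when
#'   the stream does not end with the EOF block.
#' @return A list with `data` (raw), `index` (data.frame with columns
#'   `coffset`, `uoffset`, `isize`) and `eof` (logical).
#' @export
bgzf_decompress <- function(x, check_crc = TRUE, on_missing_eof = "warn") {
  r <- if (is.raw(x)) x else readBin(x, "raw", n = file.size(x))
  pos <- 1L
  n <- length(r)
  chunks <- list()
  k <- 0L
  coff <- numeric(0)
  uoff <- numeric(0)
  isz <- numeric(0)
  total_u <- 0
  eof_seen <- FALSE
  while (pos <= n) {
    if (n - pos + 1L < 18L || r[pos] != as.raw(0x1f) ||
        r[pos + 1L] != as.raw(0x8b) || r[pos + 2L] != as.raw(0x08)) {
      pg_stop("bad_magic_error", "not a gzip member at offset %d", pos - 1L)
    }
    flg <- r_u8(r, pos + 3L)
    if (bitwAnd(flg, 4L) == 0L) {
      pg_stop("bad_magic_error",
              "gzip member at offset %d lacks the FEXTRA field (not BGZF)",
              pos - 1L)
    }
    xlen <- r_u16(r, pos + 10L)
    # scan extra subfields for BC
    sp <- pos + 12L
    send <- sp + xlen
    bsize <- NA_real_
    while (sp < send) {
      si1 <- r_u8(r, sp)
      si2 <- r_u8(r, sp + 1L)
      slen <- r_u16(r, sp + 2L)
      if (si1 == 0x42 && si2 == 0x43 && slen == 2L) {
        bsize <- r_u16(r, sp + 4L)
      }
      sp <- sp + 4L + slen
    }
    if (is.na(bsize)) {
      pg_stop("bad_magic_error",
              "gzip member at offset %d has no BC subfield (not BGZF)",
              pos - 1L)
    }
    total <- bsize + 1
    if (pos + total - 1 > n) {
      pg_stop("truncation_error", "truncated BGZF block at offset %d",
              pos - 1L)
    }
    cstart <- pos + 12L + xlen
    cend <- pos + total - 9
    cdata <- if (cend >= cstart) r[cstart:cend] else raw(0)
    isize <- r_u32(r, pos + total - 4)
    stored_crc <- r_u32(r, pos + total - 8)
    chunk <- .Call("pg_inflate_raw", cdata, isize, PACKAGE = "gintervals")
    if (check_crc && crc32(chunk) != stored_crc) {
      pg_stop("crc_mismatch_error", "CRC mismatch in block at offset %d",
              pos - 1L)
    }
    k <- k + 1L
    chunks[[k]] <- chunk
    coff[k] <- pos - 1
    uoff[k] <- total_u
    isz[k] <- isize
    total_u <- total_u + isize
    eof_seen <- isize == 0 && pos + total - 1 == n
    pos <- pos + as.integer(total)
  }
  if (!eof_seen && on_missing_eof != "ignore") {
    if (on_missing_eof == "error") {
      pg_stop("truncation_error", "BGZF stream does not end with the EOF block")
    }
    pg_warn("truncation_warning", "BGZF stream does not end with the EOF block")
  }
  list(data = if (k == 0L) raw(0) else do.call(c, chunks),
       index = data.frame(coffset = coff, uoffset = uoff, isize = isz),
       eof = eof_seen)
}

#' Virtual offsets into a BGZF stream
#'
#' A virtual offset packs a compressed block offset (48 bits) and an
#' uncompressed within-block offset (16 bits) into one number:
#' `coffset * 2^16 + within`.  `vo_resolve()` turns a virtual offset into
#' an absolute position in the decompressed stream using the block index
#' from [bgzf_decompress()].
#'
#' @param coffset compressed offset of the block's first byte.
#' @param within uncompressed offset within the block (< 65536).
#' @return `virtual_offset()` returns the packed number.
#' @examples
#' virtual_offset(0, 0)
#' @export
virtual_offset <- function(coffset, within) {
  if (within < 0 || within >= 65536) {
    pg_stop("virtual_offset_error", "within-block offset must be in [0, 65536)")
  }
  coffset * 65536 + within
}

#' @rdname virtual_offset
#' @param vo a packed virtual offset.
#' @export
vo_unpack <- function(vo) {
  list(coffset = vo %/% 65536, within = vo %% 65536)
}

#' @rdname virtual_offset
#' @param index block index from [bgzf_decompress()].
#' @export
vo_resolve <- function(index, vo) {
  p <- vo_unpack(vo)
  row <- which(index$coffset == p$coffset)
  if (length(row) == 0L) {
    pg_stop("virtual_offset_error", "no block at compressed offset %s",
            fmt_int(p$coffset))
  }
  if (p$within > index$isize[row]) {
    pg_stop("virtual_offset_error", "within-block offset past block end")
  }
  index$uoffset[row] + p$within
}
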
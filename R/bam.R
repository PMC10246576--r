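# BAM binary layout: magic "BAM\1", SAM header text, binary reference
# list, then one binary record per alignment, all inside a BGZF stream.
# Records decode to the same SamRecord objects the SAM text parser yields,
# with two documented canonicalizations: integer tag types (c C s S i I)
# all surface as SAM type "i", and RNEXT "=" is expanded to the mate's
# reference name.

BAM_MAGIC <- as.raw(c(0x42, 0x41, 0x4d, 0x01))  # "BAM\1"
BAM_SEQ_NIBBLES <- strsplit("=ACMGRSVTWYHKDBN", "")[[1L]]
BAM_CIGAR_OPS <- strsplit("MIDNSHP=X", "")[[1L]]

# Standard UCSC-binning region-to-bin mapping (written because the format
# requires the field; nothing in this package reads it back).
reg2bin <- function(beg, end) {
  if (beg < 0) return(4680)
  end <- end - 1
  for (lv in list(c(14, 4681), c(17, 585), c(20, 73), c(23, 9), c(26, 1))) {
    if (beg %/% 2^lv[1L] == end %/% 2^lv[1L]) {
      return(lv[2L] + beg %/% 2^lv[1L])
    }
  }
  0
}

encode_bam_tag <- function(token) {
  tag <- charToRaw(substr(token, 1L, 2L))
  type <- substr(token, 4L, 4L)
  val <- substr(token, 6L, nchar(token))
  body <- switch(type,
    A = c(charToRaw("A"), charToRaw(val)),
    i = c(charToRaw("i"), w_i32(as.numeric(val))),
    f = c(charToRaw("f"), w_f32(as.numeric(val))),
    Z = c(charToRaw("Z"), charToRaw(val), as.raw(0L)),
    H = c(charToRaw("H"), charToRaw(val), as.raw(0L)),
    B = {
      parts <- strsplit(val, ",", fixed = TRUE)[[1L]]
      sub <- parts[1L]
      nums <- as.numeric(parts[-1L])
      enc <- switch(sub,
        c = , C = do.call(c, lapply(nums, function(v) w_u8(v %% 256))),
        s = , S = do.call(c, lapply(nums, function(v) w_u16(v %% 65536))),
        i = , I = do.call(c, lapply(nums, w_i32)),
        f = do.call(c, lapply(nums, w_f32)),
        pg_stop("tag_error", "unknown B-array subtype '%s'", sub))
      c(charToRaw("B"), charToRaw(sub), w_i32(length(nums)),
        if (length(nums)) enc else raw(0))
    },
    pg_stop("tag_error", "unknown tag type '%s'", type))
  c(tag, body)
}

decode_bam_tags <- function(r, i, end) {
  tags <- character(0)
  while (i <= end) {
    tag <- rawToChar(r[i:(i + 1L)])
    type <- rawToChar(r[i + 2L])
    i <- i + 3L
    if (type == "A") {
      tags <- c(tags, sprintf("%s:A:%s", tag, rawToChar(r[i])))
      i <- i + 1L
    } else if (type %in% c("c", "C", "s", "S", "i", "I")) {
      v <- switch(type,
        c = {x <- r_u8(r, i); if (x > 127) x - 256 else x},
        C = r_u8(r, i),
        s = {x <- r_u16(r, i); if (x > 32767) x - 65536 else x},
        S = r_u16(r, i),
        i = r_i32(r, i),
        I = r_u32(r, i))
      tags <- c(tags, sprintf("%s:i:%s", tag, fmt_int(v)))
      i <- i + switch(type, c = 1L, C = 1L, s = 2L, S = 2L, 4L)
    } else if (type == "f") {
      tags <- c(tags, sprintf("%s:f:%s", tag,
                              as.character(r_f32(r, i))))
      i <- i + 4L
    } else if (type %in% c("Z", "H")) {
      j <- i
      while (r[j] != as.raw(0L)) j <- j + 1L
      s <- if (j > i) rawToChar(r[i:(j - 1L)]) else ""
      tags <- c(tags, sprintf("%s:%s:%s", tag, type, s))
      i <- j + 1L
    } else if (type == "B") {
      sub <- rawToChar(r[i])
      cnt <- r_i32(r, i + 1L)
      i <- i + 5L
      w <- switch(sub, c = 1L, C = 1L, s = 2L, S = 2L, i = 4L, I = 4L,
                  f = 4L, pg_stop("tag_error", "bad B subtype"))
      vals <- vapply(seq_len(cnt), function(k) {
        o <- i + (k - 1L) * w
        switch(sub,
          c = {x <- r_u8(r, o); if (x > 127) x - 256 else x},
          C = r_u8(r, o),
          s = {x <- r_u16(r, o); if (x > 32767) x - 65536 else x},
          S = r_u16(r, o),
          i = r_i32(r, o),
          I = r_u32(r, o),
          f = r_f32(r, o))
      }, 0)
      txt <- if (sub == "f") as.character(vals) else fmt_int(vals)
      tags <- c(tags, sprintf("%s:B:%s", tag,
                              paste(c(sub, txt), collapse = ",")))
      i <- i + cnt * w
    } else {
      pg_stop("tag_error", "unknown BAM tag type '%s'", type)
    }
  }
  tags
}

encode_bam_record <- function(rec, ref_index) {
  refid <- if (rec$rname == "*") -1L else {
    ix <- ref_index[[rec$rname]]
    if (is.null(ix)) {
      pg_stop("unknown_reference_error",
              "RNAME '%s' not in header @SQ lines", rec$rname)
    }
    ix
  }
  pos0 <- rec$pos - 1
  cig <- parse_cigar(rec$cigar)
  refspan <- cigar_reference_span(cig)
  bin <- if (refid >= 0L && pos0 >= 0) reg2bin(pos0, pos0 + max(refspan, 1)) else 4680
  next_refid <- if (rec$rnext == "*") -1L else if (rec$rnext == "=") refid else {
    ix <- ref_index[[rec$rnext]]
    if (is.null(ix)) {
      pg_stop("unknown_reference_error",
              "RNEXT '%s' not in header @SQ lines", rec$rnext)
    }
    ix
  }
  l_seq <- if (rec$seq == "*") 0L else nchar(rec$seq)
  name_raw <- c(charToRaw(rec$qname), as.raw(0L))
  cig_raw <- if (length(cig$ops) == 0L) raw(0) else {
    do.call(c, lapply(seq_along(cig$ops), function(i) {
      w_u32(cig$lengths[i] * 16 + (match(cig$ops[i], BAM_CIGAR_OPS) - 1L))
    }))
  }
  seq_raw <- if (l_seq == 0L) raw(0) else {
    codes <- match(strsplit(toupper(rec$seq), "")[[1L]], BAM_SEQ_NIBBLES) - 1L
    codes[is.na(codes)] <- 15L
    if (length(codes) %% 2L == 1L) codes <- c(codes, 0L)
    as.raw(codes[seq(1L, length(codes), by = 2L)] * 16L +
           codes[seq(2L, length(codes), by = 2L)])
  }
  qual_raw <- if (l_seq == 0L) raw(0) else if (rec$qual == "*") {
    as.raw(rep(0xff, l_seq))
  } else {
    as.raw(vapply(strsplit(rec$qual, "")[[1L]],
                  function(ch) utf8ToInt(ch) - 33L, 0L))
  }
  tag_raw <- if (length(rec$tags) == 0L) raw(0) else {
    do.call(c, lapply(rec$tags, encode_bam_tag))
  }
  body <- c(w_i32(refid), w_i32(pos0),
            w_u8(length(name_raw)), w_u8(rec$mapq), w_u16(bin),
            w_u16(length(cig$ops)), w_u16(rec$flag), w_i32(l_seq),
            w_i32(next_refid), w_i32(rec$pnext - 1), w_i32(rec$tlen),
            name_raw, cig_raw, seq_raw, qual_raw, tag_raw)
  c(w_i32(length(body)), body)
}

decode_bam_record <- function(r, i, ref_names, ordinal) {
  if (i + 3L > length(r)) {
    pg_stop("truncated_record_error", "truncated BAM record %d", ordinal)
  }
  block_size <- r_i32(r, i)
  if (i + 3L + block_size > length(r)) {
    pg_stop("truncated_record_error", "truncated BAM record %d", ordinal)
  }
  b <- i + 4L  # first byte of the record body
  refid <- r_i32(r, b)
  pos0 <- r_i32(r, b + 4L)
  l_read_name <- r_u8(r, b + 8L)
  mapq <- r_u8(r, b + 9L)
  n_cigar <- r_u16(r, b + 12L)
  flag <- r_u16(r, b + 14L)
  l_seq <- r_i32(r, b + 16L)
  next_refid <- r_i32(r, b + 20L)
  next_pos <- r_i32(r, b + 24L)
  tlen <- r_i32(r, b + 28L)
  if (refid >= length(ref_names) || next_refid >= length(ref_names)) {
    pg_stop("refid_error", "reference ID out of range in BAM record %d",
            ordinal)
  }
  p <- b + 32L
  qname <- rawToChar(r[p:(p + l_read_name - 2L)])
  p <- p + l_read_name
  cigar <- "*"
  if (n_cigar > 0L) {
    pieces <- vapply(seq_len(n_cigar), function(k) {
      v <- r_u32(r, p + (k - 1L) * 4L)
      sprintf("%s%s", fmt_int(v %/% 16), BAM_CIGAR_OPS[v %% 16 + 1L])
    }, "")
    cigar <- paste(pieces, collapse = "")
  }
  p <- p + n_cigar * 4L
  seq <- "*"
  qual <- "*"
  if (l_seq > 0L) {
    nbytes <- (l_seq + 1L) %/% 2L
    bytes <- as.integer(r[p:(p + nbytes - 1L)])
    codes <- c(rbind(bytes %/% 16L, bytes %% 16L))[seq_len(l_seq)]
    seq <- paste(BAM_SEQ_NIBBLES[codes + 1L], collapse = "")
    p <- p + nbytes
    qvals <- as.integer(r[p:(p + l_seq - 1L)])
    qual <- if (all(qvals == 255L)) "*" else {
      intToUtf8(qvals + 33L, multiple = FALSE)
    }
    p <- p + l_seq
  }
  tags <- decode_bam_tags(r, p, i + 3L + block_size)
  rec <- structure(list(
    qname = qname, flag = as.numeric(flag),
    rname = if (refid < 0L) "*" else ref_names[refid + 1L],
    pos = if (pos0 < 0L) 0 else as.numeric(pos0) + 1,
    mapq = as.numeric(mapq), cigar = cigar,
    rnext = if (next_refid < 0L) "*" else ref_names[next_refid + 1L],
    pnext = if (next_pos < 0L) 0 else as.numeric(next_pos) + 1,
    tlen = as.numeric(tlen), seq = seq, qual = qual, tags = tags),
    class = "SamRecord")
  list(record = rec, next_offset = i + 4L + block_size)
}

#' Write a BAM file
#'
#' Serializes a SAM header and records into the BAM binary layout inside a
#' BGZF stream terminated by the EOF block.  Every mapped record's RNAME
#' must appear among the header's `@SQ` lines.
#'
#' @param doc list with `header` (a `SamHeader`) and `records` (list of
#'   `SamRecord`), as returned by [read_sam()] or [read_bam()].
#' @param path output path, connection, or NULL to return the raw stream.
#' @param level BGZF compression level.
#' @return The compressed stream (raw), invisibly when written to a path.
#' @export
write_bam <- function(doc, path = NULL, level = 6L) {
  header <- doc$header
  asm <- header$assembly
  ref_names <- if (is.null(asm)) character(0) else asm$names
  ref_index <- as.list(stats::setNames(seq_along(ref_names) - 1L, ref_names))
  text <- if (length(header$lines) > 0L) {
    paste0(paste(header$lines, collapse = "\n"), "\n")
  } else {
    ""
  }
  refs_raw <- if (length(ref_names) == 0L) raw(0) else {
    do.call(c, lapply(ref_names, function(nm) {
      c(w_i32(nchar(nm) + 1L), charToRaw(nm), as.raw(0L),
        w_i32(asm$lengths[[nm]]))
    }))
  }
  rec_raw <- if (length(doc$records) == 0L) raw(0) else {
    do.call(c, lapply(doc$records, encode_bam_record, ref_index = ref_index))
  }
  payload <- c(BAM_MAGIC, w_i32(nchar(text)), charToRaw(text),
               w_i32(length(ref_names)), refs_raw, rec_raw)
  stream <- bgzf_compress(payload, level)
  if (is.null(path)) return(stream)
  writeBin(stream, path)
  invisible(stream)
}

#' Read a BAM file
#'
#' Decompresses the BGZF stream, checks the `"BAM\1"` magic, decodes the
#' header text and binary reference list, and decodes every record into
#' the same `SamRecord` representation the SAM text parser produces.
#'
#' @param x raw BGZF stream or path to a BAM file.
#' @param check_crc validate BGZF block checksums (default TRUE).
#' @return A list with `header` (a `SamHeader`) and `records`.
#' @export
read_bam <- function(x, check_crc = TRUE) {
  r <- bgzf_decompress(x, check_crc = check_crc)$data
  if (length(r) < 8L || !identical(r[1:4], BAM_MAGIC)) {
    pg_stop("bad_magic_error", "not a BAM stream (bad magic)")
  }
  l_text <- r_i32(r, 5L)
  # header text may be NUL-padded per the format: trim before decoding
  tlen <- l_text
  while (tlen > 0L && r[8L + tlen] == as.raw(0L)) tlen <- tlen - 1L
  text <- if (tlen > 0L) rawToChar(r[9L:(8L + tlen)]) else ""
  p <- 9L + l_text
  n_ref <- r_i32(r, p)
  p <- p + 4L
  ref_names <- character(n_ref)
  ref_lens <- numeric(n_ref)
  for (k in seq_len(n_ref)) {
    l_name <- r_i32(r, p)
    ref_names[k] <- rawToChar(r[(p + 4L):(p + 2L + l_name)])
    ref_lens[k] <- r_i32(r, p + 4L + l_name)
    p <- p + 8L + l_name
  }
  hlines <- if (nzchar(text)) strsplit(text, "\n", fixed = TRUE)[[1L]] else character(0)
  header <- sam_header(hlines)
  if (is.null(header$assembly) && n_ref > 0L) {
    header$assembly <- genome_assembly(ref_names, ref_lens)
  }
  records <- list()
  k <- 0L
  while (p <= length(r)) {
    dec <- decode_bam_record(r, p, ref_names, k + 1L)
    k <- k + 1L
    records[[k]] <- dec$record
    p <- dec$next_offset
  }
  list(header = header, records = records)
}

#' Compare SAM records modulo the documented canonicalizations
#'
#' Equality used by the round-trip suites: RNEXT `"="` is equivalent to
#' the record's own RNAME, integer tag types compare by value under SAM
#' type `i`, and `f`-typed tags compare numerically (float32 values do not
#' have one canonical decimal form).
#'
#' @param a,b `SamRecord` objects.
#' @return TRUE if equivalent.
#' @export
sam_records_equal <- function(a, b) {
  canon <- function(x) {
    if (x$rnext == "=") x$rnext <- x$rname
    x$tags <- sub("^(..):[cCsSiI]:", "\\1:i:", x$tags)
    x
  }
  a <- canon(a)
  b <- canon(b)
  fixed <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "rnext",
             "pnext", "tlen", "seq", "qual")
  for (f in fixed) {
    va <- a[[f]]
    vb <- b[[f]]
    if (is.numeric(va) && is.numeric(vb)) {
      if (va != vb) return(FALSE)
    } else if (!identical(va, vb)) {
      return(FALSE)
    }
  }
  if (length(a$tags) != length(b$tags)) return(FALSE)
  for (i in seq_along(a$tags)) {
    ta <- a$tags[i]
    tb <- b$tags[i]
    if (substr(ta, 4L, 4L) == "f" && substr(tb, 4L, 4L) == "f") {
      if (substr(ta, 1L, 2L) != substr(tb, 1L, 2L)) return(FALSE)
      va <- as.numeric(substr(ta, 6L, nchar(ta)))
      vb <- as.numeric(substr(tb, 6L, nchar(tb)))
      if (!isTRUE(all.equal(va, vb, tolerance = 1e-6))) return(FALSE)
    } else if (!identical(ta, tb)) {
      return(FALSE)
    }
  }
  TRUE
}
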
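#' GFF3 records
#'
#' GFF3 uses 1-based inclusive coordinates over nine tab-separated columns.
#' The attribute column is kept verbatim for byte-exact writing; attribute
#' values are percent-decoded on access only (the reserved set: tab,
#' newline, `%`, `;`, `=`, `&`, `,`), mirroring how they must be encoded,
#' so decode and re-encode are mutual inverses.
#'
#' @param line one 9-column GFF3 feature line (not a `#` directive).
#' @return `parse_gff3_record()` returns a `Gff3Record`; `format()` is its
#'   inverse.
#' @examples
#' rec <- parse_gff3_record("chr1\t.\tgene\t11\t20\t.\t+\t.\tID=g1")
#' gff3_attr(rec, "ID")
#' as_interval(rec)
#' @export
parse_gff3_record <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) != 9L) {
    pg_stop("column_count_error", "GFF3 line has %d column(s); 9 required",
            length(f))
  }
  start <- suppressWarnings(as.numeric(f[4L]))
  end <- suppressWarnings(as.numeric(f[5L]))
  if (is.na(start) || is.na(end) || start != floor(start) ||
      end != floor(end) || start < 1) {
    pg_stop("coordinate_error", "invalid GFF3 coordinates '%s'..'%s'",
            f[4L], f[5L])
  }
  if (start > end) {
    pg_stop("coordinate_error", "GFF3 start %s > end %s", f[4L], f[5L])
  }
  if (!f[7L] %in% c("+", "-", ".", "?")) {
    pg_stop("malformed_field_error", "invalid GFF3 strand '%s'", f[7L])
  }
  if (!f[8L] %in% c(".", "0", "1", "2")) {
    pg_stop("malformed_field_error", "invalid GFF3 phase '%s'", f[8L])
  }
  if (f[9L] != ".") {
    pieces <- strsplit(f[9L], ";", fixed = TRUE)[[1L]]
    pieces <- pieces[nzchar(pieces)]
    if (!all(grepl("^[^=]+=", pieces))) {
      pg_stop("attribute_syntax_error",
              "GFF3 attribute without tag=value form: '%s'", f[9L])
    }
  }
  if (f[3L] == "CDS" && f[8L] == ".") {
    pg_warn("phase_warning", "CDS feature without phase")
  }
  structure(list(seqid = f[1L], source = f[2L], type = f[3L],
                 start = start, end = end, score = f[6L], strand = f[7L],
                 phase = f[8L], attributes = f[9L]),
            class = "Gff3Record")
}

#' @export
format.Gff3Record <- function(x, ...) {
  paste(x$seqid, x$source, x$type, fmt_int(x$start), fmt_int(x$end),
        x$score, x$strand, x$phase, x$attributes, sep = "\t")
}

#' @export
print.Gff3Record <- function(x, ...) {
  cat("Gff3Record:", format(x), "\n")
  invisible(x)
}

# GFF3 reserved-set percent decoding / encoding: exact mutual inverses.
gff3_decode <- function(s) {
  for (p in list(c("%09", "\t"), c("%0A", "\n"), c("%3B", ";"),
                 c("%3D", "="), c("%26", "&"), c("%2C", ","))) {
    s <- gsub(p[1L], p[2L], s, fixed = TRUE)
  }
  gsub("%25", "%", s, fixed = TRUE)
}

gff3_encode <- function(s) {
  s <- gsub("%", "%25", s, fixed = TRUE)
  for (p in list(c("\t", "%09"), c("\n", "%0A"), c(";", "%3B"),
                 c("=", "%3D"), c("&", "%26"), c(",", "%2C"))) {
    s <- gsub(p[1L], p[2L], s, fixed = TRUE)
  }
  s
}

#' @rdname parse_gff3_record
#' @param x a `Gff3Record`.
#' @param tag attribute tag to look up.
#' @return `gff3_attr()` returns the percent-decoded value(s) of `tag`
#'   (split on the multi-value comma separator), or NULL when absent.
#' @export
gff3_attr <- function(x, tag) {
  if (x$attributes == ".") return(NULL)
  pieces <- strsplit(x$attributes, ";", fixed = TRUE)[[1L]]
  pieces <- pieces[nzchar(pieces)]
  tags <- sub("=.*$", "", pieces)
  hit <- which(tags == tag)
  if (length(hit) == 0L) return(NULL)
  val <- sub("^[^=]+=", "", pieces[hit[1L]])
  gff3_decode(strsplit(val, ",", fixed = TRUE)[[1L]])
}

#' @export
as_interval.Gff3Record <- function(x, ...) {
  gi(x$seqid, x$start - 1, x$end,
     if (x$strand %in% c("+", "-")) x$strand else "*")
}

#' GTF records
#'
#' GTF shares GFF3's first eight columns but its attribute column is a
#' sequence of `key "value";` pairs separated by single spaces, trailing
#' semicolon required (parsing is strict: a line whose attribute column is
#' not byte-identical to its canonical re-serialization is rejected).
#'
#' @param line one 9-column GTF feature line.
#' @return `parse_gtf_record()` returns a `GtfRecord`; `format()` is its
#'   inverse.
#' @examples
#' rec <- parse_gtf_record(
#'   "chr1\thavana\texon\t11\t20\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";")
#' gtf_attr(rec, "gene_id")
#' @export
parse_gtf_record <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) != 9L) {
    pg_stop("column_count_error", "GTF line has %d column(s); 9 required",
            length(f))
  }
  g <- parse_gff3_record(paste(c(f[1:8], "."), collapse = "\t"))
  pairs <- regmatches(f[9L], gregexpr('([^ "]+) "([^"]*)";', f[9L]))[[1L]]
  keys <- sub('^([^ "]+) ".*$', "\\1", pairs)
  vals <- sub('^[^ "]+ "([^"]*)";$', "\\1", pairs)
  canon <- paste(pairs, collapse = " ")
  if (!identical(canon, f[9L]) || length(pairs) == 0L) {
    pg_stop("attribute_syntax_error",
            "GTF attributes not in strict 'key \"value\";' form: '%s'", f[9L])
  }
  structure(list(seqid = g$seqid, source = g$source, type = g$type,
                 start = g$start, end = g$end, score = f[6L],
                 strand = g$strand, phase = g$phase,
                 attr_keys = keys, attr_values = vals),
            class = "GtfRecord")
}

#' @export
format.GtfRecord <- function(x, ...) {
  attrs <- paste(sprintf('%s "%s";', x$attr_keys, x$attr_values),
                 collapse = " ")
  paste(x$seqid, x$source, x$type, fmt_int(x$start), fmt_int(x$end),
        x$score, x$strand, x$phase, attrs, sep = "\t")
}

#' @export
print.GtfRecord <- function(x, ...) {
  cat("GtfRecord:", format(x), "\n")
  invisible(x)
}

#' @rdname parse_gtf_record
#' @param x a `GtfRecord`.
#' @param key attribute key to look up.
#' @export
gtf_attr <- function(x, key) {
  hit <- which(x$attr_keys == key)
  if (length(hit) == 0L) NULL else x$attr_values[hit[1L]]
}

#' @export
as_interval.GtfRecord <- function(x, ...) {
  gi(x$seqid, x$start - 1, x$end,
     if (x$strand %in% c("+", "-")) x$strand else "*")
}

gff_passthrough <- function(line) !nzchar(line) || startsWith(line, "#")

#' Read or write GFF3 / GTF files
#'
#' `#`-prefixed directive and comment lines are preserved verbatim in
#' place, so read-then-write reproduces a file byte-for-byte.
#'
#' @param x path, connection, or character vector of lines.
#' @return A list with `records` and `layout` as in [read_bed()].
#' @export
read_gff3 <- function(x) read_tabular(x, parse_gff3_record, gff_passthrough)

#' @rdname read_gff3
#' @export
read_gtf <- function(x) read_tabular(x, parse_gtf_record, gff_passthrough)

#' @rdname read_gff3
#' @param doc list from `read_gff3()`/`read_gtf()` or a bare record list.
#' @param path output path, connection, or NULL to return the lines.
#' @export
write_gff3 <- function(doc, path = NULL) write_tabular(doc, path)

#' @rdname read_gff3
#' @export
write_gtf <- function(doc, path = NULL) write_tabular(doc, path)
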
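#' CIGAR strings
#'
#' A CIGAR is a run-length encoding of an alignment over the operation
#' alphabet `MIDNSHP=X`.  Reference-consuming operations (`M D N = X`)
#' determine the genomic interval a mapped read covers; query-consuming
#' operations (`M I S = X`) must sum to the read sequence length.
#'
#' @param token CIGAR string, e.g. `"5S10M3D2M"`.
#' @return `parse_cigar()` returns a `Cigar`: a list with integer vector
#'   `lengths` and character vector `ops`.
#' @examples
#' cigar_reference_span(parse_cigar("8M2I4M"))  # 12
#' cigar_query_span(parse_cigar("8M2I4M"))      # 14
#' @export
parse_cigar <- function(token) {
  if (token == "*") {
    return(structure(list(lengths = numeric(0), ops = character(0)),
                     class = "Cigar"))
  }
  pieces <- regmatches(token, gregexpr("([0-9]+)([MIDNSHP=X])", token))[[1L]]
  if (length(pieces) == 0L || paste(pieces, collapse = "") != token) {
    pg_stop("cigar_error", "malformed CIGAR '%s'", token)
  }
  lens <- as.numeric(sub("[MIDNSHP=X]$", "", pieces))
  ops <- sub("^[0-9]+", "", pieces)
  if (any(lens < 1)) pg_stop("cigar_error", "zero-length CIGAR operation")
  # H only at the ends; S only at the ends or immediately inside H
  n <- length(ops)
  h <- which(ops == "H")
  if (length(h) > 0L && !all(h %in% c(1L, n))) {
    pg_stop("cigar_error", "H operation not at CIGAR end in '%s'", token)
  }
  s <- which(ops == "S")
  for (i in s) {
    left_ok <- i == 1L || all(ops[seq_len(i - 1L)] == "H")
    right_ok <- i == n || all(ops[seq(i + 1L, n)] == "H")
    if (!left_ok && !right_ok) {
      pg_stop("cigar_error", "S operation not at CIGAR end in '%s'", token)
    }
  }
  structure(list(lengths = lens, ops = ops), class = "Cigar")
}

#' @export
format.Cigar <- function(x, ...) {
  if (length(x$ops) == 0L) "*" else
    paste0(fmt_int(x$lengths), x$ops, collapse = "")
}

#' @rdname parse_cigar
#' @param c a `Cigar`.
#' @export
cigar_reference_span <- function(c) {
  sum(c$lengths[c$ops %in% c("M", "D", "N", "=", "X")])
}

#' @rdname parse_cigar
#' @export
cigar_query_span <- function(c) {
  sum(c$lengths[c$ops %in% c("M", "I", "S", "=", "X")])
}

#' SAM headers
#'
#' Header lines (`@HD`, `@SQ`, `@RG`, `@PG`, `@CO`) are kept verbatim and
#' in order; a `GenomeAssembly` is derived from the `@SQ` `SN`/`LN` tags.
#'
#' @param lines character vector of `@`-prefixed header lines (may be
#'   empty).
#' @return A `SamHeader` with elements `lines` and `assembly` (NULL when
#'   there are no `@SQ` lines).
#' @export
sam_header <- function(lines) {
  if (length(lines) > 0L && !all(startsWith(lines, "@"))) {
    pg_stop("header_error", "SAM header line without leading '@'")
  }
  sq <- lines[startsWith(lines, "@SQ")]
  assembly <- NULL
  if (length(sq) > 0L) {
    get_tag <- function(line, tag) {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1L]][-1L]
      hit <- fields[startsWith(fields, paste0(tag, ":"))]
      if (length(hit) == 0L) {
        pg_stop("header_error", "@SQ line lacks %s tag", tag)
      }
      sub("^..:", "", hit[1L])
    }
    nm <- vapply(sq, get_tag, "", tag = "SN", USE.NAMES = FALSE)
    ln <- as.numeric(vapply(sq, get_tag, "", tag = "LN", USE.NAMES = FALSE))
    assembly <- genome_assembly(nm, ln)
  }
  structure(list(lines = lines, assembly = assembly), class = "SamHeader")
}

#' @export
format.SamHeader <- function(x, ...) x$lines

#' @export
print.SamHeader <- function(x, ...) {
  cat(sprintf("SamHeader: %d line(s), %d reference(s)\n", length(x$lines),
              if (is.null(x$assembly)) 0L else length(x$assembly$names)))
  invisible(x)
}

# SAM tag-type validation: two-char tag, one-char type, value grammar.
sam_tag_pattern <- "^[A-Za-z][A-Za-z0-9]:[AifZHB]:"

#' SAM records
#'
#' The eleven mandatory columns plus optional `TAG:TYPE:VALUE` fields.
#' Tokens are stored verbatim (writing a parsed line reproduces it);
#' numeric fields and the CIGAR are validated on parse.  When both CIGAR
#' and SEQ are present their query lengths must agree.
#'
#' @param line one SAM alignment line.
#' @param header optional `SamHeader`; an unknown RNAME (when the header
#'   carries `@SQ` lines) is a warning, not an error.
#' @return `parse_sam_record()` returns a `SamRecord`.
#' @examples
#' r <- parse_sam_record("r1\t0\tchr1\t100\t60\t5M\t*\t0\t0\tACGTA\t*")
#' as_interval(r)
#' @export
parse_sam_record <- function(line, header = NULL) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 11L) {
    pg_stop("field_count_error",
            "SAM record has %d field(s); 11 mandatory fields required",
            length(f))
  }
  num <- suppressWarnings(as.numeric(f[c(2L, 4L, 5L, 8L, 9L)]))
  if (anyNA(num) || any(num != floor(num))) {
    pg_stop("malformed_field_error",
            "non-integer FLAG/POS/MAPQ/PNEXT/TLEN in SAM record")
  }
  flag <- num[1L]
  pos <- num[2L]
  mapq <- num[3L]
  if (flag < 0 || flag > 65535) {
    pg_stop("malformed_field_error", "FLAG %s out of 16-bit range", f[2L])
  }
  if (mapq < 0 || mapq > 255) {
    pg_stop("malformed_field_error", "MAPQ %s out of 0..255", f[5L])
  }
  cig <- parse_cigar(f[6L])
  if (f[6L] != "*" && f[10L] != "*" &&
      cigar_query_span(cig) != nchar(f[10L])) {
    pg_stop("consistency_error",
            "CIGAR query length %s differs from SEQ length %d",
            fmt_int(cigar_query_span(cig)), nchar(f[10L]))
  }
  if (f[10L] != "*" && f[11L] != "*" && nchar(f[10L]) != nchar(f[11L])) {
    pg_stop("consistency_error", "SEQ and QUAL lengths differ")
  }
  tags <- if (length(f) > 11L) f[12:length(f)] else character(0)
  if (length(tags) > 0L && !all(grepl(sam_tag_pattern, tags))) {
    pg_stop("malformed_field_error", "malformed SAM tag field '%s'",
            tags[!grepl(sam_tag_pattern, tags)][1L])
  }
  if (!is.null(header) && !is.null(header$assembly) && f[3L] != "*" &&
      !f[3L] %in% header$assembly$names) {
    pg_warn("unknown_reference_warning",
            "RNAME '%s' not among header @SQ sequences", f[3L])
  }
  unmapped_flag <- bitwAnd(as.integer(flag), 4L) != 0L
  if (unmapped_flag && f[3L] != "*" && f[6L] != "*") {
    # legal (placed unmapped mates) but worth flagging
    pg_warn("flag_consistency_warning",
            "unmapped flag 0x4 set on a record with RNAME and CIGAR")
  }
  structure(list(qname = f[1L], flag = flag, rname = f[3L], pos = pos,
                 mapq = mapq, cigar = f[6L], rnext = f[7L],
                 pnext = num[4L], tlen = num[5L], seq = f[10L],
                 qual = f[11L], tags = tags),
            class = "SamRecord")
}

#' @export
format.SamRecord <- function(x, ...) {
  paste(c(x$qname, fmt_int(x$flag), x$rname, fmt_int(x$pos),
          fmt_int(x$mapq), x$cigar, x$rnext, fmt_int(x$pnext),
          fmt_int(x$tlen), x$seq, x$qual, x$tags), collapse = "\t")
}

#' @export
print.SamRecord <- function(x, ...) {
  cat("SamRecord:", format(x), "\n")
  invisible(x)
}

#' @rdname parse_sam_record
#' @param x a `SamRecord`.
#' @param tag two-character tag name.
#' @return `sam_tag()` returns the typed value of `tag` (integer types and
#'   `f` as numeric, `A`/`Z`/`H` as character, `B` as numeric vector) or
#'   NULL when absent.
#' @export
sam_tag <- function(x, tag) {
  hit <- x$tags[startsWith(x$tags, paste0(tag, ":"))]
  if (length(hit) == 0L) return(NULL)
  type <- substr(hit[1L], 4L, 4L)
  val <- substr(hit[1L], 6L, nchar(hit[1L]))
  switch(type,
         i = as.numeric(val),
         f = as.numeric(val),
         B = as.numeric(strsplit(val, ",", fixed = TRUE)[[1L]][-1L]),
         val)
}

#' Is a record mapped?
#'
#' A record is unmapped if flag bit 0x4 is set, or RNAME/POS/CIGAR carry
#' their missing values.
#'
#' @param x a `SamRecord`.
#' @export
sam_is_mapped <- function(x) {
  bitwAnd(as.integer(x$flag), 4L) == 0L && x$rname != "*" && x$pos > 0 &&
    x$cigar != "*"
}

#' @export
as_interval.SamRecord <- function(x, ...) {
  if (!sam_is_mapped(x)) return(NULL)
  span <- cigar_reference_span(parse_cigar(x$cigar))
  if (span == 0) return(NULL)
  strand <- if (bitwAnd(as.integer(x$flag), 16L) != 0L) "-" else "+"
  gi(x$rname, x$pos - 1, x$pos - 1 + span, strand)
}

#' Read or write a SAM file
#'
#' @param x path, connection, or character vector of lines.
#' @return `read_sam()` returns a list with `header` (a `SamHeader`) and
#'   `records` (list of `SamRecord`).
#' @export
read_sam <- function(x) {
  lines <- read_lines_any(x)
  is_h <- startsWith(lines, "@")
  n_h <- match(FALSE, is_h, nomatch = length(lines) + 1L) - 1L
  header <- sam_header(lines[seq_len(n_h)])
  body <- if (n_h < length(lines)) lines[(n_h + 1L):length(lines)] else character(0)
  body <- body[nzchar(body)]
  records <- lapply(seq_along(body), function(i) {
    tryCatch(parse_sam_record(body[i], header), error = function(e) {
      pg_stop("parse_error", "SAM record %d: %s", i, conditionMessage(e))
    })
  })
  list(header = header, records = records)
}

#' @rdname read_sam
#' @param doc list with `header` and `records`.
#' @param path output path, connection, or NULL to return the lines.
#' @export
write_sam <- function(doc, path = NULL) {
  lines <- c(format(doc$header), vapply(doc$records, format, ""))
  write_lines_any(lines, path)
}
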
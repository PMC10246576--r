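#' BED records
#'
#' BED is already 0-based half-open, so its coordinates pass straight into
#' the canonical interval model.  Columns 4-12 (name, score, strand,
#' thickStart, thickEnd, itemRgb, blockCount, blockSizes, blockStarts) are
#' optional but must form a prefix of that order; they are stored verbatim
#' so that writing a parsed line reproduces it byte-for-byte.
#'
#' @param line a single tab-separated BED data line (not a `track`/`browser`
#'   or `#` comment line).
#' @return `parse_bed_line()` returns a `BedRecord`; `format()` is its
#'   inverse.
#' @examples
#' rec <- parse_bed_line("chr1\t10\t20\tfeat1\t0\t+")
#' format(rec)
#' as_interval(rec)
#' @export
parse_bed_line <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 3L) {
    pg_stop("malformed_field_error",
            "BED line has %d column(s); at least 3 required", length(f))
  }
  if (length(f) > 12L) {
    pg_stop("malformed_field_error",
            "BED line has %d columns; at most 12 allowed", length(f))
  }
  start <- suppressWarnings(as.numeric(f[2L]))
  end <- suppressWarnings(as.numeric(f[3L]))
  if (is.na(start) || start != floor(start) || start < 0) {
    pg_stop("malformed_field_error", "column 2 (chromStart) not a non-negative integer: '%s'", f[2L])
  }
  if (is.na(end) || end != floor(end)) {
    pg_stop("malformed_field_error", "column 3 (chromEnd) not an integer: '%s'", f[3L])
  }
  if (start >= end) {
    pg_stop("coordinate_error", "chromStart %s >= chromEnd %s", f[2L], f[3L])
  }
  extra <- if (length(f) > 3L) f[4L:length(f)] else character(0)
  if (length(extra) >= 2L) {
    sc <- suppressWarnings(as.numeric(extra[2L]))
    if (is.na(sc) || sc != floor(sc) || sc < 0 || sc > 1000) {
      pg_stop("malformed_field_error",
              "column 5 (score) not an integer in 0..1000: '%s'", extra[2L])
    }
  }
  if (length(extra) >= 3L && !extra[3L] %in% c("+", "-", ".")) {
    pg_stop("malformed_field_error", "column 6 (strand) invalid: '%s'",
            extra[3L])
  }
  if (length(extra) >= 9L) {
    bc <- suppressWarnings(as.integer(extra[7L]))
    sizes <- strsplit(sub(",$", "", extra[8L]), ",", fixed = TRUE)[[1L]]
    starts <- strsplit(sub(",$", "", extra[9L]), ",", fixed = TRUE)[[1L]]
    if (is.na(bc) || length(sizes) != bc || length(starts) != bc) {
      pg_stop("malformed_field_error",
              "blockCount %s does not match blockSizes/blockStarts", extra[7L])
    }
  }
  structure(list(chrom = f[1L], start = start, end = end, extra = extra),
            class = "BedRecord")
}

#' @export
format.BedRecord <- function(x, ...) {
  paste(c(x$chrom, fmt_int(x$start), fmt_int(x$end), x$extra),
        collapse = "\t")
}

#' @export
print.BedRecord <- function(x, ...) {
  cat("BedRecord:", format(x), "\n")
  invisible(x)
}

#' @rdname parse_bed_line
#' @param x a `BedRecord`.
#' @export
bed_name <- function(x) if (length(x$extra) >= 1L) x$extra[1L] else NA_character_

#' @rdname parse_bed_line
#' @export
bed_score <- function(x) {
  if (length(x$extra) >= 2L) as.numeric(x$extra[2L]) else NA_real_
}

#' @rdname parse_bed_line
#' @export
bed_strand <- function(x) {
  if (length(x$extra) >= 3L && x$extra[3L] %in% c("+", "-")) x$extra[3L] else "*"
}

#' Project a format record onto a canonical genomic interval
#'
#' Every interval-bearing record maps onto the package's canonical 0-based
#' half-open coordinates: BED passes through, GFF3/GTF/WIG/VCF shift their
#' 1-based starts down by one.
#'
#' @param x a format record.
#' @param ... unused.
#' @return A `GenomicInterval`.
#' @export
as_interval <- function(x, ...) UseMethod("as_interval")

#' @export
as_interval.BedRecord <- function(x, ...) {
  gi(x$chrom, x$start, x$end, bed_strand(x))
}

# Data lines vs pass-through (comment/track/browser/blank) lines.
bed_passthrough <- function(line) {
  !nzchar(line) || startsWith(line, "#") || startsWith(line, "track") ||
    startsWith(line, "browser")
}

#' Read or write a BED file
#'
#' Comment, `track` and `browser` lines are preserved verbatim in their
#' original positions, so reading then writing a file reproduces it exactly.
#'
#' @param x path, connection, or character vector of lines.
#' @return `read_bed()` returns a list with `records` (list of `BedRecord`)
#'   and `layout` (character vector; `NA` marks a record slot, anything else
#'   is a pass-through line).
#' @export
read_bed <- function(x) {
  read_tabular(x, parse_bed_line, bed_passthrough)
}

#' @rdname read_bed
#' @param doc a list as returned by `read_bed()`, or a bare list of records.
#' @param path output path, connection, or NULL to return the lines.
#' @export
write_bed <- function(doc, path = NULL) {
  write_tabular(doc, path)
}

# Shared scaffolding for the line-oriented formats: parse data lines with
# `parse_fn`, keep pass-through lines verbatim in place.
read_tabular <- function(x, parse_fn, passthrough_fn) {
  lines <- read_lines_any(x)
  is_pass <- vapply(lines, passthrough_fn, NA, USE.NAMES = FALSE)
  records <- lapply(which(!is_pass), function(i) {
    tryCatch(parse_fn(lines[i]), error = function(e) {
      pg_stop("parse_error", "line %d: %s", i, conditionMessage(e))
    })
  })
  layout <- ifelse(is_pass, lines, NA_character_)
  list(records = records, layout = layout)
}

write_tabular <- function(doc, path = NULL) {
  if (is.null(doc$layout)) {
    doc <- list(records = doc, layout = rep(NA_character_, length(doc)))
  }
  lines <- doc$layout
  lines[is.na(lines)] <- vapply(doc$records, format, "")
  write_lines_any(lines, path)
}
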
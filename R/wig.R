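#' Wiggle (WIG) values
#'
#' A WIG file interleaves `fixedStep`/`variableStep` declaration lines with
#' value lines.  Reading expands both section kinds into explicit
#' `WigValue` tuples `(chrom, start, span, value)` in canonical 0-based
#' coordinates (WIG declarations are 1-based).  `track` lines are kept as
#' pass-through.  Writing emits canonical `variableStep` sections (the
#' original sectioning is not retained after expansion); a value's original
#' lexical form is preserved so written numbers match the source tokens.
#'
#' @param chrom sequence name.
#' @param start canonical 0-based start.
#' @param span number of bases the value covers (>= 1).
#' @param value numeric value or its original string token.
#' @return A `WigValue`.
#' @examples
#' v <- wig_value("chr1", 10, 5, 3.5)
#' as_interval(v)
#' @export
wig_value <- function(chrom, start, span, value) {
  token <- as.character(value)
  num <- suppressWarnings(as.numeric(token))
  if (is.na(num)) pg_stop("malformed_field_error", "non-numeric WIG value '%s'", token)
  if (!is_count(start)) pg_stop("coordinate_error", "invalid WIG start")
  if (!is_count(span) || span < 1) {
    pg_stop("malformed_field_error", "WIG span must be >= 1")
  }
  structure(list(chrom = chrom, start = as.numeric(start),
                 span = as.numeric(span), value = num, token = token),
            class = "WigValue")
}

#' @export
print.WigValue <- function(x, ...) {
  cat(sprintf("WigValue: %s:[%s, %s) = %s\n", x$chrom, fmt_int(x$start),
              fmt_int(x$start + x$span), x$token))
  invisible(x)
}

#' @export
as_interval.WigValue <- function(x, ...) {
  gi(x$chrom, x$start, x$start + x$span)
}

parse_wig_keyvals <- function(line) {
  parts <- strsplit(line, "[ \t]+")[[1L]][-1L]
  kv <- strsplit(parts, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) {
    pg_stop("malformed_field_error", "bad WIG declaration: '%s'", line)
  }
  stats::setNames(vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L))
}

#' Read a WIG stream
#'
#' @param x path, connection, or character vector of lines.
#' @return A list with `values` (list of `WigValue`) and `track_lines`
#'   (any `track`/comment lines encountered, verbatim).
#' @export
read_wig <- function(x) {
  lines <- read_lines_any(x)
  values <- list()
  nvals <- 0L
  track_lines <- character(0)
  mode <- NULL        # "fixed" or "variable"
  chrom <- NULL
  span <- 1
  fixed_next <- NULL  # next canonical start in a fixedStep section
  step <- NULL
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line) || startsWith(line, "#")) next
    if (startsWith(line, "track") || startsWith(line, "browser")) {
      track_lines <- c(track_lines, line)
      next
    }
    if (startsWith(line, "fixedStep")) {
      kv <- parse_wig_keyvals(line)
      if (!all(c("chrom", "start", "step") %in% names(kv))) {
        pg_stop("malformed_field_error",
                "fixedStep requires chrom, start and step (line %d)", i)
      }
      mode <- "fixed"
      chrom <- kv[["chrom"]]
      step <- as.numeric(kv[["step"]])
      span <- if ("span" %in% names(kv)) as.numeric(kv[["span"]]) else 1
      fixed_next <- as.numeric(kv[["start"]]) - 1
      if (is.na(fixed_next) || fixed_next < 0 || is.na(step) || step < 1 ||
          is.na(span) || span < 1 || span > step) {
        pg_stop("malformed_field_error",
                "inconsistent fixedStep parameters (line %d): span must be <= step", i)
      }
      next
    }
    if (startsWith(line, "variableStep")) {
      kv <- parse_wig_keyvals(line)
      if (!"chrom" %in% names(kv)) {
        pg_stop("malformed_field_error",
                "variableStep requires chrom (line %d)", i)
      }
      mode <- "variable"
      chrom <- kv[["chrom"]]
      span <- if ("span" %in% names(kv)) as.numeric(kv[["span"]]) else 1
      if (is.na(span) || span < 1) {
        pg_stop("malformed_field_error", "invalid span (line %d)", i)
      }
      next
    }
    if (is.null(mode)) {
      pg_stop("declaration_missing_error",
              "WIG value line %d before any fixedStep/variableStep declaration", i)
    }
    if (mode == "fixed") {
      v <- wig_value(chrom, fixed_next, span, line)
      fixed_next <- fixed_next + step
    } else {
      parts <- strsplit(line, "[ \t]+")[[1L]]
      if (length(parts) != 2L) {
        pg_stop("malformed_field_error",
                "variableStep value line %d needs 'position value'", i)
      }
      pos <- suppressWarnings(as.numeric(parts[1L]))
      if (is.na(pos) || pos < 1 || pos != floor(pos)) {
        pg_stop("coordinate_error", "invalid WIG position '%s' (line %d)",
                parts[1L], i)
      }
      v <- wig_value(chrom, pos - 1, span, parts[2L])
    }
    nvals <- nvals + 1L
    values[[nvals]] <- v
  }
  list(values = values, track_lines = track_lines)
}

#' Write WIG values
#'
#' Values are grouped into runs of identical (chrom, span) and emitted as
#' `variableStep` sections; `span=1` is left implicit.  `read_wig()` of the
#' output returns the input values, and writing a file that is already in
#' this canonical layout reproduces it byte-for-byte.
#'
#' @param doc list as returned by `read_wig()`, or a bare list of `WigValue`.
#' @param path output path, connection, or NULL to return the lines.
#' @export
write_wig <- function(doc, path = NULL) {
  if (is.null(doc$values)) doc <- list(values = doc, track_lines = character(0))
  lines <- doc$track_lines
  vals <- doc$values
  cur_chrom <- NULL
  cur_span <- NULL
  for (v in vals) {
    if (is.null(cur_chrom) || v$chrom != cur_chrom || v$span != cur_span) {
      decl <- sprintf("variableStep chrom=%s", v$chrom)
      if (v$span != 1) decl <- sprintf("%s span=%s", decl, fmt_int(v$span))
      lines <- c(lines, decl)
      cur_chrom <- v$chrom
      cur_span <- v$span
    }
    lines <- c(lines, sprintf("%s %s", fmt_int(v$start + 1), v$token))
  }
  write_lines_any(lines, path)
}
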
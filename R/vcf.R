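#' VCF headers
#'
#' The header is every `##` meta line (kept verbatim and in order) plus the
#' `#CHROM` column line.  Structured views of INFO/FORMAT/FILTER/contig
#' meta lines are computed on demand with [vcf_header_meta()]; the raw
#' lines remain authoritative for writing, so round-trips are byte-exact.
#'
#' @param lines character vector: the `##` lines followed by the `#CHROM`
#'   line.
#' @return A `VcfHeader` with elements `meta` (the `##` lines), `columns`
#'   (the `#CHROM` line) and `samples` (character vector of sample names).
#' @export
vcf_header <- function(lines) {
  if (length(lines) == 0L || !startsWith(lines[1L], "##fileformat=")) {
    pg_stop("missing_header_error",
            "VCF must begin with a ##fileformat line")
  }
  chrom_i <- which(startsWith(lines, "#CHROM"))
  if (length(chrom_i) != 1L || chrom_i != length(lines)) {
    pg_stop("missing_header_error",
            "VCF header must end with a single #CHROM column line")
  }
  meta <- lines[-chrom_i]
  if (!all(startsWith(meta, "##"))) {
    pg_stop("missing_header_error", "non-meta line inside VCF header")
  }
  cols <- strsplit(lines[chrom_i], "\t", fixed = TRUE)[[1L]]
  fixed <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(cols) < 8L || !identical(cols[1:8], fixed)) {
    pg_stop("missing_header_error", "malformed #CHROM column line")
  }
  samples <- if (length(cols) > 9L) cols[10:length(cols)] else character(0)
  if (length(cols) == 9L) {
    pg_stop("missing_header_error", "FORMAT column present but no samples")
  }
  structure(list(meta = meta, columns = lines[chrom_i], samples = samples),
            class = "VcfHeader")
}

#' @export
format.VcfHeader <- function(x, ...) c(x$meta, x$columns)

#' @export
print.VcfHeader <- function(x, ...) {
  cat(sprintf("VcfHeader: %d meta line(s), %d sample(s)\n",
              length(x$meta), length(x$samples)))
  invisible(x)
}

#' @rdname vcf_header
#' @param header a `VcfHeader`.
#' @param kind one of "INFO", "FORMAT", "FILTER", "contig".
#' @return `vcf_header_meta()` returns a data.frame of the structured
#'   fields (ID and, where present, Number/Type/Description/length).
#' @export
vcf_header_meta <- function(header, kind = "INFO") {
  prefix <- sprintf("##%s=<", kind)
  sel <- header$meta[startsWith(header$meta, prefix)]
  body <- sub("^##[^=]+=<", "", sub(">$", "", sel))
  fields <- lapply(body, function(b) {
    # split on commas outside double quotes
    chars <- strsplit(b, "")[[1L]]
    inq <- FALSE
    cut <- logical(length(chars))
    for (i in seq_along(chars)) {
      if (chars[i] == '"') inq <- !inq
      if (chars[i] == "," && !inq) cut[i] <- TRUE
    }
    parts <- strsplit(paste(ifelse(cut, "\x01", chars), collapse = ""),
                      "\x01", fixed = TRUE)[[1L]]
    kv <- regmatches(parts, regexec("^([^=]+)=(.*)$", parts))
    stats::setNames(vapply(kv, `[[`, "", 3L), vapply(kv, `[[`, "", 2L))
  })
  keys <- unique(unlist(lapply(fields, names)))
  out <- as.data.frame(stats::setNames(
    lapply(keys, function(k) {
      vapply(fields, function(f) if (k %in% names(f)) f[[k]] else NA_character_, "")
    }), keys), optional = TRUE, stringsAsFactors = FALSE)
  out
}

#' VCF records
#'
#' A record stores the tab-separated column tokens verbatim (so writing
#' reproduces the line exactly) and exposes typed accessors.  `pos` is
#' 1-based as in the format.
#'
#' @param line one VCF data line.
#' @param header optional `VcfHeader`; when given, the per-sample column
#'   count is validated against the header's sample count.
#' @return `parse_vcf_record()` returns a `VcfRecord`.
#' @examples
#' h <- vcf_header(c("##fileformat=VCFv4.3",
#'                   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"))
#' rec <- parse_vcf_record("chr1\t100\trs1\tA\tG\t50\tPASS\t.")
#' vcf_alt(rec)
#' @export
parse_vcf_record <- function(line, header = NULL) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 8L) {
    pg_stop("column_count_error", "VCF record has %d column(s); 8 required",
            length(f))
  }
  pos <- suppressWarnings(as.numeric(f[2L]))
  if (is.na(pos) || pos < 1 || pos != floor(pos)) {
    pg_stop("malformed_field_error", "invalid POS '%s'", f[2L])
  }
  if (!nzchar(f[4L])) {
    pg_stop("malformed_field_error", "empty REF allele")
  }
  if (!is.null(header)) {
    expected <- if (length(header$samples) > 0L) 9L + length(header$samples) else 8L
    if (length(f) != expected) {
      pg_stop("column_count_error",
              "VCF record has %d column(s); header implies %d",
              length(f), expected)
    }
  }
  structure(list(chrom = f[1L], pos = pos, id = f[3L], ref = f[4L],
                 alt = f[5L], qual = f[6L], filter = f[7L], info = f[8L],
                 format = if (length(f) >= 9L) f[9L] else NULL,
                 samples = if (length(f) >= 10L) f[10:length(f)] else character(0)),
            class = "VcfRecord")
}

#' @export
format.VcfRecord <- function(x, ...) {
  paste(c(x$chrom, fmt_int(x$pos), x$id, x$ref, x$alt, x$qual, x$filter,
          x$info, x$format, x$samples), collapse = "\t")
}

#' @export
print.VcfRecord <- function(x, ...) {
  cat("VcfRecord:", format(x), "\n")
  invisible(x)
}

#' @rdname parse_vcf_record
#' @param x a `VcfRecord`.
#' @export
vcf_alt <- function(x) {
  if (x$alt == ".") character(0) else strsplit(x$alt, ",", fixed = TRUE)[[1L]]
}

#' @rdname parse_vcf_record
#' @param key INFO key to look up.
#' @return `vcf_info()` returns the raw INFO value string, TRUE for
#'   flag-style keys, or NULL when absent.
#' @export
vcf_info <- function(x, key) {
  if (x$info == ".") return(NULL)
  for (piece in strsplit(x$info, ";", fixed = TRUE)[[1L]]) {
    eq <- regexpr("=", piece, fixed = TRUE)
    if (eq == -1L) {
      if (piece == key) return(TRUE)
    } else if (substr(piece, 1L, eq - 1L) == key) {
      return(substr(piece, eq + 1L, nchar(piece)))
    }
  }
  NULL
}

is_literal_allele <- function(a) grepl("^[ACGTNacgtn]+$", a)

#' @export
as_interval.VcfRecord <- function(x, ...) {
  if (!is_literal_allele(x$ref)) {
    pg_stop("symbolic_allele_error",
            "REF allele '%s' is not a literal sequence", x$ref)
  }
  end_info <- vcf_info(x, "END")
  end <- if (!is.null(end_info) && !isTRUE(end_info)) {
    as.numeric(end_info)
  } else {
    x$pos - 1 + nchar(x$ref)
  }
  gi(x$chrom, x$pos - 1, end)
}

#' Classify a single-nucleotide substitution
#'
#' A substitution within the purines `{A, G}` or within the pyrimidines
#' `{C, T}` is a transition; any other single-base substitution is a
#' transversion.  Pairs that are not a single-base substitution (indels,
#' multi-base alleles, symbolic alleles, identical alleles) are `not_snv`.
#' Case-insensitive and symmetric in its arguments.
#'
#' @param ref,alt allele strings.
#' @return One of `"transition"`, `"transversion"`, `"not_snv"`.
#' @examples
#' classify_snv("A", "G")  # transition
#' classify_snv("A", "C")  # transversion
#' classify_snv("A", "AT") # not_snv
#' @export
classify_snv <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  bases <- c("A", "C", "G", "T")
  if (nchar(ref) != 1L || nchar(alt) != 1L || ref == alt ||
      !ref %in% bases || !alt %in% bases) {
    return("not_snv")
  }
  purine <- c("A", "G")
  if ((ref %in% purine) == (alt %in% purine)) "transition" else "transversion"
}

#' Read or write a VCF file
#'
#' @param x path, connection, or character vector of lines (plain or gzip;
#'   for BGZF-compressed VCF decode the stream with [bgzf_decompress()]
#'   first).
#' @return `read_vcf()` returns a list with `header` (a `VcfHeader`) and
#'   `records` (list of `VcfRecord`).
#' @export
read_vcf <- function(x) {
  lines <- read_lines_any(x)
  n_header <- match(TRUE, !startsWith(lines, "#")) - 1L
  if (is.na(n_header)) n_header <- length(lines)
  if (n_header == 0L) {
    pg_stop("missing_header_error", "VCF data line before any header line")
  }
  header <- vcf_header(lines[seq_len(n_header)])
  body <- lines[-seq_len(n_header)]
  body <- body[nzchar(body)]
  records <- lapply(seq_along(body), function(i) {
    tryCatch(parse_vcf_record(body[i], header), error = function(e) {
      pg_stop("parse_error", "VCF record %d: %s", i, conditionMessage(e))
    })
  })
  list(header = header, records = records)
}

#' @rdname read_vcf
#' @param doc list with `header` and `records` as returned by `read_vcf()`.
#' @param path output path, connection, or NULL to return the lines.
#' @export
write_vcf <- function(doc, path = NULL) {
  lines <- c(format(doc$header), vapply(doc$records, format, ""))
  write_lines_any(lines, path)
}

#' Stream over VCF records without materializing the file
#'
#' Reads the file in chunks of `chunk` lines and invokes `fn` once per
#' record, so per-record state is all that accumulates.
#'
#' @param path file path or connection.
#' @param fn function called with each `VcfRecord`.
#' @param chunk lines per read.
#' @return The number of records processed, invisibly.
#' @export
vcf_apply <- function(path, fn, chunk = 512L) {
  con <- if (inherits(path, "connection")) path else file(path, "rt")
  if (!inherits(path, "connection")) on.exit(close(con))
  header_lines <- character(0)
  n <- 0L
  carry <- character(0)
  header <- NULL
  repeat {
    lines <- c(carry, readLines(con, n = chunk, warn = FALSE))
    carry <- character(0)
    if (length(lines) == 0L) break
    if (is.null(header)) {
      is_h <- startsWith(lines, "#")
      if (all(is_h)) {
        header_lines <- c(header_lines, lines)
        next
      }
      split_at <- match(FALSE, is_h)
      header_lines <- c(header_lines, lines[seq_len(split_at - 1L)])
      header <- vcf_header(header_lines)
      lines <- lines[split_at:length(lines)]
    }
    for (line in lines[nzchar(lines)]) {
      fn(parse_vcf_record(line, header))
      n <- n + 1L
    }
  }
  invisible(n)
}
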
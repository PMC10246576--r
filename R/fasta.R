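#' FASTA records
#'
#' A record is the first whitespace-delimited token of the `>` header (the
#' identifier), the remainder of the header (the description), and the
#' concatenation of all following sequence lines.  The sequence alphabet
#' is not validated: the package transports sequences, it does not
#' interpret them.  Original line wrapping is not preserved; writing at
#' the source wrap width reproduces a file exactly.
#'
#' @param identifier non-empty record identifier.
#' @param sequence sequence string (may be empty).
#' @param description header remainder (default "").
#' @return A `FastaRecord`.
#' @export
fasta_record <- function(identifier, sequence = "", description = "") {
  if (!nzchar(identifier) || grepl("[ \t]", identifier)) {
    pg_stop("record_error", "FASTA identifier must be non-empty, no whitespace")
  }
  structure(list(identifier = identifier, description = description,
                 sequence = sequence),
            class = "FastaRecord")
}

#' @export
print.FastaRecord <- function(x, ...) {
  cat(sprintf("FastaRecord %s (%d bp)\n", x$identifier, nchar(x$sequence)))
  invisible(x)
}

#' Read FASTA
#'
#' @param x path, connection, or character vector of lines (plain or gzip
#'   on read).
#' @return A list of `FastaRecord`.
#' @export
read_fasta <- function(x) {
  lines <- read_lines_any(x)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  if (!startsWith(lines[1L], ">")) {
    pg_stop("leading_garbage_error", "data before the first '>' header")
  }
  starts <- which(startsWith(lines, ">"))
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    hdr <- substring(lines[starts[i]], 2L)
    sp <- regexpr("[ \t]", hdr)
    if (sp == -1L) {
      id <- hdr
      desc <- ""
    } else {
      id <- substr(hdr, 1L, sp - 1L)
      desc <- substr(hdr, sp + 1L, nchar(hdr))
    }
    seq <- if (ends[i] > starts[i]) {
      paste(lines[(starts[i] + 1L):ends[i]], collapse = "")
    } else {
      ""
    }
    fasta_record(id, seq, desc)
  })
}

#' Write FASTA
#'
#' @param records list of `FastaRecord`.
#' @param path output path, connection, or NULL to return the lines.
#' @param wrap wrap sequence lines at this many characters, or NULL for one
#'   line per record.
#' @export
write_fasta <- function(records, path = NULL, wrap = NULL) {
  lines <- character(0)
  for (r in records) {
    hdr <- paste0(">", r$identifier,
                  if (nzchar(r$description)) paste0(" ", r$description) else "")
    body <- if (!nzchar(r$sequence)) {
      character(0)
    } else if (is.null(wrap)) {
      r$sequence
    } else {
      n <- nchar(r$sequence)
      substring(r$sequence, seq(1L, n, by = wrap),
                pmin(seq(1L, n, by = wrap) + wrap - 1L, n))
    }
    lines <- c(lines, hdr, body)
  }
  write_lines_any(lines, path)
}

#' FASTQ records
#'
#' Strict four-line FASTQ: `@header`, sequence, `+`, quality.  Sequence
#' and quality must have equal length; quality is carried as an opaque
#' string (Phred+33 presumed, never decoded).  Any repeated identifier on
#' the `+` line is dropped on read and never written back.
#'
#' @param identifier,sequence,quality,description record fields.
#' @return A `FastqRecord`.
#' @export
fastq_record <- function(identifier, sequence, quality, description = "") {
  if (!nzchar(identifier) || grepl("[ \t]", identifier)) {
    pg_stop("record_error", "FASTQ identifier must be non-empty, no whitespace")
  }
  if (nchar(sequence) != nchar(quality)) {
    pg_stop("length_mismatch_error",
            "sequence length %d != quality length %d",
            nchar(sequence), nchar(quality))
  }
  structure(list(identifier = identifier, description = description,
                 sequence = sequence, quality = quality),
            class = "FastqRecord")
}

#' @export
print.FastqRecord <- function(x, ...) {
  cat(sprintf("FastqRecord %s (%d bp)\n", x$identifier, nchar(x$sequence)))
  invisible(x)
}

#' Read FASTQ
#'
#' @param x path, connection, or character vector of lines (plain or gzip
#'   on read).
#' @return A list of `FastqRecord`.
#' @export
read_fastq <- function(x) {
  lines <- read_lines_any(x)
  if (length(lines) > 0L && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4L != 0L) {
    pg_stop("structure_error",
            "FASTQ line count %d is not a multiple of 4 (strict 4-line records)",
            length(lines))
  }
  n <- length(lines) %/% 4L
  lapply(seq_len(n), function(i) {
    base <- (i - 1L) * 4L
    if (!startsWith(lines[base + 1L], "@")) {
      pg_stop("structure_error", "line %d: expected '@' header", base + 1L)
    }
    if (!startsWith(lines[base + 3L], "+")) {
      pg_stop("structure_error", "line %d: expected '+' separator", base + 3L)
    }
    hdr <- substring(lines[base + 1L], 2L)
    sp <- regexpr("[ \t]", hdr)
    id <- if (sp == -1L) hdr else substr(hdr, 1L, sp - 1L)
    desc <- if (sp == -1L) "" else substr(hdr, sp + 1L, nchar(hdr))
    tryCatch(
      fastq_record(id, lines[base + 2L], lines[base + 4L], desc),
      error = function(e) {
        pg_stop("length_mismatch_error", "record at line %d: %s",
                base + 1L, conditionMessage(e))
      }
    )
  })
}

#' Write FASTQ
#'
#' @param records list of `FastqRecord`.
#' @param path output path, connection, or NULL to return the lines.
#' @export
write_fastq <- function(records, path = NULL) {
  lines <- unlist(lapply(records, function(r) {
    hdr <- paste0("@", r$identifier,
                  if (nzchar(r$description)) paste0(" ", r$description) else "")
    c(hdr, r$sequence, "+", r$quality)
  }))
  if (is.null(lines)) lines <- character(0)
  write_lines_any(lines, path)
}
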
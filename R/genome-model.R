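#' Genome assembly: the universe that bounds all intervals
#'
#' A `GenomeAssembly` is an ordered collection of assembled sequence
#' (chromosome, scaffold or contig) names with their lengths in base pairs.
#' Every genomic interval in the package is anchored to one of its sequences
#' and bounded by that sequence's length.  The order of sequences is
#' significant: it defines the sort order of multi-sequence outputs.
#'
#' @param names character vector of unique, non-empty sequence names.
#' @param lengths numeric vector of sequence lengths (>= 1), same length as
#'   `names`.  Stored as doubles so lengths beyond 2^31 are representable.
#' @return An object of class `GenomeAssembly`.
#' @examples
#' asm <- genome_assembly(c("chr1", "chr2"), c(1000, 500))
#' seq_lengths(asm)
#' @export
genome_assembly <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) != length(lengths)) {
    pg_stop("assembly_error", "names and lengths differ in length")
  }
  if (anyNA(names) || any(!nzchar(names))) {
    pg_stop("assembly_error", "sequence names must be non-empty")
  }
  if (anyDuplicated(names)) {
    pg_stop("assembly_error", "duplicate sequence name: %s",
            names[duplicated(names)][1L])
  }
  if (anyNA(lengths) || any(lengths < 1) || any(lengths != floor(lengths))) {
    pg_stop("assembly_error", "sequence lengths must be integers >= 1")
  }
  structure(list(names = names, lengths = stats::setNames(lengths, names)),
            class = "GenomeAssembly")
}

#' @rdname genome_assembly
#' @param asm a `GenomeAssembly`.
#' @export
seq_names <- function(asm) asm$names

#' @rdname genome_assembly
#' @export
seq_lengths <- function(asm) asm$lengths

#' @export
print.GenomeAssembly <- function(x, ...) {
  cat(sprintf("GenomeAssembly with %d sequence(s)\n", length(x$names)))
  utils::head(data.frame(name = x$names, length = unname(x$lengths)), 10L)
}

#' @export
format.GenomeAssembly <- function(x, ...) {
  paste0(x$names, "\t", fmt_int(unname(x$lengths)))
}

#' Read or write a two-column genome file
#'
#' Genome files are tab-separated `name<TAB>length` text (the conventional
#' ".genome" shape, equal to the first two columns of a FASTA index).
#'
#' @param x a file path, connection, or character vector of lines.
#' @return `read_genome()` returns a `GenomeAssembly`.
#' @export
read_genome <- function(x) {
  lines <- read_lines_any(x)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    pg_stop("genome_file_error", "genome file line lacks a length column")
  }
  nm <- vapply(parts, `[[`, "", 1L)
  ln <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(ln)) {
    pg_stop("genome_file_error", "non-numeric sequence length in genome file")
  }
  genome_assembly(nm, ln)
}

#' @rdname read_genome
#' @param asm a `GenomeAssembly`.
#' @param path output path, connection, or NULL to return lines.
#' @export
write_genome <- function(asm, path = NULL) {
  write_lines_any(format(asm), path)
}

#' Genomic intervals
#'
#' A `GenomicInterval` is a span on a named assembled sequence in the
#' package's canonical coordinates: 0-based, half-open `[start, end)`.
#' Empty intervals are not representable (`start < end` strictly); empty
#' results of set operations are empty collections instead.  Strand is
#' carried as metadata and does not partition the interval algebra.
#'
#' @param seq_name sequence (chromosome/scaffold/contig) name.
#' @param start 0-based inclusive start, a non-negative integer.
#' @param end exclusive end, an integer greater than `start`.
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded).
#' @return An object of class `GenomicInterval`.
#' @examples
#' gi("chr1", 0, 10)
#' interval_length(gi("chr1", 5, 6))
#' @export
gi <- function(seq_name, start, end, strand = "*") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (!is.character(seq_name) || length(seq_name) != 1L || !nzchar(seq_name)) {
    pg_stop("interval_error", "seq_name must be a non-empty string")
  }
  if (!is_count(start) || !is.numeric(end) || length(end) != 1L || is.na(end)) {
    pg_stop("interval_error", "start and end must be non-negative integers")
  }
  if (start >= end) {
    pg_stop("degenerate_interval_error",
            "degenerate interval: start %s >= end %s on %s",
            fmt_int(start), fmt_int(end), seq_name)
  }
  if (!strand %in% c("+", "-", "*")) {
    pg_stop("interval_error", "strand must be one of '+', '-', '*'")
  }
  structure(list(seq_name = seq_name, start = start, end = end,
                 strand = strand),
            class = "GenomicInterval")
}

#' @export
print.GenomicInterval <- function(x, ...) {
  cat(sprintf("%s:[%s, %s) %s\n", x$seq_name, fmt_int(x$start),
              fmt_int(x$end), x$strand))
  invisible(x)
}

#' @export
format.GenomicInterval <- function(x, ...) {
  sprintf("%s\t%s\t%s", x$seq_name, fmt_int(x$start), fmt_int(x$end))
}

#' Validate an interval against a genome assembly
#'
#' Checks that the interval's sequence exists in the assembly and that the
#' interval lies within `[0, length)` of that sequence.  Returns the interval
#' unchanged (the function is idempotent and has no side effects).
#'
#' @param iv a `GenomicInterval`.
#' @param asm a `GenomeAssembly`.
#' @return `iv`, invisibly unchanged, if valid; otherwise an error of class
#'   `unknown_sequence_error` or `bounds_error`.
#' @export
validate_interval <- function(iv, asm) {
  stopifnot(inherits(iv, "GenomicInterval"), inherits(asm, "GenomeAssembly"))
  len <- asm$lengths[iv$seq_name]
  if (is.na(len)) {
    pg_stop("unknown_sequence_error", "unknown sequence '%s'", iv$seq_name)
  }
  if (iv$end > len) {
    pg_stop("bounds_error", "interval end %s exceeds length %s of %s",
            fmt_int(iv$end), fmt_int(len), iv$seq_name)
  }
  iv
}

#' @rdname gi
#' @param iv a `GenomicInterval`.
#' @export
interval_length <- function(iv) iv$end - iv$start

#' Do two intervals overlap?
#'
#' Half-open semantics: intervals sharing only a boundary point do not
#' overlap.  Intervals on different sequences never overlap.  Strand is
#' ignored.
#'
#' @param a,b `GenomicInterval` objects.
#' @return TRUE iff the per-base occupancy sets of `a` and `b` intersect.
#' @export
intervals_overlap <- function(a, b) {
  a$seq_name == b$seq_name && a$start < b$end && b$start < a$end
}

# Convert a list of GenomicInterval to a data.frame (assembly order when
# given, else first-seen sequence order; rows sorted by (seq, start, end)).
intervals_to_df <- function(ivs, asm = NULL) {
  if (length(ivs) == 0L) {
    return(data.frame(seq_name = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    seq_name = vapply(ivs, `[[`, "", "seq_name"),
    start = vapply(ivs, `[[`, 0, "start"),
    end = vapply(ivs, `[[`, 0, "end"),
    strand = vapply(ivs, `[[`, "", "strand"),
    stringsAsFactors = FALSE
  )
  lev <- if (is.null(asm)) unique(df$seq_name) else asm$names
  ord <- order(match(df$seq_name, lev), df$start, df$end)
  df[ord, , drop = FALSE]
}
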
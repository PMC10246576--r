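#' Seeded synthetic-data generators
#'
#' The validation methodology of the package is property-based: seeded
#' generators produce random assemblies, intervals and format records;
#' round-trip and oracle properties are then checked on them.  A fixed
#' `(config, seed)` pair regenerates every artifact byte-identically, and
#' generators never emit invalid data (negative cases come from
#' [gen_invalid_line()]).
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_seq range (length-2 vector) for the number of assembly
#'   sequences.
#' @param seq_len range for sequence lengths in bp.
#' @param n_records range for per-file record counts.
#' @param n_intervals range for generated interval counts.
#' @return `gen_config()` returns a `GeneratorConfig` list.
#' @export
gen_config <- function(seed = 1L, n_seq = c(1L, 3L),
                       seq_len = c(1000, 10000),
                       n_records = c(5L, 30L),
                       n_intervals = c(1L, 100L)) {
  structure(list(seed = as.integer(seed), n_seq = n_seq, seq_len = seq_len,
                 n_records = n_records, n_intervals = n_intervals),
            class = "GeneratorConfig")
}

rint <- function(lo, hi, n = 1L) {
  if (lo >= hi) rep(lo, n) else lo + floor(stats::runif(n) * (hi - lo + 1))
}

#' @rdname gen_config
#' @param cfg a `GeneratorConfig`.
#' @return `gen_assembly()` returns a `GenomeAssembly` with sequences
#'   named `seq1..seqN`.
#' @export
gen_assembly <- function(cfg) {
  with_seed(cfg$seed, {
    n <- rint(cfg$n_seq[1L], cfg$n_seq[2L])
    genome_assembly(paste0("seq", seq_len(n)),
                    rint(cfg$seq_len[1L], cfg$seq_len[2L], n))
  })
}

#' @rdname gen_config
#' @param asm a `GenomeAssembly` to bound the intervals.
#' @return `gen_intervals()` returns a list of valid `GenomicInterval`.
#' @export
gen_intervals <- function(cfg, asm) {
  with_seed(cfg$seed + 1L, {
    n <- rint(cfg$n_intervals[1L], cfg$n_intervals[2L])
    lapply(seq_len(n), function(i) {
      nm <- asm$names[rint(1L, length(asm$names))]
      len <- asm$lengths[[nm]]
      st <- rint(0, len - 1)
      gi(nm, st, rint(st + 1, len), sample(c("+", "-", "*"), 1L))
    })
  })
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_word <- function(min = 3L, max = 8L) {
  paste(sample(c(letters, LETTERS, 0:9), rint(min, max), replace = TRUE),
        collapse = "")
}

gen_bed_lines <- function(cfg, asm, n) {
  vapply(seq_len(n), function(i) {
    nm <- asm$names[rint(1L, length(asm$names))]
    len <- asm$lengths[[nm]]
    st <- rint(0, len - 1)
    en <- rint(st + 1, len)
    ncol <- sample(c(3L, 4L, 5L, 6L, 12L), 1L,
                   prob = c(.3, .2, .2, .2, .1))
    f <- c(nm, fmt_int(st), fmt_int(en))
    if (ncol >= 4L) f <- c(f, rand_word())
    if (ncol >= 5L) f <- c(f, fmt_int(rint(0, 1000)))
    if (ncol >= 6L) f <- c(f, sample(c("+", "-", "."), 1L))
    if (ncol == 12L) {
      nb <- rint(1L, 3L)
      width <- en - st
      sizes <- rint(1L, max(1, width %/% (nb + 1L)), nb)
      gap <- max(1, width %/% nb)
      starts <- sort(c(0, if (nb > 1L) cumsum(rep(gap, nb - 1L))))
      f <- c(f, fmt_int(st), fmt_int(en), "0,0,0", fmt_int(nb),
             paste0(paste(fmt_int(sizes), collapse = ","), ","),
             paste0(paste(fmt_int(starts), collapse = ","), ","))
    }
    paste(f, collapse = "\t")
  }, "")
}

gen_gff3_lines <- function(cfg, asm, n) {
  types <- c("gene", "mRNA", "exon", "CDS")
  vapply(seq_len(n), function(i) {
    nm <- asm$names[rint(1L, length(asm$names))]
    len <- asm$lengths[[nm]]
    st <- rint(1, len)
    en <- rint(st, len)
    ty <- sample(types, 1L)
    phase <- if (ty == "CDS") as.character(rint(0L, 2L)) else "."
    val <- rand_word()
    if (stats::runif(1) < .3) val <- paste0(val, gff3_encode(";=,"))
    attrs <- sprintf("ID=%s;Name=%s", rand_word(), val)
    paste(nm, sample(c(".", "src"), 1L), ty, fmt_int(st), fmt_int(en),
          sample(c(".", "0.5", "12"), 1L), sample(c("+", "-", ".", "?"), 1L),
          phase, attrs, sep = "\t")
  }, "")
}

gen_gtf_lines <- function(cfg, asm, n) {
  vapply(seq_len(n), function(i) {
    nm <- asm$names[rint(1L, length(asm$names))]
    len <- asm$lengths[[nm]]
    st <- rint(1, len)
    en <- rint(st, len)
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     rand_word(), rand_word())
    ty <- sample(c("exon", "CDS", "transcript"), 1L)
    phase <- if (ty == "CDS") as.character(rint(0L, 2L)) else "."
    paste(nm, "src", ty, fmt_int(st), fmt_int(en),
          sample(c(".", "0.1"), 1L), sample(c("+", "-"), 1L), phase,
          attrs, sep = "\t")
  }, "")
}

gen_wig_lines <- function(cfg, asm, n) {
  # canonical variableStep sections with ascending unique positions
  nm <- asm$names[rint(1L, length(asm$names))]
  len <- asm$lengths[[nm]]
  span <- rint(1L, 5L)
  npos <- min(n, max(1, (len %/% (span + 1)) - 1))
  pos <- sort(sample.int(max(1, len - span), npos)) # 1-based starts
  vals <- sprintf("%.2f", round(stats::runif(npos) * 100, 2))
  decl <- sprintf("variableStep chrom=%s", nm)
  if (span != 1) decl <- sprintf("%s span=%s", decl, fmt_int(span))
  c(decl, paste(fmt_int(pos), vals))
}

gen_vcf_lines <- function(cfg, asm, n) {
  with_samples <- stats::runif(1) < .5
  hdr <- c("##fileformat=VCFv4.3",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Interval end\">",
           sprintf("##contig=<ID=%s,length=%s>", asm$names,
                   fmt_int(unname(asm$lengths))))
  cols <- "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  if (with_samples) {
    hdr <- c(hdr,
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
    cols <- paste(cols, "FORMAT", "s1", "s2", sep = "\t")
  }
  body <- vapply(seq_len(n), function(i) {
    nm <- asm$names[rint(1L, length(asm$names))]
    len <- asm$lengths[[nm]]
    pos <- rint(1, len - 5)
    kind <- sample(c("snv", "mnv", "ins", "del", "multi"), 1L,
                   prob = c(.5, .1, .15, .15, .1))
    ref <- switch(kind, snv = rand_dna(1L), mnv = rand_dna(2L),
                  ins = rand_dna(1L), del = rand_dna(rint(2L, 4L)),
                  multi = rand_dna(1L))
    alt <- switch(kind,
                  snv = sample(setdiff(c("A", "C", "G", "T"),
                                       strsplit(ref, "")[[1L]][1L]), 1L),
                  mnv = rand_dna(2L),
                  ins = paste0(ref, rand_dna(rint(1L, 3L))),
                  del = substr(ref, 1L, 1L),
                  multi = paste(sample(setdiff(c("A", "C", "G", "T"),
                                               strsplit(ref, "")[[1L]][1L]),
                                       2L), collapse = ","))
    f <- c(nm, fmt_int(pos), sample(c(".", paste0("rs", rint(1, 99999))), 1L),
           ref, alt, sample(c(".", "50", "99.5"), 1L),
           sample(c("PASS", "."), 1L),
           sample(c(".", sprintf("DP=%s", fmt_int(rint(1, 500)))), 1L))
    if (with_samples) {
      f <- c(f, "GT", sample(c("0/0", "0/1", "1/1"), 1L),
             sample(c("0/0", "0/1", "1/1"), 1L))
    }
    paste(f, collapse = "\t")
  }, "")
  c(hdr, cols, body)
}

gen_cigar <- function(qlen) {
  # query-consuming core of M/I/=/X plus D/N, soft clips at the ends,
  # optional hard clips outside them; query span equals qlen by construction
  sl <- if (qlen > 2 && stats::runif(1) < .3) rint(1L, qlen %/% 3L) else 0L
  sr <- if (qlen - sl > 2 && stats::runif(1) < .3) rint(1L, qlen %/% 3L) else 0L
  core_q <- qlen - sl - sr
  ops <- character(0)
  lens <- numeric(0)
  rem <- core_q
  while (rem > 0) {
    op <- sample(c("M", "I", "=", "X", "D", "N"), 1L,
                 prob = c(.55, .1, .1, .05, .15, .05))
    if (op %in% c("D", "N")) {
      if (length(ops) == 0L || ops[length(ops)] %in% c("D", "N")) next
      lens <- c(lens, rint(1L, 10L))
      ops <- c(ops, op)
    } else {
      l <- rint(1L, rem)
      lens <- c(lens, l)
      ops <- c(ops, op)
      rem <- rem - l
    }
  }
  if (length(ops) == 0L || ops[length(ops)] %in% c("D", "N")) {
    lens <- c(lens, 1L)
    ops <- c(ops, "M")
    # keep query span exact: absorbed below by trimming a soft clip
    if (sl > 0L) sl <- sl - 1L else if (sr > 0L) sr <- sr - 1L else {
      lens[length(lens)] <- 0L
    }
    if (lens[length(lens)] == 0L) {
      lens <- lens[-length(lens)]
      ops <- ops[-length(ops)]
    }
  }
  if (sl > 0L) {
    lens <- c(sl, lens)
    ops <- c("S", ops)
  }
  if (sr > 0L) {
    lens <- c(lens, sr)
    ops <- c(ops, "S")
  }
  if (stats::runif(1) < .15) {
    lens <- c(rint(1L, 5L), lens)
    ops <- c("H", ops)
  }
  paste0(fmt_int(lens), ops, collapse = "")
}

gen_sam_lines <- function(cfg, asm, n) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%s", asm$names, fmt_int(unname(asm$lengths))))
  body <- vapply(seq_len(n), function(i) {
    mapped <- stats::runif(1) < .85
    qlen <- rint(20L, 80L)
    seq <- rand_dna(qlen)
    qual <- if (stats::runif(1) < .8) {
      paste(sample(strsplit(rawToChar(as.raw(33:73)), "")[[1L]], qlen,
                   replace = TRUE), collapse = "")
    } else {
      "*"
    }
    tags <- character(0)
    if (stats::runif(1) < .6) tags <- c(tags, sprintf("NM:i:%s", fmt_int(rint(0, 9))))
    if (stats::runif(1) < .3) tags <- c(tags, sprintf("XS:A:%s", sample(c("+", "-"), 1L)))
    if (stats::runif(1) < .3) tags <- c(tags, sprintf("RG:Z:%s", rand_word()))
    if (stats::runif(1) < .2) tags <- c(tags, sprintf("XF:f:%s", as.character(rint(0, 40) / 4)))
    if (stats::runif(1) < .15) {
      tags <- c(tags, sprintf("XB:B:i,%s", paste(fmt_int(rint(-50, 50, 3L)), collapse = ",")))
    }
    if (!mapped) {
      f <- c(paste0("r", fmt_int(i)), "4", "*", "0", "0", "*", "*", "0", "0",
             seq, qual)
      return(paste(c(f, tags), collapse = "\t"))
    }
    repeat {
      cig <- gen_cigar(qlen)
      refspan <- cigar_reference_span(parse_cigar(cig))
      nm <- asm$names[rint(1L, length(asm$names))]
      len <- asm$lengths[[nm]]
      if (refspan >= 1 && refspan <= len) break
    }
    pos <- rint(1, len - refspan + 1)
    flag <- sample(c(0L, 16L), 1L)
    f <- c(paste0("r", fmt_int(i)), fmt_int(flag), nm, fmt_int(pos),
           fmt_int(rint(0, 60)), cig, "*", "0", "0", seq, qual)
    paste(c(f, tags), collapse = "\t")
  }, "")
  c(hdr, body)
}

gen_fasta_lines <- function(cfg, asm, n) {
  unlist(lapply(seq_len(n), function(i) {
    id <- rand_word()
    desc <- if (stats::runif(1) < .5) paste("len", i) else ""
    hdr <- paste0(">", id, if (nzchar(desc)) paste0(" ", desc) else "")
    slen <- rint(0L, 200L)
    if (slen == 0L) hdr else c(hdr, rand_dna(slen))
  }))
}

gen_fastq_lines <- function(cfg, asm, n) {
  unlist(lapply(seq_len(n), function(i) {
    slen <- rint(1L, 150L)
    c(paste0("@", rand_word()), rand_dna(slen), "+",
      paste(sample(strsplit(rawToChar(as.raw(33:73)), "")[[1L]], slen,
                   replace = TRUE), collapse = ""))
  }))
}

#' Generate a synthetic file image plus its parsed records
#'
#' For each supported format, produces a valid serialized file image and
#' the records it parses to; the image re-serializes byte-identically,
#' which is the seed property of the round-trip suites.
#'
#' @param cfg a `GeneratorConfig`.
#' @param asm a `GenomeAssembly`.
#' @param format one of `"bed"`, `"gff3"`, `"gtf"`, `"wig"`, `"vcf"`,
#'   `"sam"`, `"fasta"`, `"fastq"`.
#' @return A list with `lines` (the file image) and `records` (parsed
#'   representation; for VCF/SAM a list with `header` and `records`).
#' @export
gen_records <- function(cfg, asm, format) {
  formats <- c("bed", "gff3", "gtf", "wig", "vcf", "sam", "fasta", "fastq")
  format <- match.arg(format, formats)
  lines <- with_seed(cfg$seed + 1000L * match(format, formats), {
    n <- rint(cfg$n_records[1L], cfg$n_records[2L])
    switch(format,
           bed = gen_bed_lines(cfg, asm, n),
           gff3 = gen_gff3_lines(cfg, asm, n),
           gtf = gen_gtf_lines(cfg, asm, n),
           wig = gen_wig_lines(cfg, asm, n),
           vcf = gen_vcf_lines(cfg, asm, n),
           sam = gen_sam_lines(cfg, asm, n),
           fasta = gen_fasta_lines(cfg, asm, n),
           fastq = gen_fastq_lines(cfg, asm, n))
  })
  records <- switch(format,
                    bed = read_bed(lines)$records,
                    gff3 = read_gff3(lines)$records,
                    gtf = read_gtf(lines)$records,
                    wig = read_wig(lines)$values,
                    vcf = read_vcf(lines),
                    sam = read_sam(lines),
                    fasta = read_fasta(lines),
                    fastq = read_fastq(lines))
  list(lines = lines, records = records)
}

#' Deliberately invalid format lines
#'
#' Takes a valid generated line and applies one format-aware corruption
#' (dropping a mandatory column, inverting coordinates, or injecting a
#' non-numeric token) guaranteed to violate the format; parsers must
#' reject the result with a classed diagnostic error, never crash.
#'
#' @param format format name as in [gen_records()].
#' @param seed integer seed.
#' @return A single invalid line (for FASTQ, a character vector of 4
#'   lines).
#' @export
gen_invalid_line <- function(format, seed) {
  with_seed(seed, {
    asm <- genome_assembly("seq1", 1000)
    switch(match.arg(format, c("bed", "gff3", "gtf", "wig", "vcf", "sam",
                               "fastq")),
      bed = {
        line <- gen_bed_lines(NULL, asm, 1L)
        f <- strsplit(line, "\t")[[1L]]
        sample(list(paste(f[c(1L, 3L, 2L)], collapse = "\t"),  # start >= end
                    f[1L],                                     # too few columns
                    paste(c(f[1L], "x", f[3L]), collapse = "\t")), 1L)[[1L]]
      },
      gff3 = {
        line <- gen_gff3_lines(NULL, asm, 1L)
        f <- strsplit(line, "\t")[[1L]]
        sample(list(paste(f[1:8], collapse = "\t"),            # 8 columns
                    paste(c(f[1:6], "x", f[8:9]), collapse = "\t"),
                    paste(c(f[1:8], "no-equals-sign"), collapse = "\t")),
               1L)[[1L]]
      },
      gtf = {
        line <- gen_gtf_lines(NULL, asm, 1L)
        sub(';$', "", line)                                    # drop final ;
      },
      wig = "10 1.5",                                          # value, no declaration
      vcf = {
        line <- gen_vcf_lines(NULL, asm, 1L)
        line <- line[length(line)]
        f <- strsplit(line, "\t")[[1L]]
        paste(c(f[1L], "zero", f[3:8]), collapse = "\t")       # bad POS
      },
      sam = {
        line <- gen_sam_lines(NULL, asm, 1L)
        line <- line[length(line)]
        f <- strsplit(line, "\t")[[1L]]
        sample(list(paste(f[1:10], collapse = "\t"),           # 10 fields
                    paste(c(f[1:5], "5M", f[7:9], "ACGT", "*", f[-(1:11)]),
                          collapse = "\t")), 1L)[[1L]]         # CIGAR/SEQ clash
      },
      fastq = c("@r1", "ACGT", "+", "III")                     # length mismatch
    )
  })
}

#' Per-base occupancy oracle for the interval algebra
#'
#' An independent brute-force implementation of merge, intersect, subtract
#' and complement: materialize a boolean occupancy vector per sequence,
#' apply the boolean operation, and read maximal TRUE runs back as
#' intervals.  Ground truth for the tree-based operations on instances
#' small enough to materialize.
#'
#' @param intervals list of `GenomicInterval`.
#' @param op one of `"merge"`, `"intersect"`, `"subtract"`, `"complement"`.
#' @param other second interval list for the binary operations.
#' @param asm a `GenomeAssembly` (bounds the occupancy vectors).
#' @return List of `GenomicInterval`, sorted by (sequence, start).
#' @export
oracle_interval_ops <- function(intervals, op, other = NULL, asm) {
  if (sum(asm$lengths) > 1e6) {
    pg_stop("size_limit_error",
            "assembly too large to materialize (> 1e6 bases)")
  }
  occupancy <- function(ivs) {
    v <- lapply(stats::setNames(asm$lengths, asm$names), function(l) logical(l))
    for (iv in ivs) {
      validate_interval(iv, asm)
      v[[iv$seq_name]][(iv$start + 1):iv$end] <- TRUE
    }
    v
  }
  a <- occupancy(intervals)
  res <- switch(match.arg(op, c("merge", "intersect", "subtract",
                                "complement")),
                merge = a,
                intersect = {
                  b <- occupancy(other)
                  Map(`&`, a, b)
                },
                subtract = {
                  b <- occupancy(other)
                  Map(function(x, y) x & !y, a, b)
                },
                complement = lapply(a, `!`))
  out <- list()
  for (nm in asm$names) {
    r <- rle(res[[nm]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    for (k in which(r$values)) {
      out[[length(out) + 1L]] <- gi(nm, starts[k], ends[k])
    }
  }
  out
}
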
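test_that("CIGAR parsing validates grammar and computes both spans", {
  expect_equal(cigar_reference_span(parse_cigar("8M2I4M")), 12)
  expect_equal(cigar_reference_span(parse_cigar("5S10M3D2M")), 15)
  expect_equal(cigar_reference_span(parse_cigar("10S")), 0)
  expect_equal(cigar_query_span(parse_cigar("8M2I4M")), 14)
  expect_equal(cigar_query_span(parse_cigar("5S10M3D2M")), 17)
  expect_identical(format(parse_cigar("3H2S5M1=2X4N7D2S")), "3H2S5M1=2X4N7D2S")
  expect_error(parse_cigar("5M3H2M"), class = "cigar_error")
  expect_error(parse_cigar("2M3S2M"), class = "cigar_error")
  expect_error(parse_cigar("0M"), class = "cigar_error")
  expect_error(parse_cigar("5MX"), class = "cigar_error")
  # per-op simulation oracle: reference and query spans on random CIGARs
  withr::with_seed(13, {
    consume <- c(M = "rq", I = "q", D = "r", N = "r", S = "q", H = "",
                 P = "", `=` = "rq", X = "rq")
    for (i in 1:100) {
      n <- sample(1:6, 1)
      ops <- sample(c("M", "I", "D", "=", "X"), n, replace = TRUE)
      lens <- sample(1:20, n, replace = TRUE)
      tok <- paste0(lens, ops, collapse = "")
      cig <- parse_cigar(tok)
      expect_equal(cigar_reference_span(cig),
                   sum(lens[grepl("r", consume[ops])]))
      expect_equal(cigar_query_span(cig),
                   sum(lens[grepl("q", consume[ops])]))
    }
  })
})

test_that("SAM records parse with validation and serialize back exactly", {
  line <- "r1\t0\tchr1\t100\t60\t5M\t*\t0\t0\tACGTA\t*"
  r <- parse_sam_record(line)
  expect_equal(c(r$flag, r$pos, r$mapq), c(0, 100, 60))
  expect_identical(r$cigar, "5M")
  expect_identical(format(r), line)
  expect_error(parse_sam_record("r1\t0\tchr1\t100\t60\t5M\t*\t0\t0\tACGT\t*"),
               class = "consistency_error")
  expect_error(parse_sam_record("r1\t0\tchr1\t100\t60\t5M\t*\t0\t0\tACGTA"),
               class = "field_count_error")
  hdr <- sam_header(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000"))
  expect_warning(parse_sam_record("r\t0\tchrUn\t1\t0\t5M\t*\t0\t0\tACGTA\t*",
                                  hdr),
                 class = "unknown_reference_warning")
  tagged <- parse_sam_record(paste0(line, "\tNM:i:3\tRG:Z:grp\tXF:f:1.5"))
  expect_equal(sam_tag(tagged, "NM"), 3)
  expect_identical(sam_tag(tagged, "RG"), "grp")
  expect_equal(sam_tag(tagged, "XF"), 1.5)
  expect_null(sam_tag(tagged, "ZZ"))
})

test_that("mapped records project to reference-span intervals, unmapped to NULL", {
  iv <- as_interval(parse_sam_record("r\t0\tchr1\t100\t60\t5M\t*\t0\t0\t*\t*"))
  expect_equal(c(iv$start, iv$end), c(99, 104))
  expect_null(as_interval(parse_sam_record("r\t4\t*\t0\t0\t*\t*\t0\t0\tAC\t*")))
  clip <- as_interval(parse_sam_record("r\t0\tchr1\t1\t60\t3S7M\t*\t0\t0\t*\t*"))
  expect_equal(c(clip$start, clip$end), c(0, 7))
  # reverse-strand flag carried through as metadata
  rev <- as_interval(parse_sam_record("r\t16\tchr1\t10\t60\t4M\t*\t0\t0\t*\t*"))
  expect_identical(rev$strand, "-")
})

test_that("headers derive a genome assembly from @SQ lines", {
  h <- sam_header(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:100",
                    "@SQ\tSN:chr2\tLN:50", "@PG\tID:p"))
  expect_identical(h$assembly$names, c("chr1", "chr2"))
  expect_equal(unname(h$assembly$lengths), c(100, 50))
  expect_error(sam_header("@SQ\tSN:chr1"), class = "header_error")
  expect_error(sam_header("no-at-sign"), class = "header_error")
})

test_that("generated SAM files round-trip byte-exactly", {
  total <- 0L
  for (seed in 1:8) {
    cfg <- gen_config(seed = seed)
    asm <- gen_assembly(cfg)
    g <- gen_records(cfg, asm, "sam")
    expect_identical(write_sam(g$records), g$lines)
    expect_identical(read_sam(write_sam(g$records)), g$records)
    total <- total + length(g$records$records)
    # every mapped record's interval validates against the @SQ assembly
    for (rec in g$records$records) {
      iv <- as_interval(rec)
      if (!is.null(iv)) expect_silent(validate_interval(iv, asm))
    }
  }
  expect_gt(total, 50)
})
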
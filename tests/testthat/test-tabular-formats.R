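test_that("BED lines parse to records that serialize back exactly", {
  r <- parse_bed_line("chr1\t10\t20")
  expect_equal(c(r$chrom, r$start, r$end), c("chr1", 10, 20))
  expect_identical(format(r), "chr1\t10\t20")
  r6 <- parse_bed_line("chr1\t10\t20\tfeat1\t0\t+")
  expect_identical(bed_name(r6), "feat1")
  expect_equal(bed_score(r6), 0)
  expect_identical(bed_strand(r6), "+")
  expect_identical(format(r6), "chr1\t10\t20\tfeat1\t0\t+")
  expect_error(parse_bed_line("chr1\t20\t10"), class = "coordinate_error")
  expect_error(parse_bed_line("chr1\t10"), class = "malformed_field_error")
  expect_error(parse_bed_line("chr1\t10\t20\tx\t2000"),
               class = "malformed_field_error")
})

test_that("GFF3 lines parse, project to canonical intervals, and re-encode attributes", {
  r <- parse_gff3_record("chr1\t.\tgene\t11\t20\t.\t+\t.\tID=g1")
  expect_equal(c(r$start, r$end), c(11, 20))
  expect_identical(gff3_attr(r, "ID"), "g1")
  iv <- as_interval(r)
  expect_equal(c(iv$start, iv$end), c(10, 20))
  # single-base feature
  iv1 <- as_interval(parse_gff3_record("c\t.\tgene\t1\t1\t.\t.\t.\t."))
  expect_equal(c(iv1$start, iv1$end), c(0, 1))
  expect_error(parse_gff3_record("chr1\t.\tgene\t11\t20\t.\t+\t."),
               class = "column_count_error")
  expect_error(parse_gff3_record("chr1\t.\tgene\t21\t20\t.\t+\t.\t."),
               class = "coordinate_error")
  expect_error(parse_gff3_record("chr1\t.\tgene\t11\t20\t.\t+\t.\tnoequals"),
               class = "attribute_syntax_error")
  # percent-decoding on access, raw retained for writing
  enc <- "chr1\t.\tgene\t1\t2\t.\t+\t.\tNote=a%3Bb%2Cc"
  r2 <- parse_gff3_record(enc)
  expect_identical(gff3_attr(r2, "Note"), "a;b,c")
  expect_identical(format(r2), enc)
  expect_warning(parse_gff3_record("chr1\t.\tCDS\t1\t9\t.\t+\t.\tID=c1"),
                 class = "phase_warning")
})

test_that("GTF attribute grammar is strict and order-preserving", {
  line <- "chr1\thavana\texon\t11\t20\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t1\";"
  r <- parse_gtf_record(line)
  expect_identical(r$attr_keys, c("gene_id", "transcript_id"))
  expect_identical(r$attr_values, c("g1", "t1"))
  expect_identical(gtf_attr(r, "transcript_id"), "t1")
  expect_identical(format(r), line)
  expect_error(parse_gtf_record(sub(";$", "", line)),
               class = "attribute_syntax_error")
})

test_that("WIG sections expand to explicit values in canonical coordinates", {
  fixed <- c("fixedStep chrom=chr1 start=1 step=10 span=5", "1.0", "2.0")
  v <- read_wig(fixed)$values
  expect_equal(length(v), 2)
  expect_equal(c(v[[1]]$chrom, v[[1]]$start, v[[1]]$span, v[[1]]$value),
               c("chr1", 0, 5, 1.0))
  expect_equal(c(v[[2]]$start, v[[2]]$value), c(10, 2.0))
  vv <- read_wig(c("variableStep chrom=chr1", "11 3.5"))$values
  expect_equal(c(vv[[1]]$start, vv[[1]]$span, vv[[1]]$value), c(10, 1, 3.5))
  iv <- as_interval(wig_value("chr1", 10, 5, 1))
  expect_equal(c(iv$start, iv$end), c(10, 15))
  expect_error(read_wig("7 1.5"), class = "declaration_missing_error")
  expect_error(read_wig(c("fixedStep chrom=c start=1 step=2 span=5", "1")),
               class = "malformed_field_error")
})

test_that("round-trips are exact in both directions for generated tabular files", {
  for (fmt in c("bed", "gff3", "gtf", "wig")) {
    total <- 0L
    for (seed in 1:8) {
      cfg <- gen_config(seed = seed)
      asm <- gen_assembly(cfg)
      g <- gen_records(cfg, asm, fmt)
      # write(parse(x)) == x, byte for byte
      expect_identical(write_format(fmt, g$records), g$lines)
      # parse(write(r)) == r
      expect_identical(parse_format(fmt, write_format(fmt, g$records)),
                       g$records)
      total <- total + length(g$records)
    }
    expect_gt(total, 50)
  }
})

test_that("file-level reads preserve comment and track lines verbatim", {
  lines <- c("track name=test", "# a comment", "chr1\t0\t5", "",
             "chr2\t3\t9")
  doc <- read_bed(lines)
  expect_equal(length(doc$records), 2)
  expect_identical(write_bed(doc), lines)
  glines <- c("##gff-version 3", "chr1\t.\tgene\t1\t5\t.\t+\t.\tID=g1",
              "# trailing comment")
  expect_identical(write_gff3(read_gff3(glines)), glines)
})

test_that("every projected interval validates against a covering assembly", {
  cfg <- gen_config(seed = 23)
  asm <- gen_assembly(cfg)
  for (fmt in c("bed", "gff3", "gtf")) {
    recs <- gen_records(cfg, asm, fmt)$records
    for (r in recs) {
      expect_silent(validate_interval(as_interval(r), asm))
    }
  }
  for (v in gen_records(cfg, asm, "wig")$records) {
    expect_silent(validate_interval(as_interval(v), asm))
  }
})
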
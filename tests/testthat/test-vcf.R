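minimal_header <- c("##fileformat=VCFv4.3",
                    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")

test_that("a minimal VCF parses to one record with typed fields", {
  doc <- read_vcf(c(minimal_header, "chr1\t100\trs1\tA\tG\t50\tPASS\t."))
  expect_length(doc$records, 1)
  r <- doc$records[[1]]
  expect_equal(r$pos, 100)
  expect_identical(r$ref, "A")
  expect_identical(vcf_alt(r), "G")
  expect_identical(format(r), "chr1\t100\trs1\tA\tG\t50\tPASS\t.")
  expect_error(read_vcf("chr1\t100\t.\tA\tG\t.\t.\t."),
               class = "missing_header_error")
  expect_error(parse_vcf_record("chr1\t100\t.\tA\tG\t.\t."),
               class = "column_count_error")
  expect_error(parse_vcf_record("chr1\t0\t.\tA\tG\t.\t.\t."),
               class = "malformed_field_error")
})

test_that("header meta lines are structured on demand and preserved verbatim", {
  lines <- c("##fileformat=VCFv4.3",
             "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total, depth\">",
             "##FILTER=<ID=q10,Description=\"Q below 10\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  h <- vcf_header(lines)
  info <- vcf_header_meta(h, "INFO")
  expect_identical(info$ID, "DP")
  expect_identical(info$Type, "Integer")
  # comma inside a quoted Description must not split fields
  expect_identical(info$Description, "\"Total, depth\"")
  expect_identical(format(h), lines)
})

test_that("records with samples validate per-sample column counts", {
  h <- vcf_header(c("##fileformat=VCFv4.3",
                    paste("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                          "FORMAT", "s1", "s2", sep = "\t")))
  expect_identical(h$samples, c("s1", "s2"))
  good <- "chr1\t5\t.\tA\tT\t.\t.\t.\tGT\t0/1\t1/1"
  expect_identical(format(parse_vcf_record(good, h)), good)
  expect_error(parse_vcf_record("chr1\t5\t.\tA\tT\t.\t.\t.\tGT\t0/1", h),
               class = "column_count_error")
})

test_that("variant records project to intervals, honoring END when present", {
  r <- parse_vcf_record("chr1\t100\t.\tA\tG\t.\t.\t.")
  expect_equal(unlist(as_interval(r)[c("start", "end")]), c(start = 99, end = 100))
  del <- parse_vcf_record("chr1\t100\t.\tAT\tA\t.\t.\t.")
  expect_equal(unlist(as_interval(del)[c("start", "end")]), c(start = 99, end = 101))
  ended <- parse_vcf_record("chr1\t100\t.\tA\tG\t.\t.\tEND=150")
  iv <- as_interval(ended)
  expect_equal(c(iv$start, iv$end), c(99, 150))
  # END must agree with the span a per-base reading implies
  expect_equal(interval_length(iv), 150 - 99)
  sym <- parse_vcf_record("chr1\t100\t.\t<DEL>\tA\t.\t.\t.")
  expect_error(as_interval(sym), class = "symbolic_allele_error")
})

test_that("SNV classification is exhaustive, symmetric, and correctly split", {
  bases <- c("A", "C", "G", "T")
  cls <- outer(bases, bases, Vectorize(classify_snv))
  expect_equal(sum(cls == "transition"), 4)
  expect_equal(sum(cls == "transversion"), 8)
  expect_equal(sum(cls == "not_snv"), 4)  # the diagonal
  for (r in bases) for (a in bases) {
    expect_identical(classify_snv(r, a), classify_snv(a, r))
  }
  expect_identical(classify_snv("A", "G"), "transition")
  expect_identical(classify_snv("A", "C"), "transversion")
  expect_identical(classify_snv("A", "AT"), "not_snv")
  expect_identical(classify_snv("<DEL>", "A"), "not_snv")
})

test_that("generated VCF files round-trip byte-exactly", {
  total <- 0L
  for (seed in 1:8) {
    cfg <- gen_config(seed = seed)
    asm <- gen_assembly(cfg)
    g <- gen_records(cfg, asm, "vcf")
    expect_identical(write_vcf(g$records), g$lines)
    reparsed <- read_vcf(write_vcf(g$records))
    expect_identical(reparsed, g$records)
    total <- total + length(g$records$records)
  }
  expect_gt(total, 50)
})

test_that("vcf_apply streams records one at a time", {
  cfg <- gen_config(seed = 9, n_records = c(40L, 60L))
  asm <- gen_assembly(cfg)
  g <- gen_records(cfg, asm, "vcf")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(g$lines, path)
  seen <- 0L
  max_pos <- 0
  n <- vcf_apply(path, function(rec) {
    seen <<- seen + 1L
    max_pos <<- max(max_pos, rec$pos)
  }, chunk = 7L)
  expect_equal(n, length(g$records$records))
  expect_equal(seen, n)
  expect_gt(max_pos, 0)
})
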
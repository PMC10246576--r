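mk_read <- function(rname, pos1, len, flag = 0) {
  parse_sam_record(sprintf("r\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                           flag, rname, pos1, len))
}

test_that("breadth of coverage matches the worked example and per-base oracle", {
  asm <- genome_assembly("chr1", 100)
  tgt <- interval_set(asm, list(gi("chr1", 0, 20)))
  reads <- list(mk_read("chr1", 1, 10), mk_read("chr1", 6, 10))
  cv <- coverage(tgt, reads)
  expect_equal(cv$covered, 15)
  expect_equal(cv$breadth, 0.75)
  # per-base oracle on the same toy
  covered_bases <- sum(seq(0, 19) %in% c(0:9, 5:14))
  expect_equal(cv$covered, covered_bases)
  # no reads
  cv0 <- coverage(tgt, list())
  expect_equal(cv0$covered, 0)
  expect_equal(cv0$breadth, 0)
  # read exactly equal to target
  cv1 <- coverage(tgt, list(mk_read("chr1", 1, 20)))
  expect_equal(cv1$breadth, 1.0)
})

test_that("unmapped, secondary and supplementary reads are excluded by default", {
  asm <- genome_assembly("chr1", 100)
  tgt <- interval_set(asm, list(gi("chr1", 0, 20)))
  reads <- list(mk_read("chr1", 1, 10, flag = 256),
                mk_read("chr1", 1, 10, flag = 2048))
  expect_equal(coverage(tgt, reads)$covered, 0)
  expect_equal(coverage(tgt, reads, include_secondary = TRUE)$covered, 10)
  expect_equal(coverage(tgt, reads, include_secondary = TRUE,
                        include_supplementary = TRUE)$covered, 10)
})

test_that("coverage equals per-base counting and is monotone on random instances", {
  for (seed in 1:25) {
    cfg <- gen_config(seed = seed, n_seq = c(1L, 2L), seq_len = c(200, 5000))
    asm <- gen_assembly(cfg)
    tgt_ivs <- gen_intervals(gen_config(seed = seed + 1000L,
                                        n_intervals = c(1L, 10L)), asm)
    targets <- interval_set(asm, tgt_ivs)
    reads <- withr::with_seed(seed, {
      lapply(seq_len(sample(0:20, 1)), function(i) {
        nm <- sample(asm$names, 1)
        len <- sample(10:100, 1)
        maxp <- asm$lengths[[nm]] - len
        mk_read(nm, sample(seq_len(max(1, maxp)), 1), len)
      })
    })
    cv <- coverage(targets, reads)
    expect_true(all(cv$breadth >= 0 & cv$breadth <= 1))
    # per-base oracle
    occ <- lapply(stats::setNames(asm$lengths, asm$names), function(l) logical(l))
    for (r in reads) {
      iv <- as_interval(r)
      occ[[iv$seq_name]][(iv$start + 1):iv$end] <- TRUE
    }
    merged <- as.data.frame(iset_merge(targets))
    for (i in seq_len(nrow(merged))) {
      expect_equal(cv$covered[i],
                   sum(occ[[merged$seq_name[i]]][(merged$start[i] + 1):merged$end[i]]))
    }
    # monotone under read addition
    if (length(reads) > 1) {
      cv_half <- coverage(targets, reads[seq_len(length(reads) %/% 2)])
      expect_true(all(cv$covered >= cv_half$covered))
      expect_equal(attr(cv, "total")$covered, sum(cv$covered))
    }
  }
})

mk_var <- function(pos, ref, alt, chrom = "chr1") {
  parse_vcf_record(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", chrom, pos, ref, alt))
}

test_that("the worked substitution set yields Ti/Tv = 2.0", {
  asm <- genome_assembly("chr1", 100)
  strata <- list(all = interval_set(asm, list(gi("chr1", 0, 100))))
  vars <- mapply(mk_var, 1:6, c("A", "C", "G", "T", "A", "G"),
                 c("G", "T", "A", "C", "C", "T"), SIMPLIFY = FALSE)
  tt <- titv_summary(vars, strata)
  expect_equal(tt$transitions, 4)
  expect_equal(tt$transversions, 2)
  expect_equal(tt$ratio, 2.0)
})

test_that("variants outside all regions and zero-transversion strata are handled", {
  asm <- genome_assembly("chr1", 1000)
  strata <- list(left = interval_set(asm, list(gi("chr1", 0, 100))),
                 right = interval_set(asm, list(gi("chr1", 500, 600))))
  vars <- list(mk_var(50, "A", "G"),    # transition in left
               mk_var(300, "A", "C"),   # outside all strata
               mk_var(550, "C", "T"))   # transition in right
  tt <- titv_summary(vars, strata)
  expect_equal(tt$transitions, c(1, 1))
  expect_equal(tt$transversions, c(0, 0))
  expect_true(all(is.na(tt$ratio)))     # undefined, not infinite
})

test_that("multi-allelic records count once per alternate allele", {
  asm <- genome_assembly("chr1", 100)
  strata <- list(all = interval_set(asm, list(gi("chr1", 0, 100))))
  tt <- titv_summary(list(mk_var(10, "A", "G,C"), mk_var(20, "A", "AT,G")),
                     strata)
  expect_equal(tt$transitions, 2)   # A>G twice; A>AT ignored
  expect_equal(tt$transversions, 1) # A>C
})

test_that("Ti/Tv counts are permutation-invariant and add over disjoint strata", {
  cfg <- gen_config(seed = 77, n_records = c(40L, 60L))
  asm <- gen_assembly(cfg)
  vars <- gen_records(cfg, asm, "vcf")$records$records
  half <- lapply(asm$names, function(nm) {
    l <- asm$lengths[[nm]]
    list(gi(nm, 0, floor(l / 2)), gi(nm, floor(l / 2), l))
  })
  lo <- interval_set(asm, lapply(half, `[[`, 1))
  hi <- interval_set(asm, lapply(half, `[[`, 2))
  full <- interval_set(asm, lapply(asm$names,
                                   function(nm) gi(nm, 0, asm$lengths[[nm]])))
  strata <- list(lo = lo, hi = hi, all = full)
  tt <- titv_summary(vars, strata)
  tt_perm <- titv_summary(rev(vars), strata)
  expect_equal(tt, tt_perm)
  # disjoint exhaustive strata sum to the unstratified counts; variants
  # straddling the midpoint are counted in both halves, so restrict to
  # single-base events (every SNV lies wholly in one half)
  expect_equal(tt$transitions[tt$stratum == "lo"] +
                 tt$transitions[tt$stratum == "hi"],
               tt$transitions[tt$stratum == "all"])
  expect_equal(tt$transversions[tt$stratum == "lo"] +
                 tt$transversions[tt$stratum == "hi"],
               tt$transversions[tt$stratum == "all"])
})

test_that("summaries serialize as tab-separated tables with a header", {
  asm <- genome_assembly("chr1", 100)
  strata <- list(all = interval_set(asm, list(gi("chr1", 0, 100))))
  lines <- write_summary(titv_summary(list(mk_var(1, "A", "G")), strata))
  expect_identical(lines[1], "stratum\ttransitions\ttransversions\tratio")
  expect_identical(lines[2], "all\t1\t0\tNA")
})
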
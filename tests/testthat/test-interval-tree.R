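gint <- asNamespace("gintervals")

test_that("a single insert yields a black root and inserts are persistent", {
  asm <- genome_assembly("chr1", 100)
  s0 <- interval_set(asm)
  s1 <- iset_insert(s0, gi("chr1", 0, 10))
  expect_identical(s1$trees[["chr1"]]$color, "B")
  expect_equal(iset_size(s1), 1)
  # the pre-insert set is observably unchanged
  expect_equal(iset_size(s0), 0)
  expect_null(s0$trees[["chr1"]])
})

test_that("duplicate intervals are retained with multiset semantics", {
  asm <- genome_assembly("chr1", 100)
  s <- interval_set(asm, rep(list(gi("chr1", 0, 10)), 3L))
  expect_equal(iset_size(s), 3)
  expect_equal(length(iset_intervals(s)), 3)
  # merge collapses them to one covering interval
  expect_equal(nrow(as.data.frame(iset_merge(s))), 1)
})

test_that("red-black invariants hold after randomized insertion", {
  withr::with_seed(97, {
    root <- NULL
    for (i in 1:2000) {
      st <- sample(0:9998, 1)
      root <- gint$rb_insert(root, gi("chr1", st, st + sample(1:(9999 - st), 1)))
    }
    audit <- gint$rb_audit(root)
    expect_equal(audit$size, 2000)
    expect_equal(audit$red_red_violations, 0)
    expect_true(audit$black_height_uniform)
    expect_equal(audit$max_end_violations, 0)
    expect_equal(audit$order_violations, 0)
    expect_true(audit$root_black)
    expect_true(audit$height_bound_ok)
  })
})

test_that("in-order traversal is sorted by (start, end) and stable", {
  withr::with_seed(5, {
    ivs <- lapply(1:500, function(i) {
      st <- sample(0:99, 1)
      gi("chr1", st, st + sample(1:10, 1))
    })
    asm <- genome_assembly("chr1", 200)
    s <- interval_set(asm, ivs)
    got <- ivs_df(iset_intervals(s))
    want <- ivs_df(ivs)
    want <- want[order(want$start, want$end), ]
    rownames(want) <- NULL
    expect_equal(got, want)
  })
})

test_that("overlap search equals a linear scan and respects half-open bounds", {
  asm <- genome_assembly(c("chr1", "chr2"), c(10000, 10000))
  # worked examples
  s <- interval_set(asm, list(gi("chr1", 0, 10), gi("chr1", 20, 30)))
  expect_equal(ivs_df(iset_search(s, gi("chr1", 5, 25))),
               data.frame(seq_name = "chr1", start = c(0, 20), end = c(10, 30),
                          stringsAsFactors = FALSE))
  expect_length(iset_search(s, gi("chr2", 1, 100)), 0)
  expect_length(iset_search(interval_set(asm, list(gi("chr1", 0, 10))),
                            gi("chr1", 10, 20)), 0)
  # property: equal to the brute-force linear scan
  withr::with_seed(31, {
    for (rep in 1:20) {
      ivs <- lapply(seq_len(sample(50:150, 1)), function(i) {
        st <- sample(0:9000, 1)
        gi("chr1", st, st + sample(1:500, 1))
      })
      set <- interval_set(asm, ivs)
      qs <- sample(0:9000, 1)
      q <- gi("chr1", qs, qs + sample(1:800, 1))
      scan <- Filter(function(iv) intervals_overlap(iv, q), ivs)
      scan_df <- ivs_df(scan)
      scan_df <- scan_df[order(scan_df$start, scan_df$end), ]
      rownames(scan_df) <- NULL
      expect_equal(ivs_df(iset_search(set, q)), scan_df)
    }
  })
})

test_that("set operations leave their inputs untouched (persistence)", {
  withr::with_seed(77, {
    inst <- random_instance(1, max_intervals = 40, max_len = 2000)
    a <- interval_set(inst$asm, inst$a)
    b <- interval_set(inst$asm, inst$b)
    snap_a <- as.data.frame(a)
    snap_b <- as.data.frame(b)
    invisible(iset_merge(a))
    invisible(iset_intersect(a, b))
    invisible(iset_subtract(a, b))
    invisible(iset_complement(a))
    invisible(iset_insert(a, gi(inst$asm$names[1L], 0, 1)))
    invisible(iset_search(a, gi(inst$asm$names[1L], 0,
                                inst$asm$lengths[[1L]])))
    expect_identical(as.data.frame(a), snap_a)
    expect_identical(as.data.frame(b), snap_b)
  })
})

test_that("operations on sets bound to different assemblies are rejected", {
  a <- interval_set(genome_assembly("chr1", 100), list(gi("chr1", 0, 10)))
  b <- interval_set(genome_assembly("chr1", 200), list(gi("chr1", 0, 10)))
  expect_error(iset_intersect(a, b), class = "assembly_mismatch_error")
  expect_error(iset_subtract(a, b), class = "assembly_mismatch_error")
})
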
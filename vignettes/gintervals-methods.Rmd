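---
title: "gintervals: design and validation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gintervals: design and validation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gintervals)
```

This vignette is the package's own account of its model, the design
choices that were genuinely open, and what its property-based test suite
does and does not demonstrate.

## The interval model

A genomic interval differs from a general numeric interval in two ways
that the whole package exploits: it is anchored to a named assembled
sequence (chromosome, scaffold or contig), and its coordinates are
non-negative integers bounded by that sequence's length. The
`GenomeAssembly` object carries the ordered name/length list and is the
universe against which every interval validates; the order of sequences
defines the sort order of all multi-sequence output.

Internal coordinates are uniformly 0-based and half-open, `[start, end)`.
Formats that use 1-based inclusive coordinates (GFF3, GTF, WIG, VCF, SAM)
are converted at the I/O boundary and nowhere else, which confines the
off-by-one error class to a handful of `±1` expressions in the readers
and writers. Two further model decisions:

* **Empty intervals are unrepresentable** (`start < end` strictly).
  Set operations therefore never have to distinguish "empty interval"
  from "no interval"; an empty result is an empty collection.
* **Strand is metadata.** `merge`, `intersect`, `subtract`, `complement`
  and overlap search ignore strand. Strand-aware algebra can be layered
  on top by partitioning inputs before calling the operations; building
  it in would have imposed a semantics the interval model itself does
  not need.

## The persistent red-black engine

Interval sets are per-sequence red-black trees ordered by `(start, end)`,
with each node augmented by the maximum interval end in its subtree
(`max_end`). Insertion uses the functional four-case rebalancing scheme:
rather than rotating in place, each insert rebuilds the O(log n) path
from root to insertion point and rewires the four red/black
configurations that can violate the invariants. The payoff is
persistence for free — the new tree shares every untouched subtree with
the old one, so any previously held reference remains valid and
operations are pure by construction. Deletion is deliberately absent;
sets are rebuilt, which is the honest operation under immutability.

Duplicates are retained on insert (multiset semantics, routed to the
right subtree so traversal stays stable); parsers may legitimately read
duplicate records, and dropping them silently would break the round-trip
law below. `iset_merge()` is the operation that collapses them.

`merge` coalesces abutting intervals (`end == next start`) as well as
overlapping ones. This follows from defining all four set operations on
*covered base sets*: two abutting intervals cover a contiguous run of
bases, and the minimal disjoint representation of that run is a single
interval. The binary operations (`intersect`, `subtract`) and
`complement` are linear sweeps over the merged per-sequence runs;
`complement` emits gaps for every assembly sequence, including ones with
no stored intervals.

Overlap search prunes with the `max_end` augmentation: a subtree whose
`max_end` is at or below the query start cannot contain an overlap, and
a node whose start is at or past the query end rules out its right
subtree.

## The round-trip law and the format codecs

The seed property of the validation framework is that the function
converting a record to a string is the inverse of the function parsing
the record from a string, and vice versa. All eight text codecs are
written against it, which forces a specific storage design: records keep
the *lexical* form of every token they do not need to interpret (BED
optional columns, GFF3 attribute strings, VCF column tokens, SAM tag
fields), and typed views are computed on access. Three cases are lossy
by documented design rather than byte-exact:

* **FASTA line wrapping** is not recorded; writing at the source wrap
  width reproduces the file exactly, and the sequence content always
  round-trips.
* **FASTQ `+line` repeated identifiers** are dropped on read.
* **SAM/BAM canonicalization**: BAM's six integer tag types all surface
  as SAM type `i` (SAM text has no narrower integer types), and RNEXT
  `"="` is expanded to the reference name on BAM decoding. Record
  equality for the round-trip suites (`sam_records_equal`) is defined
  modulo exactly these two rewrites plus numeric comparison of `f`-typed
  tags, whose float32 values have no single canonical decimal form.

WIG is read by expanding `fixedStep`/`variableStep` sections into
explicit `(chrom, start, span, value)` tuples; writing emits canonical
`variableStep` sections, so the byte-exact direction of the law holds
for files already in that canonical layout, and the record-level
direction holds for all inputs.

GFF3 percent-encoding is handled by decoding only the reserved set
(tab, newline, `%`, `;`, `=`, `&`, `,`) on *access* while the raw
attribute string remains authoritative for writing: decode and re-encode
are mutual inverses on that set, and separator commas (multi-valued
attributes) are never confused with encoded ones. GTF attribute parsing
is strict — a line whose attribute column is not byte-identical to its
canonical `key "value";` re-serialization is rejected — because a strict
grammar is what makes the round-trip law testable; a lenient reader flag
can be added without disturbing the law.

## BGZF and BAM

BGZF is blocked gzip: a series of independently decompressible gzip
members of at most 64 KiB uncompressed payload, each carrying its
compressed size in a `BC` extra subfield, terminated by a canonical
28-byte empty block. The codec here is written from the container
specification on top of a three-function zlib shim (CRC-32, raw deflate,
raw inflate); R's own `memCompress()` exposes only zlib-wrapped streams
with Adler-32 checksums, which is not what the container requires.
Choices:

* Write-side chunk size is 65,280 uncompressed bytes — the conventional
  maximum leaving room for the fixed 26 bytes of framing within 2^16.
  Any block size up to 65,536 is accepted on read.
* Deflate level is the zlib default; output equality is defined at the
  decompressed level, so the compression level is semantically inert.
* CRC-32 and ISIZE of every block are validated on read by default
  (`check_crc = FALSE` opts out); a missing EOF block is a warning by
  default and configurable to error or ignore, since truncated-but-valid
  prefixes are common in practice.
* A virtual offset is `compressed_block_offset * 2^16 + within_block
  offset`, carried as an R double (exact far beyond any real file size);
  `vo_resolve()` maps it to an absolute uncompressed position via the
  block index the decompressor returns.

The BAM codec implements the binary record layout directly (packed
CIGAR, 4-bit sequence nibbles over `=ACMGRSVTWYHKDBN`, typed tags) and
defines success as decoding to the *same record objects* the SAM text
parser produces, modulo the canonicalizations above. The `bin` field is
recomputed on write with the standard region-to-bin function and ignored
on read, as nothing in this package consumes indices.

## Analysis operations

`coverage()` computes breadth only (fraction of target bases covered by
at least one read), entirely with the interval algebra: reads project to
reference spans through their CIGARs (`M`, `D`, `N`, `=`, `X` consume
reference; soft clips do not), the spans are merged, and per-target
covered bases come from intersecting merged targets with merged reads.
Reads flagged unmapped (0x4), secondary (0x100) or supplementary (0x800)
are excluded by default with explicit arguments to include them — the
common convention, stated rather than assumed.

`titv_summary()` classifies each `(REF, ALT)` pair — one classification
per alternate allele of multi-allelic records, which changes counts and
is therefore stated here — and attributes it to every stratum whose
region set overlaps the variant's interval under half-open semantics.
Strata are caller-supplied labelled region sets; how "populations" map
onto VCF content (sample subsets, separate files) is left to the caller
rather than guessed. A stratum with zero transversions reports an
undefined (NA) ratio, never infinity. VCF records with an `END` INFO key
take their interval end from it; symbolic REF alleles are an error at
projection time.

## The synthetic-data generators and what the tests show

All fixtures are generated, never stored. `gen_config(seed, ...)`
defaults describe the standing study conditions: assemblies of 1-3
sequences of 1,000-10,000 bp (small enough for the per-base oracle to
materialize, large enough for non-trivial tree shapes), 5-30 records per
generated file, interval counts up to 100, CIGAR strings built so the
query span equals the sequence length by construction, FASTQ qualities
drawn from the Phred+33 range. Every generator draws from an explicitly
seeded RNG whose state is restored afterwards, so the full corpus
regenerates byte-identically from `(config, seed)` and no test perturbs
another's randomness.

The independent oracle, `oracle_interval_ops()`, computes merge,
intersect, subtract and complement on an explicit boolean occupancy
vector per sequence and reads maximal runs back off it. It shares no
code with the tree path and is deliberately brute-force; a size guard
(10^6 bases) keeps it honest about when it may be used.

What the passing suite demonstrates: the algebra agrees base-for-base
with an independent implementation on 1,000 random instances; the
red-black and augmentation invariants hold after 10^4 randomized
insertions with tree height within the 2·log2(n+1) bound; operations
never disturb prior versions; serialization and parsing are mutual
inverses on 500+ generated records per format; the BGZF/BAM codec
round-trips and interoperates with generic gzip and (in the test suite)
with an independent BAM reader; and the analysis operations match
per-base counting and their combinatorial ground truths (4/8 of the 12
substitutions; Ti/Tv = 2.0 on the worked set; breadth 0.75 on the
coverage toy).

What it does not demonstrate: behavior on biologically realistic data.
The generators exercise the formats' structural properties, not mutation
spectra, read-error profiles, coverage biases or real annotation
hierarchies (GFF3 Parent/ID graphs are out of scope, as are bigWig/
bigBed, CRAM, tabix/BAI indices and liftover). Numeric behavior on
coordinates beyond 2^31 is supported by carrying positions as doubles,
but the generators do not reach such coordinates.

## Problem sizes and numerical choices

The full-scale validation runs use 1,000 algebra instances (≤ 100
intervals on sequences ≤ 10^4 bp), 10^4 tree insertions, 100 persistence
sequences, ≥ 500 records per format, 100 generated BAM files, and 100
BGZF payloads of up to 1 MiB — sizes chosen so the whole suite completes
in about a minute on a single core while keeping every instance large
enough to exercise rebalancing, multi-block compression and multi-file
variation. Coordinates and sizes are doubles throughout (exact to 2^53);
equality comparisons are exact except for `f`-typed SAM tags (float32,
compared at 10^-6 relative tolerance).
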
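#' Breadth of coverage of target intervals by aligned reads
#'
#' For every merged target interval, counts the bases covered by at least
#' one mapped read (reads are projected to their reference spans via
#' `as_interval()`), entirely with interval algebra — no per-base
#' materialization.  Reads flagged unmapped (0x4), secondary (0x100) or
#' supplementary (0x800) are excluded by default.
#'
#' @param targets an `IntervalSet` of target regions.
#' @param reads list of `SamRecord` (e.g. from [read_sam()] or
#'   [read_bam()]).
#' @param include_secondary,include_supplementary include reads with the
#'   corresponding flag bits.
#' @return A `CoverageSummary`: data.frame with one row per merged target
#'   interval (`seq_name`, `start`, `end`, `length`, `covered`, `breadth`)
#'   and a `total` attribute with the set-wide sums.
#' @examples
#' asm <- genome_assembly("chr1", 100)
#' tgt <- interval_set(asm, list(gi("chr1", 0, 20)))
#' reads <- list(parse_sam_record(
#'   "r1\t0\tchr1\t1\t60\t10M\t*\t0\t0\t*\t*"))
#' coverage(tgt, reads)
#' @export
coverage <- function(targets, reads, include_secondary = FALSE,
                     include_supplementary = FALSE) {
  drop_bits <- 4L + (if (include_secondary) 0L else 256L) +
    (if (include_supplementary) 0L else 2048L)
  read_ivs <- list()
  for (rec in reads) {
    if (bitwAnd(as.integer(rec$flag), drop_bits) != 0L) next
    iv <- as_interval(rec)
    if (!is.null(iv)) read_ivs[[length(read_ivs) + 1L]] <- iv
  }
  asm <- targets$assembly
  reads_set <- iset_merge(interval_set(asm, read_ivs))
  merged <- iset_merge(targets)
  hit <- iset_intersect(merged, reads_set)
  hit_df <- as.data.frame(hit)
  tgt <- as.data.frame(merged)
  covered <- numeric(nrow(tgt))
  for (i in seq_len(nrow(tgt))) {
    sel <- hit_df$seq_name == tgt$seq_name[i] &
      hit_df$start >= tgt$start[i] & hit_df$end <= tgt$end[i]
    covered[i] <- sum(hit_df$end[sel] - hit_df$start[sel])
  }
  out <- data.frame(seq_name = tgt$seq_name, start = tgt$start,
                    end = tgt$end, length = tgt$end - tgt$start,
                    covered = covered, stringsAsFactors = FALSE)
  out$breadth <- out$covered / out$length
  attr(out, "total") <- list(length = sum(out$length),
                             covered = sum(out$covered),
                             breadth = if (sum(out$length) > 0) {
                               sum(out$covered) / sum(out$length)
                             } else {
                               NA_real_
                             })
  class(out) <- c("CoverageSummary", "data.frame")
  out
}

#' @export
print.CoverageSummary <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  tot <- attr(x, "total")
  cat(sprintf("total: %s of %s bases covered (breadth %.4f)\n",
              fmt_int(tot$covered), fmt_int(tot$length), tot$breadth))
  invisible(x)
}

#' Transition/transversion summary stratified by region sets
#'
#' Classifies every (REF, ALT) pair of every variant (one classification
#' per alternate allele of multi-allelic records) and attributes it to
#' every stratum whose region set overlaps the variant's interval under
#' half-open semantics.  Pairs that are not single-base substitutions are
#' ignored.  The Ti/Tv ratio is NA (undefined) where a stratum has no
#' transversions.
#'
#' @param variants list of `VcfRecord`.
#' @param strata named list of `IntervalSet` region sets, one per stratum
#'   (e.g. population x genome-region labels).
#' @return A `TiTvSummary` data.frame with columns `stratum`,
#'   `transitions`, `transversions`, `ratio`.
#' @export
titv_summary <- function(variants, strata) {
  if (is.null(names(strata)) || any(!nzchar(names(strata)))) {
    pg_stop("strata_error", "strata must be a named list of IntervalSet")
  }
  ti <- stats::setNames(numeric(length(strata)), names(strata))
  tv <- ti
  for (rec in variants) {
    classes <- vapply(vcf_alt(rec), function(a) classify_snv(rec$ref, a), "")
    classes <- classes[classes != "not_snv"]
    if (length(classes) == 0L) next
    iv <- tryCatch(as_interval(rec), error = function(e) NULL)
    if (is.null(iv)) next
    for (nm in names(strata)) {
      set <- strata[[nm]]
      if (!iv$seq_name %in% set$assembly$names) next
      if (iv$end > set$assembly$lengths[[iv$seq_name]]) next
      if (length(iset_search(set, iv)) == 0L) next
      ti[nm] <- ti[nm] + sum(classes == "transition")
      tv[nm] <- tv[nm] + sum(classes == "transversion")
    }
  }
  out <- data.frame(stratum = names(strata), transitions = unname(ti),
                    transversions = unname(tv),
                    ratio = ifelse(unname(tv) > 0, unname(ti) / unname(tv),
                                   NA_real_),
                    stringsAsFactors = FALSE)
  class(out) <- c("TiTvSummary", "data.frame")
  out
}

#' @export
print.TiTvSummary <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Serialize a summary as a tab-separated table
#'
#' @param x a `CoverageSummary` or `TiTvSummary`.
#' @param path output path, connection, or NULL to return the lines.
#' @export
write_summary <- function(x, path = NULL) {
  df <- as.data.frame(x)
  cols <- vapply(df, function(col) {
    if (is.numeric(col)) {
      ifelse(is.na(col), "NA",
             ifelse(col == floor(col), fmt_int(col), format(col, digits = 6)))
    } else {
      as.character(col)
    }
  }, character(nrow(df)))
  if (nrow(df) == 1L) cols <- matrix(cols, nrow = 1L)
  lines <- c(paste(names(df), collapse = "\t"),
             apply(cols, 1L, paste, collapse = "\t"))
  write_lines_any(lines, path)
}
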
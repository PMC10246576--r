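#' Immutable sets of genomic intervals
#'
#' An `IntervalSet` holds, for every sequence of a genome assembly, a
#' persistent red-black interval tree of the stored intervals.  All
#' operations are pure: they return new sets and leave their arguments
#' observably unchanged.  Duplicate intervals are retained on insert
#' (multiset semantics); `iset_merge()` collapses them.
#'
#' @param asm a `GenomeAssembly` bounding all stored intervals.
#' @param intervals optional list of `GenomicInterval` to insert.
#' @return An object of class `IntervalSet`.
#' @examples
#' asm <- genome_assembly("chr1", 100)
#' s <- interval_set(asm, list(gi("chr1", 0, 10), gi("chr1", 20, 30)))
#' iset_size(s)
#' @export
interval_set <- function(asm, intervals = list()) {
  stopifnot(inherits(asm, "GenomeAssembly"))
  set <- structure(list(assembly = asm,
                        trees = stats::setNames(
                          vector("list", length(asm$names)), asm$names),
                        counts = stats::setNames(
                          integer(length(asm$names)), asm$names)),
                   class = "IntervalSet")
  for (iv in intervals) set <- iset_insert(set, iv)
  set
}

#' Insert an interval, returning a new set
#'
#' The input set is not modified; the result shares all untouched subtrees
#' with it.  The interval is validated against the set's assembly first.
#'
#' @param set an `IntervalSet`.
#' @param iv a `GenomicInterval`.
#' @return A new `IntervalSet` containing all prior intervals plus `iv`.
#' @export
iset_insert <- function(set, iv) {
  validate_interval(iv, set$assembly)
  nm <- iv$seq_name
  set$trees[[nm]] <- rb_insert(set$trees[[nm]], iv)
  set$counts[[nm]] <- set$counts[[nm]] + 1L
  set
}

#' @rdname interval_set
#' @param set an `IntervalSet`.
#' @export
iset_size <- function(set) sum(set$counts)

#' All stored intervals, sorted
#'
#' @param set an `IntervalSet`.
#' @param seq_name optional single sequence name to restrict to.
#' @return A list of `GenomicInterval` sorted by (assembly sequence order,
#'   start, end); duplicates appear as many times as stored.
#' @export
iset_intervals <- function(set, seq_name = NULL) {
  nms <- if (is.null(seq_name)) set$assembly$names else seq_name
  out <- list()
  for (nm in nms) {
    n <- set$counts[[nm]]
    if (n > 0L) out <- c(out, rb_inorder(set$trees[[nm]], n))
  }
  out
}

#' @export
print.IntervalSet <- function(x, ...) {
  cat(sprintf("IntervalSet: %d interval(s) on %d sequence(s)\n",
              iset_size(x), sum(x$counts > 0L)))
  invisible(x)
}

#' @export
as.data.frame.IntervalSet <- function(x, ...) {
  intervals_to_df(iset_intervals(x), x$assembly)
}

#' Search for stored intervals overlapping a query
#'
#' Uses the tree's max-end augmentation to prune subtrees that cannot
#' contain an overlap; equivalent to (but faster than) a linear scan.
#'
#' @param set an `IntervalSet`.
#' @param query a `GenomicInterval` (validated against the set's assembly).
#' @return List of overlapping stored intervals, sorted by (start, end).
#' @export
iset_search <- function(set, query) {
  validate_interval(query, set$assembly)
  root <- set$trees[[query$seq_name]]
  if (is.null(root)) return(list())
  rb_search_overlap(root, query$start, query$end)
}

# Merged, disjoint (start, end) matrix for one sequence; 0x2 matrix if none.
# Coalesces overlapping AND abutting intervals (end == next start), so the
# result is the minimal disjoint cover of the stored bases.
merge_runs <- function(set, nm) {
  n <- set$counts[[nm]]
  if (n == 0L) return(matrix(numeric(0), ncol = 2L))
  ivs <- rb_inorder(set$trees[[nm]], n)
  starts <- vapply(ivs, `[[`, 0, "start")
  ends <- vapply(ivs, `[[`, 0, "end")
  out_s <- numeric(n)
  out_e <- numeric(n)
  k <- 1L
  out_s[1L] <- starts[1L]
  out_e[1L] <- ends[1L]
  if (n > 1L) {
    for (i in 2L:n) {
      if (starts[i] <= out_e[k]) {
        if (ends[i] > out_e[k]) out_e[k] <- ends[i]
      } else {
        k <- k + 1L
        out_s[k] <- starts[i]
        out_e[k] <- ends[i]
      }
    }
  }
  cbind(out_s[seq_len(k)], out_e[seq_len(k)])
}

# Build an IntervalSet from per-sequence run matrices (already disjoint &
# sorted), skipping validation for speed.
set_from_runs <- function(asm, runs) {
  set <- interval_set(asm)
  for (nm in asm$names) {
    m <- runs[[nm]]
    if (is.null(m) || nrow(m) == 0L) next
    root <- NULL
    for (i in seq_len(nrow(m))) {
      root <- rb_insert(root, gi(nm, m[i, 1L], m[i, 2L]))
    }
    set$trees[[nm]] <- root
    set$counts[[nm]] <- nrow(m)
  }
  set
}

#' Interval-set algebra: merge, intersect, subtract, complement
#'
#' The four operations are defined on covered base sets.  `iset_merge()`
#' replaces the stored intervals with the maximal runs of
#' overlapping-or-abutting intervals; the result is disjoint, non-abutting,
#' and covers exactly the same bases.  `iset_intersect()` and
#' `iset_subtract()` operate on the merged covered-base sets of their
#' arguments; `iset_complement()` covers, for every assembly sequence
#' (including ones with no stored intervals), exactly the bases not covered
#' by the set.  Strand is ignored throughout.
#'
#' @param set,a,b `IntervalSet` objects; `a` and `b` must share an assembly.
#' @return A new merged `IntervalSet`; inputs are unchanged.
#' @examples
#' asm <- genome_assembly("chr1", 100)
#' a <- interval_set(asm, list(gi("chr1", 1, 5), gi("chr1", 4, 8)))
#' as.data.frame(iset_merge(a))
#' @export
iset_merge <- function(set) {
  runs <- lapply(stats::setNames(set$assembly$names, set$assembly$names),
                 function(nm) merge_runs(set, nm))
  set_from_runs(set$assembly, runs)
}

check_same_assembly <- function(a, b) {
  if (!identical(a$assembly, b$assembly)) {
    pg_stop("assembly_mismatch_error",
            "interval sets are bound to different assemblies")
  }
}

#' @rdname iset_merge
#' @export
iset_intersect <- function(a, b) {
  check_same_assembly(a, b)
  asm <- a$assembly
  runs <- list()
  for (nm in asm$names) {
    ma <- merge_runs(a, nm)
    mb <- merge_runs(b, nm)
    out <- matrix(numeric(0), ncol = 2L)
    if (nrow(ma) > 0L && nrow(mb) > 0L) {
      acc_s <- numeric(0)
      acc_e <- numeric(0)
      i <- 1L
      j <- 1L
      while (i <= nrow(ma) && j <= nrow(mb)) {
        s <- max(ma[i, 1L], mb[j, 1L])
        e <- min(ma[i, 2L], mb[j, 2L])
        if (s < e) {
          acc_s <- c(acc_s, s)
          acc_e <- c(acc_e, e)
        }
        if (ma[i, 2L] <= mb[j, 2L]) i <- i + 1L else j <- j + 1L
      }
      out <- cbind(acc_s, acc_e)
    }
    runs[[nm]] <- out
  }
  set_from_runs(asm, runs)
}

#' @rdname iset_merge
#' @export
iset_subtract <- function(a, b) {
  check_same_assembly(a, b)
  asm <- a$assembly
  runs <- list()
  for (nm in asm$names) {
    ma <- merge_runs(a, nm)
    mb <- merge_runs(b, nm)
    if (nrow(ma) == 0L) {
      runs[[nm]] <- ma
      next
    }
    acc_s <- numeric(0)
    acc_e <- numeric(0)
    j <- 1L
    for (i in seq_len(nrow(ma))) {
      cur <- ma[i, 1L]
      e <- ma[i, 2L]
      while (j <= nrow(mb) && mb[j, 2L] <= cur) j <- j + 1L
      jj <- j
      while (jj <= nrow(mb) && mb[jj, 1L] < e) {
        if (mb[jj, 1L] > cur) {
          acc_s <- c(acc_s, cur)
          acc_e <- c(acc_e, mb[jj, 1L])
        }
        cur <- max(cur, mb[jj, 2L])
        jj <- jj + 1L
      }
      if (cur < e) {
        acc_s <- c(acc_s, cur)
        acc_e <- c(acc_e, e)
      }
    }
    runs[[nm]] <- cbind(acc_s, acc_e)
  }
  set_from_runs(asm, runs)
}

#' @rdname iset_merge
#' @export
iset_complement <- function(set) {
  asm <- set$assembly
  runs <- list()
  for (nm in asm$names) {
    m <- merge_runs(set, nm)
    len <- asm$lengths[[nm]]
    bounds <- c(0, t(m), len)
    s <- bounds[seq(1L, length(bounds), by = 2L)]
    e <- bounds[seq(2L, length(bounds), by = 2L)]
    keep <- s < e
    runs[[nm]] <- cbind(s[keep], e[keep])
  }
  set_from_runs(asm, runs)
}
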
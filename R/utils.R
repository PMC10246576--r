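#' @useDynLib gintervals, .registration = TRUE
#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generator determinism rests on this; no global randomness elsewhere.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Integer-valued doubles formatted without scientific notation; genomic
# coordinates may exceed .Machine$integer.max so doubles are used throughout.
fmt_int <- function(x) sprintf("%.0f", x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

pg_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "gintervals_error")))
}

pg_warn <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c(class, "gintervals_warning")))
}

# Read all lines from a path (plain or gzip; `file()` sniffs the magic),
# an open connection, or a character vector passed through as-is.
read_lines_any <- function(x) {
  if (is.character(x) && length(x) == 1L && !grepl("[\n\t]", x) &&
      file.exists(x)) {
    con <- file(x, "rt")
    on.exit(close(con))
    return(readLines(con, warn = FALSE))
  }
  if (inherits(x, "connection")) {
    return(readLines(x, warn = FALSE))
  }
  as.character(x)
}

# Write lines to a path, an open connection, or return them invisibly when
# `path` is NULL (the in-memory form used by the round-trip suites).
write_lines_any <- function(lines, path) {
  if (is.null(path)) {
    return(lines)
  }
  if (inherits(path, "connection")) {
    writeLines(lines, path, sep = "\n")
  } else {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
  }
  invisible(lines)
}
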
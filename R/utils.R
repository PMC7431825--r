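# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_probability <- function(x, name, allow_one = TRUE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || !hi_ok) {
    stopf("`%s` must be a probability in [0, %s], got %s",
          name, if (allow_one) "1" else "1)", format(x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stopf("`%s` must be an integer >= %d", name, min)
  }
  invisible(as.integer(x))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Write a CSV table with a provenance header
#'
#' Writes `#`-prefixed comment lines (package version, timestamp-free
#' provenance fields such as the seed and configuration hash) followed by a
#' regular CSV body, so that reruns with the same inputs produce
#' byte-identical files.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @param provenance Named list of provenance fields written as `# key: value`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_table_with_provenance <- function(x, path, provenance = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# package: rdnaclock %s",
                     as.character(utils::packageVersion("rdnaclock"))), con)
  for (nm in names(provenance)) {
    writeLines(sprintf("# %s: %s", nm, format(provenance[[nm]])), con)
  }
  write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV table written by [write_table_with_provenance()]
#'
#' @param path File path.
#' @return A data frame (provenance comment lines are skipped).
#' @export
read_table_with_provenance <- function(path) {
  read.csv(path, comment.char = "#")
}
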
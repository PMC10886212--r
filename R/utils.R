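# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded package functions never perturb the session stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# stop() without the call, with sprintf-style formatting
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# write a data.frame as a plain TSV (deterministic, no quoting surprises)
write_tsv <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path,
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    check.names = FALSE, ...
  )
}
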
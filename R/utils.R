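#' @importFrom methods new validObject is slot
#' @importFrom stats var sd pf predict
#' @importFrom utils read.csv write.csv head
#' @importFrom ranger ranger
NULL

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so package functions never clobber the session stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Commercial rounding: 0.5 always rounds away from zero (x >= 0 here).
roundHalfUp <- function(x) floor(x + 0.5)

# Derived sub-seed, kept inside 32-bit integer range.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% .Machine$integer.max)
}

# Write `lines` atomically: temp file in the target directory, then rename.
writeLinesAtomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
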
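#' @useDynLib apneaScatter, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic entry points funnel through
# this so a single integer seed fully determines their output.
withLocalSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and a stream index, kept within the
# 32-bit signed integer range.
childSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * stream) %% 2147483647)
}

# Stable hash of an R object (used for provenance stamping of pipeline
# artifacts): serialize to a temp file and md5 it.
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
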
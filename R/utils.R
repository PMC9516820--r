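`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a base seed, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483647)
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# Glorot-uniform initial weight matrix
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

zeros <- function(nin, nout = 1L) matrix(0, nin, nout)

pathgnn_version <- function() as.character(utils::packageVersion("pathgnn"))
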
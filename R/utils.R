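# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit
# so generators never perturb the session stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  force(code)
}

# Canonical unordered key for an edge, used for deduplication.
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

stop_pivotnet <- function(...) stop(..., call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

# All-at-once range checks used by validate_config(); returns character(0)
# when `ok` holds.
check_that <- function(ok, msg) if (isTRUE(ok)) character(0) else msg
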
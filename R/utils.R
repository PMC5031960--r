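#' @importFrom rlang abort warn .data
#' @importFrom stats runif rexp setNames
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "genetrace_input_error")
  }
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
  })
  set.seed(as.integer(seed))
  expr
}

stop_input <- function(...) abort(paste0(...), class = "genetrace_input_error")
stop_capability <- function(...) abort(paste0(...), class = "genetrace_capability_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
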
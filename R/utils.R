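#' Evaluate an expression with a fixed RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generator calls are deterministic without clobbering the
#' global stream. All randomised functions in the package route their draws
#' through this helper: one integer seed feeds one documented stream per call.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
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
  code
}

# Derive a deterministic sub-seed from a master seed; keeps derived seeds
# inside the 32-bit integer range.
derive_seed <- function(seed, k) {
  (as.integer(seed) + 99991L * as.integer(k)) %% 2147483587L
}

# Structured log line to stderr. Quiet by default inside tests unless
# options(memnano.verbose = TRUE).
mn_log <- function(...) {
  if (isTRUE(getOption("memnano.verbose", FALSE))) {
    message("[memnano] ", ...)
  }
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
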
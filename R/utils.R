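#' Derive a deterministic sub-stream seed
#'
#' One user-facing seed fans out to independent per-operation seeds so that
#' each stage of the synthetic pipeline is reproducible on its own.
#' A small multiplicative hash keeps the result a valid 32-bit integer.
#' @noRd
substream_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(label)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so library code never
#' clobbers the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Stop with a consistent input-error message
#' @noRd
abort_input <- function(...) stop(..., call. = FALSE)

#' Check a completeness column
#' @noRd
check_completeness <- function(c_vals) {
  if (any(!is.finite(c_vals)) || any(c_vals <= 0) || any(c_vals > 1)) {
    abort_input("completeness must lie in (0, 1]")
  }
  invisible(TRUE)
}
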
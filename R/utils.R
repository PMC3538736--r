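`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Seeds the generator, evaluates `code`, and restores the caller's RNG
#' state afterwards so simulation helpers do not perturb the session stream.
#' With `seed = NULL` the code runs on the current stream untouched.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) stop(sprintf("`%s` must be a single %s number", name,
                        if (strict) "positive" else "non-negative"),
                call. = FALSE)
  invisible(x)
}
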
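# internal helpers shared across modules

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible child seed from a master seed and a text label.
# Keeps module substreams independent: adding a pipeline stage with a new
# label never perturbs the streams of existing stages.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483563
  as.integer((as.numeric(seed) %% 2147483563 + h) %% 2147483563) + 1L
}

# Evaluate with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_if_not_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
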
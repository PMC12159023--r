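# Internal helpers: seeded sub-streams and small validators.

# Deterministic 31-bit hash of a label path, folded with the master seed.
# Used to give every (plot, quadrat, metric) draw its own RNG sub-stream so
# that adding plots or metrics never reshuffles draws already made.
substream_seed <- function(seed, ...) {
  s <- paste(c(format(seed), vapply(list(...), format, character(1))),
             collapse = "/")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_substream <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("`", name, "` must be a finite numeric scalar", call. = FALSE)
  if (if (strict) x <= min else x < min)
    stop("`", name, "` must be ", if (strict) "> " else ">= ", min,
         call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
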
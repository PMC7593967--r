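# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derived from a master seed and a character tag.
# Keeps results < 2^31 so they remain valid R integer seeds. Distinct tags
# give effectively independent streams for (stage, event, repetition).
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  tag <- paste(list(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(tag)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invasim <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_invasim(msg)
}
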
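# Internal helpers shared across modules.

# Deterministic integer stream-seed derived from a base seed plus string
# labels (patient id, timepoint, stage name ...). Polynomial string hash,
# kept below 2^31 so it is a valid R RNG seed.
derive_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (c in utf8ToInt(labels)) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopf <- function(class, fmt, ...) {
  rlang::abort(sprintf(fmt, ...), class = c(class, "bmetex_error"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
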
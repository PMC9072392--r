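# internal helpers: seeded evaluation, config hashing, small checks

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate code under a given seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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
  force(code)
}

# 32-bit polynomial rolling hash of a serialized R object, as 8 hex digits;
# stamps output files with the configuration they were produced from. The
# multiply is split into two factors so intermediates stay below 2^53.
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 216613626
  for (b in as.integer(raw)) {
    h <- ((h * 403) %% 4294967296 * 41623 + b) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (strict_lower && x <= lower || !strict_lower && x < lower ||
      strict_upper && x >= upper || !strict_upper && x > upper) {
    stop(sprintf("'%s' = %g is outside the allowed range", name, x),
         call. = FALSE)
  }
  invisible(x)
}
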
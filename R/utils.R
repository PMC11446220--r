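# Internal helpers: deterministic seed fan-out and small input checks.

#' Stable string hash
#'
#' Polynomial rolling hash of a character string, reduced modulo 2^31 - 1.
#' Used to derive independent random substreams (per plot, per model) from a
#' single run seed so that results do not depend on iteration order.
#'
#' @param x A character scalar.
#' @return A non-negative integer scalar below 2^31 - 1.
#' @keywords internal
#' @noRd
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% m
  h
}

# Derive a substream seed from a base seed and a string key.
derive_seed <- function(seed, key) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + stable_hash(key)) %% m)
}

# Run an expression under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Scalar checks ---------------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop(sprintf("`%s` must be a finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x != as.integer(x)) {
    stop(sprintf("`%s` must be an integer >= %d", name, lower), call. = FALSE)
  }
  invisible(as.integer(x))
}
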
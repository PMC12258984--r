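# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace so that lists coming from
#' different omics tables (e.g. "Irs1" vs "IRS1") intersect correctly.
#'
#' @param x character vector of symbols.
#' @return normalized character vector.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. Every generator routes its randomness through this so
# that identical config + seed gives identical output without clobbering
# the session RNG.
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("`seed` must be a single finite number, got %s", deparse(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Stable 31-ary string hash (mod a prime below 2^31); used to derive
# per-stage seeds from the global pipeline seed so adding a stage never
# perturbs the randomness of earlier stages.
hash_string <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483629
  h
}

#' Derive a stage seed from a global seed
#'
#' @param global_seed single integer.
#' @param stage stage name, e.g. "proximity".
#' @return an integer seed below 2^31, a pure function of its inputs.
#' @export
derive_seed <- function(global_seed, stage) {
  stopifnot(length(stage) == 1L, is.character(stage))
  as.integer(((as.numeric(global_seed) %% 2147483629) * 48271 +
                hash_string(stage)) %% 2147483629)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x))
    stopf("`%s` must be a single integer >= %d, got %s", name, min,
          deparse(x))
  as.integer(x)
}

check_prob <- function(x, name, lo = 0, hi = 1, open_lo = FALSE,
                       open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok)
    stopf("`%s` must be a single number in %s%g, %g%s, got %s", name,
          if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]",
          deparse(x))
  as.numeric(x)
}
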
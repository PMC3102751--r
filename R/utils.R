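# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# log10(sum(w * 10^x)) computed stably
log10_weighted_sum <- function(x, w) {
  m <- max(x)
  m + log10(sum(w * 10^(x - m)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

# Seeded evaluation that does not disturb the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
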
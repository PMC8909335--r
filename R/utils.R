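#' @keywords internal
#' @importFrom utils head tail
#' @importFrom stats rnorm runif
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic child seeds: one user-facing seed fans out to per-stage
## streams without collisions for small offsets; kept below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

## dB <-> linear power helpers used throughout the spectral code
db_to_power <- function(db) 10^(db / 10)
power_to_db <- function(p) 10 * log10(p)
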
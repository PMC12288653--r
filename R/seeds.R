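# Deterministic seeding: a single global seed plus named salts, so adding a
# new stochastic component never shifts existing random streams.

#' Validate and coerce a seed to integer
#'
#' @param seed a single number representable as a 32-bit integer.
#' @return integer seed.
#' @keywords internal
#' @export
as_seed_int <- function(seed) {
  seed <- as.numeric(seed)
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed) ||
      abs(seed) >= 2^31) {
    stop("`seed` must be a single integer below 2^31", call. = FALSE)
  }
  as.integer(seed)
}

#' Derive a substream seed from a global seed and a named salt
#'
#' Hashes the salt string and mixes it with the global seed by modular
#' multiplicative congruences; the result is a positive 32-bit integer,
#' deterministic in `(seed, salt)` and (for practical purposes) decorrelated
#' across salts.
#'
#' @param seed global integer seed.
#' @param salt character label of the stochastic component.
#' @return positive integer seed for the substream.
#' @export
derive_seed <- function(seed, salt) {
  seed <- as_seed_int(seed)
  h <- 0
  for (code in utf8ToInt(as.character(salt))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807 + 12345) %% 2147483629 + 1)
}
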
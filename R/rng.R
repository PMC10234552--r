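# Seed derivation and counter-based random streams.
#
# The synthetic world uses one master seed; each stochastic stage draws from
# its own derived stream so stages can be regenerated independently (re-running
# the population assignment does not disturb the monitor noise, etc.).

.streams <- c("roads", "monitors", "blocks", "population", "frac25",
              "observe", "dispersion", "baseline")

#' Derive a per-stage seed from the master seed
#'
#' @param seed Master integer seed.
#' @param stream Stage name, one of `"roads"`, `"monitors"`, `"blocks"`,
#'   `"population"`, `"frac25"`, `"observe"`, `"dispersion"`, `"baseline"`.
#' @return A deterministic integer seed < 2^31.
#' @export
derive_seed <- function(seed, stream) {
  idx <- match(stream, .streams)
  if (is.na(idx)) stop("unknown random stream: ", stream, call. = FALSE)
  m <- 2147483647
  h <- (as.numeric(seed) %% m)
  h <- (h * 48271 + idx * 7919) %% m
  h <- (h * 48271 + 11) %% m
  as.integer(h)
}

# Counter-based uniform hash (MINSTD-style chained congruential mix).
# Deterministic per (key1, key2, key3) triple and vectorised; used where a
# value must be reproducible for a given (point, day, seed) regardless of how
# calls are batched. All arithmetic stays below 2^53 so doubles are exact.
hash_uniform <- function(k1, k2, k3) {
  m <- 2147483647
  h <- (abs(as.numeric(k1)) %% m)
  h <- (h * 48271 + (abs(as.numeric(k2)) %% m)) %% m
  h <- (h * 48271 + (abs(as.numeric(k3)) %% m)) %% m
  h <- (h * 48271 + 17) %% m
  h <- (h * 48271 + 29) %% m
  (h + 0.5) / m
}
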
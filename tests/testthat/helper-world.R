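# Shared fixtures: small, fast synthetic configurations built in code.

# compact world: 3x3 grid, short year, few blocks - for unit tests.
# overrides are deep-merged so callers can refine nested sections.
tiny_config <- function(...) {
  base <- list(
    grid = list(n_rows = 3L, n_cols = 3L),
    n_days = 30L,
    monitors = list(n_monitors = 12L),
    blocks = list(n_blocks = 300L),
    ramp = list(n_sites = 6L, min_pairs = 50L)
  )
  do.call(build_config, utils::modifyList(base, list(...)))
}

# a config in which every stochastic / biased stage collapses to truth:
# no model bias, unit dispersion multiplier, noiseless daily monitors
exact_config <- function(...) {
  base <- list(
    bias = list(enabled = FALSE),
    dispersion = list(median_bias = 1, sigma = 0),
    monitors = list(noise_sd = 0, one_in_three_fraction = 0)
  )
  do.call(tiny_config, utils::modifyList(base, list(...)))
}

# flat world: constant background, no roads -> truth is spatially uniform
flat_config <- function(base = 8, ...) {
  flat <- list(
    background = list(base = base, amplitudes = c(0, 0), seasonal_amp = 0),
    roads = list(n_roads = 0L)
  )
  do.call(tiny_config, utils::modifyList(flat, list(...)))
}

random_curve <- function(n_bins = 10L) {
  pairs <- data.frame(predicted = stats::runif(200, 0, 20),
                      observed = stats::runif(200, 0, 20))
  fit_ramp(pairs, n_bins = n_bins, min_pairs = 1L)
}

# hand-built blocks table for health/equity unit tests
toy_blocks <- function(n = 4) {
  data.frame(
    block_id = seq_len(n),
    x = seq(1000, by = 2000, length.out = n),
    y = rep(1000, n),
    county_id = rep(1:2, length.out = n),
    tract_id = rep(10001:10002, length.out = n),
    block_group_id = rep(1000101:1000102, length.out = n),
    distance_to_road = seq(10, by = 40, length.out = n),
    pop_total = rep(400L, n),
    pop_white = rep(200L, n),
    pop_black = rep(80L, n),
    pop_asian = rep(40L, n),
    pop_hispanic = rep(60L, n),
    pop_other = rep(20L, n),
    frac_25plus = rep(0.6, n)
  )
}
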
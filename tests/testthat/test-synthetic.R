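test_that("identical (config, seed) gives bit-identical worlds", {
  cfg <- tiny_config()
  w1 <- build_domain(cfg, 11)
  w2 <- build_domain(cfg, 11)
  expect_identical(w1$roads, w2$roads)
  expect_identical(w1$monitors, w2$monitors)
  expect_identical(w1$blocks, w2$blocks)
  expect_identical(w1$counties, w2$counties)
  w3 <- build_domain(cfg, 12)
  expect_false(identical(w1$blocks, w3$blocks))
})

test_that("a zero-road world is valid and all road increments vanish", {
  w <- build_domain(flat_config(), 3)
  expect_equal(nrow(w$roads), 0L)
  pts <- data.frame(x = c(1000, 20000), y = c(1000, 15000))
  expect_equal(road_increment(pts, w$roads), c(0, 0))
})

test_that("background: constant mode, Lipschitz bound, non-negativity", {
  w <- build_domain(flat_config(base = 8), 5)
  pts <- data.frame(x = runif(20, 0, 36000), y = runif(20, 0, 36000))
  bg <- simulate_background(w, pts, 1:10)
  expect_true(all(bg == 8))

  wv <- build_domain(tiny_config(), 5)
  cfgb <- wv$config$background
  lip <- sum(cfgb$amplitudes * 2 * pi / cfgb$wavelengths)
  p1 <- data.frame(x = 5000, y = 5000)
  p2 <- data.frame(x = 5001, y = 5000)
  d <- abs(simulate_background(wv, p1, 1) - simulate_background(wv, p2, 1))
  expect_lt(d, lip * 1 + 1e-12)
  expect_error(simulate_background(wv, p1, 9999), "simulated year")
})

test_that("road increment follows the exponential line-source closed form", {
  roads <- data.frame(road_id = 1L, x0 = -100, y0 = 0, x1 = 100, y1 = 0,
                      emission_rate = 2, road_class = "interstate")
  on_road <- data.frame(x = 0, y = 0)
  expect_equal(road_increment(on_road, roads, alpha = 1, L = 150), 2)
  at_L <- data.frame(x = 0, y = 150)
  roads1 <- transform(roads, emission_rate = 1)
  expect_equal(road_increment(at_L, roads1, alpha = 1, L = 150), exp(-1))
  # additivity for overlapping segments
  expect_equal(road_increment(at_L, rbind(roads1, roads1), 1, 150),
               2 * exp(-1))
  # decay contract at 200 m for a single segment
  v0 <- road_increment(on_road, roads1, 1, 150)
  v200 <- road_increment(data.frame(x = 0, y = 200), roads1, 1, 150)
  expect_equal(v200, exp(-200 / 150) * v0)
  expect_error(road_increment(on_road, roads, L = -1), "L")
})

test_that("coarse-model emulator: identity bias and plug-in distortion", {
  # bias off -> exactly the subgrid truth mean; flat world makes that the base
  w <- build_domain(flat_config(base = 10,
                                bias = list(enabled = FALSE)), 2)
  ctm <- emulate_ctm(w, 1:3)
  expect_true(all(ctm$value == 10))

  # g(x) = 0 + 1*x + 1*x^2/(x+10) at uniform truth 10 -> 15
  w2 <- build_domain(flat_config(base = 10,
                                 bias = list(enabled = TRUE, a = 0,
                                             a_range = 0, b = 1, b_range = 0,
                                             s = 1, s_range = 0, h = 10)), 2)
  ctm2 <- emulate_ctm(w2, 1)
  expect_equal(ctm2$value, rep(15, n_cells(w2$grid)))

  # additive-only bias shifts the cell mean by a
  w3 <- build_domain(flat_config(base = 7,
                                 bias = list(enabled = TRUE, a = 1,
                                             a_range = 0, b = 1, b_range = 0,
                                             s = 0, s_range = 0, h = 10)), 2)
  expect_equal(emulate_ctm(w3, 1)$value, rep(8, 9))
})

test_that("dispersion emulator: degenerate multiplier and per-point determinism", {
  cfg <- tiny_config(dispersion = list(median_bias = 1.2, sigma = 0))
  w <- build_domain(cfg, 9)
  pts <- data.frame(x = c(3000, 9000), y = c(2000, 20000))
  inc <- road_increment(pts, w$roads, w$config$decay$alpha, w$config$decay$L)
  disp <- emulate_dispersion(w, pts, 1:4)
  expect_equal(unname(disp), cbind(inc, inc, inc, inc) * 1.2,
               ignore_attr = TRUE)

  cfg2 <- tiny_config(dispersion = list(median_bias = 1.2, sigma = 0.3))
  w2 <- build_domain(cfg2, 9)
  d_all <- emulate_dispersion(w2, pts, 1:4)
  d_sub <- emulate_dispersion(w2, pts[2, , drop = FALSE], c(2L, 4L))
  # same (point, day, seed) -> same realisation however calls are batched
  expect_equal(unname(d_sub[1, ]), unname(d_all[2, c(2, 4)]))
  # zero roads -> all zero whatever the error model
  w0 <- build_domain(flat_config(), 9)
  expect_true(all(emulate_dispersion(w0, pts, 1:3) == 0))
})

test_that("observations: noiseless equals truth; schedules and CLT bound", {
  w <- build_domain(exact_config(), 21)
  obs <- observe(w, 1:9)
  tr <- truth_field(w, w$monitors, 1:9)
  truth_at <- tr[cbind(match(obs$site_id, w$monitors$site_id), obs$day)]
  expect_equal(obs$value, unname(truth_at))

  cfg13 <- tiny_config(monitors = list(n_monitors = 5L, noise_sd = 0,
                                       one_in_three_fraction = 1))
  w13 <- build_domain(cfg13, 4)
  obs13 <- observe(w13, 1:9)
  expect_equal(sort(unique(obs13$day)), c(1L, 4L, 7L))
  expect_equal(nrow(obs13), 5 * 3)

  # additive noise is zero-mean: 10,000+ draws, sample mean within +/- 0.05
  cfgn <- build_config(grid = list(n_rows = 3L, n_cols = 3L), n_days = 365L,
                       monitors = list(n_monitors = 30L, noise_sd = 1,
                                       one_in_three_fraction = 0))
  wn <- build_domain(cfgn, 8)
  obsn <- observe(wn, 1:365)
  trn <- truth_field(wn, wn$monitors, 1:365)
  resid <- obsn$value - trn[cbind(match(obsn$site_id, wn$monitors$site_id),
                                  obsn$day)]
  expect_gte(length(resid), 10000)
  expect_lt(abs(mean(resid)), 0.05)
  expect_error(observe(wn, 1:5, noise_sd = -1), "noise_sd")
})

test_that("population assignment: conservation, shared tract fraction, enrichment", {
  cfg <- build_config(blocks = list(n_blocks = 1500L, theta = 2))
  w <- build_domain(cfg, 31)
  b <- w$blocks
  race <- b$pop_white + b$pop_black + b$pop_asian + b$pop_hispanic +
    b$pop_other
  expect_identical(race, b$pop_total)
  expect_true(all(b$pop_total >= 0))
  # one fraction_25plus value per tract
  per_tract <- tapply(b$frac_25plus, b$tract_id,
                      function(v) length(unique(v)))
  expect_true(all(per_tract == 1))
  # admin nesting: a block group sits in exactly one tract, a tract in one county
  expect_true(all(tapply(b$tract_id, b$block_group_id,
                         function(v) length(unique(v))) == 1))
  expect_true(all(tapply(b$county_id, b$tract_id,
                         function(v) length(unique(v))) == 1))
  # theta = 2: near-road blocks carry a larger Minority share than far blocks
  minority_share <- 1 - b$pop_white / pmax(b$pop_total, 1)
  near <- b$distance_to_road < 100 & b$pop_total > 0
  far <- b$distance_to_road > 1000 & b$pop_total > 0
  expect_gt(mean(minority_share[near]), mean(minority_share[far]))
})

test_that("configuration validation rejects bad values and unknown keys", {
  expect_error(build_config(bias = list(h = 0)), "h must be > 0")
  expect_error(build_config(dispersion = list(sigma = -1)), "sigma")
  expect_error(build_config(nonsense = 1), "unknown configuration key")
  expect_error(build_config(blocks = list(wrong = 2)),
               "unknown configuration key: blocks\\$wrong")
  expect_error(build_config(blocks = list(n_blocks = 0L)), "n_blocks")
})
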
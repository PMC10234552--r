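test_that("site selection: nearest-n, ties by id, saturation", {
  g <- grid_definition(cell_size = 100, n_rows = 1, n_cols = 1)
  # cell centroid at (50, 50)
  sites <- data.frame(site_id = c(3L, 1L, 2L),
                      x = c(50, 60, 40), y = c(51, 50, 50))
  sel <- select_sites(1L, g, sites, 2)
  expect_equal(sel$site_id, c(3L, 1L))  # distances 1, 10, 10; tie -> id 1
  sel1 <- select_sites(1L, g, sites, 1)
  expect_equal(sel1$site_id, 3L)
  # equidistant pair: lower id wins
  sites_tie <- data.frame(site_id = c(9L, 4L), x = c(60, 40), y = c(50, 50))
  expect_equal(select_sites(1L, g, sites_tie, 1)$site_id, 4L)
  # n beyond the site count returns everything without error
  expect_equal(nrow(select_sites(1L, g, sites, 99)), 3L)
  expect_error(select_sites(1L, g, sites[0, ], 1), "empty")
})

test_that("daily pairing keeps only (site, day) keys present on both sides", {
  model <- data.frame(point_id = rep(1:2, each = 9), day = rep(1:9, 2),
                      value = 1:18)
  obs <- data.frame(site_id = 1L, day = c(1L, 4L, 7L), value = c(10, 11, 12))
  pairs <- pair_daily(model, obs)
  expect_equal(nrow(pairs), 3L)
  expect_equal(pairs$predicted, c(1, 4, 7))
  expect_equal(pairs$observed, c(10, 11, 12))
  # complete obs x complete model -> full cross count
  obs_full <- data.frame(site_id = rep(1:2, each = 9), day = rep(1:9, 2),
                         value = 0)
  expect_equal(nrow(pair_daily(model, obs_full)), 18L)
  expect_equal(nrow(pair_daily(model[0, ], obs)), 0L)
})

test_that("decile-bin fit reproduces the sort-and-chunk construction", {
  pairs <- data.frame(predicted = 1:20, observed = 2 * (1:20))
  cv <- fit_ramp(pairs, min_pairs = 1L)
  expect_equal(cv$x, seq(1.5, 19.5, by = 2))
  expect_equal(cv$lambda1, seq(3, 39, by = 4))
  expect_equal(cv$lambda1_m, mean(2 * (1:20)))

  # identity data: nodes on the 1:1 line, grand mean = grand mean
  idp <- data.frame(predicted = 1:20, observed = 1:20)
  cvi <- fit_ramp(idp, min_pairs = 1L)
  expect_equal(cvi$x, cvi$lambda1)

  # all predictions identical: degenerate constant curve
  dg <- fit_ramp(data.frame(predicted = rep(4, 30), observed = 1:30),
                 min_pairs = 1L)
  expect_true(dg$degenerate)
  expect_equal(apply_ramp(enforce_monotone(dg), c(0, 4, 100)),
               rep(mean(1:30), 3))

  expect_error(fit_ramp(idp, min_pairs = 100L), "pooled")
})

test_that("remainder pairs go to the lowest bins and ties keep rank order", {
  pairs <- data.frame(predicted = c(rep(1, 5), 2:19), observed = 1:23)
  cv <- fit_ramp(pairs, min_pairs = 1L)
  # 23 pairs -> bins of 3,3,3,2,... ; stable sort keeps tied obs in order
  expect_equal(cv$x[1], 1)
  expect_equal(cv$lambda1[1], 2)  # mean(1:3): first three tied-predicted pairs
  sizes <- c(rep(3, 3), rep(2, 7))
  expect_equal(sum(sizes), 23)
})

test_that("centre-out monotonicity safeguard matches the hand-traced example", {
  cv <- structure(list(cell = 1, x = 1:10,
                       lambda1 = c(2, 3, 5, 4, 7, 6, 8, 7, 9, 10),
                       lambda1_m = 6.5, n_pairs = 100, degenerate = FALSE,
                       monotone = FALSE), class = "ramp_curve")
  out <- enforce_monotone(cv)
  expect_equal(out$lambda1, c(2, 3, 4, 4, 6.5, 6.5, 8, 8, 9, 10))

  # grand mean below the 5th node: node 5 is capped
  cv2 <- cv; cv2$lambda1 <- 1:10; cv2$lambda1_m <- 4.5
  out2 <- enforce_monotone(cv2)
  expect_equal(out2$lambda1[5], 4.5)
  # already monotone with node5 <= mean <= node6: untouched
  cv3 <- cv; cv3$lambda1 <- 1:10; cv3$lambda1_m <- 5.5
  expect_equal(enforce_monotone(cv3)$lambda1, as.numeric(1:10))
})

test_that("safeguard yields a non-decreasing curve bracketing the grand mean", {
  set.seed(101)
  ok <- vapply(1:500, function(i) {
    cv <- enforce_monotone(random_curve())
    all(diff(cv$lambda1) >= 0) && cv$lambda1[5] <= cv$lambda1_m &&
      cv$lambda1[6] >= cv$lambda1_m
  }, TRUE)
  expect_true(all(ok))
})

test_that("curve application: node hits, midpoints, terminal extrapolation", {
  cv <- structure(list(cell = 1, x = c(1, 3), lambda1 = c(2, 4),
                       lambda1_m = 3, n_pairs = 10, degenerate = FALSE,
                       monotone = TRUE), class = "ramp_curve")
  expect_equal(apply_ramp(cv, c(1, 3)), c(2, 4))
  expect_equal(apply_ramp(cv, 2), 3)
  expect_equal(apply_ramp(cv, 0), 1)   # slope-1 extension below
  expect_equal(apply_ramp(cv, 5), 6)   # slope-1 extension above
  # floored at zero when extrapolation would go negative
  expect_equal(apply_ramp(cv, -10), 0)
  # duplicate-x nodes collapse to their mean
  cvd <- cv; cvd$x <- c(1, 1); cvd$lambda1 <- c(2, 6)
  expect_equal(apply_ramp(cvd, c(0, 1, 9)), rep(4, 3))
  expect_error(apply_ramp(structure(cv[setdiff(names(cv), "monotone")],
                                    class = "ramp_curve"), 1), "safeguard")
})

test_that("identity pairs give an identity correction inside the node range", {
  set.seed(7)
  vals <- runif(300, 0, 20)
  pairs <- data.frame(predicted = vals, observed = vals)
  cv <- enforce_monotone(fit_ramp(pairs, min_pairs = 1L))
  inside <- seq(min(cv$x), max(cv$x), length.out = 100)
  expect_lt(max(abs(apply_ramp(cv, inside) - inside)), 1e-12)
})

test_that("a safeguarded correction is non-decreasing in its input", {
  set.seed(33)
  for (i in 1:50) {
    cv <- enforce_monotone(random_curve())
    v <- sort(runif(50, -5, 30))
    out <- apply_ramp(cv, v)
    expect_true(all(diff(out) >= -1e-12))
  }
})

test_that("field correction is per-cell and preserves within-cell ordinality", {
  g <- grid_definition(cell_size = 100, n_rows = 1, n_cols = 2)
  id_curve <- function(cell) {
    enforce_monotone(fit_ramp(
      data.frame(predicted = 1:20, observed = 1:20),
      min_pairs = 1L, cell = cell))
  }
  dbl_curve <- function(cell) {
    enforce_monotone(fit_ramp(
      data.frame(predicted = 1:20, observed = 2 * (1:20)),
      min_pairs = 1L, cell = cell))
  }
  curves <- list("1" = id_curve(1L), "2" = dbl_curve(2L))
  pts <- data.frame(point_id = 1:2, x = c(50, 150), y = 50)
  field <- data.frame(point_id = rep(1:2, each = 2), day = rep(1:2, 2),
                      value = c(5, 10, 5, 10))
  out <- correct_field(field, pts, curves, g)
  expect_equal(out$value[out$point_id == 1], c(5, 10))
  expect_equal(out$value[out$point_id == 2], c(10, 20))
  # ordinality within a cell
  expect_true(all(diff(out$value[out$point_id == 2]) >= 0))
  pts_out <- data.frame(point_id = 1L, x = 999, y = 50)
  expect_error(correct_field(field[field$point_id == 1, ], pts_out, curves, g),
               "outside")
})

test_that("coarse regridding averages blocks per cell and is idempotent on cell-constant fields", {
  g <- grid_definition(cell_size = 100, n_rows = 1, n_cols = 2)
  pts <- data.frame(point_id = 1:3, x = c(10, 90, 150), y = 50)
  vals <- data.frame(point_id = 1:3, value = c(1, 3, 7))
  out <- regrid_to_coarse(vals, pts, g)
  expect_equal(out$value, c(2, 7))
  # single block per cell: the block value comes straight back
  out2 <- regrid_to_coarse(vals[3, ], pts, g)
  expect_equal(out2$value, c(NA_real_, 7))
  # cell-constant input is recovered exactly
  vals3 <- data.frame(point_id = 1:3, value = c(4, 4, 9))
  expect_equal(regrid_to_coarse(vals3, pts, g)$value, c(4, 9))
})
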
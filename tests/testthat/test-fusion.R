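test_that("cell averaging of receptors: constants, exact mean, locality", {
  g <- grid_definition(cell_size = 1200, n_rows = 1, n_cols = 2)
  rec <- cell_receptors(g, 12L)
  pf <- data.frame(point_id = rec$point_id, x = rec$x, y = rec$y, day = 1L,
                   value = 5)
  out <- grid_average_receptors(pf, g)
  expect_equal(out$value, c(5, 5))

  pf$value[rec$cell == 1] <- 1:144
  out2 <- grid_average_receptors(pf, g)
  expect_equal(out2$value[out2$cell == 1], 72.5)
  # permuting the other cell's values must not change cell 1's mean
  pf3 <- pf
  idx2 <- which(rec$cell == 2)
  pf3$value[idx2] <- rev(pf3$value[idx2])
  expect_equal(grid_average_receptors(pf3, g)$value[1], out2$value[1])

  # a cell with no receptors is an error naming the cell
  pf_missing <- pf[rec$cell == 1, ]
  expect_error(grid_average_receptors(pf_missing, g), "2")
})

test_that("on-road subtraction keeps negatives and validates keys", {
  a <- data.frame(cell = c(1L, 2L), day = 1L, value = c(10, 2))
  b <- data.frame(cell = c(1L, 2L), day = 1L, value = c(3, 5))
  d <- subtract_onroad(a, b)
  expect_equal(d$value, c(7, -3))
  expect_equal(subtract_onroad(a, transform(b, value = 0))$value, a$value)
  expect_error(subtract_onroad(a, b[1, ]), "do not match")
})

test_that("bilinear interpolation: uniform fields, cell centres, midpoints", {
  g <- grid_definition(cell_size = 100, n_rows = 2, n_cols = 2)
  field <- data.frame(cell = 1:4, day = 1L, value = 7)
  pts <- data.frame(point_id = 1:3, x = c(10, 50, 199), y = c(10, 100, 150))
  expect_equal(interpolate_to_points(field, pts, g)$value, rep(7, 3))

  field2 <- data.frame(cell = 1:4, day = 1L, value = c(2, 4, 6, 8))
  cc <- cell_centroids(g)
  at_centres <- interpolate_to_points(
    field2, data.frame(point_id = 1:4, x = cc$x, y = cc$y), g)
  expect_equal(at_centres$value, c(2, 4, 6, 8))
  # midway between two horizontally adjacent centres with values 2 and 4 -> 3
  mid <- interpolate_to_points(field2,
                               data.frame(point_id = 1L, x = 100, y = 50), g)
  expect_equal(mid$value, 3)
  # outside the centre hull: clamped to the nearest edge coordinate
  corner <- interpolate_to_points(field2,
                                  data.frame(point_id = 1L, x = 0, y = 0), g)
  expect_equal(corner$value, 2)
  expect_error(interpolate_to_points(field2[0, ], pts, g), "empty")
})

test_that("hybrid combination applies the zero-out rule", {
  diffs <- data.frame(point_id = 1:3, day = 1L, value = c(6, -1, 0))
  cbc <- data.frame(point_id = 1:3, day = 1L, value = c(2, 3, 0))
  out <- combine_hybrid(diffs, cbc)
  expect_equal(out$value, c(8, 3, 0))
  expect_true(all(out$value >= cbc$value))
  expect_error(combine_hybrid(diffs, transform(cbc, value = c(-1, 0, 0))),
               "non-negative")
})

test_that("NO2 yield polynomial recovers nested models exactly", {
  nox <- seq(2, 40, length.out = 30)
  fit_const <- fit_no2_yield(nox, 0.75 * nox)
  expect_equal(nox_to_no2(nox, fit_const), 0.75 * nox, tolerance = 1e-9)

  yield_lin <- 0.9 - 0.01 * nox
  fit_lin <- fit_no2_yield(nox, yield_lin * nox)
  expect_equal(nox_to_no2(20, fit_lin), 0.7 * 20, tolerance = 1e-9)

  # duplicated pairs do not change the least-squares solution
  fit_dup <- fit_no2_yield(c(nox, nox), c(yield_lin * nox, yield_lin * nox))
  expect_equal(fit_dup$coefficients, fit_lin$coefficients, tolerance = 1e-8)

  expect_error(fit_no2_yield(nox[1:10], nox[1:10]), "20 pairs")
  expect_error(fit_no2_yield(c(-1, nox[-1]), nox), "> 0")
})

test_that("NO2 transform clips the yield to [0, 1] and clamps the range", {
  yield <- structure(list(coefficients = c(1.2, 0, 0, 0, 0),
                          range = c(1, 50)), class = "no2_yield")
  expect_equal(nox_to_no2(10, yield), 10)  # yield clipped at 1
  lin <- fit_no2_yield(seq(2, 40, length.out = 30),
                       (0.9 - 0.01 * seq(2, 40, length.out = 30)) *
                         seq(2, 40, length.out = 30))
  # outside the fitted range the input is clamped before evaluation
  expect_equal(nox_to_no2(100, lin), 100 * (0.9 - 0.01 * 40),
               tolerance = 1e-6)
  out <- nox_to_no2(seq(0, 100, by = 5), lin)
  expect_true(all(out >= 0 & out <= seq(0, 100, by = 5)))
})

test_that("with zero roads the fused field equals the interpolated coarse field", {
  w <- build_domain(flat_config(bias = list(enabled = FALSE)), 6)
  days <- 1:5
  cmaq <- emulate_ctm(w, days)
  rec <- cell_receptors(w$grid, w$config$receptors_per_side)
  gavg <- grid_average_receptors(
    data.frame(point_id = rep(rec$point_id, length(days)),
               x = rep(rec$x, length(days)), y = rep(rec$y, length(days)),
               cell = rep(rec$cell, length(days)),
               day = rep(days, each = nrow(rec)),
               value = as.vector(emulate_dispersion(w, rec, days))),
    w$grid)
  diff <- subtract_onroad(cmaq, gavg)
  pts <- data.frame(point_id = 1:3, x = c(5000, 17000, 30000),
                    y = c(4000, 20000, 33000))
  interp <- interpolate_to_points(diff, pts, w$grid)
  cbc <- data.frame(point_id = rep(pts$point_id, length(days)),
                    day = rep(days, each = 3),
                    value = as.vector(emulate_dispersion(w, pts, days)))
  hyb <- combine_hybrid(interp, cbc)
  ref <- interpolate_to_points(cmaq, pts, w$grid)
  expect_equal(hyb$value[order(hyb$point_id, hyb$day)],
               ref$value[order(ref$point_id, ref$day)])
})
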
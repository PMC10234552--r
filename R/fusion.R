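# Hybrid data fusion: remove the on-road contribution from the coarse grid
# field, interpolate the remainder to points, and add back the fine-scale
# near-road field, with a zero-out rule when the remainder goes negative.
#
# Field schemas used throughout:
#   grid field : data.frame(cell, day, value)
#   point field: data.frame(point_id, day, value)

# long grid field -> matrix [cells x days] in (sorted cell, sorted day) order
grid_field_matrix <- function(field) {
  cells <- sort(unique(field$cell))
  days <- sort(unique(field$day))
  m <- matrix(NA_real_, length(cells), length(days),
              dimnames = list(cells, days))
  m[cbind(match(field$cell, cells), match(field$day, days))] <- field$value
  m
}

point_field_matrix <- function(field) {
  ids <- sort(unique(field$point_id))
  days <- sort(unique(field$day))
  m <- matrix(NA_real_, length(ids), length(days),
              dimnames = list(ids, days))
  m[cbind(match(field$point_id, ids), match(field$day, days))] <- field$value
  m
}

matrix_to_point_field <- function(m, ids = as.integer(rownames(m)),
                                  days = as.integer(colnames(m))) {
  data.frame(point_id = rep(ids, times = ncol(m)),
             day = rep(days, each = nrow(m)),
             value = as.vector(m))
}

#' Average a receptor point field within each coarse cell
#'
#' Averages the dense receptor lattice of the dispersion model inside every
#' coarse cell, giving the cell-average on-road contribution that is
#' subtracted from the coarse total to avoid double counting.
#'
#' @param receptors data.frame `point_id`, `x`, `y`, `day`, `value` (or with a
#'   precomputed `cell` column).
#' @param grid A [grid_definition()].
#' @return Grid field data.frame `cell`, `day`, `value`.
#' @export
grid_average_receptors <- function(receptors, grid) {
  if (!nrow(receptors)) stop("empty receptor field", call. = FALSE)
  if (is.null(receptors$cell))
    receptors$cell <- point_to_cell(grid, receptors$x, receptors$y)
  counts <- table(receptors$cell[receptors$day == receptors$day[1]])
  missing <- setdiff(seq_len(n_cells(grid)), as.integer(names(counts)))
  if (length(missing))
    stop("cell(s) with zero receptors: ", paste(missing, collapse = ", "),
         call. = FALSE)
  agg <- rowsum(receptors$value, interaction(receptors$cell, receptors$day,
                                             drop = TRUE, lex.order = TRUE))
  n <- rowsum(rep(1, nrow(receptors)),
              interaction(receptors$cell, receptors$day,
                          drop = TRUE, lex.order = TRUE))
  keys <- do.call(rbind, strsplit(rownames(agg), ".", fixed = TRUE))
  out <- data.frame(cell = as.integer(keys[, 1]), day = as.integer(keys[, 2]),
                    value = agg[, 1] / n[, 1])
  out <- out[order(out$cell, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove the cell-average on-road contribution from the coarse field
#'
#' Computes `coarse_total - cell_average_onroad` per (cell, day). Negative
#' differences are retained here; the zero-out rule is applied at
#' [combine_hybrid()] after interpolation.
#'
#' @param cmaq_tot Grid field of coarse totals.
#' @param gavg Grid field of cell-averaged dispersion values.
#' @return Grid field of differences (may be negative).
#' @export
subtract_onroad <- function(cmaq_tot, gavg) {
  a <- cmaq_tot[order(cmaq_tot$cell, cmaq_tot$day), ]
  b <- gavg[order(gavg$cell, gavg$day), ]
  if (nrow(a) != nrow(b) || !all(a$cell == b$cell) || !all(a$day == b$day))
    stop("grid/date sets of the two fields do not match", call. = FALSE)
  data.frame(cell = a$cell, day = a$day, value = a$value - b$value)
}

#' Bilinearly interpolate a grid field to points
#'
#' Linear interpolation among the four surrounding cell-centre values; points
#' outside the hull of cell centres use the clamped (nearest-edge) coordinate,
#' which reduces to nearest-cell / linear-edge behaviour at the domain rim.
#'
#' @param field Grid field data.frame `cell`, `day`, `value` covering every
#'   cell of `grid`.
#' @param points data.frame with `point_id`, `x`, `y`.
#' @param grid A [grid_definition()].
#' @return Point field data.frame `point_id`, `day`, `value`.
#' @export
interpolate_to_points <- function(field, points, grid) {
  if (!nrow(field)) stop("empty grid field", call. = FALSE)
  m <- grid_field_matrix(field)         # [cells x days], cell-sorted
  if (nrow(m) != n_cells(grid) || anyNA(m))
    stop("grid field must cover every cell of the grid", call. = FALSE)
  cs <- grid$cell_size
  # fractional (col,row) coordinates in cell-centre space, clamped to hull
  gx <- (points$x - grid$origin_x) / cs - 0.5
  gy <- (points$y - grid$origin_y) / cs - 0.5
  gx <- pmin(pmax(gx, 0), grid$n_cols - 1)
  gy <- pmin(pmax(gy, 0), grid$n_rows - 1)
  i0 <- pmin(floor(gx), grid$n_cols - 2 + (grid$n_cols == 1))
  j0 <- pmin(floor(gy), grid$n_rows - 2 + (grid$n_rows == 1))
  i0 <- pmax(i0, 0); j0 <- pmax(j0, 0)
  wx <- gx - i0
  wy <- gy - j0
  if (grid$n_cols == 1) wx <- 0 * wx
  if (grid$n_rows == 1) wy <- 0 * wy
  id00 <- j0 * grid$n_cols + i0 + 1
  id10 <- id00 + (grid$n_cols > 1)
  id01 <- id00 + if (grid$n_rows > 1) grid$n_cols else 0
  id11 <- id01 + (grid$n_cols > 1)
  vals <- (1 - wx) * (1 - wy) * m[id00, , drop = FALSE] +
          wx * (1 - wy) * m[id10, , drop = FALSE] +
          (1 - wx) * wy * m[id01, , drop = FALSE] +
          wx * wy * m[id11, , drop = FALSE]
  rownames(vals) <- points$point_id
  matrix_to_point_field(vals, ids = points$point_id)
}

#' Combine interpolated difference and fine-scale on-road field
#'
#' The fused estimate is `diff + onroad` where the interpolated difference is
#' non-negative; where the difference is negative (the two models' biases
#' produced a negative road-free coarse field) the fused estimate falls back
#' to the fine-scale on-road value alone (the zero-out rule).
#'
#' @param diff_pts Point field of interpolated differences (may be negative).
#' @param onroad_pts Point field of non-negative fine-scale on-road values at
#'   the same (point, day) keys.
#' @return Point field of fused values (always `>= onroad`).
#' @export
combine_hybrid <- function(diff_pts, onroad_pts) {
  a <- diff_pts[order(diff_pts$point_id, diff_pts$day), ]
  b <- onroad_pts[order(onroad_pts$point_id, onroad_pts$day), ]
  if (nrow(a) != nrow(b) || !all(a$point_id == b$point_id) ||
      !all(a$day == b$day))
    stop("point/date sets of the two fields do not match", call. = FALSE)
  if (any(b$value < 0))
    stop("on-road field must be non-negative", call. = FALSE)
  data.frame(point_id = a$point_id, day = a$day,
             value = ifelse(a$value >= 0, a$value + b$value, b$value))
}

#' Fit an NO2/NOx yield polynomial from near-road pairs
#'
#' Fits the yield `no2/nox` as a degree-4 polynomial in `nox` by least
#' squares, the empirical transform used to turn fused NOx fields into NO2.
#' The observed NOx range is stored and inputs are clamped to it on
#' evaluation, preventing wild extrapolation of a quartic.
#'
#' @param nox,no2 Paired near-road observations; `nox` must be positive and
#'   at least 20 pairs are required.
#' @return Object of class `no2_yield` (coefficients c0..c4, fitted range).
#' @export
fit_no2_yield <- function(nox, no2) {
  if (length(nox) != length(no2)) stop("length mismatch", call. = FALSE)
  if (any(nox <= 0)) stop("all `nox` values must be > 0", call. = FALSE)
  if (length(nox) < 20) stop("need at least 20 pairs", call. = FALSE)
  yield <- no2 / nox
  fit <- stats::lm(yield ~ poly(nox, 4, raw = TRUE))
  structure(list(coefficients = unname(stats::coef(fit)),
                 range = range(nox)),
            class = "no2_yield")
}

#' @export
print.no2_yield <- function(x, ...) {
  cat("<no2_yield> degree-4 yield polynomial, NOx range [",
      format(x$range[1]), ", ", format(x$range[2]), "]\n", sep = "")
  invisible(x)
}

#' Transform NOx concentrations to NO2 via a fitted yield polynomial
#'
#' `no2 = nox * clip(poly(clamp(nox)), 0, 1)`: the input is clamped to the
#' fitted range before evaluating the polynomial, and the yield is clipped to
#' `[0, 1]` so the output always lies in `[0, nox]`.
#'
#' @param nox Non-negative NOx values.
#' @param yield An object from [fit_no2_yield()] (or a list with
#'   `coefficients` c0..c4 and `range`).
#' @return NO2 values, same length as `nox`.
#' @export
nox_to_no2 <- function(nox, yield) {
  if (any(nox < 0)) stop("`nox` must be >= 0", call. = FALSE)
  xc <- pmin(pmax(nox, yield$range[1]), yield$range[2])
  co <- yield$coefficients
  y <- co[1] + co[2] * xc + co[3] * xc^2 + co[4] * xc^3 + co[5] * xc^4
  y <- pmin(pmax(y, 0), 1)
  nox * y
}
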
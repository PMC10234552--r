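# RAMP (Regionalized Air quality Model Performance) bias correction: for each
# coarse cell, pair daily model values with observations at the nearest
# monitoring sites, stratify the pairs into ten equal-count bins of increasing
# predicted value, take the mean observed value per bin, safeguard the
# resulting calibration curve to be monotone (anchored centre-out at the
# grand observed mean), and apply the piecewise-linear curve to model values.

#' Select the monitoring sites nearest a cell
#'
#' Euclidean distance from the cell centroid; ties broken by ascending site
#' id. If fewer than `n` sites exist, all are returned. The published
#' operating points are 50 sites for PM2.5 (sparser one-in-three sampling)
#' and 10 for NO2.
#'
#' @param cell Cell id.
#' @param grid A [grid_definition()].
#' @param sites data.frame `site_id`, `x`, `y`.
#' @param n Number of sites to select.
#' @return The selected rows of `sites`, nearest first.
#' @export
select_sites <- function(cell, grid, sites, n) {
  if (!nrow(sites)) stop("empty site list", call. = FALSE)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  cc <- cell_centroids(grid)
  cx <- cc$x[cc$cell == cell]; cy <- cc$y[cc$cell == cell]
  d <- sqrt((sites$x - cx)^2 + (sites$y - cy)^2)
  ord <- order(d, sites$site_id)
  sites[ord[seq_len(min(n, nrow(sites)))], , drop = FALSE]
}

#' Pair model values with observations by site and day
#'
#' One pair per (site, day) where both a model value and an observation
#' exist; records missing on either side produce no pair.
#'
#' @param model Point field data.frame `point_id`, `day`, `value` evaluated at
#'   site locations, keyed by site id.
#' @param observations data.frame `site_id`, `day`, `value`.
#' @param site_ids Optional site ids to restrict the pairing to.
#' @return data.frame `site_id`, `day`, `observed`, `predicted`.
#' @export
pair_daily <- function(model, observations, site_ids = NULL) {
  if (!is.null(site_ids)) {
    model <- model[model$point_id %in% site_ids, , drop = FALSE]
    observations <- observations[observations$site_id %in% site_ids, ,
                                 drop = FALSE]
  }
  m <- data.frame(site_id = model$point_id, day = model$day,
                  predicted = model$value)
  o <- data.frame(site_id = observations$site_id, day = observations$day,
                  observed = observations$value)
  out <- merge(o, m, by = c("site_id", "day"))
  out <- out[order(out$site_id, out$day), c("site_id", "day", "observed",
                                            "predicted")]
  rownames(out) <- NULL
  out
}

#' Fit a decile-bin calibration curve
#'
#' Sorts pairs by predicted value (stable, so ties keep rank order), splits
#' them into `n_bins` contiguous rank-based bins of near-equal size (the
#' remainder spread over the lowest bins), and records per bin the mean
#' predicted value (node x) and the mean observed value (node value,
#' `lambda1`), along with the grand mean of all observed values
#' (`lambda1_m`). If every predicted value is identical the curve is flagged
#' degenerate and collapses to the constant `lambda1_m`.
#'
#' @param pairs data.frame with `observed`, `predicted`.
#' @param n_bins Number of bins (default 10, i.e. deciles).
#' @param min_pairs Minimum pair count (default 100); fewer pairs is an
#'   error, signalling the caller to fall back to a pooled curve.
#' @param cell Optional cell id stored on the curve.
#' @return Object of class `ramp_curve`: `x`, `lambda1` (length `n_bins`),
#'   `lambda1_m`, `n_pairs`, `degenerate`, `monotone`, `cell`.
#' @export
fit_ramp <- function(pairs, n_bins = 10L, min_pairs = 100L, cell = NA) {
  n <- nrow(pairs)
  if (n < min_pairs)
    stop("only ", n, " pairs (< min_pairs = ", min_pairs,
         "); fall back to a pooled all-sites curve", call. = FALSE)
  ord <- order(pairs$predicted)           # radix: stable for ties
  pred <- pairs$predicted[ord]
  obs <- pairs$observed[ord]
  base <- n %/% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, n %% n_bins),
                                 rep(0L, n_bins - n %% n_bins))
  bin <- rep(seq_len(n_bins), times = sizes)
  x <- as.vector(tapply(pred, bin, mean))
  lam <- as.vector(tapply(obs, bin, mean))
  lam_m <- mean(pairs$observed)
  degen <- isTRUE(diff(range(pairs$predicted)) == 0)
  if (degen) lam <- rep(lam_m, n_bins)
  structure(list(cell = cell, x = x, lambda1 = lam, lambda1_m = lam_m,
                 n_pairs = n, degenerate = degen, monotone = FALSE),
            class = "ramp_curve")
}

#' @export
print.ramp_curve <- function(x, ...) {
  cat(sprintf(
    "<ramp_curve> cell %s, %d pairs, lambda1_m = %.4g%s%s\n",
    format(x$cell), x$n_pairs, x$lambda1_m,
    if (x$degenerate) ", degenerate" else "",
    if (x$monotone) ", safeguarded" else ""))
  invisible(x)
}

#' Centre-out monotonicity safeguard for a calibration curve
#'
#' Anchors the curve at the grand observed mean: the 5th-bin node is capped
#' at `lambda1_m` and the 6th-bin node floored at it; then a sweep from the
#' centre outwards clamps each lower node from above by its right neighbour
#' (k = 5..2) and each upper node from below by its left neighbour
#' (k = 7..10). The result is non-decreasing with
#' `node[5] <= lambda1_m <= node[6]`, which preserves the ordinality of
#' estimates corrected by the same curve.
#'
#' @param curve A `ramp_curve`.
#' @return The safeguarded curve (`monotone = TRUE`).
#' @export
enforce_monotone <- function(curve) {
  lam <- curve$lambda1
  m <- curve$lambda1_m
  nb <- length(lam)
  lo <- nb %/% 2                      # 5 for deciles
  hi <- lo + 1L
  if (lam[lo] > m) lam[lo] <- m
  if (lo >= 2L)
    for (k in seq(lo, 2L)) if (lam[k - 1L] > lam[k]) lam[k - 1L] <- lam[k]
  if (lam[hi] < m) lam[hi] <- m
  if (hi + 1L <= nb)
    for (k in seq(hi + 1L, nb)) if (lam[k] < lam[k - 1L]) lam[k] <- lam[k - 1L]
  curve$lambda1 <- lam
  curve$monotone <- TRUE
  curve
}

#' Apply a calibration curve to model values
#'
#' Piecewise-linear interpolation through the `(x, lambda1)` nodes; beyond
#' the outer nodes the terminal segment's slope is extended. Nodes sharing an
#' x-position are merged into a single node whose value is their mean; a
#' degenerate (single-node) curve returns the constant `lambda1_m`. Results
#' are floored at zero.
#'
#' @param curve A safeguarded `ramp_curve` (see [enforce_monotone()]).
#' @param values Numeric model values to correct.
#' @return Corrected values, same length.
#' @export
apply_ramp <- function(curve, values) {
  if (!isTRUE(curve$monotone))
    stop("apply the monotonicity safeguard first (enforce_monotone)",
         call. = FALSE)
  if (curve$degenerate)
    return(pmax(rep(curve$lambda1_m, length(values)), 0))
  x <- curve$x; y <- curve$lambda1
  if (anyDuplicated(x)) {
    y <- as.vector(tapply(y, x, mean))
    x <- sort(unique(x))
  }
  if (length(x) == 1L) return(pmax(rep(y, length(values)), 0))
  out <- stats::approx(x, y, xout = values, rule = 2)$y
  n <- length(x)
  s_lo <- (y[2] - y[1]) / (x[2] - x[1])
  s_hi <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  below <- values < x[1]
  above <- values > x[n]
  out[below] <- y[1] + s_lo * (values[below] - x[1])
  out[above] <- y[n] + s_hi * (values[above] - x[n])
  pmax(out, 0)
}

#' Fit safeguarded calibration curves for every grid cell
#'
#' For each cell, pairs daily model values and observations at the `n_sites`
#' nearest monitors and fits the decile-bin curve with the monotonicity
#' safeguard. Cells that cannot reach `min_pairs` pairs use a pooled curve
#' fitted on all sites' pairs (an error if even the pool is too small).
#'
#' @param model Point field of model values at site locations (point_id =
#'   site_id).
#' @param observations data.frame `site_id`, `day`, `value`.
#' @param sites data.frame `site_id`, `x`, `y`.
#' @param grid A [grid_definition()].
#' @param n_sites Sites per cell (50 for PM2.5, 10 for NO2 by default
#'   config).
#' @param n_bins,min_pairs See [fit_ramp()].
#' @return Named list of `ramp_curve`s, one per cell id.
#' @export
fit_ramp_curves <- function(model, observations, sites, grid,
                            n_sites = 50L, n_bins = 10L, min_pairs = 100L) {
  pooled <- NULL
  curves <- vector("list", n_cells(grid))
  names(curves) <- as.character(seq_len(n_cells(grid)))
  for (cell in seq_len(n_cells(grid))) {
    sel <- select_sites(cell, grid, sites, n_sites)
    pairs <- pair_daily(model, observations, sel$site_id)
    curve <- tryCatch(
      fit_ramp(pairs, n_bins = n_bins, min_pairs = min_pairs, cell = cell),
      error = function(e) {
        if (is.null(pooled)) {
          all_pairs <- pair_daily(model, observations)
          pooled <<- fit_ramp(all_pairs, n_bins = n_bins,
                              min_pairs = min_pairs, cell = "pooled")
        }
        p <- pooled; p$cell <- cell; p
      })
    curves[[cell]] <- enforce_monotone(curve)
  }
  curves
}

#' Correct a point field with per-cell calibration curves
#'
#' Each point's values are corrected with the curve of the cell containing
#' the point. In `"daily"` mode every daily value is corrected (annual means
#' are then means of corrected dailies); in `"annual"` mode the caller passes
#' annual values directly.
#'
#' @param field Point field `point_id`, `day`, `value`.
#' @param points data.frame `point_id`, `x`, `y` locating every point.
#' @param curves Named list of safeguarded curves keyed by cell id.
#' @param grid A [grid_definition()].
#' @return Corrected point field.
#' @export
correct_field <- function(field, points, curves, grid) {
  cell <- point_to_cell(grid, points$x, points$y)
  if (anyNA(cell)) stop("point(s) outside the grid", call. = FALSE)
  cell_of <- cell[match(field$point_id, points$point_id)]
  out <- field
  for (cl in unique(cell_of)) {
    curve <- curves[[as.character(cl)]]
    if (is.null(curve)) stop("no curve for cell ", cl, call. = FALSE)
    idx <- which(cell_of == cl)
    out$value[idx] <- apply_ramp(curve, field$value[idx])
  }
  out
}

#' Annual mean of a point field
#' @param field Point field `point_id`, `day`, `value`.
#' @return data.frame `point_id`, `value` (mean over days present).
#' @export
annual_mean <- function(field) {
  agg <- rowsum(field$value, field$point_id)
  n <- rowsum(rep(1, nrow(field)), field$point_id)
  data.frame(point_id = as.integer(rownames(agg)), value = agg[, 1] / n[, 1],
             row.names = NULL)
}

#' Re-grid point values to the coarse grid
#'
#' Unweighted mean of point values within each cell; cells containing no
#' points are returned as missing. Used to compare the fine-scale corrected
#' field against itself at coarse resolution.
#'
#' @param values data.frame `point_id`, `value` (e.g. annual means).
#' @param points data.frame `point_id`, `x`, `y`.
#' @param grid A [grid_definition()].
#' @return data.frame `cell`, `value` for all cells (NA where empty).
#' @export
regrid_to_coarse <- function(values, points, grid) {
  cell <- point_to_cell(grid, points$x, points$y)
  cell <- cell[match(values$point_id, points$point_id)]
  agg <- rowsum(values$value, cell)
  n <- rowsum(rep(1, nrow(values)), cell)
  out <- data.frame(cell = seq_len(n_cells(grid)), value = NA_real_)
  out$value[as.integer(rownames(agg))] <- agg[, 1] / n[, 1]
  out
}
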
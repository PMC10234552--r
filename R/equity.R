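# Exposure equity: population-weighted exposure by race group, the Exposure
# Inequity Ratio (EIR, Minority over White population-weighted exposure), its
# distribution across administrative units, and distance-from-road profiles.

.race_cols <- c("pop_white", "pop_black", "pop_asian", "pop_hispanic",
                "pop_other")
.minority_cols <- setdiff(.race_cols, "pop_white")

#' Distance from block centroids to the nearest road
#'
#' Minimum point-to-segment Euclidean distance over all road segments. With
#' an empty road list all distances are `Inf` (with a warning).
#'
#' @param points data.frame with `x`, `y`.
#' @param roads Roads data.frame (`x0`, `y0`, `x1`, `y1`).
#' @return Numeric vector of distances (m).
#' @export
distance_to_nearest_road <- function(points, roads) {
  if (!nrow(roads)) {
    warning("no roads: distances are infinite")
    return(rep(Inf, nrow(points)))
  }
  d <- rep(Inf, nrow(points))
  for (j in seq_len(nrow(roads))) {
    dj <- dist_point_segment(points$x, points$y, roads$x0[j], roads$y0[j],
                             roads$x1[j], roads$y1[j])
    d <- pmin(d, dj)
  }
  d
}

#' Population-weighted exposure
#'
#' `sum(pop_i * conc_i) / sum(pop_i)`; an error if the group population is
#' zero everywhere.
#'
#' @param pop Population weights per block.
#' @param conc Annual concentration per block.
#' @return Scalar weighted mean.
#' @export
pop_weighted_exposure <- function(pop, conc) {
  if (length(pop) != length(conc)) stop("length mismatch", call. = FALSE)
  tot <- sum(pop)
  if (tot <= 0) stop("zero group population", call. = FALSE)
  sum(pop * conc) / tot
}

#' Exposure inequity ratio
#'
#' Population-weighted exposure of the Minority group (all non-White race
#' groups combined) divided by that of the White group. Per-race-group
#' ratios against White are also returned.
#'
#' @param blocks Blocks data.frame with the race population columns.
#' @param conc Annual concentration per block (aligned with `blocks` rows).
#' @return List: `eir`, `pw_minority`, `pw_white`, `by_group` (named vector
#'   of group/White ratios).
#' @export
eir <- function(blocks, conc) {
  pw_w <- pop_weighted_exposure(blocks$pop_white, conc)
  pop_min <- rowSums(as.matrix(blocks[.minority_cols]))
  pw_m <- pop_weighted_exposure(pop_min, conc)
  by_group <- vapply(.minority_cols, function(cl) {
    if (sum(blocks[[cl]]) > 0)
      pop_weighted_exposure(blocks[[cl]], conc) / pw_w
    else NA_real_
  }, 0.0)
  names(by_group) <- sub("^pop_", "", .minority_cols)
  list(eir = pw_m / pw_w, pw_minority = pw_m, pw_white = pw_w,
       by_group = by_group)
}

#' Distribution of unit-level exposure inequity ratios
#'
#' Computes the EIR within each administrative unit (county, tract or block
#' group) and summarises the distribution across units: count, mean, sd, and
#' the 50/95/99/99.9 percentiles (linear interpolation between order
#' statistics). Units where either the White or the Minority population is
#' zero are excluded; the exclusion count is reported.
#'
#' @param blocks Blocks data.frame.
#' @param conc Annual concentration per block.
#' @param level `"county"`, `"tract"` or `"block_group"`.
#' @return List: `level`, `by_unit` (unit id, EIR, populations), `summary`
#'   (count/mean/std/percentiles), `n_excluded`.
#' @export
eir_by_unit <- function(blocks, conc,
                        level = c("county", "tract", "block_group")) {
  level <- match.arg(level)
  key <- switch(level, county = blocks$county_id, tract = blocks$tract_id,
                block_group = blocks$block_group_id)
  pop_min <- rowSums(as.matrix(blocks[.minority_cols]))
  agg <- rowsum(cbind(w = blocks$pop_white, m = pop_min,
                      wc = blocks$pop_white * conc, mc = pop_min * conc),
                key)
  units <- data.frame(unit_id = as.numeric(rownames(agg)),
                      pop_white = agg[, "w"], pop_minority = agg[, "m"],
                      row.names = NULL)
  ok <- units$pop_white > 0 & units$pop_minority > 0
  units$eir <- NA_real_
  units$eir[ok] <- (agg[ok, "mc"] / agg[ok, "m"]) /
                   (agg[ok, "wc"] / agg[ok, "w"])
  e <- units$eir[ok]
  qs <- if (length(e)) stats::quantile(e, c(0.5, 0.95, 0.99, 0.999),
                                       type = 7, names = FALSE)
        else rep(NA_real_, 4)
  summary <- data.frame(
    count = length(e), mean = mean(e), std = stats::sd(e),
    p50 = qs[1], p95 = qs[2], p99 = qs[3], p999 = qs[4]
  )
  if (length(e) == 1) summary$std <- 0
  list(level = level, by_unit = units, summary = summary,
       n_excluded = sum(!ok))
}

#' Exposure inequity profile by distance from road
#'
#' Groups blocks into half-open distance bins `[k*w, (k+1)*w)` (default 10 m)
#' and reports per bin the White and Minority population-weighted exposures
#' and their ratio. Bins where either group has zero population get `NA`;
#' bins beyond `max_confident_distance` (default 2 km) are flagged
#' low-confidence, since few blocks and small populations make the ratio
#' noisy there.
#'
#' @param blocks Blocks data.frame with `distance_to_road`.
#' @param conc Annual concentration per block.
#' @param width Bin width (m).
#' @param max_confident_distance Flag threshold (m).
#' @return data.frame `bin_start`, `pw_white`, `pw_minority`, `eir`,
#'   `pop_white`, `pop_minority`, `low_confidence`.
#' @export
eir_by_distance <- function(blocks, conc, width = 10,
                            max_confident_distance = 2000) {
  key <- floor(blocks$distance_to_road / width) * width
  pop_min <- rowSums(as.matrix(blocks[.minority_cols]))
  agg <- rowsum(cbind(w = blocks$pop_white, m = pop_min,
                      wc = blocks$pop_white * conc, mc = pop_min * conc),
                key)
  out <- data.frame(bin_start = as.numeric(rownames(agg)), row.names = NULL)
  w <- agg[, "w"]; m <- agg[, "m"]
  out$pw_white <- ifelse(w > 0, agg[, "wc"] / w, NA_real_)
  out$pw_minority <- ifelse(m > 0, agg[, "mc"] / m, NA_real_)
  out$eir <- out$pw_minority / out$pw_white
  out$pop_white <- w
  out$pop_minority <- m
  out$low_confidence <- out$bin_start >= max_confident_distance
  out <- out[order(out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
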
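# Synthetic world generator: grid, roads, monitors, census blocks, and the
# true / model-biased / observed concentration fields the fusion pipeline
# consumes. Everything is deterministic given (config, seed); each stochastic
# stage uses its own derived seed (see derive_seed) so stages can be
# regenerated independently.

#' Build a seeded synthetic study domain
#'
#' Generates a world with the statistical structure the analysis assumes: a
#' regular coarse grid, long straight road segments with per-segment emission
#' rates, monitoring sites (a configurable fraction sited near roads),
#' census blocks nested in block groups, tracts and counties, race-stratified
#' block populations with configurable near-road Minority enrichment, and
#' per-county baseline mortality rates.
#'
#' @param config A `roadfusion_config` from [build_config()].
#' @param seed Master integer seed.
#' @return A list of class `synthetic_world` with elements `grid`, `roads`,
#'   `monitors`, `blocks`, `counties`, `bias`, `config`, `seed`.
#' @export
build_domain <- function(config, seed) {
  validate_config(config)
  grid <- grid_definition(config$grid$origin_x, config$grid$origin_y,
                          config$grid$cell_size, config$grid$n_rows,
                          config$grid$n_cols)
  ext <- grid_extent(grid)

  roads <- make_roads(grid, config, derive_seed(seed, "roads"))
  monitors <- make_monitors(grid, roads, config, derive_seed(seed, "monitors"))
  blocks <- make_blocks(grid, roads, config, derive_seed(seed, "blocks"))

  world <- list(grid = grid, roads = roads, monitors = monitors,
                blocks = blocks, config = config, seed = seed)
  class(world) <- "synthetic_world"

  world$blocks <- assign_population(world, theta = config$blocks$theta,
                                    seed = seed)
  # per-county baseline all-cause mortality rate, ages >= 25 (deaths/person-yr)
  set.seed(derive_seed(seed, "baseline"))
  county_ids <- sort(unique(world$blocks$county_id))
  rr <- config$baseline_rate_range
  world$counties <- data.frame(
    county_id = county_ids,
    baseline_rate = stats::runif(length(county_ids), rr[1], rr[2])
  )
  world$bias <- cell_bias_params(grid, config$bias)
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_world> %d cells, %d roads, %d monitors, ",
                     "%d blocks, %d days, pollutant %s, seed %d\n"),
              n_cells(x$grid), nrow(x$roads), nrow(x$monitors),
              nrow(x$blocks), x$config$n_days, x$config$pollutant,
              x$seed))
  invisible(x)
}

# long chords across the domain: endpoints on two random distinct edges
make_roads <- function(grid, config, seed) {
  n <- config$roads$n_roads
  if (n == 0L) {
    return(data.frame(road_id = integer(), x0 = numeric(), y0 = numeric(),
                      x1 = numeric(), y1 = numeric(),
                      emission_rate = numeric(), road_class = character()))
  }
  set.seed(seed)
  ext <- grid_extent(grid)
  edge_point <- function(edge, t) {
    # edges numbered 1 bottom, 2 right, 3 top, 4 left
    x <- switch(edge,
                ext["xmin"] + t * (ext["xmax"] - ext["xmin"]),
                ext["xmax"],
                ext["xmin"] + t * (ext["xmax"] - ext["xmin"]),
                ext["xmin"])
    y <- switch(edge,
                ext["ymin"],
                ext["ymin"] + t * (ext["ymax"] - ext["ymin"]),
                ext["ymax"],
                ext["ymin"] + t * (ext["ymax"] - ext["ymin"]))
    c(x, y)
  }
  classes <- c("interstate", "principal_artery", "minor_artery",
               "major_collector")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    e1 <- sample.int(4L, 1L)
    e2 <- sample(setdiff(1:4, e1), 1L)
    p1 <- edge_point(e1, stats::runif(1))
    p2 <- edge_point(e2, stats::runif(1))
    out[[i]] <- data.frame(road_id = i, x0 = p1[1], y0 = p1[2],
                           x1 = p2[1], y1 = p2[2])
  }
  roads <- do.call(rbind, out)
  roads$emission_rate <- stats::runif(n, config$roads$emission_min,
                                      config$roads$emission_max)
  roads$road_class <- sample(classes, n, replace = TRUE)
  rownames(roads) <- NULL
  roads
}

make_monitors <- function(grid, roads, config, seed) {
  set.seed(seed)
  n <- config$monitors$n_monitors
  ext <- grid_extent(grid)
  n_near <- if (nrow(roads)) round(n * config$monitors$near_road_fraction) else 0L
  xy <- matrix(NA_real_, n, 2)
  if (n_near > 0L) {
    pts <- points_near_roads(roads, n_near, min_off = 10, max_off = 150)
    xy[seq_len(n_near), ] <- pts
  }
  idx <- seq.int(n_near + 1L, length.out = n - n_near)
  xy[idx, 1] <- stats::runif(length(idx), ext["xmin"], ext["xmax"])
  xy[idx, 2] <- stats::runif(length(idx), ext["ymin"], ext["ymax"])
  xy[, 1] <- pmin(pmax(xy[, 1], ext["xmin"]), ext["xmax"])
  xy[, 2] <- pmin(pmax(xy[, 2], ext["ymin"]), ext["ymax"])
  sched <- rep("daily", n)
  n13 <- round(n * config$monitors$one_in_three_fraction)
  if (n13 > 0L) sched[sample.int(n, n13)] <- "one_in_three"
  data.frame(site_id = seq_len(n), x = xy[, 1], y = xy[, 2],
             pollutant = config$pollutant, schedule = sched)
}

# sample points offset perpendicular from random positions on random segments
points_near_roads <- function(roads, n, min_off, max_off) {
  j <- sample.int(nrow(roads), n, replace = TRUE)
  t <- stats::runif(n)
  dx <- roads$x1[j] - roads$x0[j]
  dy <- roads$y1[j] - roads$y0[j]
  len <- sqrt(dx^2 + dy^2)
  px <- roads$x0[j] + t * dx
  py <- roads$y0[j] + t * dy
  off <- stats::runif(n, min_off, max_off) * sample(c(-1, 1), n, replace = TRUE)
  cbind(px - off * dy / len, py + off * dx / len)
}

make_blocks <- function(grid, roads, config, seed) {
  set.seed(seed)
  n <- config$blocks$n_blocks
  ext <- grid_extent(grid)
  n_near <- if (nrow(roads)) round(n * config$blocks$near_fraction) else 0L
  xy <- matrix(NA_real_, n, 2)
  if (n_near > 0L) {
    xy[seq_len(n_near), ] <- points_near_roads(roads, n_near,
                                               min_off = 5, max_off = 250)
  }
  idx <- seq.int(n_near + 1L, length.out = n - n_near)
  xy[idx, 1] <- stats::runif(length(idx), ext["xmin"], ext["xmax"])
  xy[idx, 2] <- stats::runif(length(idx), ext["ymin"], ext["ymax"])
  xy[, 1] <- pmin(pmax(xy[, 1], ext["xmin"]), ext["xmax"])
  xy[, 2] <- pmin(pmax(xy[, 2], ext["ymin"]), ext["ymax"])

  blocks <- data.frame(block_id = seq_len(n), x = xy[, 1], y = xy[, 2])
  blocks <- cbind(blocks, admin_ids(grid, xy[, 1], xy[, 2], config$admin))
  blocks$distance_to_road <- if (nrow(roads))
    distance_to_nearest_road(blocks, roads) else rep(Inf, n)
  blocks
}

# nested admin geography from regular partitions of the domain; nesting is
# guaranteed because each finer partition subdivides the coarser one
admin_ids <- function(grid, x, y, admin) {
  ext <- grid_extent(grid)
  part <- function(per_side) {
    i <- pmin(floor((x - ext["xmin"]) / (ext["xmax"] - ext["xmin"]) * per_side),
              per_side - 1)
    j <- pmin(floor((y - ext["ymin"]) / (ext["ymax"] - ext["ymin"]) * per_side),
              per_side - 1)
    as.integer(j * per_side + i + 1)
  }
  county <- part(admin$counties_per_side)
  tract <- part(admin$tracts_per_side)
  bg <- part(admin$block_groups_per_side)
  data.frame(county_id = county,
             tract_id = county * 10000L + tract,
             block_group_id = (county * 10000L + tract) * 1000L + bg)
}

#' Assign race-stratified population to blocks
#'
#' Draws each block's total population from a lognormal distribution and
#' splits it across race groups \{White, Black, Asian, Hispanic, Other\} with
#' a multinomial draw, so group counts always sum to the block total. The
#' Minority (non-White) share follows
#' `plogis(base_logit + theta * exp(-distance_to_road / 200))`: `theta > 0`
#' enriches Minority share near roads, `theta = 0` makes race independent of
#' road proximity. The fraction of residents aged 25+ is drawn once per tract
#' and copied to all blocks in the tract.
#'
#' @param world A `synthetic_world` (its `blocks` must carry
#'   `distance_to_road` and `tract_id`).
#' @param theta Near-road Minority enrichment strength (logit units).
#' @param seed Master seed; population and tract-fraction streams are derived.
#' @return The blocks data.frame with population columns added.
#' @export
assign_population <- function(world, theta = world$config$blocks$theta,
                              seed = world$seed) {
  blocks <- world$blocks
  cfg <- world$config$blocks
  set.seed(derive_seed(seed, "population"))
  n <- nrow(blocks)
  total <- as.integer(pmax(round(stats::rlnorm(n, cfg$pop_meanlog,
                                               cfg$pop_sdlog)), 0))
  d <- blocks$distance_to_road
  d[!is.finite(d)] <- 1e9
  p_min <- stats::plogis(cfg$base_logit + theta * exp(-d / 200))
  mix <- cfg$minority_mix / sum(cfg$minority_mix)
  groups <- matrix(0L, n, 5,
                   dimnames = list(NULL, c("pop_white", "pop_black",
                                           "pop_asian", "pop_hispanic",
                                           "pop_other")))
  for (i in seq_len(n)) {
    if (total[i] > 0) {
      pr <- c(1 - p_min[i], p_min[i] * mix)
      groups[i, ] <- stats::rmultinom(1, total[i], pr)[, 1]
    }
  }
  blocks$pop_total <- total
  blocks <- cbind(blocks, as.data.frame(groups))

  set.seed(derive_seed(seed, "frac25"))
  tr <- sort(unique(blocks$tract_id))
  f25 <- stats::runif(length(tr), cfg$frac25_range[1], cfg$frac25_range[2])
  blocks$frac_25plus <- f25[match(blocks$tract_id, tr)]
  blocks
}

#' Regional background concentration
#'
#' Smooth deterministic field: a constant plus two low-spatial-frequency plane
#' waves plus a seasonal sinusoid, floored at zero:
#' `base + sum_k A_k sin(2*pi*(x*cos(th_k) + y*sin(th_k))/lambda_k + phi_k)
#'  + S * sin(2*pi*(day-1)/n_days + phi_s)`.
#' Its spatial gradient is bounded by `sum_k A_k * 2*pi/lambda_k`.
#'
#' @param world A `synthetic_world`.
#' @param points data.frame with columns `x`, `y`.
#' @param days Integer vector of day indices in `1:n_days`.
#' @return Matrix `[n_points x n_days]` of concentrations.
#' @export
simulate_background <- function(world, points, days) {
  cfg <- world$config$background
  n_days <- world$config$n_days
  if (any(days < 1L | days > n_days))
    stop("`days` outside the simulated year (1..", n_days, ")", call. = FALSE)
  spatial <- rep(cfg$base, nrow(points))
  for (k in seq_along(cfg$amplitudes)) {
    proj <- points$x * cos(cfg$angles[k]) + points$y * sin(cfg$angles[k])
    spatial <- spatial +
      cfg$amplitudes[k] * sin(2 * pi * proj / cfg$wavelengths[k] +
                              cfg$phases[k])
  }
  seasonal <- cfg$seasonal_amp * sin(2 * pi * (days - 1) / n_days +
                                     cfg$seasonal_phase)
  out <- outer(spatial, seasonal, `+`)
  out[out < 0] <- 0
  dimnames(out) <- list(NULL, paste0("d", days))
  out
}

# minimum distance from points to one segment, vectorised over points
dist_point_segment <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx^2 + dy^2
  if (len2 == 0) return(sqrt((px - x0)^2 + (py - y0)^2))
  t <- ((px - x0) * dx + (py - y0) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2)
}

#' Near-road concentration increment
#'
#' Exponential line-source kernel: the increment at a point is
#' `sum_j alpha * E_j * exp(-d_j / L)` over road segments `j`, with `d_j` the
#' point-to-segment distance. This reproduces the near-road premise that
#' traffic-related concentrations decay to background within roughly 150-200 m
#' of a major road (default decay length `L = 150` m).
#'
#' @param points data.frame with `x`, `y`.
#' @param roads Roads data.frame (`x0,y0,x1,y1,emission_rate`).
#' @param alpha Kernel scaling (> 0).
#' @param L Decay length in metres (> 0).
#' @return Numeric vector of increments, one per point (time-invariant).
#' @export
road_increment <- function(points, roads, alpha = 1, L = 150) {
  if (L <= 0) stop("`L` must be > 0", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  inc <- numeric(nrow(points))
  if (!nrow(roads)) return(inc)
  for (j in seq_len(nrow(roads))) {
    d <- dist_point_segment(points$x, points$y, roads$x0[j], roads$y0[j],
                            roads$x1[j], roads$y1[j])
    inc <- inc + alpha * roads$emission_rate[j] * exp(-d / L)
  }
  inc
}

#' True concentration field at points
#'
#' Truth = smooth regional background + near-road increment (no model bias,
#' no noise). This is the reference every emulated model is compared against.
#'
#' @inheritParams simulate_background
#' @return Matrix `[n_points x n_days]`.
#' @export
truth_field <- function(world, points, days) {
  bg <- simulate_background(world, points, days)
  inc <- road_increment(points, world$roads, world$config$decay$alpha,
                        world$config$decay$L)
  bg + inc
}

# smoothly varying per-cell bias coefficients for g_c(x) = a + b x + s x^2/(x+h)
cell_bias_params <- function(grid, bias_cfg) {
  cc <- cell_centroids(grid)
  ext <- grid_extent(grid)
  W <- ext["xmax"] - ext["xmin"]; H <- ext["ymax"] - ext["ymin"]
  u <- (cc$x - ext["xmin"]) / W
  v <- (cc$y - ext["ymin"]) / H
  data.frame(
    cell = cc$cell,
    a = bias_cfg$a + bias_cfg$a_range * sin(2 * pi * u) * cos(2 * pi * v),
    b = bias_cfg$b + bias_cfg$b_range * sin(2 * pi * (u + v) / 2),
    s = pmax(bias_cfg$s + bias_cfg$s_range * sin(2 * pi * v), 0),
    h = bias_cfg$h
  )
}

#' Emulate the coarse chemical-transport model field
#'
#' Averages the true field over a dense subgrid of points in each cell
#' (default 12 x 12, matching the 144-receptor lattice) and then distorts the
#' cell value with a smoothly varying nonhomogeneous, nonlinear bias
#' `g_c(x) = a_c + b_c * x + s_c * x^2 / (x + h)`, floored at zero. With
#' `bias$enabled = FALSE` (or `a=0, b=1, s=0`) the output is exactly the
#' subgrid truth mean.
#'
#' @param world A `synthetic_world`.
#' @param days Day indices.
#' @return Long data.frame `cell`, `day`, `value` (role: coarse total field).
#' @export
emulate_ctm <- function(world, days) {
  if (world$config$bias$h <= 0)
    stop("configuration error: bias$h must be > 0", call. = FALSE)
  rec <- cell_receptors(world$grid, world$config$receptors_per_side)
  tr <- truth_field(world, rec, days)
  k <- world$config$receptors_per_side^2
  cell_mean <- rowsum(tr, rec$cell) / k          # [n_cells x n_days]
  bias <- world$bias
  if (is.null(bias)) bias <- cell_bias_params(world$grid, world$config$bias)
  if (isTRUE(world$config$bias$enabled)) {
    x <- cell_mean
    cell_mean <- bias$a + bias$b * x + bias$s * x^2 / (x + bias$h)
    cell_mean[cell_mean < 0] <- 0
  }
  data.frame(
    cell = rep(as.integer(rownames(cell_mean)), times = length(days)),
    day = rep(as.integer(days), each = nrow(cell_mean)),
    value = as.vector(cell_mean)
  )
}

#' Emulate the near-road dispersion model at points
#'
#' The dispersion emulator returns the road increment times a lognormal
#' multiplicative error (dispersion models typically carry multiplicative
#' bias, e.g. overestimation under low-dispersion conditions). The multiplier
#' has configurable median (`dispersion$median_bias`, default 1.2) and log-sd
#' (`dispersion$sigma`); with `sigma = 0` every value is exactly
#' `median_bias * increment`. The error realisation is a counter-based hash of
#' (rounded point location, day, seed), so a given (point, day, seed) always
#' sees the same multiplier no matter how calls are batched.
#'
#' @param world A `synthetic_world`.
#' @param points data.frame with `x`, `y`.
#' @param days Day indices.
#' @param seed Seed (defaults to the world's master seed).
#' @return Matrix `[n_points x n_days]` of concentrations.
#' @export
emulate_dispersion <- function(world, points, days, seed = world$seed) {
  cfg <- world$config$dispersion
  if (cfg$sigma < 0)
    stop("configuration error: dispersion$sigma must be >= 0", call. = FALSE)
  inc <- road_increment(points, world$roads, world$config$decay$alpha,
                        world$config$decay$L)
  n_pts <- nrow(points); n_day <- length(days)
  if (cfg$sigma == 0) {
    mult <- matrix(cfg$median_bias, n_pts, n_day)
  } else {
    key_pt <- round(points$x) * 100003 + round(points$y)
    u <- hash_uniform(rep(key_pt, times = n_day),
                      rep(as.numeric(days), each = n_pts),
                      derive_seed(seed, "dispersion"))
    mult <- matrix(exp(log(cfg$median_bias) + cfg$sigma * stats::qnorm(u)),
                   n_pts, n_day)
  }
  out <- inc * mult
  dimnames(out) <- list(NULL, paste0("d", days))
  out
}

#' Generate monitor observations
#'
#' Observations are truth at the site location plus additive zero-mean
#' Gaussian noise, floored at zero. Sites on the `one_in_three` schedule
#' report only days 1, 4, 7, ... of the simulated year (the typical filter
#' sampling cadence for daily PM2.5).
#'
#' @param world A `synthetic_world`.
#' @param days Day indices.
#' @param noise_sd Observation noise sd; default from the config.
#' @param seed Master seed (observation stream is derived from it).
#' @return Long data.frame `site_id`, `day`, `value`.
#' @export
observe <- function(world, days, noise_sd = world$config$monitors$noise_sd,
                    seed = world$seed) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  mons <- world$monitors
  tr <- truth_field(world, mons, days)
  set.seed(derive_seed(seed, "observe"))
  noise <- matrix(stats::rnorm(length(tr), 0, noise_sd),
                  nrow(tr), ncol(tr))
  obs <- tr + if (noise_sd > 0) noise else 0
  obs[obs < 0] <- 0
  keep_day <- matrix(TRUE, nrow(tr), length(days))
  one3 <- mons$schedule == "one_in_three"
  if (any(one3)) {
    sched_days <- seq(1L, world$config$n_days, by = 3L)
    keep_day[one3, ] <- matrix(rep(days %in% sched_days, each = sum(one3)),
                               nrow = sum(one3))
  }
  idx <- which(keep_day, arr.ind = TRUE)
  out <- data.frame(site_id = mons$site_id[idx[, 1]],
                    day = as.integer(days[idx[, 2]]),
                    value = obs[idx])
  out <- out[order(out$site_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}
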
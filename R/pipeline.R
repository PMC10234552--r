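# End-to-end orchestration: simulate -> fuse -> RAMP -> evaluate -> health ->
# equity, with optional CSV output and a run manifest.

# point field of coarse cell values sampled at points (cell-constant field)
cell_values_at_points <- function(field, points, grid) {
  cell <- point_to_cell(grid, points$x, points$y)
  m <- grid_field_matrix(field)
  vals <- m[cell, , drop = FALSE]
  rownames(vals) <- points$point_id
  matrix_to_point_field(vals, ids = points$point_id)
}

# per-site annual means of observations and of a model point field over the
# days each site actually observed
annual_pairs <- function(observations, model) {
  m <- data.frame(site_id = model$point_id, day = model$day,
                  modeled = model$value)
  j <- merge(observations, m, by = c("site_id", "day"))
  obs_m <- rowsum(j$value, j$site_id)
  mod_m <- rowsum(j$modeled, j$site_id)
  n <- rowsum(rep(1, nrow(j)), j$site_id)
  data.frame(site_id = as.integer(rownames(obs_m)),
             observed = obs_m[, 1] / n[, 1],
             modeled = mod_m[, 1] / n[, 1], row.names = NULL)
}

fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full fusion / correction / assessment pipeline
#'
#' Builds the seeded synthetic world, emulates the coarse and dispersion
#' models, fuses them at block centroids, fits and applies the per-cell
#' calibration curves, evaluates all models at the monitors, computes
#' attributable mortality for each exposure model (coarse, fused, corrected,
#' and corrected-regridded-to-coarse) with county / distance aggregations and
#' model differences, and computes exposure inequity ratios nationally, per
#' administrative unit, and by distance from road.
#'
#' @param config A `roadfusion_config`.
#' @param seed Master integer seed.
#' @param out_dir Optional directory; when given, the main tables are written
#'   as CSV along with a `manifest.json` recording the config hash and seed.
#' @return A list with elements `world`, `annual` (per-block annual exposure
#'   by model), `curves`, `evaluation`, `health`, `equity`, `config`, `seed`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         out_dir = NULL) {
  world <- build_domain(config, seed)
  grid <- world$grid
  days <- seq_len(config$n_days)
  blocks <- world$blocks
  block_pts <- data.frame(point_id = blocks$block_id, x = blocks$x,
                          y = blocks$y)
  site_pts <- data.frame(point_id = world$monitors$site_id,
                         x = world$monitors$x, y = world$monitors$y,
                         site_id = world$monitors$site_id)

  # --- fusion ---------------------------------------------------------------
  cmaq <- emulate_ctm(world, days)
  rec <- cell_receptors(grid, config$receptors_per_side)
  disp_rec <- emulate_dispersion(world, rec, days)
  gavg_m <- rowsum(disp_rec, rec$cell) / config$receptors_per_side^2
  gavg <- data.frame(cell = rep(as.integer(rownames(gavg_m)), ncol(gavg_m)),
                     day = rep(days, each = nrow(gavg_m)),
                     value = as.vector(gavg_m))
  diff <- subtract_onroad(cmaq, gavg)

  cbc <- matrix_to_point_field(emulate_dispersion(world, block_pts, days),
                               ids = block_pts$point_id, days = days)
  hyb_blocks <- combine_hybrid(interpolate_to_points(diff, block_pts, grid),
                               cbc)

  disp_sites <- matrix_to_point_field(
    emulate_dispersion(world, site_pts, days),
    ids = site_pts$point_id, days = days)
  hyb_sites <- combine_hybrid(interpolate_to_points(diff, site_pts, grid),
                              disp_sites)

  # --- RAMP correction ------------------------------------------------------
  obs <- observe(world, days)
  curves <- fit_ramp_curves(hyb_sites, obs, site_pts, grid,
                            n_sites = config$ramp$n_sites,
                            n_bins = config$ramp$n_bins,
                            min_pairs = config$ramp$min_pairs)
  if (config$ramp$mode == "daily") {
    ramp_blocks <- correct_field(hyb_blocks, block_pts, curves, grid)
    ramp_sites <- correct_field(hyb_sites, site_pts, curves, grid)
    annual_ramp <- annual_mean(ramp_blocks)
  } else {
    ann_hyb <- annual_mean(hyb_blocks)
    ann_field <- data.frame(point_id = ann_hyb$point_id, day = 1L,
                            value = ann_hyb$value)
    annual_ramp <- annual_mean(correct_field(ann_field, block_pts, curves,
                                             grid))
    ramp_sites <- correct_field(hyb_sites, site_pts, curves, grid)
  }

  # --- per-block annual exposures by model ----------------------------------
  annual <- data.frame(block_id = blocks$block_id)
  truth_b <- truth_field(world, block_pts, days)
  annual$truth <- rowMeans(truth_b)
  ann_cmaq_b <- annual_mean(cell_values_at_points(cmaq, block_pts, grid))
  annual$cmaq <- ann_cmaq_b$value[match(blocks$block_id, ann_cmaq_b$point_id)]
  ann_hyb_b <- annual_mean(hyb_blocks)
  annual$hyb <- ann_hyb_b$value[match(blocks$block_id, ann_hyb_b$point_id)]
  annual$ramp_hyb <- annual_ramp$value[match(blocks$block_id,
                                             annual_ramp$point_id)]
  regrid <- regrid_to_coarse(
    data.frame(point_id = annual$block_id, value = annual$ramp_hyb),
    block_pts, grid)
  cell_of_block <- point_to_cell(grid, blocks$x, blocks$y)
  annual$ramp_hyb_coarse <- regrid$value[cell_of_block]

  # --- evaluation at monitors ----------------------------------------------
  cmaq_sites <- cell_values_at_points(cmaq, site_pts, grid)
  models_at_sites <- list(cmaq = cmaq_sites, hyb = hyb_sites,
                          ramp_hyb = ramp_sites)
  evaluation <- do.call(rbind, lapply(names(models_at_sites), function(nm) {
    p <- annual_pairs(obs, models_at_sites[[nm]])
    cbind(model = nm, evaluate_model(p$observed, p$modeled))
  }))

  # --- health impact --------------------------------------------------------
  crf <- if (config$pollutant == "pm25") pm25_crf() else no2_crf()
  rate <- world$counties$baseline_rate[match(blocks$county_id,
                                             world$counties$county_id)]
  to_ugm3 <- function(v) {
    if (config$pollutant == "no2") ppb_to_ugm3(v, config$health$ppb_to_ugm3)
    else v
  }
  health_block <- lapply(c("cmaq", "hyb", "ramp_hyb", "ramp_hyb_coarse"),
    function(nm) attributable_deaths(to_ugm3(annual[[nm]]), blocks$pop_total,
                                     blocks$frac_25plus, rate, crf))
  names(health_block) <- c("cmaq", "hyb", "ramp_hyb", "ramp_hyb_coarse")
  health_county <- lapply(health_block, aggregate_health, blocks = blocks,
                          by = "county")
  cmp_cmaq_ramp <- compare_models(health_county$cmaq, health_county$ramp_hyb)
  cmp_coarse_fine <- compare_models(health_county$ramp_hyb_coarse,
                                    health_county$ramp_hyb)
  w <- config$health$distance_bin_width
  health <- list(
    block = health_block,
    county = health_county,
    totals = do.call(rbind, lapply(names(health_block), function(nm) {
      cbind(model = nm, data.frame(t(colSums(health_block[[nm]]))))
    })),
    cmaq_vs_ramp = cmp_cmaq_ramp,
    coarse_vs_fine = cmp_coarse_fine,
    top_counties = top_counties(cmp_cmaq_ramp),
    distance_curve = mortality_by_distance_curve(
      health_block$cmaq, health_block$ramp_hyb, blocks, width = w)
  )

  # --- exposure inequity ----------------------------------------------------
  conc <- annual$ramp_hyb
  equity <- list(
    national = eir(blocks, conc),
    county = eir_by_unit(blocks, conc, "county"),
    tract = eir_by_unit(blocks, conc, "tract"),
    block_group = eir_by_unit(blocks, conc, "block_group"),
    by_distance = eir_by_distance(blocks, conc,
                                  width = config$equity$distance_bin_width,
                                  config$equity$max_confident_distance)
  )

  result <- list(world = world, annual = annual, curves = curves,
                 evaluation = evaluation, health = health, equity = equity,
                 config = config, seed = seed)
  if (!is.null(out_dir)) write_run_outputs(result, out_dir)
  result
}

#' Write the main pipeline tables and a run manifest
#'
#' @param result Output of [run_pipeline()].
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  world <- result$world
  write_table(world$blocks, file.path(out_dir, "blocks.csv"))
  write_table(world$monitors, file.path(out_dir, "monitors.csv"))
  write_table(world$counties, file.path(out_dir, "county_baseline.csv"))
  if (nrow(world$roads))
    write_roads_geojson(world$roads, file.path(out_dir, "roads.geojson"))
  write_table(result$annual, file.path(out_dir, "annual_exposure.csv"))
  write_table(result$evaluation, file.path(out_dir, "evaluation.csv"))
  write_table(result$health$totals, file.path(out_dir, "health_totals.csv"))
  write_table(result$health$cmaq_vs_ramp$summary,
              file.path(out_dir, "health_cmaq_vs_ramp.csv"))
  write_table(result$health$distance_curve,
              file.path(out_dir, "mortality_by_distance.csv"))
  write_table(result$equity$by_distance,
              file.path(out_dir, "eir_by_distance.csv"))
  curves_df <- do.call(rbind, lapply(result$curves, function(cv) {
    data.frame(cell = cv$cell, node = seq_along(cv$x), x = cv$x,
               lambda1 = cv$lambda1, lambda1_m = cv$lambda1_m,
               n_pairs = cv$n_pairs)
  }))
  write_table(curves_df, file.path(out_dir, "ramp_curves.csv"))
  cfg_json <- jsonlite::toJSON(unclass(result$config), auto_unbox = TRUE,
                               digits = NA)
  manifest <- list(seed = result$seed, config_hash = fnv1a(cfg_json),
                   config = result$config,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Reference identity checks
#'
#' Recomputes, with the package's own accounting and CI-propagation
#' functions, the arithmetic identities that the national-scale application
#' of this method reports: excess/net mortality-difference accounting between
#' exposure models, slope-ratio CI scaling of total burdens, the
#' back-calculated total burden from a 40% reduction scenario, and relative
#' R-squared improvements. Each row gives the computed value next to the
#' published reference value and the absolute difference.
#'
#' @return data.frame `check`, `value`, `reference`, `abs_diff`.
#' @export
consistency_checks <- function() {
  mk_county <- function(central, lower, upper) {
    data.frame(county_id = seq_along(central), central = central,
               lower = lower, upper = upper)
  }
  # two-region excess/net accounting, PM2.5 and NO2, fine-vs-coarse included
  acct <- function(exc_a, exc_b) {
    a <- mk_county(c(exc_a[1], 0), c(exc_a[2], 0), c(exc_a[3], 0))
    b <- mk_county(c(0, exc_b[1]), c(0, exc_b[2]), c(0, exc_b[3]))
    compare_models(a, b)$summary
  }
  s_pm <- acct(c(18079, 15276, 21023), c(15310, 12936, 17802))
  s_no2 <- acct(c(28876, 14438, 43315), c(6301, 3150, 9451))
  s_pm_re <- acct(c(3203, 2706, 3725), c(1975, 1669, 2297))
  s_no2_re <- acct(c(10065, 5033, 15098), c(4854, 2427, 7281))
  net <- function(s) s$central[s$quantity == "net"]

  b_no2 <- ci_scale_bounds(138550, no2_crf())
  b_pm <- ci_scale_bounds(264516, pm25_crf())

  st <- function(r2) data.frame(r2_pearson = r2, rmse = 0)
  rel_pm <- compare_performance(st(0.30), st(0.51))$rel_delta_r2_pct
  rel_no2 <- compare_performance(st(0.62), st(0.81))$rel_delta_r2_pct

  out <- data.frame(
    check = c("pm25_net_difference", "no2_net_difference",
              "pm25_regrid_net_difference", "no2_regrid_net_difference",
              "no2_total_ci_lower", "no2_total_ci_upper",
              "pm25_total_ci_lower", "pm25_total_ci_upper",
              "pm25_total_from_40pct_reduction",
              "pm25_rel_r2_improvement_pct", "no2_rel_r2_improvement_pct"),
    value = c(net(s_pm), net(s_no2), net(s_pm_re), net(s_no2_re),
              b_no2$lower, b_no2$upper, b_pm$lower, b_pm$upper,
              total_from_reduction(104786, 0.40), rel_pm, rel_no2),
    reference = c(2769, 22576, 1228, 5211, 69275, 207826, 223506, 307577,
                  261965, 70, 31)
  )
  out$abs_diff <- abs(out$value - out$reference)
  out
}
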
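#' Default pipeline configuration
#'
#' Returns the full nested configuration for the synthetic world and the
#' analysis stages. Values follow the method's published operating points
#' where one exists (144 receptors per cell, 10 calibration bins, 50 paired
#' monitoring sites for PM2.5 and 10 for NO2, 25-m mortality distance bins,
#' 10-m equity distance bins, a 150-m near-road decay length) and otherwise
#' are fixed, documented choices of this package (see the methods vignette).
#'
#' @param pollutant `"pm25"` or `"no2"`.
#' @return A nested named list of class `roadfusion_config`.
#' @export
default_config <- function(pollutant = c("pm25", "no2")) {
  pollutant <- match.arg(pollutant)
  cfg <- list(
    pollutant = pollutant,
    grid = list(origin_x = 0, origin_y = 0, cell_size = 12000,
                n_rows = 4L, n_cols = 4L),
    n_days = 365L,
    receptors_per_side = 12L,     # 144 receptors per coarse cell
    background = list(
      # regional field: constant + 2 low-frequency plane waves + seasonal term
      base = if (pollutant == "pm25") 8 else 10,
      amplitudes = c(1.5, 0.8),
      wavelengths = c(60000, 25000),
      angles = c(0.4, 1.9),
      phases = c(0.0, 2.0),
      seasonal_amp = 1.5,
      seasonal_phase = 0.0
    ),
    roads = list(n_roads = 12L, emission_min = 0.5, emission_max = 3.0),
    decay = list(alpha = 1.0, L = 150),
    monitors = list(
      n_monitors = 40L,
      near_road_fraction = 0.25,
      one_in_three_fraction = if (pollutant == "pm25") 0.67 else 0.0,
      noise_sd = 0.5
    ),
    bias = list(enabled = TRUE,
                a = 1.0, a_range = 0.5,
                b = 1.15, b_range = 0.1,
                s = 0.6, s_range = 0.15, h = 10),
    dispersion = list(median_bias = 1.2, sigma = 0.25),
    blocks = list(
      n_blocks = 2000L,
      near_fraction = 0.3,
      pop_meanlog = log(40),
      pop_sdlog = 0.8,
      theta = 1.0,
      base_logit = -1.0,
      minority_mix = c(black = 0.35, asian = 0.15, hispanic = 0.35,
                       other = 0.15),
      frac25_range = c(0.55, 0.75)
    ),
    admin = list(counties_per_side = 2L, tracts_per_side = 8L,
                 block_groups_per_side = 16L),
    baseline_rate_range = c(0.007, 0.010),
    ramp = list(n_sites = if (pollutant == "pm25") 50L else 10L,
                min_pairs = 100L, n_bins = 10L,
                mode = "daily"),
    health = list(distance_bin_width = 25, ppb_to_ugm3 = 1.88),
    equity = list(distance_bin_width = 10, max_confident_distance = 2000)
  )
  structure(cfg, class = c("roadfusion_config", "list"))
}

# recursively merge user overrides into defaults, rejecting unknown keys
merge_config <- function(base, override, path = "") {
  if (anyDuplicated(names(override)))
    stop("duplicated configuration key(s): ",
         paste(unique(names(override)[duplicated(names(override))]),
               collapse = ", "), call. = FALSE)
  for (nm in names(override)) {
    key <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key: ", key, call. = FALSE)
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], key)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Build a configuration from defaults plus overrides
#'
#' @param ... Named overrides, possibly nested lists (e.g.
#'   `blocks = list(n_blocks = 500)`), or a single list in `.overrides`.
#' @param pollutant Passed to [default_config()].
#' @param .overrides Optional list of overrides (e.g. read from a YAML file).
#' @return A validated `roadfusion_config`.
#' @export
build_config <- function(..., pollutant = "pm25", .overrides = NULL) {
  cfg <- default_config(pollutant)
  dots <- list(...)
  if (length(dots)) cfg <- merge_config(cfg, dots)
  if (!is.null(.overrides)) {
    .overrides$pollutant <- NULL
    cfg <- merge_config(cfg, .overrides)
  }
  validate_config(cfg)
  structure(cfg, class = c("roadfusion_config", "list"))
}

validate_config <- function(cfg) {
  stopifnot(cfg$pollutant %in% c("pm25", "no2"))
  if (cfg$grid$cell_size <= 0)
    stop("configuration error: grid$cell_size must be > 0", call. = FALSE)
  for (k in c("n_roads")) if (cfg$roads[[k]] < 0)
    stop("configuration error: roads$", k, " must be >= 0", call. = FALSE)
  if (cfg$monitors$n_monitors < 1)
    stop("configuration error: monitors$n_monitors must be >= 1", call. = FALSE)
  if (cfg$blocks$n_blocks < 1)
    stop("configuration error: blocks$n_blocks must be >= 1", call. = FALSE)
  if (cfg$monitors$noise_sd < 0)
    stop("configuration error: monitors$noise_sd must be >= 0", call. = FALSE)
  if (cfg$bias$h <= 0)
    stop("configuration error: bias$h must be > 0", call. = FALSE)
  if (cfg$dispersion$sigma < 0)
    stop("configuration error: dispersion$sigma must be >= 0", call. = FALSE)
  if (cfg$decay$L <= 0 || cfg$decay$alpha <= 0)
    stop("configuration error: decay$L and decay$alpha must be > 0",
         call. = FALSE)
  if (cfg$n_days < 1)
    stop("configuration error: n_days must be >= 1", call. = FALSE)
  # admin partitions must nest: block group | tract | county
  a <- cfg$admin
  if (a$tracts_per_side %% a$counties_per_side != 0 ||
      a$block_groups_per_side %% a$tracts_per_side != 0)
    stop("configuration error: admin partitions must nest ",
         "(block_groups_per_side | tracts_per_side | counties_per_side)",
         call. = FALSE)
  invisible(cfg)
}

#' Synthetic-study configuration
#'
#' The fixed operating point used for the package's end-to-end synthetic
#' study: a 4 x 4 grid of 12-km cells, 40 monitors, 5,000 census blocks and
#' a full 365-day year. Calibration uses the 10 monitors nearest each cell:
#' with a 40-site network this keeps the correction regional (the published
#' national operating points select a comparably small fraction of the
#' monitor network), which is what lets the per-cell curves correct the
#' spatially varying component of the model bias.
#'
#' @param pollutant `"pm25"` or `"no2"`.
#' @param ... Further overrides passed to [build_config()].
#' @return A `roadfusion_config`.
#' @export
study_config <- function(pollutant = "pm25", ...) {
  base <- list(blocks = list(n_blocks = 5000L), ramp = list(n_sites = 10L))
  build_config(pollutant = pollutant,
               .overrides = utils::modifyList(base, list(...)))
}

#' Read a configuration from a YAML file
#'
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path Path to a YAML file of overrides; may include `pollutant`.
#' @return A validated `roadfusion_config`.
#' @export
read_config <- function(path) {
  ov <- yaml::read_yaml(path)
  pollutant <- if (!is.null(ov$pollutant)) ov$pollutant else "pm25"
  build_config(pollutant = pollutant, .overrides = ov)
}
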
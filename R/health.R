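# Health impact: long-term attributable premature mortality from annual
# concentrations via a log-linear concentration-response function, with
# proportional slope-ratio confidence-interval scaling, plus the county and
# distance-bin aggregations and two-model difference accounting.

#' Concentration-response function specification
#'
#' Relative risk per 10 ug/m3 with 95% CI bounds and a counterfactual
#' concentration. Defaults: all-cause mortality RR 1.0129 [1.0109, 1.0150]
#' per 10 ug/m3 for PM2.5 (a 1.29% increase) and hazard ratio 1.04
#' [1.02, 1.06] per 10 ug/m3 for NO2, both with counterfactual 0 (burden
#' attributable to all sources).
#'
#' @param pollutant `"pm25"` or `"no2"`.
#' @param rr_central,rr_lower,rr_upper Relative risk per 10 ug/m3.
#' @param c0 Counterfactual concentration (ug/m3).
#' @return Object of class `crf_spec`.
#' @export
crf_spec <- function(pollutant, rr_central, rr_lower, rr_upper, c0 = 0) {
  if (!(rr_lower <= rr_central && rr_central <= rr_upper))
    stop("require rr_lower <= rr_central <= rr_upper", call. = FALSE)
  if (rr_central <= 1)
    stop("rr_central must exceed 1", call. = FALSE)
  structure(list(pollutant = pollutant, rr_central = rr_central,
                 rr_lower = rr_lower, rr_upper = rr_upper, c0 = c0),
            class = "crf_spec")
}

#' @rdname crf_spec
#' @export
pm25_crf <- function() crf_spec("pm25", 1.0129, 1.0109, 1.0150)

#' @rdname crf_spec
#' @export
no2_crf <- function() crf_spec("no2", 1.04, 1.02, 1.06)

#' Convert ppb to ug/m3
#'
#' NO2 fields modelled in ppb are converted to ug/m3 before applying a CRF
#' stated per 10 ug/m3. The default factor 1.88 corresponds to NO2 at 25 C
#' and 1 atm.
#'
#' @param x Concentrations in ppb.
#' @param factor ug/m3 per ppb.
#' @return Concentrations in ug/m3.
#' @export
ppb_to_ugm3 <- function(x, factor = 1.88) x * factor

#' CI bounds by proportional slope-ratio scaling
#'
#' Scales a central attributable-mortality estimate to its CI bounds by the
#' ratio of excess relative risks: `lower = central * (rr_lower - 1) /
#' (rr_central - 1)` and analogously for the upper bound. For RR 1.04
#' [1.02, 1.06] the bounds are exactly 0.5x and 1.5x the central value.
#'
#' @param central Central estimate(s).
#' @param crf A [crf_spec()].
#' @return data.frame `central`, `lower`, `upper`.
#' @export
ci_scale_bounds <- function(central, crf) {
  data.frame(
    central = central,
    lower = central * (crf$rr_lower - 1) / (crf$rr_central - 1),
    upper = central * (crf$rr_upper - 1) / (crf$rr_central - 1)
  )
}

#' Attributable premature deaths for block-level exposures
#'
#' Log-linear attributable fraction `AF = 1 - exp(-beta * (conc - c0))` with
#' `beta = log(rr_central) / 10`, floored at 0 below the counterfactual.
#' Central deaths are `pop * frac25 * baseline_rate * AF`; CI bounds scale
#' the central estimate by the slope ratios (see [ci_scale_bounds()]).
#'
#' @param conc Annual concentration (ug/m3), vectorised over blocks.
#' @param pop Block population (all ages).
#' @param frac25 Fraction of the block population aged 25+.
#' @param baseline_rate All-cause baseline mortality rate (deaths per
#'   person-year, ages 25+).
#' @param crf A [crf_spec()].
#' @return data.frame `central`, `lower`, `upper` (deaths per block).
#' @export
attributable_deaths <- function(conc, pop, frac25, baseline_rate, crf) {
  if (any(conc < 0) || any(pop < 0) || any(baseline_rate < 0))
    stop("negative inputs", call. = FALSE)
  if (any(frac25 < 0 | frac25 > 1))
    stop("`frac25` must lie in [0, 1]", call. = FALSE)
  beta <- log(crf$rr_central) / 10
  af <- pmax(1 - exp(-beta * (conc - crf$c0)), 0)
  ci_scale_bounds(pop * frac25 * baseline_rate * af, crf)
}

#' Aggregate block-level health results
#'
#' Sums central/lower/upper within counties or within half-open
#' distance-from-road bins `[k*w, (k+1)*w)` (default width 25 m).
#'
#' @param result data.frame `central`, `lower`, `upper`, one row per block
#'   (row order matching `blocks`).
#' @param blocks Blocks data.frame with `county_id` and `distance_to_road`.
#' @param by `"county"` or `"distance_bin"`.
#' @param width Bin width in metres for `by = "distance_bin"`.
#' @return Aggregated data.frame, one row per group.
#' @export
aggregate_health <- function(result, blocks, by = c("county", "distance_bin"),
                             width = 25) {
  by <- match.arg(by)
  if (nrow(result) != nrow(blocks))
    stop("`result` and `blocks` must align row-for-row", call. = FALSE)
  if (by == "county") {
    if (anyNA(blocks$county_id))
      stop("block with unknown county", call. = FALSE)
    key <- blocks$county_id
    keyname <- "county_id"
  } else {
    key <- floor(blocks$distance_to_road / width) * width
    keyname <- "bin_start"
  }
  agg <- rowsum(as.matrix(result[c("central", "lower", "upper")]), key)
  out <- data.frame(key = as.numeric(rownames(agg)), agg, row.names = NULL)
  names(out)[1] <- keyname
  out[order(out[[keyname]]), , drop = FALSE]
}

#' Excess / net difference accounting between two models
#'
#' Given county-aggregated results from two exposure models, computes the
#' per-county difference `d = a - b` and splits it into the regions where
#' model a exceeds (`excess_a = sum(max(d, 0))`), the regions where model b
#' exceeds (`excess_b = sum(max(-d, 0))`) and the net `excess_a - excess_b`.
#' The same accounting is applied component-wise to the CI bounds.
#'
#' @param result_a,result_b County tables from [aggregate_health()] with
#'   identical county sets.
#' @return List with `by_county` (per-county differences) and `summary`
#'   (rows excess_a / excess_b / net x columns central/lower/upper).
#' @export
compare_models <- function(result_a, result_b) {
  a <- result_a[order(result_a$county_id), ]
  b <- result_b[order(result_b$county_id), ]
  if (nrow(a) != nrow(b) || !all(a$county_id == b$county_id))
    stop("county sets differ", call. = FALSE)
  d <- data.frame(county_id = a$county_id,
                  central = a$central - b$central,
                  lower = a$lower - b$lower,
                  upper = a$upper - b$upper)
  pos <- function(v) sum(pmax(v, 0))
  neg <- function(v) sum(pmax(-v, 0))
  summary <- data.frame(
    quantity = c("excess_a", "excess_b", "net"),
    central = c(pos(d$central), neg(d$central), pos(d$central) - neg(d$central)),
    lower = c(pos(d$lower), neg(d$lower), pos(d$lower) - neg(d$lower)),
    upper = c(pos(d$upper), neg(d$upper), pos(d$upper) - neg(d$upper))
  )
  list(by_county = d, summary = summary)
}

#' Counties with the largest model differences
#'
#' @param comparison Output of [compare_models()].
#' @param k Count per side (default 20).
#' @return data.frame of up to `k` most-positive and `k` most-negative county
#'   differences, ties broken by ascending county id, with a `side` column.
#' @export
top_counties <- function(comparison, k = 20L) {
  d <- comparison$by_county
  pos <- d[d$central > 0, , drop = FALSE]
  pos <- pos[order(-pos$central, pos$county_id), , drop = FALSE]
  neg <- d[d$central < 0, , drop = FALSE]
  neg <- neg[order(neg$central, neg$county_id), , drop = FALSE]
  pos <- utils::head(pos, k); neg <- utils::head(neg, k)
  pos$side <- rep("a_exceeds", nrow(pos))
  neg$side <- rep("b_exceeds", nrow(neg))
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  out
}

#' Net mortality difference versus distance from road
#'
#' Aggregates the block-level difference between two models into half-open
#' distance bins (default 25 m), together with bin population and the
#' cumulative population with increasing distance.
#'
#' @param result_a,result_b Block-level tables (`central`, `lower`, `upper`),
#'   rows aligned with `blocks`.
#' @param blocks Blocks with `distance_to_road` and `pop_total`.
#' @param width Bin width (m).
#' @return data.frame `bin_start`, `net_central`, `net_lower`, `net_upper`,
#'   `population`, `cum_population`.
#' @export
mortality_by_distance_curve <- function(result_a, result_b, blocks,
                                        width = 25) {
  key <- floor(blocks$distance_to_road / width) * width
  diff <- as.matrix(result_a[c("central", "lower", "upper")]) -
          as.matrix(result_b[c("central", "lower", "upper")])
  agg <- rowsum(cbind(diff, pop = blocks$pop_total), key)
  out <- data.frame(bin_start = as.numeric(rownames(agg)),
                    net_central = agg[, "central"],
                    net_lower = agg[, "lower"],
                    net_upper = agg[, "upper"],
                    population = agg[, "pop"], row.names = NULL)
  out <- out[order(out$bin_start), , drop = FALSE]
  out$cum_population <- cumsum(out$population)
  rownames(out) <- NULL
  out
}

#' Back-calculate a total burden from a fractional-reduction estimate
#'
#' Under the (near-linear at these slopes) attributable-fraction model, the
#' deaths avoided by reducing concentrations everywhere by a fraction `f`
#' are `f` times the total attributable burden, so
#' `total = avoided / f`. Used to place reduction-scenario estimates on the
#' same footing as total-burden estimates.
#'
#' @param avoided Deaths avoided under the reduction scenario.
#' @param fraction Fractional concentration reduction in (0, 1].
#' @return Implied total attributable deaths.
#' @export
total_from_reduction <- function(avoided, fraction) {
  if (fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  avoided / fraction
}
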
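# Model performance statistics for paired annual (observed, modelled) values.

#' Model performance statistics
#'
#' Computes the standard air-quality evaluation suite for paired annual
#' values: FAC2 (% of modelled values within a factor of two of the
#' observation, boundaries inclusive), mean error (ME), standard deviation of
#' the error (SDE), root mean squared error (RMSE), mean and sd of the
#' modelled values (MZ, SDZ) and of the observations (MO, SDO), squared
#' Pearson correlation and squared Spearman rank correlation (average ranks
#' for ties). All moments are population moments (divide by n), so the
#' decomposition `RMSE^2 = ME^2 + SDE^2` holds exactly.
#'
#' @param observed,modeled Equal-length numeric vectors (n >= 2); observations
#'   must be positive (FAC2 is a ratio criterion).
#' @return A one-row data.frame of class `eval_stats`.
#' @export
evaluate_model <- function(observed, modeled) {
  if (length(observed) != length(modeled))
    stop("`observed` and `modeled` must have equal length", call. = FALSE)
  n <- length(observed)
  if (n < 2) stop("need at least 2 paired values", call. = FALSE)
  if (any(observed <= 0))
    stop("FAC2 requires strictly positive observed values", call. = FALSE)
  err <- modeled - observed
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  ratio <- modeled / observed
  out <- data.frame(
    n_sites = n,
    fac2 = 100 * mean(ratio >= 0.5 & ratio <= 2),
    me = mean(err),
    sde = pop_sd(err),
    rmse = sqrt(mean(err^2)),
    mz = mean(modeled),
    sdz = pop_sd(modeled),
    mo = mean(observed),
    sdo = pop_sd(observed),
    r2_pearson = stats::cor(observed, modeled)^2,
    rho2_spearman = stats::cor(observed, modeled, method = "spearman")^2
  )
  class(out) <- c("eval_stats", "data.frame")
  out
}

#' Compare two models' performance
#'
#' @param stats_a,stats_b `eval_stats` rows (a = reference, b = candidate).
#' @return data.frame with `delta_r2`, `rel_delta_r2_pct` (rounded to the
#'   nearest integer; `NA` when the reference R2 is 0) and `delta_rmse`.
#' @export
compare_performance <- function(stats_a, stats_b) {
  d_r2 <- stats_b$r2_pearson - stats_a$r2_pearson
  rel <- if (stats_a$r2_pearson == 0) NA_real_ else
    round(100 * d_r2 / stats_a$r2_pearson)
  data.frame(delta_r2 = d_r2, rel_delta_r2_pct = rel,
             delta_rmse = stats_b$rmse - stats_a$rmse)
}
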
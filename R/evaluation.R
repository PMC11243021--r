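#' Paired t-test on two-week weight changes
#'
#' Tests whether simulated weight changes differ from actual ones over
#' matched periods. Differences are oriented as `b - a` (simulated minus
#' actual), so a weight-reducing intervention yields a negative t-statistic;
#' the p-value is two-sided and directionality is read off the sign of t.
#'
#' @param a Numeric vector (kg), e.g. actual weight changes.
#' @param b Numeric vector of equal length, e.g. simulated weight changes.
#' @return List of class `paired_t_result`: `t_statistic`, `p_value`, `df`,
#'   `mean_difference` (kg).
#' @export
#' @examples
#' paired_t_test(c(0, 0, 0, 0), c(0.2, 0.3, 0.3, 0.3))
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop_input("a and b must have equal length")
  if (length(a) < 2) stop_input("need at least 2 paired observations")
  d <- b - a
  if (anyNA(d)) stop_input("paired differences contain missing values")
  if (sd(d) == 0) {
    stop_input("zero-variance differences: the two series are identical up to a constant shift")
  }
  ht <- stats::t.test(d)
  structure(list(t_statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 df = unname(ht$parameter),
                 mean_difference = mean(d)),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.3f (df = %.0f), p = %.3g, mean diff = %.3f kg\n",
              x$t_statistic, x$df, x$p_value, x$mean_difference))
  invisible(x)
}

#' Regress weight change on the energy-balance difference
#'
#' Ordinary least squares of period weight change `dw` (kg) on the period's
#' cumulative energy-balance difference `delta_eb` (kcal) between the actual
#' diet and its biohacked counterpart, with intercept. Reports the slope
#' (kg/kcal), intercept, R-squared, Pearson correlation, and the two-sided
#' p-value of the slope.
#'
#' @param outcomes Data frame with numeric columns `delta_eb` and `dw`.
#' @return List of class `dw_regression`: `slope`, `intercept`, `r_squared`,
#'   `pearson_r`, `p_value`, `n`.
#' @export
regress_dw_on_deb <- function(outcomes) {
  stopifnot(all(c("delta_eb", "dw") %in% names(outcomes)))
  x <- outcomes$delta_eb; y <- outcomes$dw
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_input("need at least 3 periods for regression")
  if (sd(x) == 0) stop_input("constant predictor: delta_eb has no variation")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 pearson_r = cor(x, y),
                 p_value = sm$coefficients[2, 4],
                 n = length(x)),
            class = "dw_regression")
}

#' @export
print.dw_regression <- function(x, ...) {
  cat(sprintf("OLS dw ~ delta_eb (n = %d): slope = %.3g kg/kcal, R2 = %.3f, r = %.3f, p = %.3g\n",
              x$n, x$slope, x$r_squared, x$pearson_r, x$p_value))
  invisible(x)
}

#' Cohort-level evaluation report
#'
#' Assembles the per-participant comparison of simulated versus actual
#' two-week weight changes (mean +/- sd of each, their difference, paired
#' t-test) and the per-participant regression of weight change on the
#' energy-balance difference. Participants whose simulated and actual
#' changes are identical are reported with `note = "no difference"` instead
#' of a t-statistic.
#'
#' @param results Named list (one element per participant) of period tibbles
#'   as returned by [simulate_biohacked_periods()], i.e. with columns
#'   `dw_actual`, `dw_simulated`, `delta_eb`.
#' @param summaries Optional named list of [intervention_summary()] results,
#'   used to add a cohort-average intervention table.
#' @return List of class `cohort_report` with tibbles `weight_comparison`
#'   and `regression`, and (when `summaries` is given) a list
#'   `intervention`.
#' @export
evaluate_cohort <- function(results, summaries = NULL) {
  stopifnot(is.list(results), length(results) >= 1)
  if (is.null(names(results))) names(results) <- as.character(seq_along(results))
  wc <- purrr::imap(results, function(res, id) {
    if (nrow(res) < 2) stop_input("participant %s: need >= 2 periods", id)
    note <- NA_character_
    tt <- tryCatch(paired_t_test(res$dw_actual, res$dw_simulated),
                   biohackr_error = function(e) NULL)
    if (is.null(tt)) {
      note <- "no difference"
      tt <- list(t_statistic = NA_real_, p_value = NA_real_)
    }
    tibble::tibble(
      participant = id,
      n_periods = nrow(res),
      dw_actual_mean = mean(res$dw_actual),
      dw_actual_sd = sd(res$dw_actual),
      dw_simulated_mean = mean(res$dw_simulated),
      dw_simulated_sd = sd(res$dw_simulated),
      delta_weight_loss_mean = mean(res$dw_simulated - res$dw_actual),
      delta_weight_loss_sd = sd(res$dw_simulated - res$dw_actual),
      t_statistic = tt$t_statistic,
      p_value = tt$p_value,
      note = note)
  })
  rg <- purrr::imap(results, function(res, id) {
    reg <- tryCatch(
      regress_dw_on_deb(tibble::tibble(delta_eb = res$delta_eb,
                                       dw = res$dw_actual)),
      biohackr_error = function(e) {
        stop_input("participant %s: %s", id, conditionMessage(e))
      })
    tibble::tibble(participant = id, slope_kg_per_kcal = reg$slope,
                   intercept_kg = reg$intercept, r_squared = reg$r_squared,
                   pearson_r = reg$pearson_r, p_value = reg$p_value)
  })
  report <- list(weight_comparison = dplyr::bind_rows(wc),
                 regression = dplyr::bind_rows(rg))
  if (!is.null(summaries)) {
    mat <- purrr::map(summaries, ~ unlist(.x[c(
      "avg_daily_kcal_reduction", "kcal_reduction_pct",
      "avg_daily_co2_reduction", "co2_reduction_pct")]))
    mm <- do.call(rbind, mat)
    report$intervention <- list(
      avg_daily_kcal_reduction = mean(mm[, 1]),
      avg_daily_kcal_reduction_sd = sd(mm[, 1]),
      kcal_reduction_pct = mean(mm[, 2]),
      kcal_reduction_pct_sd = sd(mm[, 2]),
      avg_daily_co2_reduction = mean(mm[, 3]),
      avg_daily_co2_reduction_sd = sd(mm[, 3]),
      co2_reduction_pct = mean(mm[, 4]),
      co2_reduction_pct_sd = sd(mm[, 4]))
  }
  class(report) <- "cohort_report"
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort evaluation\n\nSimulated vs actual two-week weight change:\n")
  print(x$weight_comparison)
  cat("\nRegression of dw on delta_EB:\n")
  print(x$regression)
  if (!is.null(x$intervention)) {
    cat(sprintf("\nIntervention: %.1f kcal/day (%.1f%%), %.1f gCO2eq/day (%.1f%%)\n",
                x$intervention$avg_daily_kcal_reduction,
                x$intervention$kcal_reduction_pct,
                x$intervention$avg_daily_co2_reduction,
                x$intervention$co2_reduction_pct))
  }
  invisible(x)
}
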
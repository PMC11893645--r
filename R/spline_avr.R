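# Smoothing-spline multiplier curves and the timing-vs-age residual
# comparison (absolute values of residuals, paired Wilcoxon signed-rank).

#' Fit a smoothing spline to multiplier observations
#'
#' Cubic smoothing spline of the multiplier against either spurt-relative
#' timing or chronological age, with the smoothing parameter chosen by
#' generalized cross-validation. A monotone-nonincreasing check on the
#' fitted curve is reported as a diagnostic, not enforced.
#'
#' @param observations A [compute_multipliers()] tibble (single method
#'   recommended).
#' @param predictor `"timing"` (uses `timing_yr`) or `"age"` (uses
#'   `age_yr`).
#' @param sex Optional `"F"`/`"M"` filter (age-based curves are fitted per
#'   sex; timing-based curves pool the sexes).
#' @return A list of class `"multiplier_spline"`: the `smooth.spline` fit
#'   plus a tibble `points` with per-observation `fitted` and `residual`,
#'   and `monotone_decreasing` (diagnostic flag on the fitted grid).
#' @export
fit_multiplier_spline <- function(observations,
                                  predictor = c("timing", "age"),
                                  sex = NULL) {
  predictor <- match.arg(predictor)
  obs <- observations
  if (!is.null(sex)) obs <- dplyr::filter(obs, .data$sex == !!sex)
  if (nrow(obs) < 20) {
    rlang::abort("need at least 20 observations for a smoothing spline",
                 class = "spinegrowth_fit_error")
  }
  x <- if (predictor == "timing") obs$timing_yr else obs$age_yr
  fit <- stats::smooth.spline(x, obs$multiplier)  # GCV by default
  fitted <- stats::predict(fit, x)$y
  grid <- seq(min(x), max(x), length.out = 200)
  on_grid <- stats::predict(fit, grid)$y
  structure(
    list(
      fit = fit,
      predictor = predictor,
      sex = sex,
      points = dplyr::mutate(obs, predictor_value = x, fitted = fitted,
                             residual = .data$multiplier - fitted),
      monotone_decreasing = all(diff(on_grid) <= 1e-8)
    ),
    class = "multiplier_spline"
  )
}

#' @export
print.multiplier_spline <- function(x, ...) {
  cat("Multiplier smoothing spline vs", x$predictor,
      if (!is.null(x$sex)) paste0("(sex ", x$sex, ")") else "(sexes pooled)",
      "\n  n =", nrow(x$points),
      " lambda =", format(x$fit$lambda, digits = 3),
      " monotone decreasing:", x$monotone_decreasing, "\n")
  invisible(x)
}

#' Tidy a multiplier spline
#' @method tidy multiplier_spline
#' @param x A `"multiplier_spline"` object.
#' @param ... Unused.
#' @return The per-observation tibble with fitted values and residuals.
#' @export
tidy.multiplier_spline <- function(x, ...) x$points

#' Glance at a multiplier spline
#' @method glance multiplier_spline
#' @param x A `"multiplier_spline"` object.
#' @param ... Unused.
#' @return One-row tibble with `nobs`, `lambda`, `df`, `median_avr`.
#' @export
glance.multiplier_spline <- function(x, ...) {
  tibble::tibble(
    nobs = nrow(x$points),
    lambda = x$fit$lambda,
    df = x$fit$df,
    median_avr = stats::median(abs(x$points$residual))
  )
}

#' Paired signed-rank test on absolute residuals
#'
#' The statistical core of [avr_compare()]: given per-visit absolute
#' residuals (AVRs) under two fitted curves, paired by visit, runs a
#' two-sided paired Wilcoxon signed-rank test on the differences and
#' returns both medians. Identical vectors give p = 1 by convention (the
#' signed-rank statistic is undefined when every difference is zero).
#'
#' @param avr_a,avr_b Paired nonnegative AVR vectors of equal length.
#' @return A list with `median_a`, `median_b`, `p_value`, `n_pairs`.
#' @export
avr_test <- function(avr_a, avr_b) {
  if (length(avr_a) != length(avr_b)) {
    rlang::abort("AVR vectors must be paired (equal length) (PAIRING)",
                 class = "spinegrowth_validation_error")
  }
  p <- if (all(avr_a == avr_b)) 1 else {
    stats::wilcox.test(avr_a, avr_b, paired = TRUE, exact = FALSE)$p.value
  }
  list(median_a = stats::median(avr_a), median_b = stats::median(avr_b),
       p_value = p, n_pairs = length(avr_a))
}

#' Compare timing-based and age-based multiplier curves by their residuals
#'
#' Fits the multiplier spline against spurt-relative timing (sexes pooled)
#' and against chronological age (per sex, residuals pooled), pairs the
#' absolute residuals (AVRs) by visit, and runs a paired two-sided Wilcoxon
#' signed-rank test on the AVR differences. A smaller timing median says the
#' spurt-aligned curve tracks the multipliers more tightly than the
#' age-based curves. Because the two models use different predictors, the
#' comparison is exploratory rather than a formal model comparison — the
#' result carries that caveat.
#'
#' @param observations A [compute_multipliers()] tibble (one method).
#' @return A list of class `"avr_comparison"`: `median_avr_timing`,
#'   `median_avr_age` (pooled over sexes), `p_value`, `n_pairs`, `caveat`.
#' @export
avr_compare <- function(observations) {
  if (length(unique(observations$method)) > 1) {
    rlang::abort("observations mix methods; filter to one method first",
                 class = "spinegrowth_validation_error")
  }
  sex_counts <- table(observations$sex)
  if (nrow(observations) < 20 || any(sex_counts < 20)) {
    rlang::abort(
      "need at least 20 observations overall and per sex for the AVR curves",
      class = "spinegrowth_fit_error")
  }
  key <- c("subject_id", "age_yr")
  spl_t <- fit_multiplier_spline(observations, "timing")
  res_t <- dplyr::select(spl_t$points, dplyr::all_of(key),
                         resid_timing = "residual")
  res_a <- purrr::map(
    intersect(c("F", "M"), unique(observations$sex)),
    function(s) {
      spl <- fit_multiplier_spline(observations, "age", sex = s)
      dplyr::select(spl$points, dplyr::all_of(key), resid_age = "residual")
    }) |> dplyr::bind_rows()
  paired <- dplyr::inner_join(res_t, res_a, by = key)
  if (nrow(paired) != nrow(res_t) || nrow(paired) != nrow(res_a)) {
    rlang::abort("residuals could not be paired one-to-one by visit (PAIRING)",
                 class = "spinegrowth_validation_error")
  }
  tst <- avr_test(abs(paired$resid_timing), abs(paired$resid_age))
  structure(
    list(
      median_avr_timing = tst$median_a,
      median_avr_age = tst$median_b,
      p_value = tst$p_value,
      n_pairs = tst$n_pairs,
      caveat = paste("the predictors differ, so this residual comparison is",
                     "exploratory rather than a formal comparison of models")
    ),
    class = "avr_comparison"
  )
}

#' @export
print.avr_comparison <- function(x, ...) {
  cat("AVR comparison (paired Wilcoxon signed-rank, n =", x$n_pairs, ")\n",
      " median AVR vs timing:", format(x$median_avr_timing, digits = 3),
      "\n  median AVR vs age:   ", format(x$median_avr_age, digits = 3),
      "\n  two-sided p:", format.pval(x$p_value, digits = 3),
      "\n  note:", x$caveat, "\n")
  invisible(x)
}
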
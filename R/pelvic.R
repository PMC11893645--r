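# External consistency check: spine length predicted from pelvic width with
# a confidence band, and the fraction of method estimates falling inside it.
#
# The published pelvic-width regression coefficients are not embedded — a
# model must be supplied explicitly (or calibrated on synthetic truth for
# testing); there is deliberately no silent default.

#' Pelvic-width spine-length model
#'
#' A linear model `spine = intercept + slope * pelvic_width` with a
#' confidence band of the given half-width. The half-width may be a constant
#' (cm) or a function of pelvic width.
#'
#' @param intercept Intercept, cm.
#' @param slope Slope, cm spine per cm pelvic width (must be > 0).
#' @param ci_halfwidth Constant half-width (cm) or `function(width)` -> cm.
#' @return An object of class `"pelvic_model"`.
#' @export
pelvic_model <- function(intercept, slope, ci_halfwidth) {
  if (slope <= 0) {
    rlang::abort("pelvic model slope must be positive",
                 class = "spinegrowth_config_error")
  }
  hw <- if (is.function(ci_halfwidth)) ci_halfwidth else {
    force(ci_halfwidth); function(width) rep(ci_halfwidth, length(width))
  }
  structure(list(intercept = intercept, slope = slope, ci_halfwidth = hw),
            class = "pelvic_model")
}

assert_pelvic_model <- function(model) {
  if (!inherits(model, "pelvic_model")) {
    rlang::abort(
      "a pelvic_model() is required; coefficients are never defaulted (MODEL_REQUIRED)",
      class = "spinegrowth_config_error"
    )
  }
  invisible(model)
}

#' Predict spine length from pelvic width
#'
#' @param model A [pelvic_model()].
#' @param pelvic_width Pelvic width(s), cm.
#' @return Tibble with `pelvic_width`, `predicted`, `lower`, `upper` (cm).
#' @export
pelvic_predict <- function(model, pelvic_width) {
  assert_pelvic_model(model)
  point <- model$intercept + model$slope * pelvic_width
  hw <- model$ci_halfwidth(pelvic_width)
  tibble::tibble(pelvic_width = pelvic_width, predicted = point,
                 lower = point - hw, upper = point + hw)
}

#' Calibrate a pelvic-width model on a synthetic cohort's truth
#'
#' Test helper: regresses the latent true T1-S1 on the recorded pelvic width
#' across all visits of a simulated cohort and sets the band half-width to
#' the given quantile of the absolute residuals, so the band covers roughly
#' that fraction of visits by construction. Only meaningful for synthetic
#' data where the truth is known.
#'
#' With `estimate_sd > 0` the half-width is widened in quadrature for the
#' measurement noise of the estimates the band will be compared against
#' (a prediction-style band): a band calibrated on noiseless truth
#' undercovers noisy reconstructions by construction.
#'
#' @param sim A [simulate_cohort()] result.
#' @param config The [generator_config()] used.
#' @param coverage Target coverage of the band (default 0.95).
#' @param estimate_sd Measurement sd (cm) of the estimates to be checked
#'   against the band (default 0: cover the latent truth only).
#' @return A [pelvic_model()].
#' @export
calibrate_pelvic_model <- function(sim, config, coverage = 0.95,
                                   estimate_sd = 0) {
  per_subject <- split(sim$visits, sim$visits$subject_id)
  truth <- sim$truth
  t1s1_true <- unlist(lapply(names(per_subject), function(id) {
    tr <- truth[truth$subject_id == id, ]
    spine_trajectory(tr, config, per_subject[[id]]$age_yr - tr$true_pga_age)
  }))
  width <- unlist(lapply(per_subject, function(df) df$pelvic_width))
  fit <- stats::lm(t1s1_true ~ width)
  hw <- stats::quantile(abs(stats::residuals(fit)), coverage, names = FALSE)
  if (estimate_sd > 0) {
    # widen in quadrature so the band is a prediction band for estimates
    # carrying estimate_sd of measurement noise
    s_resid <- stats::sd(stats::residuals(fit))
    hw <- hw * sqrt(s_resid^2 + estimate_sd^2) / s_resid
  }
  pelvic_model(intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]),
               ci_halfwidth = hw)
}

#' Fraction of spine estimates inside the pelvic-width band
#'
#' Pairs spine estimates with pelvic-width predictions by visit (visits
#' without a pelvic width are skipped) and reports, per method, the fraction
#' whose T1-S1 estimate lies inside `[lower, upper]`.
#'
#' @param estimates Long spine-estimate tibble (from [spine_heights()]).
#' @param visits Cohort tibble rows carrying `pelvic_width`.
#' @param model A [pelvic_model()].
#' @return Tibble with `method`, `in_band` (fraction), `n_pairs`.
#' @export
agreement_rate <- function(estimates, visits, model) {
  assert_pelvic_model(model)
  widths <- visits |>
    dplyr::filter(!is.na(.data$pelvic_width)) |>
    dplyr::select("subject_id", "age_yr", "pelvic_width")
  paired <- dplyr::inner_join(estimates, widths,
                              by = c("subject_id", "age_yr"))
  if (nrow(paired) == 0) {
    rlang::abort("no visits with both a spine estimate and a pelvic width (NO_PAIRS)",
                 class = "spinegrowth_validation_error")
  }
  band <- pelvic_predict(model, paired$pelvic_width)
  paired |>
    dplyr::mutate(in_band = .data$t1s1 >= band$lower &
                    .data$t1s1 <= band$upper) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(in_band = mean(.data$in_band),
                     n_pairs = dplyr::n(), .groups = "drop")
}
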
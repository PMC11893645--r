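# Growth-remaining multipliers: per-visit observations, the binned
# multiplier table on the half-year timing grid, interpolation, and adult
# spine-height prediction with method-based bounds.

#' Per-visit growth-remaining multiplier observations
#'
#' For every mature subject and method, the adult T1-S1 is the mean of that
#' subject's estimates at timing >= `mature_timing` (averaging over the
#' mature visits reduces single-visit noise); each visit's multiplier is
#' adult T1-S1 divided by the current estimate. Its reciprocal is the
#' fraction of mature spine height already attained. Subjects with no
#' mature-phase visit for a method are skipped with a warning.
#'
#' @param estimates Long spine-estimate tibble with `timing_yr` (from
#'   [spine_heights()] on an aligned cohort).
#' @param mature_timing Timing from which visits count as mature (default 4).
#' @return Tibble with `subject_id`, `sex`, `age_yr`, `timing_yr`, `method`,
#'   `t1s1`, `adult_t1s1`, `multiplier`.
#' @export
compute_multipliers <- function(estimates, mature_timing = 4) {
  adult <- estimates |>
    dplyr::filter(.data$timing_yr >= mature_timing) |>
    dplyr::group_by(.data$subject_id, .data$method) |>
    dplyr::summarise(adult_t1s1 = mean(.data$t1s1), .groups = "drop")
  skipped <- estimates |>
    dplyr::distinct(.data$subject_id, .data$method) |>
    dplyr::anti_join(adult, by = c("subject_id", "method"))
  if (nrow(skipped) > 0) {
    rlang::warn(paste0(
      "skipping subject/method with no mature-phase visit: ",
      paste(unique(skipped$subject_id), collapse = ", ")))
  }
  estimates |>
    dplyr::inner_join(adult, by = c("subject_id", "method")) |>
    dplyr::mutate(multiplier = .data$adult_t1s1 / .data$t1s1) |>
    dplyr::select(dplyr::any_of(c("subject_id", "sex", "age_yr", "timing_yr",
                                  "method", "t1s1", "adult_t1s1",
                                  "multiplier")))
}

#' Bin multiplier observations onto the timing grid
#'
#' Averages observations into half-open half-year bins `[t - 0.25, t + 0.25)`
#' centered on the grid `timing_yr = -4, -3.5, ..., 4.5` (matching the
#' reference table's layout). Cells are clamped to >= 1; cells at timing >= 4
#' are set to exactly 1.000 because the mature-phase definition of adult
#' spine height forces them there. Empty bins are reported with `n = 0` and
#' `NA` mean — never silently interpolated.
#'
#' @param observations A [compute_multipliers()] tibble.
#' @param grid Bin centers (yr).
#' @param half_width Half bin width (yr, default 0.25).
#' @return Tibble with `timing_yr`, `method`, `multiplier` (mean), `sd`, `n`.
#' @export
build_multiplier_table <- function(observations,
                                   grid = seq(-4, 4.5, by = 0.5),
                                   half_width = 0.25) {
  cells <- tidyr::crossing(timing_yr = grid,
                           method = unique(observations$method))
  binned <- purrr::pmap(cells, function(timing_yr, method) {
    obs <- observations$multiplier[
      observations$method == method &
        observations$timing_yr >= timing_yr - half_width &
        observations$timing_yr < timing_yr + half_width]
    tibble::tibble(
      timing_yr = timing_yr, method = method,
      multiplier = if (length(obs) > 0) mean(obs) else NA_real_,
      sd = if (length(obs) > 1) stats::sd(obs) else NA_real_,
      n = length(obs)
    )
  }) |> dplyr::bind_rows()
  binned |>
    dplyr::mutate(
      multiplier = pmax(.data$multiplier, 1),
      multiplier = dplyr::if_else(.data$timing_yr >= 4 & .data$n > 0,
                                  1, .data$multiplier)
    ) |>
    dplyr::arrange(.data$method, .data$timing_yr)
}

#' Interpolate a multiplier column at an arbitrary timing
#'
#' Linear interpolation between adjacent grid cells of a multiplier table;
#' exact at grid points; 1.0 beyond the last grid point (maturity).
#' Extrapolation below the grid is refused (`OUT_OF_RANGE`).
#'
#' @param timing_yr Timing(s) in years relative to PGA90.
#' @param table A table with `timing_yr` plus the named column — by default
#'   the reference table [multiplier_reference()].
#' @param column Which multiplier column: `"body_height"` or `"pct_c1s1"`
#'   for the reference table, or `"multiplier"` for a
#'   [build_multiplier_table()] result filtered to one method.
#' @return Numeric vector of multipliers.
#' @export
interpolate_multiplier <- function(timing_yr,
                                   table = multiplier_reference(),
                                   column = "body_height") {
  grid_t <- table$timing_yr
  vals <- table[[column]]
  if (is.null(vals)) {
    rlang::abort(paste0("no column '", column, "' in multiplier table"),
                 class = "spinegrowth_table_error")
  }
  keep <- !is.na(vals)
  grid_t <- grid_t[keep]; vals <- vals[keep]
  if (any(timing_yr < min(grid_t))) {
    rlang::abort(
      paste0("timing below the table grid (OUT_OF_RANGE); multipliers are ",
             "not extrapolated before ", min(grid_t), " yr"),
      class = "spinegrowth_range_error"
    )
  }
  out <- stats::approx(grid_t, vals, xout = pmin(timing_yr, max(grid_t)),
                       method = "linear", ties = "ordered")$y
  out[timing_yr > max(grid_t)] <- 1
  out
}

#' Predict adult T1-S1 spine height with method-based bounds
#'
#' Multiplies the current T1-S1 height by the interpolated multipliers of
#' the two recommended columns: the percent-C1-S1 method (labelled the lower
#' limit) and the body-height method (labelled the upper limit). Because the
#' two columns cross near timing -0.5, the numeric `lower`/`upper` bounds
#' are ordered by value; the method labels are carried separately. The point
#' prediction is the midpoint of the bounds.
#'
#' @param current_t1s1 Current T1-S1 height(s), cm.
#' @param timing_yr Timing(s) relative to PGA90, yr.
#' @param table Multiplier table with `pct_c1s1` and `body_height` columns
#'   (default [multiplier_reference()]).
#' @return Tibble with `current_t1s1`, `timing_yr`, `predicted` (midpoint),
#'   `lower`, `upper` (cm), and the method attaining each bound.
#' @examples
#' predict_adult_spine(38, timing_yr = 0)
#' @export
predict_adult_spine <- function(current_t1s1, timing_yr,
                                table = multiplier_reference()) {
  stopifnot(all(current_t1s1 > 0))
  m_pct <- interpolate_multiplier(timing_yr, table, "pct_c1s1")
  m_body <- interpolate_multiplier(timing_yr, table, "body_height")
  a <- current_t1s1 * m_pct
  b <- current_t1s1 * m_body
  tibble::tibble(
    current_t1s1 = current_t1s1,
    timing_yr = timing_yr,
    predicted = (a + b) / 2,
    lower = pmin(a, b),
    upper = pmax(a, b),
    lower_method = dplyr::if_else(a <= b, "pct_c1s1", "body_height"),
    upper_method = dplyr::if_else(a <= b, "body_height", "pct_c1s1")
  )
}
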
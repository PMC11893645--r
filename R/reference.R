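# Published reference constants: the growth-remaining multiplier table on the
# PGA90-aligned timing grid, the phase-wise T1-S1 velocities, and the
# segmental composition fractions. These calibrate the synthetic generator
# and serve as lookup tables for prediction.

#' Reference spine-height multiplier table
#'
#' The published growth-remaining multipliers for T1-S1 spine height on the
#' half-year timing grid relative to PGA90 (the age at 90% of adult standing
#' height), from -4 to +4.5 years. Two columns of multipliers: `pct_c1s1`
#' (T1-S1 taken as a fixed percentage of C1-S1, the recommended lower bound)
#' and `body_height` (T1-S1 from its statistical relationship to standing
#' height, the recommended upper bound). A multiplier is adult length divided
#' by current length, so its reciprocal is the fraction of mature length
#' already attained.
#'
#' @return Tibble with columns `timing_yr`, `pct_c1s1`, `body_height`.
#' @export
multiplier_reference <- function() {
  tibble::tibble(
    timing_yr = seq(-4, 4.5, by = 0.5),
    pct_c1s1 = c(1.336, 1.314, 1.292, 1.270, 1.248, 1.226, 1.204, 1.182,
                 1.160, 1.138, 1.116, 1.094, 1.072, 1.050, 1.028, 1.006,
                 1.000, 1.000),
    body_height = c(1.397, 1.366, 1.336, 1.305, 1.274, 1.243, 1.211, 1.179,
                    1.148, 1.117, 1.089, 1.063, 1.042, 1.026, 1.015, 1.007,
                    1.002, 1.000)
  )
}

#' Growth phases relative to PGA90
#'
#' The four growth phases as half-open timing intervals `[lower, upper)` in
#' years relative to PGA90: childhood (below -2), growth spurt (-2 to +2),
#' terminal growth (+2 to +4) and maturity (+4 on). The knots partition the
#' timing axis.
#'
#' @return Tibble with columns `phase`, `lower`, `upper`.
#' @export
growth_phases <- function() {
  tibble::tibble(
    phase = factor(c("childhood", "spurt", "terminal", "mature"),
                   levels = c("childhood", "spurt", "terminal", "mature")),
    lower = c(-Inf, -2, 2, 4),
    upper = c(-2, 2, 4, Inf)
  )
}

#' Reference phase-wise T1-S1 growth velocities
#'
#' Published mean T1-S1 growth velocities (cm/yr) by sex and growth phase:
#' girls 1.55 (childhood), 1.75 (spurt), 0.9 (terminal), 0.0474 (mature);
#' boys 1.14, 2, 0.881, -0.12. The small negative mature-phase value for
#' boys is estimation noise around zero, not shrinkage.
#'
#' @return Tibble with columns `sex`, `phase`, `velocity` (cm/yr).
#' @export
reference_phase_velocities <- function() {
  tidyr::crossing(
    sex = factor(c("F", "M"), levels = c("F", "M")),
    phase = growth_phases()$phase
  ) |>
    dplyr::arrange(.data$sex, .data$phase) |>
    dplyr::mutate(velocity = c(1.55, 1.75, 0.9, 0.0474,
                               1.14, 2.0, 0.881, -0.12))
}
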
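# Phase-wise spinal growth velocities: per-subject OLS slopes within the
# fixed growth phases, cross-subject summaries, and per-segment rates.

#' Per-subject T1-S1 slopes within each growth phase
#'
#' Ordinary least-squares slope of T1-S1 against timing within each of the
#' half-open phases (childhood, spurt, terminal, mature), separately per
#' subject. A subject contributes a slope for a phase only when it has at
#' least two visits inside it. Slopes may legitimately be negative in the
#' mature phase (measurement noise around a flat truth); nothing is clamped
#' on the estimation side.
#'
#' @param estimates Long spine-estimate tibble with `timing_yr` and `t1s1`,
#'   typically filtered to one method.
#' @param phases Phase definition tibble (default [growth_phases()]).
#' @return Tibble with `subject_id`, `sex`, `phase`, `slope` (cm/yr),
#'   `n_visits`.
#' @export
subject_phase_slopes <- function(estimates, phases = growth_phases()) {
  if (length(unique(estimates$method)) > 1) {
    rlang::abort("estimates mix methods; filter to one method first",
                 class = "spinegrowth_validation_error")
  }
  one_phase <- function(df, lower, upper) {
    inside <- df[df$timing_yr >= lower & df$timing_yr < upper, ]
    if (nrow(inside) < 2) return(NULL)
    fit <- stats::lm(t1s1 ~ timing_yr, data = inside)
    tibble::tibble(slope = unname(stats::coef(fit)["timing_yr"]),
                   n_visits = nrow(inside))
  }
  estimates |>
    dplyr::group_by(.data$subject_id, .data$sex) |>
    dplyr::group_modify(function(df, key) {
      purrr::pmap(phases, function(phase, lower, upper) {
        res <- one_phase(df, lower, upper)
        if (is.null(res)) return(NULL)
        dplyr::mutate(res, phase = phase, .before = 1)
      }) |> dplyr::bind_rows()
    }) |>
    dplyr::ungroup()
}

#' Summarise phase slopes across subjects
#'
#' Mean, standard error of the mean and standard deviation of the
#' per-subject phase slopes, by sex and phase (the layout of the published
#' velocity table, which reports sem and sd because each cell summarises a
#' distribution of per-subject values).
#'
#' @param slopes A [subject_phase_slopes()] tibble.
#' @return Tibble with `sex`, `phase`, `velocity` (mean slope cm/yr), `sem`,
#'   `sd`, `n_subjects`. Phase/sex cells with no subject are absent, never
#'   fabricated.
#' @export
phase_velocity_summary <- function(slopes) {
  slopes |>
    dplyr::group_by(.data$sex, .data$phase) |>
    dplyr::summarise(
      velocity = mean(.data$slope),
      sd = stats::sd(.data$slope),
      sem = .data$sd / sqrt(dplyr::n()),
      n_subjects = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("sex", "phase", "velocity", "sem", "sd", "n_subjects") |>
    dplyr::arrange(.data$sex, .data$phase)
}

# round half away from zero to `digits` decimals (matches how the published
# tables are rounded; base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-segment growth rates from phase velocities
#'
#' Converts whole-spine T1-S1 velocities (cm/yr) into per-segment rates
#' (mm/segment/yr) using the segmental composition of T1-S1 height — the
#' thoracic spine 63% over 12 segments, the lumbar spine 27% over 5 — and
#' reports them to 0.1 mm (half away from zero). E.g. a childhood velocity
#' of 1.55 cm/yr gives a thoracic rate of 15.5 x 0.63 / 12 = 0.8
#' mm/segment/yr.
#'
#' @param velocities A [phase_velocity_summary()] tibble (or any tibble with
#'   `sex`, `phase`, `velocity` in cm/yr) — the reference values are
#'   [reference_phase_velocities()].
#' @param thoracic_fraction,lumbar_fraction Fractions of T1-S1 height
#'   (defaults 0.63 and 0.27).
#' @param n_thoracic,n_lumbar Segment counts (12 and 5).
#' @return The input with `thoracic_mm_per_segment` and
#'   `lumbar_mm_per_segment` columns added (rounded to 0.1 mm).
#' @export
segmental_rates <- function(velocities, thoracic_fraction = 0.63,
                            lumbar_fraction = 0.27,
                            n_thoracic = 12, n_lumbar = 5) {
  stopifnot(thoracic_fraction <= 1, lumbar_fraction <= 1)
  velocities |>
    dplyr::mutate(
      thoracic_mm_per_segment = round_half_up(
        .data$velocity * 10 * thoracic_fraction / n_thoracic, 1),
      lumbar_mm_per_segment = round_half_up(
        .data$velocity * 10 * lumbar_fraction / n_lumbar, 1)
    )
}
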
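# Growth-completion assessment and alignment on growth-spurt timing.
#
# A subject is mature when standing height increased by less than 1 cm/yr
# over the final inter-visit interval; adult height is the final visit's
# height. PGA90 is the age at which the subject first reaches 90% of adult
# height, located on a monotone interpolant of the height series.

#' Monotone standing-height interpolant
#'
#' Builds the interpolant the PGA90 estimator uses: the height sequence is
#' first made nondecreasing by isotonic regression (pool-adjacent-violators;
#' a noisy dip is averaged out rather than producing multiple crossings),
#' then interpolated by a monotone piecewise cubic (Fritsch-Carlson).
#'
#' @param age_yr,height Numeric vectors of visit ages (strictly increasing)
#'   and standing heights (cm).
#' @return A function mapping age to interpolated height; constant
#'   extrapolation outside the visit range.
#' @export
height_interpolant <- function(age_yr, height) {
  stopifnot(length(age_yr) == length(height), length(age_yr) >= 2,
            all(diff(age_yr) > 0))
  iso <- stats::isoreg(age_yr, height)$yf
  f <- stats::splinefun(age_yr, iso, method = "monoH.FC")
  lo <- age_yr[1]; hi <- age_yr[length(age_yr)]
  function(a) f(pmin(pmax(a, lo), hi))
}

#' Assess growth completion per subject
#'
#' Computes the annualized standing-height velocity over the final
#' inter-visit interval; a subject is mature when it is below 1 cm/yr. Adult
#' height is the final visit's standing height (not the maximum, which would
#' bias upward under measurement noise — the maturity criterion already
#' bounds the residual growth).
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param velocity_threshold Maturity cutoff in cm/yr (default 1).
#' @return Tibble with one row per subject: `subject_id`, `sex`, `n_visits`,
#'   `final_velocity` (cm/yr), `is_mature`, `adult_height` (cm).
#' @export
assess_maturity <- function(cohort, velocity_threshold = 1) {
  per_subject <- function(df) {
    df <- dplyr::arrange(df, .data$age_yr)
    n <- nrow(df)
    if (n < 2) {
      rlang::abort(paste0("subject ", df$subject_id[1],
                          " has fewer than 2 visits"),
                   class = "spinegrowth_validation_error")
    }
    d_age <- df$age_yr[n] - df$age_yr[n - 1]
    if (d_age <= 0) {
      rlang::abort(paste0("non-increasing ages for subject ",
                          df$subject_id[1]),
                   class = "spinegrowth_validation_error")
    }
    vel <- (df$standing_height[n] - df$standing_height[n - 1]) / d_age
    tibble::tibble(
      sex = df$sex[1],
      n_visits = n,
      final_velocity = vel,
      is_mature = vel < velocity_threshold,
      adult_height = df$standing_height[n]
    )
  }
  cohort |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ per_subject(.x |>
                                        dplyr::mutate(subject_id = .y$subject_id))) |>
    dplyr::ungroup()
}

# first crossing of a nondecreasing interpolant with `target`, bisected to
# `tol` years
first_crossing <- function(fn, age_yr, target, tol = 0.001) {
  vals <- fn(age_yr)
  idx <- which(vals >= target)[1]
  if (idx == 1) return(age_yr[1])
  lo <- age_yr[idx - 1]; hi <- age_yr[idx]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fn(mid) >= target) hi <- mid else lo <- mid
  }
  # polish within the bracket so height(pga) matches the target to
  # numerical precision, not just to the bisection grid
  if (fn(lo) < target && fn(hi) >= target) {
    root <- try(stats::uniroot(function(a) fn(a) - target, c(lo, hi),
                               tol = 1e-9)$root, silent = TRUE)
    if (!inherits(root, "try-error")) return(root)
  }
  (lo + hi) / 2
}

#' Estimate the PGA90 age of one subject
#'
#' Finds the age at which interpolated standing height first crosses 90% of
#' adult height, using [height_interpolant()] and bisection to 0.001 yr.
#'
#' @param subject_visits Visits of one subject (cohort tibble rows), at least
#'   one below and one at/above the 90% target.
#' @param adult_height Adult standing height (cm), typically from
#'   [assess_maturity()].
#' @param target_fraction Fraction of adult height defining the spurt peak
#'   (default 0.9).
#' @return The PGA90 age in years.
#' @export
estimate_pga90 <- function(subject_visits, adult_height,
                           target_fraction = 0.9) {
  df <- dplyr::arrange(subject_visits, .data$age_yr)
  target <- target_fraction * adult_height
  fn <- height_interpolant(df$age_yr, df$standing_height)
  vals <- fn(df$age_yr)
  if (vals[1] >= target) {
    rlang::abort(
      paste0("first visit already at/above ", 100 * target_fraction,
             "% of adult height (FIRST_VISIT_TOO_LATE)"),
      class = "spinegrowth_pga_error"
    )
  }
  if (max(vals) < target) {
    rlang::abort(
      paste0("height never reaches ", 100 * target_fraction,
             "% of adult height (NOT_MATURE)"),
      class = "spinegrowth_pga_error"
    )
  }
  first_crossing(fn, df$age_yr, target)
}

#' Full maturity assessment with PGA90 ages
#'
#' Runs [assess_maturity()] and, for every mature subject, [estimate_pga90()].
#' Subjects that are not mature, or whose height series does not bracket the
#' 90% target, get `NA` with a note; they are excluded from all downstream
#' multiplier and velocity estimation.
#'
#' @inheritParams assess_maturity
#' @return The [assess_maturity()] tibble with `pga90_age` and `qc_note`
#'   columns added.
#' @export
maturity_assessment <- function(cohort, velocity_threshold = 1) {
  assessment <- assess_maturity(cohort, velocity_threshold)
  res <- purrr::map(assessment$subject_id, function(id) {
    row <- assessment[assessment$subject_id == id, ]
    if (!row$is_mature) {
      return(list(pga = NA_real_, note = "not mature"))
    }
    visits <- dplyr::filter(cohort, .data$subject_id == id)
    tryCatch(
      list(pga = estimate_pga90(visits, row$adult_height), note = NA_character_),
      spinegrowth_pga_error = function(e) {
        list(pga = NA_real_, note = conditionMessage(e))
      }
    )
  })
  assessment$pga90_age <- purrr::map_dbl(res, "pga")
  assessment$qc_note <- purrr::map_chr(res, "note")
  assessment
}

#' Align visits on growth-spurt timing
#'
#' Adds `timing_yr = age_yr - pga90_age` to every visit of every subject
#' with an estimated PGA90 age; visits of subjects without one are dropped.
#'
#' @param cohort A cohort tibble.
#' @param assessment A [maturity_assessment()] tibble with `pga90_age`.
#' @return The cohort tibble with a `timing_yr` column, restricted to aligned
#'   subjects.
#' @export
align_visits <- function(cohort, assessment) {
  keyed <- dplyr::select(assessment, "subject_id", "pga90_age")
  cohort |>
    dplyr::inner_join(keyed, by = "subject_id") |>
    dplyr::filter(!is.na(.data$pga90_age)) |>
    dplyr::mutate(timing_yr = .data$age_yr - .data$pga90_age) |>
    dplyr::select(-"pga90_age") |>
    dplyr::arrange(.data$subject_id, .data$age_yr)
}
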
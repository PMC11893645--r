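# Synthetic longitudinal cohort generator.
#
# Emulates the measurement structure of a serial anthropometric +
# radiographic growth study: each child has a latent growth-spurt timing
# (PGA90 age) and adult dimensions; standing height and T1-S1 follow
# sex-independent fraction-of-adult curves aligned on that timing; visit
# records carry floor-referenced landmark heights and signed radiographic
# offsets that are geometrically consistent with the latent trajectories,
# plus independent Gaussian measurement noise.

#' Generator configuration
#'
#' Builds the configuration list for [simulate_cohort()]. Defaults encode the
#' study conditions the package's analyses are calibrated to: 35 girls and 19
#' boys; PGA90 age ~ truncated normal (girls mean 11.3 yr on (9.7, 13.4);
#' boys 13.0 on (11.7, 14.3)); adult standing height truncated normal (girls
#' 163.4 cm on (151, 175); boys 177 on (169, 183.9)), with sd = range/4 in
#' both cases; adult T1-S1 = 27% of adult height; T1-S1/C1-S1 ratio ~ normal
#' (0.762, 0.0176) truncated to (0.70, 0.82); head height (vertex to external
#' auditory meatus) constant per subject; C1 sits `eam_c1_offset` above the
#' vertex-minus-head-height point (1.7 +/- 0.3 cm).
#'
#' The spine fraction curve defaults to the reciprocal of the
#' [multiplier_reference()] body-height column; the standing-height fraction
#' curve is anchored at (-4, 0.79), (-2, 0.85), (0, 0.90), (4.25, 1.0) so
#' that height at PGA90 is exactly 90% of adult height. With
#' `trajectory_mode = "piecewise_linear"` the T1-S1 trajectory is instead
#' exactly piecewise linear in timing with the [reference_phase_velocities()]
#' slopes (negative slopes clamped to 0 to keep the truth monotone), which
#' gives velocity-recovery tests an exactly linear truth per phase.
#'
#' @param n_female,n_male Cohort composition.
#' @param trajectory_mode `"fraction_curve"` (default) or
#'   `"piecewise_linear"` for the T1-S1 trajectory.
#' @param visit_schedule `"mixed"` (biannual within 2 yr of the true spurt,
#'   annual otherwise; the default), `"annual"` or `"biannual"`. Visits run
#'   from 6 yr before to 5.5 yr after the true PGA90 age, clipped to ages
#'   >= 3.
#' @param noise_sd_anthro,noise_sd_radio Measurement noise sd (cm) for
#'   anthropometric and radiographic values.
#' @param seed Integer seed; fanned out to per-subject substreams so a
#'   subject's draws do not depend on cohort size.
#' @param ... Override any other documented field (see the function body for
#'   the full list and defaults).
#' @return A named list of class `"spine_generator_config"`.
#' @export
generator_config <- function(n_female = 35, n_male = 19,
                             trajectory_mode = c("fraction_curve", "piecewise_linear"),
                             visit_schedule = c("mixed", "annual", "biannual"),
                             noise_sd_anthro = 0.3, noise_sd_radio = 0.2,
                             seed = 1L, ...) {
  ref <- multiplier_reference()
  config <- list(
    n_female = n_female,
    n_male = n_male,
    pga_age_mean_f = 11.3, pga_age_range_f = c(9.7, 13.4),
    pga_age_mean_m = 13.0, pga_age_range_m = c(11.7, 14.3),
    adult_height_mean_f = 163.4, adult_height_range_f = c(151, 175),
    adult_height_mean_m = 177, adult_height_range_m = c(169, 183.9),
    truth_sd_scale = 1,
    spine_fraction_anchors = tibble::tibble(
      timing_yr = ref$timing_yr, fraction = 1 / ref$body_height),
    height_fraction_anchors = tibble::tibble(
      timing_yr = c(-4, -2, 0, 4.25), fraction = c(0.79, 0.85, 0.90, 1.0)),
    adult_t1s1_fraction_of_height = 0.27,
    c1s1_ratio = 0.762, c1s1_ratio_sd = 0.0176,
    c1s1_ratio_range = c(0.70, 0.82),
    eam_c1_offset_mean = 1.7, eam_c1_offset_sd = 0.3,
    head_height_mean = 13.0, head_height_sd = 0.8,
    notch_t1_offset_mean = 2.5, notch_t1_offset_sd = 0.5,
    pelvic_offset_mean = c(symphysis = 14, crest = -3, asis = -1),
    pelvic_offset_sd = 1,
    pelvic_width_adult_mean = 27, pelvic_width_adult_sd = 1.5,
    body_spine_beta = 1.378,
    phase_velocities = reference_phase_velocities(),
    noise_sd_anthro = noise_sd_anthro,
    noise_sd_radio = noise_sd_radio,
    trajectory_mode = match.arg(trajectory_mode),
    visit_schedule = match.arg(visit_schedule),
    seed = as.integer(seed)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown generator config field(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "spinegrowth_config_error")
  }
  config[names(overrides)] <- overrides
  validate_generator_config(config)
  structure(config, class = "spine_generator_config")
}

validate_generator_config <- function(config) {
  chk <- function(ok, msg) {
    if (!ok) rlang::abort(msg, class = "spinegrowth_config_error")
  }
  chk(config$n_female >= 0 && config$n_male >= 0, "cohort sizes must be >= 0")
  for (anch in list(config$spine_fraction_anchors,
                    config$height_fraction_anchors)) {
    chk(all(diff(anch$timing_yr) > 0), "anchor timings must strictly increase")
    chk(all(diff(anch$fraction) >= 0), "anchor fractions must be nondecreasing")
    chk(all(anch$fraction > 0 & anch$fraction <= 1),
        "anchor fractions must lie in (0, 1]")
    chk(abs(anch$fraction[nrow(anch)] - 1) < 1e-12,
        "anchor grids must end at fraction 1")
  }
  rng_ok <- function(m, r) r[1] <= m && m <= r[2]
  chk(rng_ok(config$pga_age_mean_f, config$pga_age_range_f) &&
        rng_ok(config$pga_age_mean_m, config$pga_age_range_m) &&
        rng_ok(config$adult_height_mean_f, config$adult_height_range_f) &&
        rng_ok(config$adult_height_mean_m, config$adult_height_range_m),
      "ranges must contain their means")
  sds <- c(config$truth_sd_scale, config$c1s1_ratio_sd, config$eam_c1_offset_sd,
           config$head_height_sd, config$notch_t1_offset_sd,
           config$pelvic_offset_sd, config$pelvic_width_adult_sd,
           config$noise_sd_anthro, config$noise_sd_radio)
  chk(all(sds >= 0), "all sds must be >= 0")
  invisible(config)
}

#' Make a generator configuration deterministic
#'
#' Sets every subject-level and measurement sd in a generator config to zero,
#' so all subjects of a sex are identical and every recorded value equals its
#' latent truth. Used for the closure tests in which the full pipeline must
#' reproduce the generator's own curves exactly.
#'
#' @param config A [generator_config()].
#' @return The modified config.
#' @export
noise_free <- function(config) {
  config$truth_sd_scale <- 0
  config$c1s1_ratio_sd <- 0
  config$eam_c1_offset_sd <- 0
  config$head_height_sd <- 0
  config$notch_t1_offset_sd <- 0
  config$pelvic_offset_sd <- 0
  config$pelvic_width_adult_sd <- 0
  config$noise_sd_anthro <- 0
  config$noise_sd_radio <- 0
  config
}

# inverse-CDF truncated normal draw; one uniform per draw so substreams are
# reproducible independent of acceptance/rejection
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Draw the latent truth for one subject
#'
#' Draws the subject-level parameters (PGA90 age, adult standing height,
#' T1-S1/C1-S1 ratio, head height, landmark offsets) from the configured
#' truncated-normal distributions, using the current RNG state. Adult T1-S1
#' is the configured fraction of adult height; adult C1-S1 is adult T1-S1
#' divided by the subject's ratio.
#'
#' @param config A [generator_config()].
#' @param sex `"F"` or `"M"`.
#' @param subject_id Identifier carried into the cohort table.
#' @return One-row tibble of latent truth values.
#' @export
sample_subject_truth <- function(config, sex, subject_id = paste0(sex, "001")) {
  stopifnot(sex %in% c("F", "M"))
  f <- sex == "F"
  s <- config$truth_sd_scale
  pga_mean <- if (f) config$pga_age_mean_f else config$pga_age_mean_m
  pga_range <- if (f) config$pga_age_range_f else config$pga_age_range_m
  ah_mean <- if (f) config$adult_height_mean_f else config$adult_height_mean_m
  ah_range <- if (f) config$adult_height_range_f else config$adult_height_range_m
  pga <- rtruncnorm(1, pga_mean, s * diff(pga_range) / 4,
                    pga_range[1], pga_range[2])
  adult_height <- rtruncnorm(1, ah_mean, s * diff(ah_range) / 4,
                             ah_range[1], ah_range[2])
  ratio <- rtruncnorm(1, config$c1s1_ratio, config$c1s1_ratio_sd,
                      config$c1s1_ratio_range[1], config$c1s1_ratio_range[2])
  adult_t1s1 <- config$adult_t1s1_fraction_of_height * adult_height
  po <- config$pelvic_offset_mean
  tibble::tibble(
    subject_id = subject_id,
    sex = sex,
    true_pga_age = pga,
    true_adult_height = adult_height,
    true_c1s1_ratio = ratio,
    true_adult_t1s1 = adult_t1s1,
    true_adult_c1s1 = adult_t1s1 / ratio,
    true_head_height = stats::rnorm(1, config$head_height_mean,
                                    config$head_height_sd),
    true_eam_c1_offset = stats::rnorm(1, config$eam_c1_offset_mean,
                                      config$eam_c1_offset_sd),
    true_notch_t1_offset = stats::rnorm(1, config$notch_t1_offset_mean,
                                        config$notch_t1_offset_sd),
    true_symphysis_s1 = stats::rnorm(1, po[["symphysis"]],
                                     config$pelvic_offset_sd),
    true_crest_s1 = stats::rnorm(1, po[["crest"]], config$pelvic_offset_sd),
    true_asis_s1 = stats::rnorm(1, po[["asis"]], config$pelvic_offset_sd),
    true_adult_pelvic_width = stats::rnorm(1, config$pelvic_width_adult_mean,
                                           config$pelvic_width_adult_sd)
  )
}

# monotone fraction-of-adult curve: monotone piecewise-cubic (Fritsch-Carlson)
# inside the anchor range, exactly 1 at/after the last anchor, linear
# extension below the first anchor at the first segment's slope
fraction_fun <- function(anchors) {
  t0 <- anchors$timing_yr
  f0 <- anchors$fraction
  interp <- stats::splinefun(t0, f0, method = "monoH.FC")
  slope1 <- (f0[2] - f0[1]) / (t0[2] - t0[1])
  n <- length(t0)
  function(timing) {
    out <- interp(pmin(pmax(timing, t0[1]), t0[n]))
    below <- timing < t0[1]
    out[below] <- pmax(f0[1] + slope1 * (timing[below] - t0[1]), 0.05)
    out[timing >= t0[n]] <- 1
    out
  }
}

#' Latent standing-height trajectory
#'
#' True standing height (cm) at a timing (years relative to the subject's
#' true PGA90 age): adult height times the monotone height-fraction curve,
#' which is 0.90 at timing 0 by construction and exactly 1 from the terminal
#' anchor on.
#'
#' @param truth One-row truth tibble from [sample_subject_truth()].
#' @param config A [generator_config()].
#' @param timing Numeric vector of timings (yr).
#' @return Numeric vector of heights (cm).
#' @export
height_trajectory <- function(truth, config, timing) {
  truth$true_adult_height * fraction_fun(config$height_fraction_anchors)(timing)
}

#' Latent T1-S1 trajectory
#'
#' True T1-S1 spine height (cm) at a timing relative to the subject's true
#' PGA90 age. In `"fraction_curve"` mode this is adult T1-S1 times the
#' monotone spine-fraction curve (the reciprocal of the reference body-height
#' multiplier column); in `"piecewise_linear"` mode it is exactly piecewise
#' linear with the configured per-sex phase velocities, anchored so that
#' T1-S1 equals adult T1-S1 at timing +4 (negative velocities clamped to 0).
#'
#' @inheritParams height_trajectory
#' @return Numeric vector of T1-S1 heights (cm).
#' @export
spine_trajectory <- function(truth, config, timing) {
  if (config$trajectory_mode == "fraction_curve") {
    return(truth$true_adult_t1s1 *
             fraction_fun(config$spine_fraction_anchors)(timing))
  }
  v <- config$phase_velocities |>
    dplyr::filter(.data$sex == truth$sex) |>
    dplyr::arrange(.data$phase)
  vel <- pmax(stats::setNames(v$velocity, as.character(v$phase)), 0)
  adult <- truth$true_adult_t1s1
  vapply(timing, function(t) {
    if (t >= 4) return(adult + vel[["mature"]] * (t - 4))
    val <- adult
    val <- val - vel[["terminal"]] * (4 - max(t, 2))
    if (t < 2) val <- val - vel[["spurt"]] * (2 - max(t, -2))
    if (t < -2) val <- val - vel[["childhood"]] * (-2 - t)
    val
  }, numeric(1))
}

visit_timings <- function(schedule) {
  switch(schedule,
    annual = c(seq(-6, 5, by = 1), 5.5),
    biannual = seq(-6, 5.5, by = 0.5),
    mixed = sort(unique(c(seq(-6, -2, by = 1), seq(-2, 2, by = 0.5),
                          seq(2, 5, by = 1), 5.5)))
  )
}

#' Generate the visit records for one subject
#'
#' Lays visits on the configured schedule from 6 yr before to 5.5 yr after
#' the subject's true PGA90 age (ages below 3 dropped), evaluates the latent
#' trajectories, derives geometrically consistent floor-referenced landmark
#' heights and signed radiographic offsets, and adds measurement noise.
#' Geometry: the top of C1 sits at standing height - head height +
#' EAM-C1 offset; S1 = C1 - C1-S1; T1 = S1 + T1-S1; each pelvic landmark sits
#' its subject-constant offset below/above S1; the sternal notch sits its
#' subject-constant offset below T1. With all sds zero every recorded value
#' equals its latent truth, so the direct reconstruction is exact.
#'
#' @inheritParams height_trajectory
#' @return A cohort tibble (one row per visit) for this subject.
#' @export
generate_subject <- function(truth, config) {
  rel <- visit_timings(config$visit_schedule)
  age <- truth$true_pga_age + rel
  keep <- age >= 3
  rel <- rel[keep]; age <- age[keep]
  n <- length(age)
  ea <- function() stats::rnorm(n, 0, config$noise_sd_anthro)
  er <- function() stats::rnorm(n, 0, config$noise_sd_radio)

  h <- height_trajectory(truth, config, rel)
  t1s1 <- spine_trajectory(truth, config, rel)
  c1s1 <- t1s1 / truth$true_c1s1_ratio
  c1_h <- h - truth$true_head_height + truth$true_eam_c1_offset
  s1_h <- c1_h - c1s1
  t1_h <- s1_h + t1s1
  spine_frac <- t1s1 / truth$true_adult_t1s1

  tibble::tibble(
    subject_id = truth$subject_id,
    sex = truth$sex,
    age_yr = age,
    standing_height = h + ea(),
    sitting_height = 0.52 * h + ea(),
    h_sternal_notch = (t1_h - truth$true_notch_t1_offset) + ea(),
    h_symphysis = (s1_h - truth$true_symphysis_s1) + ea(),
    h_iliac_crest = (s1_h - truth$true_crest_s1) + ea(),
    h_asis = (s1_h - truth$true_asis_s1) + ea(),
    h_trochanter = NA_real_,
    head_height = truth$true_head_height + ea(),
    off_notch_T1 = truth$true_notch_t1_offset + er(),
    off_pelvis_S1 = truth$true_symphysis_s1 + er(),
    pelvic_landmark = "symphysis",
    off_eam_C1 = truth$true_eam_c1_offset + er(),
    pelvic_width = truth$true_adult_pelvic_width * spine_frac + ea()
  )
}

subject_seed <- function(seed, sex, k) {
  base <- (as.numeric(seed) %% 1000003) * 2099
  offset <- if (sex == "M") 5e5 else 0
  as.integer((base + offset + k) %% 2147483629) + 1L
}

#' Simulate a longitudinal cohort
#'
#' Draws `n_female + n_male` subjects and their visit records. The global
#' seed is fanned out to one substream per subject, so changing the cohort
#' size adds or removes subjects without reshuffling the others, and the same
#' config yields an identical cohort every time. The caller's RNG state is
#' left untouched.
#'
#' @param config A [generator_config()].
#' @return A list with `visits` (cohort tibble, all subjects) and `truth`
#'   (one row of latent parameters per subject, for recovery testing).
#' @examples
#' sim <- simulate_cohort(generator_config(n_female = 2, n_male = 1))
#' dplyr::count(sim$visits, subject_id)
#' @export
simulate_cohort <- function(config = generator_config()) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  one <- function(sex, k) {
    set.seed(subject_seed(config$seed, sex, k))
    truth <- sample_subject_truth(config, sex,
                                  subject_id = sprintf("%s%03d", sex, k))
    list(truth = truth, visits = generate_subject(truth, config))
  }
  subs <- c(
    lapply(seq_len(config$n_female), function(k) one("F", k)),
    lapply(seq_len(config$n_male), function(k) one("M", k))
  )
  list(
    visits = dplyr::bind_rows(lapply(subs, `[[`, "visits")),
    truth = dplyr::bind_rows(lapply(subs, `[[`, "truth"))
  )
}

#' Simulate unit-agnostic (spine, body) calibration pairs
#'
#' The calibration generator for the through-origin regression: draws `x`
#' uniform on `x_range` and `y = beta * x + N(0, noise_sd)`. Deliberately
#' separate from the anatomical cohort — a single proportionality constant
#' between a spine measure and stature is not anatomically consistent with
#' the fraction curves, so regression recovery is tested on pairs whose truth
#' is exactly proportional.
#'
#' @param n Number of pairs.
#' @param beta True proportionality constant (default 1.378).
#' @param noise_sd Gaussian noise sd on `y` (default 0.5).
#' @param x_range Range of the uniform `x` draw.
#' @param seed Integer seed (caller's RNG state preserved).
#' @return Tibble with columns `spine` (`x`) and `body` (`y`).
#' @export
simulate_beta_pairs <- function(n = 500, beta = 1.378, noise_sd = 0.5,
                                x_range = c(30, 50), seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  x <- stats::runif(n, x_range[1], x_range[2])
  tibble::tibble(spine = x, body = beta * x + stats::rnorm(n, 0, noise_sd))
}
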
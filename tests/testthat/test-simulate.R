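test_that("degenerate (all-sds-zero) truths hit the configured means exactly", {
  cfg <- noise_free(generator_config())
  set.seed(1)
  f <- sample_subject_truth(cfg, "F")
  expect_equal(f$true_pga_age, 11.3)
  expect_equal(f$true_adult_height, 163.4)
  expect_equal(f$true_adult_t1s1, 0.27 * 163.4)  # 44.118
  expect_equal(f$true_adult_c1s1, f$true_adult_t1s1 / 0.762)
  m <- sample_subject_truth(cfg, "M")
  expect_equal(m$true_adult_height, 177)
  expect_equal(m$true_pga_age, 13.0)
})

test_that("subject-level draws match the truncated-normal oracle", {
  # closed-form truncated-normal mean, independent of the sampler
  trunc_mean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  cfg <- generator_config()
  set.seed(42)
  draws <- purrr::map_dfr(1:10000, ~ sample_subject_truth(cfg, "F"))
  sd_pga <- diff(cfg$pga_age_range_f) / 4
  expect_true(all(draws$true_pga_age >= 9.7 & draws$true_pga_age <= 13.4))
  expect_true(all(draws$true_adult_height >= 151 &
                    draws$true_adult_height <= 175))
  mc_se <- sd(draws$true_pga_age) / sqrt(nrow(draws))
  expect_equal(mean(draws$true_pga_age),
               trunc_mean(11.3, sd_pga, 9.7, 13.4),
               tolerance = 3 * mc_se / 11.3)
  sd_h <- diff(cfg$adult_height_range_f) / 4
  mc_se_h <- sd(draws$true_adult_height) / sqrt(nrow(draws))
  expect_equal(mean(draws$true_adult_height),
               trunc_mean(163.4, sd_h, 151, 175),
               tolerance = 3 * mc_se_h / 163.4)
})

test_that("latent trajectories hit the calibration anchors", {
  cfg <- noise_free(generator_config())
  set.seed(1)
  tr <- sample_subject_truth(cfg, "F")
  adult <- tr$true_adult_t1s1
  # spine fraction curve is the reciprocal of the body-height multipliers
  expect_equal(spine_trajectory(tr, cfg, 0), adult / 1.148)
  expect_equal(spine_trajectory(tr, cfg, -2), adult / 1.274)
  expect_equal(spine_trajectory(tr, cfg, 10), adult)
  expect_equal(spine_trajectory(tr, cfg, 4.5), adult)
  # standing height: 90% of adult at the spurt peak, 85% two years before
  expect_equal(height_trajectory(tr, cfg, 0), 0.90 * tr$true_adult_height)
  expect_equal(height_trajectory(tr, cfg, -2), 0.85 * tr$true_adult_height)
  expect_equal(height_trajectory(tr, cfg, 4.25), tr$true_adult_height)
})

test_that("piecewise-linear mode gives exactly linear phases with clamped slopes", {
  cfg <- noise_free(generator_config(trajectory_mode = "piecewise_linear"))
  set.seed(1)
  trf <- sample_subject_truth(cfg, "F")
  trm <- sample_subject_truth(cfg, "M")
  # girls spurt slope 1.75 between -2 and +2
  expect_equal(
    (spine_trajectory(trf, cfg, 1) - spine_trajectory(trf, cfg, -1)) / 2,
    1.75)
  # boys childhood slope 1.14
  expect_equal(
    (spine_trajectory(trm, cfg, -3) - spine_trajectory(trm, cfg, -5)) / 2,
    1.14)
  # boys' negative mature slope is clamped to zero in the truth
  expect_equal(spine_trajectory(trm, cfg, 6), spine_trajectory(trm, cfg, 4))
  # anchored at adult T1-S1 at timing +4
  expect_equal(spine_trajectory(trf, cfg, 4), trf$true_adult_t1s1)
})

test_that("generation is deterministic and per-subject streams are stable", {
  cfg <- generator_config(n_female = 3, n_male = 2, seed = 5)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_cohort(generator_config(n_female = 3, n_male = 2, seed = 6))
  expect_false(identical(s1$visits, s3$visits))
  # growing the cohort must not reshuffle existing subjects' draws
  s5 <- simulate_cohort(generator_config(n_female = 5, n_male = 2, seed = 5))
  expect_identical(
    dplyr::filter(s5$visits, subject_id %in% c("F001", "F002", "F003")),
    dplyr::filter(s1$visits, subject_id %in% c("F001", "F002", "F003")))
})

test_that("noise-free subjects are internally consistent", {
  cfg <- noise_free(generator_config())
  set.seed(2)
  tr <- sample_subject_truth(cfg, "F", "F001")
  visits <- generate_subject(tr, cfg)
  rel <- visits$age_yr - tr$true_pga_age
  # true trajectories are nondecreasing in age
  expect_true(all(diff(visits$standing_height) >= 0))
  # direct reconstruction equals the latent T1-S1 exactly
  m1 <- method1_t1s1(visits)
  expect_equal(m1$t1s1, spine_trajectory(tr, cfg, rel), tolerance = 1e-9)
  # the percent-C1-S1 method with the EAM correction is also exact
  m2 <- method2_t1s1(visits, ratio = tr$true_c1s1_ratio,
                     apply_eam_offset = TRUE)
  expect_equal(m2$t1s1, spine_trajectory(tr, cfg, rel), tolerance = 1e-9)
  # plateau: the final inter-visit interval is below 1 cm/yr annualized
  n <- nrow(visits)
  vel <- diff(visits$standing_height)[n - 1] / diff(visits$age_yr)[n - 1]
  expect_lt(vel, 1)
})

test_that("the default cohort has the study composition", {
  sim <- default_sim()
  expect_equal(length(unique(sim$visits$subject_id)), 54)
  expect_equal(sum(startsWith(unique(sim$visits$subject_id), "F")), 35)
  expect_equal(sum(startsWith(unique(sim$visits$subject_id), "M")), 19)
  expect_equal(nrow(sim$truth), 54)
  # every subject's recorded heights respect the basic anatomy
  expect_true(all(sim$visits$head_height < sim$visits$standing_height))
  expect_true(all(sim$visits$h_sternal_notch < sim$visits$standing_height))
})

test_that("config validation rejects inconsistent setups", {
  expect_error(generator_config(nonsense_field = 1),
               class = "spinegrowth_config_error")
  expect_error(generator_config(pga_age_mean_f = 20),
               class = "spinegrowth_config_error")
  expect_error(generator_config(noise_sd_anthro = -1),
               class = "spinegrowth_config_error")
})

test_that("the unit-agnostic pair generator has the declared structure", {
  pairs <- simulate_beta_pairs(n = 200, beta = 2, noise_sd = 0, seed = 4)
  expect_equal(pairs$body, 2 * pairs$spine)
  expect_true(all(pairs$spine >= 30 & pairs$spine <= 50))
  expect_identical(simulate_beta_pairs(seed = 9), simulate_beta_pairs(seed = 9))
})
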
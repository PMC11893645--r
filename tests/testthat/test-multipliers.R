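fake_obs <- function(subject_id, timing, mult, method = "direct",
                     sex = "F") {
  tibble::tibble(subject_id = subject_id, sex = sex,
                 age_yr = timing + 12, timing_yr = timing,
                 method = method, t1s1 = 44 / mult, adult_t1s1 = 44,
                 multiplier = mult)
}

test_that("the multiplier is adult over current spine height", {
  est <- tibble::tibble(
    subject_id = "A", sex = "F", age_yr = c(12, 17, 18),
    timing_yr = c(0, 4.5, 5.5), method = "direct",
    t1s1 = c(38.324, 44.0, 44.0))
  obs <- compute_multipliers(est)
  expect_equal(obs$adult_t1s1, rep(44, 3))
  expect_equal(round(obs$multiplier[1], 3), 1.148)  # 44 / 38.324
  expect_equal(obs$multiplier[2:3], c(1, 1))
  # subjects with no mature-phase visit are skipped with a warning
  young <- dplyr::filter(est, timing_yr < 4)
  expect_warning(out <- compute_multipliers(young), "skipping")
  expect_equal(nrow(out), 0)
})

test_that("the reference table satisfies its structural invariants", {
  ref <- multiplier_reference()
  expect_equal(nrow(ref), 18)
  expect_true(all(diff(ref$pct_c1s1) <= 0))
  expect_true(all(diff(ref$body_height) <= 0))
  # the percent-C1-S1 column steps down by exactly 0.022 per half year
  # from -4 through +3.5
  steps <- diff(ref$pct_c1s1[ref$timing_yr <= 3.5])
  expect_equal(steps, rep(-0.022, 15))
  expect_true(all(abs(ref$pct_c1s1[ref$timing_yr >= 4] - 1) <= 0.005))
  expect_true(all(abs(ref$body_height[ref$timing_yr >= 4] - 1) <= 0.005))
})

test_that("binning follows the half-open half-year convention", {
  obs <- dplyr::bind_rows(
    fake_obs("A", -0.25, 1.2),   # exactly on a boundary: belongs to bin 0
    fake_obs("A", -0.26, 1.2),   # just below: bin -0.5
    fake_obs("A", 0.10, 1.1)
  )
  tab <- build_multiplier_table(obs)
  expect_equal(tab$n[tab$timing_yr == 0], 2)
  expect_equal(tab$n[tab$timing_yr == -0.5], 1)
  # empty bins are reported missing, never interpolated
  expect_true(is.na(tab$multiplier[tab$timing_yr == 2]))
  expect_equal(tab$n[tab$timing_yr == 2], 0)
})

test_that("unit observations give unit cells and mature cells are 1.000", {
  obs <- dplyr::bind_rows(purrr::map(
    seq(-4, 4.5, 0.5), ~ fake_obs("A", .x, 1.0)))
  tab <- build_multiplier_table(obs)
  expect_equal(tab$multiplier, rep(1, 18))
  # mature-phase cells are pinned at 1.000 by the adult definition
  noisy <- dplyr::bind_rows(fake_obs("A", 4.0, 1.004), fake_obs("B", 4.5, 0.997))
  tab2 <- build_multiplier_table(noisy)
  expect_equal(tab2$multiplier[tab2$timing_yr >= 4 & tab2$n > 0], c(1, 1))
})

test_that("interpolation is exact at grid points and linear between them", {
  expect_equal(interpolate_multiplier(0), 1.148)
  expect_equal(interpolate_multiplier(0, column = "pct_c1s1"), 1.160)
  expect_equal(interpolate_multiplier(0.25), (1.148 + 1.117) / 2)  # 1.1325
  expect_equal(interpolate_multiplier(5), 1)
  expect_error(interpolate_multiplier(-4.5), "OUT_OF_RANGE",
               class = "spinegrowth_range_error")
})

test_that("adult spine prediction brackets with the two recommended columns", {
  p0 <- predict_adult_spine(38, 0)
  expect_equal(p0$lower, 38 * 1.148)   # 43.624 — body-height column smaller here
  expect_equal(p0$upper, 38 * 1.160)   # 44.08
  expect_equal(p0$lower_method, "body_height")
  expect_equal(p0$predicted, (p0$lower + p0$upper) / 2)

  pm2 <- predict_adult_spine(30, -2)
  expect_equal(sort(c(pm2$lower, pm2$upper)), c(30 * 1.248, 30 * 1.274))
  expect_equal(pm2$lower_method, "pct_c1s1")  # columns cross near -0.5

  # identity at maturity
  pid <- predict_adult_spine(41.7, 4.5)
  expect_equal(c(pid$predicted, pid$lower, pid$upper), rep(41.7, 3))
})

test_that("noise-free pipeline closure reproduces the inverted fraction curve", {
  res <- closure_result()
  tab <- dplyr::filter(res$multiplier_table, method == "direct", n > 0)
  joined <- dplyr::inner_join(tab, multiplier_reference(), by = "timing_yr")
  expect_gt(nrow(joined), 12)
  expect_true(all(abs(joined$multiplier - joined$body_height) < 0.01))
})

test_that("recovered multiplier columns are monotone nonincreasing", {
  res <- default_result()
  for (m in unique(res$multiplier_table$method)) {
    col <- dplyr::filter(res$multiplier_table, method == m, n >= 5)
    expect_true(all(diff(col$multiplier) <= 0.005),
                label = paste("monotone column for", m))
  }
})

test_that("the recovered direct-method cells match the reference table", {
  res <- default_result()
  tab <- dplyr::filter(res$multiplier_table, method == "direct")
  expect_equal(tab$multiplier[tab$timing_yr == -2], 1.274, tolerance = 0.02 / 1.274)
  expect_equal(tab$multiplier[tab$timing_yr == 0], 1.148, tolerance = 0.02 / 1.148)
})
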
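test_that("S1 height is the landmark height plus the signed offset", {
  sym <- s1_height(make_visit(h_symphysis = 82, off_pelvis_S1 = 14))
  expect_equal(sym$s1_height, 96)
  expect_equal(sym$landmark, "symphysis")

  crest <- s1_height(make_visit(h_iliac_crest = 99, off_pelvis_S1 = -3,
                                pelvic_landmark = "crest"))
  expect_equal(crest$s1_height, 96)
  expect_equal(crest$landmark, "crest")

  # fallback priority symphysis > crest > asis when the named landmark is NA
  fb <- s1_height(make_visit(h_symphysis = NA, h_iliac_crest = 99,
                             off_pelvis_S1 = -3))
  expect_equal(fb$landmark, "crest")
})

test_that("the direct method is T1 height minus S1 height", {
  v <- make_visit(h_sternal_notch = 134, off_notch_T1 = 2.5,
                  h_symphysis = 82, off_pelvis_S1 = 14)
  m1 <- method1_t1s1(v)
  expect_equal(m1$t1s1, 134 + 2.5 - 96)  # 40.5
  expect_equal(m1$method, "direct")
  expect_error(method1_t1s1(make_visit(off_notch_T1 = -40)),
               "NEGATIVE_SPAN", class = "spinegrowth_span_error")
})

test_that("the percent-C1-S1 method follows its stated arithmetic", {
  v <- make_visit(standing_height = 163.4, head_height = 13,
                  h_symphysis = 82, off_pelvis_S1 = 14)
  off <- method2_t1s1(v)  # EAM correction off by default
  expect_equal(off$c1s1, 163.4 - 13 - 96)           # 54.4
  expect_equal(off$t1s1, 0.762 * 54.4)               # 41.453 to 3 d.p.
  expect_equal(round(off$t1s1, 3), 41.453)

  on <- method2_t1s1(v, apply_eam_offset = TRUE)     # recorded offset 1.7
  expect_equal(on$c1s1, 56.1)
  v_no_rec <- make_visit(standing_height = 163.4, head_height = 13,
                         off_eam_C1 = NA)
  on2 <- method2_t1s1(v_no_rec, apply_eam_offset = TRUE)
  expect_equal(on2$c1s1, 56.1)                       # default 1.7 fallback

  ident <- method2_t1s1(v, ratio = 1)
  expect_equal(ident$t1s1, ident$c1s1)
})

test_that("the pooled C1-S1 ratio is a median with its sd", {
  # three visits engineered so t1s1/c1s1 is exactly 0.75, 0.76, 0.77:
  # s1 = 96, c1 = 146 (standing 163.4 - head 19.1 + eam 1.7), c1s1 = 50
  mk <- function(age, r) {
    make_visit(age_yr = age, standing_height = 163.4, head_height = 19.1,
               off_eam_C1 = 1.7, h_symphysis = 82, off_pelvis_S1 = 14,
               h_sternal_notch = 96 + 50 * r - 2, off_notch_T1 = 2)
  }
  v <- dplyr::bind_rows(mk(10, 0.75), mk(11, 0.76), mk(12, 0.77))
  expect_warning(res <- estimate_c1s1_ratio(v), "LOW_N")
  expect_equal(res$median, 0.76)
  expect_equal(res$n, 3)

  same <- dplyr::bind_rows(mk(10, 0.76), mk(11, 0.76), mk(12, 0.76))
  expect_warning(res2 <- estimate_c1s1_ratio(same), "LOW_N")
  expect_equal(res2$sd, 0)
})

test_that("fit_beta equals the closed form and an independent lm oracle", {
  expect_equal(fit_beta(tibble::tibble(spine = c(1, 2),
                                       body = c(2, 4)))$beta_hat, 2)
  expect_equal(fit_beta(tibble::tibble(spine = c(1, 1),
                                       body = c(1, 3)))$beta_hat, 2)
  set.seed(8)
  for (i in 1:5) {
    x <- runif(40, 10, 60); y <- 1.4 * x + rnorm(40)
    fit <- fit_beta(tibble::tibble(spine = x, body = y))
    expect_equal(fit$beta_hat, sum(x * y) / sum(x^2))
    expect_equal(fit$beta_hat,
                 unname(coef(lm(y ~ x + 0))), tolerance = 1e-10)
  }
  expect_error(fit_beta(tibble::tibble(spine = c(0, 0), body = c(1, 2))),
               "DEGENERATE", class = "spinegrowth_fit_error")
  expect_error(fit_beta(tibble::tibble(spine = 1, body = 1)),
               class = "spinegrowth_fit_error")
})

test_that("fit_beta recovers the generating constant from noisy pairs", {
  fit <- fit_beta(simulate_beta_pairs(n = 500, seed = 1))
  expect_equal(fit$beta_hat, 1.378, tolerance = 0.005 / 1.378)
  td <- tidy(fit)
  expect_equal(td$estimate, fit$beta_hat)
  expect_equal(glance(fit)$nobs, 500)
})

test_that("method 3 inverts its own fit and enforces the convention tag", {
  fit <- fit_beta(tibble::tibble(spine = c(30, 40), body = c(30, 40) * 1.378))
  v <- make_visit(standing_height = 163.4)
  m3 <- method3_t1s1(v, fit)
  expect_equal(m3$t1s1, 163.4 / 1.378)
  ident <- fit_beta(tibble::tibble(spine = c(1, 2), body = c(1, 2)))
  expect_equal(method3_t1s1(v, ident)$t1s1, 163.4)
  expect_error(method3_t1s1(v, fit, convention = "normalized"),
               "CONVENTION", class = "spinegrowth_fit_error")
  # algebraic inverse: on the fitting cohort, method 3 reproduces the fitted
  # spine measure at every visit
  cohort <- simulate_cohort(noise_free(generator_config(
    n_female = 1, n_male = 0, seed = 4)))$visits
  m1 <- method1_t1s1(cohort)
  pairs <- tibble::tibble(spine = m1$t1s1, body = cohort$standing_height)
  bf <- fit_beta(pairs)
  out <- method3_t1s1(cohort, bf)
  expect_equal(out$t1s1, cohort$standing_height / bf$beta_hat)
})

test_that("direct-method error matches the noise-propagation prediction", {
  sim <- default_sim()
  cfg <- generator_config(seed = 1)
  m1 <- method1_t1s1(sim$visits)
  err <- unlist(purrr::map(unique(sim$visits$subject_id), function(id) {
    tr <- sim$truth[sim$truth$subject_id == id, ]
    est <- m1[m1$subject_id == id, ]
    est$t1s1 - spine_trajectory(tr, cfg, est$age_yr - tr$true_pga_age)
  }))
  # t1s1 = (notch + offT1) - (symphysis + offS1):
  # two anthropometric + two radiographic noise terms
  predicted <- sqrt(2 * cfg$noise_sd_anthro^2 + 2 * cfg$noise_sd_radio^2)
  expect_equal(mean(err), 0, tolerance = 0.05)
  expect_equal(sd(err), predicted, tolerance = 0.1)
})

test_that("method scatter ordering: direct > percent-C1-S1 > body regression", {
  res <- default_result()
  vars <- purrr::map_dbl(
    c("direct", "c1s1_fraction", "body_regression"),
    function(m) {
      obs <- dplyr::filter(res$multipliers, method == m)
      var(tidy(fit_multiplier_spline(obs, "timing"))$residual)
    })
  expect_true(vars[1] > vars[2])
  expect_true(vars[2] > vars[3])
})
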
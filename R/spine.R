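# Per-visit T1-S1 (and C1-S1) spine-height reconstruction by three methods:
#   direct          — radiographically located T1 minus S1 (Method 1)
#   c1s1_fraction   — fixed percentage of reconstructed C1-S1 (Method 2)
#   body_regression — through-origin regression on standing height (Method 3)

#' S1 height from a pelvic landmark plus its radiographic offset
#'
#' Floor-referenced height of the top of S1: the recorded pelvic landmark
#' height plus the signed (upward-positive) radiographic offset from that
#' landmark to S1. The landmark is the one named in `pelvic_landmark`; when
#' that column is missing/NA the first available of symphysis > iliac crest >
#' ASIS is used (fixed priority, for reproducibility).
#'
#' @param visits Cohort tibble rows.
#' @return Tibble with `s1_height` (cm) and `landmark` (provenance) columns
#'   appended; rows where no landmark height or offset is available get `NA`.
#' @export
s1_height <- function(visits) {
  lm_col <- c(symphysis = "h_symphysis", crest = "h_iliac_crest",
              asis = "h_asis")
  pick <- function(landmark, sym, crest, asis) {
    if (!is.na(landmark) && landmark %in% names(lm_col)) {
      h <- c(symphysis = sym, crest = crest, asis = asis)[[landmark]]
      if (!is.na(h)) return(list(h = h, lm = landmark))
    }
    for (cand in names(lm_col)) {
      h <- c(symphysis = sym, crest = crest, asis = asis)[[cand]]
      if (!is.na(h)) return(list(h = h, lm = cand))
    }
    list(h = NA_real_, lm = NA_character_)
  }
  picked <- purrr::pmap(
    list(visits$pelvic_landmark, visits$h_symphysis,
         visits$h_iliac_crest, visits$h_asis), pick)
  visits |>
    dplyr::mutate(
      s1_height = purrr::map_dbl(picked, "h") + .data$off_pelvis_S1,
      landmark = purrr::map_chr(picked, "lm")
    )
}

spine_estimate_cols <- function(df, method) {
  df |>
    dplyr::mutate(method = method) |>
    dplyr::select(dplyr::any_of(c(
      "subject_id", "sex", "age_yr", "timing_yr", "method",
      "t1s1", "c1s1", "s1_height", "landmark")))
}

#' Method 1: direct T1-S1 reconstruction
#'
#' T1 height is the sternal-notch height plus the radiographic notch-to-T1
#' offset; T1-S1 is T1 height minus [s1_height()]. A non-positive span is an
#' error (`NEGATIVE_SPAN`) — it signals inconsistent offsets, not a short
#' spine.
#'
#' @param visits Cohort tibble rows.
#' @return Long spine-estimate tibble (`method = "direct"`), one row per
#'   visit with the needed measurements.
#' @export
method1_t1s1 <- function(visits) {
  out <- s1_height(visits) |>
    dplyr::mutate(
      t1_height = .data$h_sternal_notch + .data$off_notch_T1,
      t1s1 = .data$t1_height - .data$s1_height,
      c1s1 = NA_real_
    ) |>
    dplyr::filter(!is.na(.data$t1s1))
  if (any(out$t1s1 <= 0)) {
    rlang::abort(
      paste0("non-positive T1-S1 span (NEGATIVE_SPAN) for subject(s): ",
             paste(unique(out$subject_id[out$t1s1 <= 0]), collapse = ", ")),
      class = "spinegrowth_span_error"
    )
  }
  spine_estimate_cols(out, "direct")
}

#' Method 2: T1-S1 as a fixed percentage of C1-S1
#'
#' Approximates the top of C1 as standing height minus head height (vertex
#' to external auditory meatus); with `apply_eam_offset = TRUE` the
#' EAM-to-C1 vertical offset is added (the per-visit recorded `off_eam_C1`
#' when present, else `default_eam_offset`). C1-S1 is C1 height minus
#' [s1_height()]; T1-S1 is `ratio` times C1-S1.
#'
#' @param visits Cohort tibble rows.
#' @param ratio T1-S1 / C1-S1 ratio (default 0.762; see
#'   [estimate_c1s1_ratio()] for the cohort-derived alternative).
#' @param apply_eam_offset Apply the EAM-to-C1 correction (default `FALSE`,
#'   following the stated approximation; the offset is exposed as a
#'   refinement).
#' @param default_eam_offset Offset (cm) used when the flag is on and no
#'   per-visit value is recorded (default 1.7).
#' @return Long spine-estimate tibble (`method = "c1s1_fraction"`).
#' @export
method2_t1s1 <- function(visits, ratio = 0.762, apply_eam_offset = FALSE,
                         default_eam_offset = 1.7) {
  out <- s1_height(visits) |>
    dplyr::mutate(
      c1_height = .data$standing_height - .data$head_height +
        if (apply_eam_offset) {
          dplyr::coalesce(.data$off_eam_C1, default_eam_offset)
        } else 0,
      c1s1 = .data$c1_height - .data$s1_height,
      t1s1 = ratio * .data$c1s1
    ) |>
    dplyr::filter(!is.na(.data$t1s1))
  if (any(out$c1s1 <= 0)) {
    rlang::abort("non-positive C1-S1 span (NEGATIVE_SPAN)",
                 class = "spinegrowth_span_error")
  }
  spine_estimate_cols(out, "c1s1_fraction")
}

#' Cohort-level T1-S1 / C1-S1 ratio
#'
#' Pools the per-visit ratio of the direct (Method 1) T1-S1 estimate to the
#' reconstructed C1-S1 span over all subjects and visits, and returns the
#' median and sd. C1-S1 is reconstructed as in [method2_t1s1()] with the
#' EAM-to-C1 correction applied where recorded, so the ratio is taken
#' against the best available C1 location.
#'
#' @param visits Cohort tibble rows.
#' @return A list with `median`, `sd` and `n` (pooled visit count). Fewer
#'   than 10 usable ratios triggers a `LOW_N` warning.
#' @export
estimate_c1s1_ratio <- function(visits) {
  m1 <- method1_t1s1(visits)
  m2 <- method2_t1s1(visits, ratio = 1, apply_eam_offset = TRUE)
  paired <- dplyr::inner_join(
    dplyr::select(m1, "subject_id", "age_yr", t1s1_direct = "t1s1"),
    dplyr::select(m2, "subject_id", "age_yr", "c1s1"),
    by = c("subject_id", "age_yr")
  )
  ratios <- paired$t1s1_direct / paired$c1s1
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 10) {
    rlang::warn("fewer than 10 T1-S1/C1-S1 ratio observations (LOW_N)")
  }
  list(median = stats::median(ratios), sd = stats::sd(ratios),
       n = length(ratios))
}

#' Fit the through-origin body-height regression
#'
#' Fits `body = spine * beta + error` by least squares through the origin:
#' `beta_hat = sum(spine * body) / sum(spine^2)`. The convention tag records
#' what "spine" was (default `"raw_cm"`), and [method3_t1s1()] refuses to
#' invert a fit under a different convention — the fit and the inversion
#' must use the same scaling.
#'
#' @param pairs A data frame with columns `spine` and `body` (at least 2
#'   rows, spine values not all zero).
#' @param convention Scaling convention tag carried with the fit.
#' @return An object of class `"beta_fit"` with `beta_hat`, `n_points`,
#'   `residual_sd` (n-1 denominator) and `convention`.
#' @export
fit_beta <- function(pairs, convention = "raw_cm") {
  x <- pairs$spine
  y <- pairs$body
  if (length(x) < 2) {
    rlang::abort("need at least 2 (spine, body) pairs",
                 class = "spinegrowth_fit_error")
  }
  sxx <- sum(x^2)
  if (sxx == 0) {
    rlang::abort("all spine values are zero (DEGENERATE)",
                 class = "spinegrowth_fit_error")
  }
  beta <- sum(x * y) / sxx
  resid <- y - beta * x
  structure(
    list(beta_hat = beta, n_points = length(x),
         residual_sd = stats::sd(resid), convention = convention),
    class = "beta_fit"
  )
}

#' @export
print.beta_fit <- function(x, ...) {
  cat("Through-origin body~spine fit: beta_hat =",
      format(x$beta_hat, digits = 6),
      "(n =", x$n_points, ", residual sd =",
      format(x$residual_sd, digits = 4), "cm,",
      "convention:", x$convention, ")\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a through-origin fit
#' @method tidy beta_fit
#' @param x A `"beta_fit"` object.
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.beta_fit <- function(x, ...) {
  tibble::tibble(
    term = "beta",
    estimate = x$beta_hat,
    std.error = x$residual_sd / sqrt(x$n_points * 1)
  )
}

#' Glance at a through-origin fit
#' @method glance beta_fit
#' @param x A `"beta_fit"` object.
#' @param ... Unused.
#' @return One-row tibble with `nobs`, `sigma`, `convention`.
#' @export
glance.beta_fit <- function(x, ...) {
  tibble::tibble(nobs = x$n_points, sigma = x$residual_sd,
                 convention = x$convention)
}

#' Method 3: spine measure from standing height and the fitted beta
#'
#' Inverts the through-origin regression: spine measure = standing height /
#' `beta_hat`, on whatever convention the beta was fitted with. The estimate
#' is algebraically the fitted value of the regression, so on the convention
#' under which the fit was made it reproduces the fitted spine measure
#' exactly.
#'
#' @param visits Cohort tibble rows.
#' @param beta_fit A [fit_beta()] object.
#' @param convention Expected convention; a mismatch with the fit's tag is a
#'   `CONVENTION` error.
#' @return Long spine-estimate tibble (`method = "body_regression"`).
#' @export
method3_t1s1 <- function(visits, beta_fit, convention = "raw_cm") {
  if (!inherits(beta_fit, "beta_fit")) {
    rlang::abort("beta_fit must come from fit_beta()",
                 class = "spinegrowth_fit_error")
  }
  if (!identical(beta_fit$convention, convention)) {
    rlang::abort(
      paste0("beta was fitted under convention '", beta_fit$convention,
             "' but inversion requested '", convention, "' (CONVENTION)"),
      class = "spinegrowth_fit_error"
    )
  }
  visits |>
    dplyr::mutate(
      t1s1 = .data$standing_height / beta_fit$beta_hat,
      c1s1 = NA_real_,
      s1_height = NA_real_,
      landmark = NA_character_
    ) |>
    dplyr::filter(!is.na(.data$t1s1)) |>
    spine_estimate_cols("body_regression")
}

#' Per-visit spine estimates under one or more methods
#'
#' Convenience wrapper running the selected reconstruction methods over a
#' (typically timing-aligned) cohort and stacking the results in one long
#' tibble. For `"body_regression"` the beta is fitted on this cohort's
#' direct (Method 1) T1-S1 estimates against standing height unless a
#' `beta_fit` is supplied.
#'
#' @param visits Cohort tibble rows (with `timing_yr` if aligned).
#' @param methods Subset of `c("direct", "c1s1_fraction", "body_regression")`.
#' @param ratio,apply_eam_offset Passed to [method2_t1s1()].
#' @param beta_fit Optional [fit_beta()] object for `"body_regression"`.
#' @return Long tibble of spine estimates, one row per visit x method.
#' @export
spine_heights <- function(visits,
                          methods = c("direct", "c1s1_fraction",
                                      "body_regression"),
                          ratio = 0.762, apply_eam_offset = FALSE,
                          beta_fit = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  if ("direct" %in% methods) out$m1 <- method1_t1s1(visits)
  if ("c1s1_fraction" %in% methods) {
    out$m2 <- method2_t1s1(visits, ratio = ratio,
                           apply_eam_offset = apply_eam_offset)
  }
  if ("body_regression" %in% methods) {
    if (is.null(beta_fit)) {
      m1 <- if (!is.null(out$m1)) out$m1 else method1_t1s1(visits)
      pairs <- dplyr::inner_join(
        dplyr::select(m1, "subject_id", "age_yr", spine = "t1s1"),
        dplyr::select(visits, "subject_id", "age_yr",
                      body = "standing_height"),
        by = c("subject_id", "age_yr")
      )
      beta_fit <- fit_beta(pairs)
    }
    out$m3 <- method3_t1s1(visits, beta_fit)
  }
  dplyr::bind_rows(out)
}
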
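# Cohort table schema and CSV I/O.
#
# A cohort is an ordinary tibble with one row per measurement visit. All
# lengths are centimeters internally; ages are decimal years. Landmark
# heights are floor-referenced vertical distances; radiographic offsets are
# signed with *up positive*, so landmark_height + offset is the height of the
# radiographic structure above the floor (e.g. h_symphysis + off_pelvis_S1 is
# the height of the top of S1).

#' Cohort column schema
#'
#' Names of the canonical cohort columns, in file order. `subject_id`, `sex`
#' (`"F"`/`"M"`), `age_yr` and `pelvic_landmark`
#' (`"symphysis"`/`"crest"`/`"asis"`) are non-length columns; every other
#' column is a length stored in centimeters.
#'
#' @return Character vector of column names.
#' @export
cohort_columns <- function() {
  c(
    "subject_id", "sex", "age_yr", "standing_height", "sitting_height",
    "h_sternal_notch", "h_symphysis", "h_iliac_crest", "h_asis",
    "h_trochanter", "head_height", "off_notch_T1", "off_pelvis_S1",
    "pelvic_landmark", "off_eam_C1", "pelvic_width"
  )
}

# length-valued columns, subject to cm/mm conversion and sign checks
length_columns <- function() {
  setdiff(cohort_columns(),
          c("subject_id", "sex", "age_yr", "pelvic_landmark"))
}

# columns that are true heights (must be strictly positive when present);
# offsets are signed and may legitimately be negative
height_columns <- function() {
  c("standing_height", "sitting_height", "h_sternal_notch", "h_symphysis",
    "h_iliac_crest", "h_asis", "h_trochanter", "head_height", "pelvic_width")
}

#' Read a longitudinal cohort from CSV
#'
#' Reads a per-visit anthropometric + radiographic cohort file, checks the
#' schema, converts to centimeters if the file is stored in millimeters, and
#' returns the visits grouped by subject and sorted by age. The stored unit
#' is always declared explicitly — it is never guessed from the values.
#'
#' @param path Path to a CSV file with the columns of [cohort_columns()].
#' @param units Unit of every length column in the file: `"cm"` or `"mm"`.
#'   Ages are years regardless.
#' @return A tibble with one row per visit, lengths in cm, ordered by
#'   `subject_id` then `age_yr`.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, units = c("cm", "mm")) {
  units <- match.arg(units)
  if (!file.exists(path)) {
    rlang::abort(paste0("cohort file not found: ", path),
                 class = "spinegrowth_io_error")
  }
  raw <- readr::read_csv(
    path, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_guess(),
                            subject_id = readr::col_character(),
                            # "F" must never be parsed as FALSE
                            sex = readr::col_character(),
                            pelvic_landmark = readr::col_character()))
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("cohort file is missing mandatory column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "spinegrowth_schema_error"
    )
  }
  cohort <- dplyr::select(raw, dplyr::all_of(cohort_columns()))
  cohort <- dplyr::mutate(
    cohort,
    dplyr::across(dplyr::all_of(length_columns()), as.numeric),
    age_yr = as.numeric(.data$age_yr),
    sex = as.character(.data$sex),
    pelvic_landmark = as.character(.data$pelvic_landmark)
  )
  if (units == "mm") {
    cohort <- dplyr::mutate(
      cohort, dplyr::across(dplyr::all_of(length_columns()), ~ .x / 10))
  }
  cohort <- dplyr::arrange(cohort, .data$subject_id, .data$age_yr)
  assert_cohort_valid(cohort)
  tibble::as_tibble(cohort)
}

# hard validation used by read_cohort(): structural problems are errors,
# not findings
assert_cohort_valid <- function(cohort) {
  bad_sex <- setdiff(unique(stats::na.omit(cohort$sex)), c("F", "M"))
  if (length(bad_sex) > 0) {
    rlang::abort(paste0("sex must be 'F' or 'M'; found: ",
                        paste(bad_sex, collapse = ", ")),
                 class = "spinegrowth_validation_error")
  }
  dup <- dplyr::count(cohort, .data$subject_id, .data$age_yr) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(
      paste0("duplicate (subject, age) visits for subject(s): ",
             paste(unique(dup$subject_id), collapse = ", ")),
      class = "spinegrowth_validation_error"
    )
  }
  for (col in height_columns()) {
    v <- cohort[[col]]
    if (any(!is.na(v) & v <= 0)) {
      bad <- unique(cohort$subject_id[!is.na(v) & v <= 0])
      rlang::abort(
        paste0("non-positive ", col, " for subject(s): ",
               paste(bad, collapse = ", "),
               " (0 is never a real height; use an empty cell for missing)"),
        class = "spinegrowth_validation_error"
      )
    }
  }
  if (any(!is.na(cohort$age_yr) & cohort$age_yr <= 0)) {
    rlang::abort("ages must be positive",
                 class = "spinegrowth_validation_error")
  }
  invisible(cohort)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: missing values become empty cells (never 0),
#' and a cohort written in either unit dialect reads back identically to
#' within 0.01 cm.
#'
#' @param cohort A cohort tibble (cm internally).
#' @param path Output path.
#' @param units Unit to store lengths in: `"cm"` or `"mm"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, units = c("cm", "mm")) {
  units <- match.arg(units)
  out <- dplyr::select(cohort, dplyr::all_of(cohort_columns()))
  if (units == "mm") {
    out <- dplyr::mutate(
      out, dplyr::across(dplyr::all_of(length_columns()), ~ .x * 10))
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Validate a cohort and report findings
#'
#' Checks the per-subject longitudinal invariants and returns a
#' machine-readable findings table rather than throwing: an empty table
#' means every invariant holds. Findings are deterministic and ordered by
#' subject, visit and code.
#'
#' Codes: `TOO_FEW_VISITS` (a longitudinal subject needs at least two
#' visits), `NONMONOTONE_AGE`, `HEAD_GT_STATURE`, `LANDMARK_GT_STATURE`,
#' `NONPOSITIVE_HEIGHT`, `S1_LANDMARK_MISSING` (an S1 offset recorded with
#' no pelvic landmark height to add it to).
#'
#' @param cohort A cohort tibble.
#' @return Tibble with columns `subject_id`, `visit` (row index within the
#'   subject, `NA` for subject-level findings), `code`, `message`.
#' @export
validate_cohort <- function(cohort) {
  finding <- function(subject_id, visit, code, message) {
    tibble::tibble(subject_id = subject_id, visit = as.integer(visit),
                   code = code, message = message)
  }
  per_subject <- function(df) {
    id <- df$subject_id[1]
    out <- list()
    if (nrow(df) < 2) {
      out <- c(out, list(finding(id, NA, "TOO_FEW_VISITS",
                                 "subject has fewer than 2 visits")))
    }
    if (nrow(df) >= 2 && any(diff(df$age_yr) <= 0)) {
      i <- which(diff(df$age_yr) <= 0)[1] + 1L
      out <- c(out, list(finding(id, i, "NONMONOTONE_AGE",
                                 "ages not strictly increasing")))
    }
    for (j in seq_len(nrow(df))) {
      row <- df[j, ]
      if (!is.na(row$head_height) && !is.na(row$standing_height) &&
          row$head_height >= row$standing_height) {
        out <- c(out, list(finding(id, j, "HEAD_GT_STATURE",
                                   "head height not below standing height")))
      }
      for (col in setdiff(height_columns(),
                          c("standing_height", "head_height", "pelvic_width"))) {
        if (!is.na(row[[col]]) && !is.na(row$standing_height) &&
            row[[col]] >= row$standing_height) {
          out <- c(out, list(finding(id, j, "LANDMARK_GT_STATURE",
                                     paste0(col, " not below standing height"))))
        }
      }
      for (col in height_columns()) {
        if (!is.na(row[[col]]) && row[[col]] <= 0) {
          out <- c(out, list(finding(id, j, "NONPOSITIVE_HEIGHT",
                                     paste0(col, " is not positive"))))
        }
      }
      if (!is.na(row$off_pelvis_S1)) {
        lm_cols <- c("h_symphysis", "h_iliac_crest", "h_asis")
        if (all(is.na(unlist(row[lm_cols])))) {
          out <- c(out, list(finding(id, j, "S1_LANDMARK_MISSING",
                                     "off_pelvis_S1 present with no pelvic landmark height")))
        }
      }
    }
    if (length(out) == 0) return(finding(character(), integer(),
                                         character(), character()))
    dplyr::bind_rows(out)
  }
  res <- cohort |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_map(~ per_subject(.x |> dplyr::mutate(subject_id = .y$subject_id))) |>
    dplyr::bind_rows()
  dplyr::arrange(res, .data$subject_id, .data$visit, .data$code)
}
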
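# Shared fixtures, built in code and memoized so the heavier simulations run
# once per test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# the study-scale cohort: 35 girls, 19 boys, default noise, fraction-curve
# trajectories
default_sim <- function() fixture("default_sim", function() {
  simulate_cohort(generator_config(seed = 1))
})

default_result <- function() fixture("default_result", function() {
  run_pipeline(generator = generator_config(seed = 1))
})

# noise-free biannual cohort: every recorded value equals its latent truth
# and visits land on every half-year timing
closure_sim_config <- function() {
  noise_free(generator_config(n_female = 2, n_male = 1,
                              visit_schedule = "biannual", seed = 7))
}

closure_result <- function() fixture("closure_result", function() {
  run_pipeline(generator = closure_sim_config(), methods = "direct")
})

# piecewise-linear trajectory runs for velocity recovery
piecewise_girls <- function() fixture("piecewise_girls", function() {
  run_pipeline(generator = generator_config(
    n_female = 35, n_male = 0, trajectory_mode = "piecewise_linear",
    seed = 1), methods = "direct")
})

piecewise_boys <- function() fixture("piecewise_boys", function() {
  run_pipeline(generator = generator_config(
    n_female = 0, n_male = 19, trajectory_mode = "piecewise_linear",
    seed = 1), methods = "direct")
})

# a minimal hand-built visit row with consistent geometry, for arithmetic
# tests; override any field
make_visit <- function(subject_id = "S1", sex = "F", age_yr = 12,
                       standing_height = 163.4, sitting_height = NA,
                       h_sternal_notch = 134, h_symphysis = 82,
                       h_iliac_crest = 99, h_asis = NA, h_trochanter = NA,
                       head_height = 13, off_notch_T1 = 2.5,
                       off_pelvis_S1 = 14, pelvic_landmark = "symphysis",
                       off_eam_C1 = 1.7, pelvic_width = 27) {
  tibble::tibble(
    subject_id = subject_id, sex = sex, age_yr = age_yr,
    standing_height = standing_height, sitting_height = sitting_height,
    h_sternal_notch = h_sternal_notch, h_symphysis = h_symphysis,
    h_iliac_crest = h_iliac_crest, h_asis = h_asis,
    h_trochanter = h_trochanter, head_height = head_height,
    off_notch_T1 = off_notch_T1, off_pelvis_S1 = off_pelvis_S1,
    pelvic_landmark = pelvic_landmark, off_eam_C1 = off_eam_C1,
    pelvic_width = pelvic_width
  )
}
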
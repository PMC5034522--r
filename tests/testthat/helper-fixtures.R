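# Shared fixtures, built in code.

# a tiny hand-made LMS table with easy arithmetic
tiny_ref <- function() {
  growth_reference(data.frame(
    sex = rep(c("male", "female"), each = 3),
    age_months = rep(c(144, 180, 216), 2),
    L = c(1, 2, 1, 1, 1, 1),
    M = c(16, 18, 20, 16.5, 18.5, 20.5),
    S = c(0.1, 0.1, 0.12, 0.1, 0.1, 0.1)
  ))
}

# a record at every published reference level, zero continuous covariates;
# sr_status supplied directly so no growth lookup is needed
reference_record <- function(...) {
  rec <- list(
    sr_weight = 0, sr_height = 0, age_months = 0, puberty = 0,
    sr_status = "HW", body_size = "AboutRight", dieting = FALSE,
    cesd = 0, self_rated_health = 0, self_esteem = 0,
    race_ethnicity = "White", sex = "male", parent_education = "College_plus"
  )
  utils::modifyList(rec, list(...))
}

# small deterministic cohort for fitting tests
small_cohort <- function(n = 400, seed = 7) {
  generate_cohort(simulation_config(n = n, seed = seed))
}
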
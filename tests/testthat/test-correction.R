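test_that("published models carry the printed coefficient sets", {
  pm <- published_models()
  wt <- pm$weight; ht <- pm$height
  coef_of <- function(m, pred, lvl = NA) {
    i <- which(m$terms$predictor == pred &
                 (is.na(lvl) & is.na(m$terms$level) |
                    !is.na(lvl) & m$terms$level %in% lvl))
    m$terms$coefficient[i]
  }
  expect_equal(wt$intercept, 8.20)
  expect_equal(ht$intercept, 9.53)
  expect_equal(coef_of(wt, "sr_weight"), 0.95)
  expect_equal(coef_of(ht, "sr_height"), 0.85)
  expect_equal(coef_of(ht, "sex", "female"), 0.65)
  expect_equal(coef_of(wt, "sr_status", "UW"), 3.67)
  expect_equal(coef_of(ht, "race_ethnicity", "Asian"), -0.29)
  # weight model omits race/ethnicity, sex, and parent education
  expect_false(any(c("race_ethnicity", "sex", "parent_education") %in%
                     wt$terms$predictor))
  # height model keeps non-significant race levels with the class variable
  expect_setequal(ht$terms$level[ht$terms$predictor == "race_ethnicity"],
                  c("Hispanic", "Black", "Asian", "Other"))
  # no term may sit on a reference level
  expect_false(any(ht$terms$level %in% unlist(ht$reference_levels)))
  expect_equal(wt$units, "imperial")
})

test_that("design vectors dummy-code against the published reference levels", {
  pm <- published_models()
  v <- design_vector(reference_record(), pm$height)
  expect_true(all(v == 0))
  expect_equal(length(v), nrow(pm$height$terms))
  v2 <- design_vector(reference_record(body_size = "OW"), pm$height)
  expect_equal(unname(v2["body_size:OW"]), 1)
  expect_equal(unname(v2["body_size:UW"]), 0)
  v3 <- design_vector(reference_record(parent_education = "HS_or_less",
                                       race_ethnicity = "Black",
                                       sex = "female"), pm$height)
  expect_equal(unname(v3[c("parent_education:Below_college",
                           "race_ethnicity:Black", "sex:female")]), c(1, 1, 1))
  rec <- reference_record(); rec$cesd <- NULL
  expect_error(design_vector(rec, pm$weight), regexp = "cesd",
               class = "bmicorrect_missing_data_error")
})

test_that("applying published models reproduces hand arithmetic", {
  pm <- published_models()
  rec <- reference_record()
  expect_equal(apply_model(pm$weight, as.data.frame(rec)), 8.20)
  expect_equal(apply_model(pm$height, as.data.frame(rec)), 9.53)
  # single-covariate dot products (model units: lb / in)
  rec_w <- reference_record(sr_weight = 100 * 0.45359237)  # 100 lb in kg
  expect_equal(apply_model(pm$weight, as.data.frame(rec_w)),
               8.20 + 0.95 * 100, tolerance = 1e-9)
  rec_h <- reference_record(sr_height = 60 * 2.54)         # 60 in, in cm
  expect_equal(apply_model(pm$height, as.data.frame(rec_h)),
               9.53 + 0.85 * 60, tolerance = 1e-9)
})

test_that("published model prediction matches an independent dot product", {
  pm <- published_models()
  rec <- reference_record(sr_weight = 63.5, sr_height = 168, age_months = 196,
                          puberty = 4, sr_status = "OW", body_size = "OW",
                          dieting = TRUE, cesd = 14, self_rated_health = 3,
                          self_esteem = 4.2, race_ethnicity = "Hispanic",
                          sex = "female", parent_education = "Some_college")
  # brute-force: write out every published term by hand
  lb <- 63.5 / 0.45359237; inch <- 168 / 2.54
  by_hand_w <- 8.20 + 0.95 * lb + (-0.01) * 196 + 0.22 * 4 + 2.46 +
    3.68 + 0.93 + (-0.04) * 14 + (-0.39) * 3 + 0.35 * 4.2
  by_hand_h <- 9.53 + 0.85 * inch + 0.00 * 196 + 0.05 * 4 + 0.17 +
    (-0.11) + (-0.08) + (-0.01) * 14 + (-0.04) * 3 + (-0.06) * 4.2 +
    (-0.23) + 0.65 + 0.08
  expect_equal(apply_model(pm$weight, as.data.frame(rec)), by_hand_w,
               tolerance = 1e-12)
  expect_equal(apply_model(pm$height, as.data.frame(rec)), by_hand_h,
               tolerance = 1e-12)
})

test_that("apply_model is affine in the continuous covariates", {
  pm <- published_models()
  r1 <- reference_record(sr_weight = 40, cesd = 5, self_esteem = 2)
  r2 <- reference_record(sr_weight = 90, cesd = 30, self_esteem = 5)
  mix <- function(a) reference_record(sr_weight = a * 40 + (1 - a) * 90,
                                      cesd = a * 5 + (1 - a) * 30,
                                      self_esteem = a * 2 + (1 - a) * 5)
  p1 <- apply_model(pm$weight, as.data.frame(r1))
  p2 <- apply_model(pm$weight, as.data.frame(r2))
  for (a in c(0.25, 0.5, 0.8))
    expect_equal(apply_model(pm$weight, as.data.frame(mix(a))),
                 a * p1 + (1 - a) * p2, tolerance = 1e-9)
})

test_that("self-report weight status derives from SR BMI", {
  ref <- tiny_ref()
  d <- data.frame(sex = "female", age_months = 252,
                  sr_height = 160, sr_weight = 31 * 1.6^2)  # adult SR BMI 31
  expect_equal(as.character(derive_sr_weight_status(d, ref)), "OB")
  d2 <- data.frame(sex = "male", age_months = 180, sr_height = 170,
                   sr_weight = 18 * 1.7^2)                  # at the median
  expect_equal(as.character(derive_sr_weight_status(d2, ref)), "HW")
  d3 <- d; d3$sr_height <- 0
  expect_error(derive_sr_weight_status(d3, ref),
               class = "bmicorrect_domain_error")
})

test_that("identity models leave self-reported values unchanged", {
  id_w <- correction_model("weight", "metric", 0,
                           data.frame(predictor = "sr_weight", level = NA,
                                      coefficient = 1))
  id_h <- correction_model("height", "metric", 0,
                           data.frame(predictor = "sr_height", level = NA,
                                      coefficient = 1))
  d <- small_cohort(n = 60)
  out <- correct_cohort(d, id_w, id_h, generate_growth_fixture(7))
  expect_equal(out$corrected_weight, out$sr_weight, tolerance = 1e-12)
  expect_equal(out$corrected_height, out$sr_height, tolerance = 1e-12)
  expect_equal(out$corrected_bmi,
               out$sr_weight / (out$sr_height / 100)^2, tolerance = 1e-12)
})

test_that("correction drops incomplete records with a count, never imputes", {
  d <- small_cohort(n = 80)
  d$cesd[c(3, 10)] <- NA
  pm <- published_models()
  out <- correct_cohort(d, pm$weight, pm$height, generate_growth_fixture(7))
  expect_equal(nrow(out), 78)
  expect_equal(attr(out, "n_dropped"), 2)
  expect_false(any(out$id %in% d$id[c(3, 10)]))
  d_all_na <- d; d_all_na$cesd <- NA
  expect_error(correct_cohort(d_all_na, pm$weight, pm$height,
                              generate_growth_fixture(7)),
               class = "bmicorrect_data_error")
})

test_that("mixed-unit model pairs are rejected", {
  pm <- published_models()
  id_h <- correction_model("height", "metric", 0,
                           data.frame(predictor = "sr_height", level = NA,
                                      coefficient = 1))
  expect_error(correct_cohort(small_cohort(n = 30), pm$weight, id_h,
                              generate_growth_fixture(7)),
               class = "bmicorrect_unit_error")
})

test_that("model JSON round-trips bit-exactly", {
  pm <- published_models()
  for (m in pm) {
    path <- withr::local_tempfile(fileext = ".json")
    write_model(m, path)
    back <- read_model(path)
    expect_identical(back$intercept_chr, m$intercept_chr)
    expect_identical(back$terms$coefficient_chr, m$terms$coefficient_chr)
    expect_identical(back$terms$predictor, m$terms$predictor)
    expect_identical(back$terms$level, m$terms$level)
    expect_identical(back$units, m$units)
    # a second write is byte-identical
    path2 <- withr::local_tempfile(fileext = ".json")
    write_model(back, path2)
    expect_identical(readLines(path2), readLines(path))
  }
  # refit models round-trip through full-precision decimal strings
  d <- small_cohort(n = 200)
  fit <- fit_correction(d, "weight", c("sr_weight", "dieting"),
                        units = "metric")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit$model, path)
  expect_identical(read_model(path)$terms$coefficient,
                   fit$model$terms$coefficient)
})

test_that("invalid model terms are rejected at construction", {
  expect_error(correction_model("weight", "imperial", 1,
                                data.frame(predictor = "sr_status",
                                           level = "HW", coefficient = 2)),
               regexp = "reference level", class = "bmicorrect_schema_error")
  expect_error(correction_model("weight", "imperial", 1,
                                data.frame(predictor = "nope", level = NA,
                                           coefficient = 2)),
               class = "bmicorrect_schema_error")
})
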
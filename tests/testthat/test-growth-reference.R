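test_that("BMI follows the standard metric and 703-imperial formulas", {
  expect_equal(compute_bmi(70, 1.75), 70 / 1.75^2, tolerance = 1e-12)
  # imperial agrees with explicit unit conversion to within the 703 convention
  expect_equal(compute_bmi(150, 65, units = "imperial"), 24.96, tolerance = 0.01)
  expect_equal(150 * 0.45359237 / (65 * 0.0254)^2, 24.96, tolerance = 0.01)
  expect_error(compute_bmi(0, 1.75), class = "bmicorrect_domain_error")
  expect_error(compute_bmi(70, -1), class = "bmicorrect_domain_error")
})

test_that("LMS z-score matches closed forms on both branches", {
  expect_equal(lms_zscore(20, -1.5, 20, 0.1), 0)
  expect_equal(lms_zscore(22, 1, 20, 0.1), 1.0, tolerance = 1e-12)
  expect_equal(lms_zscore(20 * exp(0.1), 0, 20, 0.1), 1.0, tolerance = 1e-12)
  expect_error(lms_zscore(-1, 1, 20, 0.1), class = "bmicorrect_domain_error")
  expect_error(lms_zscore(20, 1, 20, 0), class = "bmicorrect_domain_error")
})

test_that("LMS transform round-trips through its inverse to 1e-9", {
  set.seed(42)
  for (i in 1:200) {
    L <- runif(1, -3, 1); if (abs(L) < 1e-3) L <- 0
    M <- runif(1, 14, 30); S <- runif(1, 0.05, 0.2)
    z <- runif(1, -3, 3)
    x <- lms_quantile(z, L, M, S)
    if (!is.finite(x) || x <= 0) next  # extreme L*S*z outside transform range
    expect_equal(lms_zscore(x, L, M, S), z, tolerance = 1e-9)
  }
  # strictly increasing in x
  xs <- seq(12, 40, by = 0.5)
  expect_true(all(diff(lms_zscore(xs, -2, 18, 0.12)) > 0))
})

test_that("LMS interpolation is linear in age and errors out of range", {
  ref <- tiny_ref()
  exact <- interpolate_lms(ref, "male", 180)
  expect_equal(unlist(exact), c(L = 2, M = 18, S = 0.1))
  mid <- interpolate_lms(ref, "male", 162)
  expect_equal(unlist(mid), c(L = 1.5, M = 17, S = 0.1))
  expect_error(interpolate_lms(ref, "male", 143),
               class = "bmicorrect_range_error")
  expect_error(interpolate_lms(ref, "female", 217),
               class = "bmicorrect_range_error")
  expect_error(interpolate_lms(ref, "male", c(150, 300)),
               regexp = "\\[144, 216\\]", class = "bmicorrect_range_error")
})

test_that("percentiles are the scaled normal CDF", {
  expect_equal(percentile_from_z(0), 50)
  expect_equal(percentile_from_z(1.6449), 95, tolerance = 0.01)
  expect_equal(percentile_from_z(-1.6449), 5, tolerance = 0.01)
  expect_error(percentile_from_z(Inf), class = "bmicorrect_domain_error")
  # median of the reference maps to the 50th percentile
  ref <- tiny_ref()
  expect_equal(bmi_percentile(18, 180, "male", ref), 50)
})

test_that("pediatric classification uses half-open percentile cutoffs", {
  ref <- tiny_ref()
  lms <- interpolate_lms(ref, "male", 180)
  at_pct <- function(p) lms_quantile(qnorm(p / 100), lms$L, lms$M, lms$S)
  cls <- function(bmi) as.character(classify_weight_status(bmi, 180, "male", ref))
  expect_equal(cls(at_pct(85)), "OW")            # 85th is overweight
  expect_equal(cls(at_pct(85) - 1e-9), "HW")
  expect_equal(cls(at_pct(95) * (1 + 1e-9)), "OB")
  expect_equal(cls(at_pct(95) * (1 - 1e-9)), "OW")
  expect_equal(cls(at_pct(5)), "HW")             # 5th is healthy weight
  expect_equal(cls(at_pct(5) - 1e-6), "UW")
})

test_that("adult classification uses inclusive WHO-style BMI cutoffs", {
  cls <- function(bmi) as.character(classify_weight_status(bmi, 252, "female"))
  expect_equal(cls(30.0), "OB")
  expect_equal(cls(25.0), "OW")
  expect_equal(cls(24.99), "HW")
  expect_equal(cls(18.5), "HW")
  expect_equal(cls(18.49), "UW")
  # age 240 is the adult boundary; 239 months needs the reference
  expect_error(classify_weight_status(22, 239, "male"),
               class = "bmicorrect_schema_error")
})

test_that("classification is monotone in BMI and always assigns one status", {
  ref <- tiny_ref()
  for (sex in c("male", "female")) for (age in c(150, 200, 250)) {
    s <- classify_weight_status(seq(10, 45, by = 0.25), age, sex, ref)
    expect_false(anyNA(s))
    expect_true(all(diff(as.integer(s)) >= 0))
  }
})

test_that("growth reference CSV round-trips in both sex dialects", {
  ref <- tiny_ref()
  path <- withr::local_tempfile(fileext = ".csv")
  write_growth_reference(ref, path)                   # CDC 1/2 coding
  expect_match(readLines(path, 1), "^sex,agemos,L,M,S$")
  back <- read_growth_reference(path)
  expect_equal(as.data.frame(back), as.data.frame(ref))
  write_growth_reference(ref, path, numeric_sex = FALSE)
  expect_equal(as.data.frame(read_growth_reference(path)), as.data.frame(ref))
})

test_that("malformed growth references are rejected", {
  expect_error(growth_reference(data.frame(sex = "male", age_months = 144,
                                           L = 1, M = -2, S = 0.1)),
               class = "bmicorrect_schema_error")
  expect_error(growth_reference(data.frame(sex = "male",
                                           age_months = c(144, 144),
                                           L = 1, M = 17, S = 0.1)),
               class = "bmicorrect_schema_error")
})
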
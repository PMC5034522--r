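# Synthetic cohorts with the statistical structure the correction method
# assumes: measured anthropometrics from sex/age growth curves, true weight
# status from an LMS reference, status-dependent self-report bias (height
# over-report, weight under-report strongest at higher status), and
# covariates correlated with status and bias. Everything is deterministic
# given the config seed; each variable draws from its own seed substream so
# adding a covariate does not perturb earlier draws.

stream_seed <- function(seed, k) {
  as.integer(((abs(as.numeric(seed)) %% 599999) * 3571 + k * 7919 + 1) %%
               2147483647)
}

with_stream <- function(seed, k, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, k))
  expr
}

#' Synthetic LMS growth-reference fixture
#'
#' A smooth, deterministic per-sex LMS table for ages 144-240 months
#' (monthly rows): the median BMI `M` rises monotonically with age, the
#' Box-Cox power `L` lies in \[-3, 1\] and the coefficient of variation `S`
#' in \[0.05, 0.2\], in the range of real pediatric BMI references. The
#' seed perturbs the curve parameters slightly, so distinct seeds give
#' distinct but equally valid references.
#'
#' @param seed integer seed.
#' @return a [growth_reference()].
#' @export
generate_growth_fixture <- function(seed = 1) {
  jit <- with_stream(seed, 901, stats::runif(6, -0.1, 0.1))
  ages <- 144:240
  t <- (ages - 144) / 96
  curve <- t + 0.3 * t * (1 - t)     # monotone (derivative 1.3 - 0.6 t > 0)
  rows <- list(
    male = data.frame(
      sex = "male", age_months = ages,
      L = -2.2 + 0.6 * t + jit[1] * 0.5,
      M = (17.4 + jit[2]) + (4.8 + jit[3]) * curve,
      S = 0.120 + 0.02 * t),
    female = data.frame(
      sex = "female", age_months = ages,
      L = -2.1 + 0.5 * t + jit[4] * 0.5,
      M = (17.6 + jit[5]) + (4.1 + jit[6]) * curve,
      S = 0.130 + 0.02 * t)
  )
  growth_reference(do.call(rbind, rows))
}

#' Simulation configuration
#'
#' Assembles the generative parameters of [generate_cohort()]. Defaults
#' emulate a mid-1990s US adolescent panel: ages 12-22 years, even sex
#' split, heights from sex/age growth curves (cm), BMI drawn through the
#' LMS reference with a right-shifted z distribution (obesity prevalence
#' around 10%), female weight under-report of 1.02 kg in the overweight and
#' obese strata and a smaller male under-report of 0.19 kg, modest height
#' over-report, and covariates (body-size estimation, dieting, CES-D,
#' self-rated health, self-esteem) loaded on true weight status.
#'
#' @param n cohort size (>= 1).
#' @param seed integer seed; all randomness derives from it.
#' @param sex_ratio proportion female.
#' @param age_range_months integer range (min, max), min >= 144.
#' @param growth_params list: per-sex height curve `base`/`gain` (cm),
#'   `height_sd`, and the BMI z-score shift `bmi_z_mean`/`bmi_z_sd`.
#' @param bias_params list: `height_overreport_mean` (cm, per sex),
#'   `weight_underreport_mean_by_status` (kg, per sex, by UW/HW/OW/OB),
#'   reporting noise `height_sd`/`weight_sd` (may be 0), and covariate
#'   bias loadings `dieting_extra_kg`, `body_ow_extra_kg`.
#' @param covariate_params list: `misperception_sd`,
#'   `dieting_logit_by_status`, `dieting_female_logit`, score means/SDs and
#'   status loadings for CES-D, self-rated health and self-esteem, and
#'   level probabilities for race/ethnicity and parent education.
#' @param weight_dispersion SD of log sampling weights (0 = uniform).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n = 2000, seed = 1, sex_ratio = 0.5,
                              age_range_months = c(144, 263),
                              growth_params = list(), bias_params = list(),
                              covariate_params = list(),
                              weight_dispersion = 0.3) {
  gp <- utils::modifyList(list(
    height = list(male = c(base = 152, gain = 24),
                  female = c(base = 150, gain = 13)),
    height_sd = 6.5, bmi_z_mean = 0.25, bmi_z_sd = 1.1
  ), growth_params)
  bp <- utils::modifyList(list(
    height_overreport_mean = c(male = 0.7, female = 0.7),
    weight_underreport_mean_by_status = list(
      male = c(UW = 0, HW = 0.1, OW = 0.19, OB = 0.19),
      female = c(UW = 0, HW = 0.5, OW = 1.02, OB = 1.02)),
    height_sd = 1.2, weight_sd = 1.5,
    dieting_extra_kg = 0.4, body_ow_extra_kg = 0.3
  ), bias_params)
  cp <- utils::modifyList(list(
    misperception_sd = 0.6,
    dieting_logit_by_status = c(UW = -4, HW = -2.5, OW = -1.2, OB = -0.6),
    dieting_female_logit = 1.2,
    cesd_mean = 11, cesd_sd = 7.5, cesd_loading = 1.0,
    srh_mean = 3.9, srh_sd = 0.85, srh_loading = -0.25,
    esteem_mean = 4.1, esteem_sd = 0.6, esteem_loading = -0.1,
    race_probs = c(White = 0.678, Hispanic = 0.119, Black = 0.159,
                   Asian = 0.039, Other = 0.005),
    parent_ed_probs = c(College_plus = 0.35, HS_or_less = 0.45,
                        Some_college = 0.20)
  ), covariate_params)
  if (n < 1) stop_schema("n must be >= 1")
  if (length(age_range_months) != 2 || age_range_months[1] < 144 ||
      diff(age_range_months) < 0)
    stop_schema("age_range_months must be (min, max) with min >= 144")
  if (gp$height_sd <= 0 || gp$bmi_z_sd <= 0)
    stop_schema("growth SDs must be positive")
  if (bp$height_sd < 0 || bp$weight_sd < 0)
    stop_schema("bias SDs must be nonnegative")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 sex_ratio = sex_ratio,
                 age_range_months = as.integer(age_range_months),
                 growth_params = gp, bias_params = bp, covariate_params = cp,
                 weight_dispersion = weight_dispersion),
            class = "simulation_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic cohort
#'
#' Draws `n` participant records: measured height from sex/age curves,
#' measured BMI through the LMS reference (z-scores truncated to keep the
#' Box-Cox transform in range), true weight status via
#' [classify_weight_status()], then self-reported values with
#' status-dependent under-report plus covariate contributions, and
#' covariates generated from their status loadings. Deterministic given
#' the config (including its seed).
#'
#' @param config a [simulation_config()].
#' @param ref growth reference; defaults to
#'   `generate_growth_fixture(config$seed)`. The config's age range must
#'   stay within the reference coverage below 240 months.
#' @return a validated cohort data.frame (metric) with measured values and
#'   a `true_status` column.
#' @export
generate_cohort <- function(config = simulation_config(), ref = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(ref)) ref <- generate_growth_fixture(config$seed)
  n <- config$n; seed <- config$seed
  gp <- config$growth_params; bp <- config$bias_params
  cp <- config$covariate_params
  ped_ages <- seq(config$age_range_months[1],
                  min(config$age_range_months[2], ADULT_AGE_MONTHS - 1))
  cover <- range(ref$age_months)
  if (min(ped_ages) < cover[1] || max(ped_ages) > cover[2])
    stop_range(sprintf(
      "config age range [%d, %d] exceeds reference coverage [%g, %g] below 240 months",
      config$age_range_months[1], config$age_range_months[2],
      cover[1], cover[2]))

  sex <- with_stream(seed, 1,
    ifelse(stats::runif(n) < config$sex_ratio, "female", "male"))
  age <- with_stream(seed, 2,
    sample(seq(config$age_range_months[1], config$age_range_months[2]),
           n, replace = TRUE))
  t_age <- clamp((age - 144) / 96, 0, 1)
  hb <- vapply(sex, function(s) gp$height[[s]]["base"], numeric(1))
  hg <- vapply(sex, function(s) gp$height[[s]]["gain"], numeric(1))
  height <- with_stream(seed, 3,
    hb + hg * t_age + stats::rnorm(n, 0, gp$height_sd))
  z_bmi <- with_stream(seed, 4,
    clamp(stats::rnorm(n, gp$bmi_z_mean, gp$bmi_z_sd), -3.5, 3.4))
  lms <- interpolate_lms(ref, sex, clamp(age, cover[1], cover[2]))
  bmi <- lms_quantile(z_bmi, lms$L, lms$M, lms$S)
  weight <- bmi * (height / 100)^2
  true_status <- classify_weight_status(bmi, age, sex, ref)
  idx <- as.integer(true_status)           # UW=1 .. OB=4

  puberty <- with_stream(seed, 5,
    as.integer(clamp(round(3 + (age - mean(age)) / 36 +
                             stats::rnorm(n, 0, 0.8)), 1, 5)))
  body_size <- with_stream(seed, 6, {
    latent <- pmin(idx, 3) + stats::rnorm(n, 0, cp$misperception_sd)
    ifelse(latent < 1.5, "UW", ifelse(latent <= 2.5, "AboutRight", "OW"))
  })
  dieting <- with_stream(seed, 7, {
    lgt <- cp$dieting_logit_by_status[idx] +
      cp$dieting_female_logit * (sex == "female")
    stats::runif(n) < stats::plogis(lgt)
  })
  cesd <- with_stream(seed, 8,
    clamp(stats::rnorm(n, cp$cesd_mean + cp$cesd_loading * (idx - 2),
                       cp$cesd_sd), 0, 60))
  srh <- with_stream(seed, 9,
    clamp(stats::rnorm(n, cp$srh_mean + cp$srh_loading * (idx - 2),
                       cp$srh_sd), 1, 5))
  esteem <- with_stream(seed, 10,
    clamp(stats::rnorm(n, cp$esteem_mean + cp$esteem_loading * (idx - 2),
                       cp$esteem_sd), 1, 5))
  race <- with_stream(seed, 11,
    sample(names(cp$race_probs), n, replace = TRUE,
           prob = cp$race_probs / sum(cp$race_probs)))
  parent_ed <- with_stream(seed, 12,
    sample(names(cp$parent_ed_probs), n, replace = TRUE,
           prob = cp$parent_ed_probs / sum(cp$parent_ed_probs)))

  under <- vapply(seq_len(n), function(i)
    bp$weight_underreport_mean_by_status[[sex[i]]][[idx[i]]], numeric(1)) +
    bp$dieting_extra_kg * dieting +
    bp$body_ow_extra_kg * (body_size == "OW")
  sr_weight <- with_stream(seed, 13,
    weight - under + stats::rnorm(n, 0, bp$weight_sd))
  over <- vapply(sex, function(s) bp$height_overreport_mean[[s]], numeric(1))
  sr_height <- with_stream(seed, 14,
    height + over + stats::rnorm(n, 0, bp$height_sd))
  samp_w <- with_stream(seed, 15,
    exp(stats::rnorm(n, 0, config$weight_dispersion)))

  out <- data.frame(
    id = sprintf("S%05d", seq_len(n)),
    sex = sex, age_months = age,
    sr_height = pmax(sr_height, 50), sr_weight = pmax(sr_weight, 10),
    measured_height = height, measured_weight = weight,
    puberty = puberty, body_size = body_size, dieting = dieting,
    cesd = cesd, self_rated_health = srh, self_esteem = esteem,
    race_ethnicity = race, parent_education = parent_ed,
    sample_weight = samp_w,
    true_status = as.character(true_status),
    stringsAsFactors = FALSE
  )
  validate_cohort(out)
}

#' End-to-end parameter-recovery check
#'
#' A simulation harness with a known generative measurement model: it
#' generates a cohort, constructs the outcome as an explicit linear
#' function of chosen design blocks (self-reported weight plus covariates)
#' with Gaussian noise, appends a pure-noise class variable
#' (race/ethnicity, which has no generative effect), runs [aic_select()],
#' and compares recovered coefficients of the truly generative terms to
#' their generating values.
#'
#' @param n cohort size.
#' @param seed integer seed.
#' @param noise_sd residual SD of the generative model (kg).
#' @param se_mult tolerance as a multiple of each estimate's standard error
#'   (default 3).
#' @param config optional [simulation_config()] overriding the cohort
#'   generator defaults (its `n`/`seed` are replaced by the arguments).
#' @return list: `report` (data.frame with term, truth, estimate, se,
#'   within_tol), `all_recovered`, `noise_excluded`, `fit`.
#' @export
oracle_refit_check <- function(n = 10000, seed = 1, noise_sd = 4,
                               se_mult = 3, config = NULL) {
  if (is.null(config)) config <- simulation_config()
  config$n <- as.integer(n); config$seed <- as.integer(seed)
  ref <- generate_growth_fixture(config$seed)
  data <- generate_cohort(config, ref)

  gen_blocks <- c("sr_weight", "body_size", "dieting", "self_rated_health")
  truth <- c(`(Intercept)` = 5, sr_weight = 0.95,
             `body_size:UW` = -1.8, `body_size:OW` = 3.7,
             dieting = 0.9, self_rated_health = -0.4)
  design <- build_block_design(data, main_blocks(gen_blocks), "metric", ref)
  Xi <- cbind(`(Intercept)` = 1, design$X)
  eps <- with_stream(seed, 101, stats::rnorm(nrow(data), 0, noise_sd))
  data$measured_weight <- drop(Xi %*% truth[colnames(Xi)]) + eps

  candidates <- c("body_size", "dieting", "self_rated_health", "race_ethnicity")
  fit <- aic_select(data, "weight", candidates = candidates,
                    mandatory = "sr_weight", units = "metric", ref = ref)
  est <- fit$wls$coefficients
  se <- fit$wls$se
  report <- do.call(rbind, lapply(names(truth), function(term) {
    present <- term %in% names(est)
    data.frame(term = term, truth = truth[[term]],
               estimate = if (present) est[[term]] else NA_real_,
               se = if (present) se[[term]] else NA_real_,
               within_tol = present &&
                 abs(est[[term]] - truth[[term]]) <= se_mult * se[[term]],
               row.names = NULL)
  }))
  list(report = report,
       all_recovered = all(report$within_tol),
       noise_excluded = !"race_ethnicity" %in% fit$blocks,
       fit = fit)
}

#' @rdname oracle_refit_check
#' @param n_rep number of replicates.
#' @param base_seed seed of the first replicate (incremented by 1 each
#'   replicate).
#' @return `oracle_noise_replicates()`: list with per-replicate
#'   `noise_excluded`/`all_recovered` flags and their means.
#' @export
oracle_noise_replicates <- function(n_rep = 20, n = 10000, base_seed = 1,
                                    noise_sd = 4) {
  runs <- lapply(seq_len(n_rep), function(i)
    oracle_refit_check(n = n, seed = base_seed + i - 1, noise_sd = noise_sd))
  excl <- vapply(runs, `[[`, logical(1), "noise_excluded")
  rec <- vapply(runs, `[[`, logical(1), "all_recovered")
  list(noise_excluded = excl, all_recovered = rec,
       exclusion_rate = mean(excl), recovery_rate = mean(rec))
}
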
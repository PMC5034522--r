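#' Growth-reference (LMS) table
#'
#' A growth reference maps (sex, age in months) to the three LMS parameters
#' of the BMI-for-age distribution: the Box-Cox power `L`, the median `M`
#' (kg/m^2), and the coefficient of variation `S`. Tables in the CDC layout
#' (one row per sex and age) are supported; a synthetic reference for testing
#' is available from [generate_growth_fixture()].
#'
#' @param data data.frame with columns `sex` (`"male"`/`"female"`),
#'   `age_months` (>= 24), `L`, `M` (> 0), `S` (> 0).
#' @return an object of class `growth_reference` (a validated data.frame,
#'   sorted by sex then age).
#' @seealso [read_growth_reference()], [classify_weight_status()]
#' @export
growth_reference <- function(data) {
  req <- c("sex", "age_months", "L", "M", "S")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0)
    stop_schema(sprintf("growth reference lacks column(s): %s",
                        paste(miss, collapse = ", ")))
  data <- as.data.frame(data)[req]
  data$sex <- as.character(data$sex)
  if (!all(data$sex %in% c("male", "female")))
    stop_schema("growth reference sex must be 'male' or 'female'")
  num <- c("age_months", "L", "M", "S")
  for (v in num) data[[v]] <- as.numeric(data[[v]])
  if (anyNA(data)) stop_schema("growth reference contains missing values")
  if (any(data$age_months < 24))
    stop_schema("growth reference ages must be >= 24 months")
  if (any(data$M <= 0) || any(data$S <= 0))
    stop_schema("growth reference requires M > 0 and S > 0")
  data <- data[order(data$sex, data$age_months), , drop = FALSE]
  for (s in unique(data$sex)) {
    a <- data$age_months[data$sex == s]
    if (anyDuplicated(a) || is.unsorted(a, strictly = TRUE))
      stop_schema(sprintf("ages must be strictly increasing within sex '%s'", s))
  }
  rownames(data) <- NULL
  structure(data, class = c("growth_reference", "data.frame"))
}

#' @export
print.growth_reference <- function(x, ...) {
  rng <- vapply(split(x$age_months, x$sex), range, numeric(2))
  cat("Growth reference (LMS):", nrow(x), "rows\n")
  for (s in colnames(rng))
    cat(sprintf("  %s: ages %g-%g months\n", s, rng[1, s], rng[2, s]))
  invisible(x)
}

#' Read / write a growth-reference CSV
#'
#' The on-disk layout follows the CDC convention: header `sex,agemos,L,M,S`
#' with sex coded `1` = male, `2` = female. String-coded sex
#' (`male`/`female`) is also accepted; coding is auto-detected unless forced
#' via `sex_coding`.
#'
#' @param path CSV file path.
#' @param sex_coding `"auto"` (default), `"numeric"` (1/2) or `"string"`.
#' @return [read_growth_reference()] returns a `growth_reference`;
#'   [write_growth_reference()] invisibly returns `path`.
#' @export
read_growth_reference <- function(path, sex_coding = c("auto", "numeric", "string")) {
  sex_coding <- match.arg(sex_coding)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("sex", "agemos", "l", "m", "s") %in% names(raw)))
    stop_schema("growth reference CSV must have header sex,agemos,L,M,S")
  sex <- raw$sex
  if (sex_coding == "auto")
    sex_coding <- if (all(sex %in% c(1, 2, "1", "2"))) "numeric" else "string"
  sex <- if (sex_coding == "numeric") {
    c("1" = "male", "2" = "female")[as.character(sex)]
  } else tolower(as.character(sex))
  growth_reference(data.frame(sex = sex, age_months = raw$agemos,
                              L = raw$l, M = raw$m, S = raw$s))
}

#' @rdname read_growth_reference
#' @param ref a `growth_reference`.
#' @param numeric_sex write sex as 1/2 (CDC dialect, default) or as strings.
#' @export
write_growth_reference <- function(ref, path, numeric_sex = TRUE) {
  out <- data.frame(
    sex = if (numeric_sex) ifelse(ref$sex == "male", 1L, 2L) else ref$sex,
    agemos = ref$age_months, L = ref$L, M = ref$M, S = ref$S
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Body mass index
#'
#' BMI from weight and height: `kg / m^2` for metric inputs, and the
#' conventional `703 * lb / in^2` for imperial inputs.
#'
#' @param weight weight in kg (metric) or lb (imperial); > 0.
#' @param height height in m (metric) or in (imperial); > 0.
#' @param units `"metric"` or `"imperial"`.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' compute_bmi(70, 1.75)                       # 22.86
#' compute_bmi(150, 65, units = "imperial")    # 24.96
compute_bmi <- function(weight, height, units = c("metric", "imperial")) {
  units <- match.arg(units)
  if (any(!is.finite(weight)) || any(!is.finite(height)) ||
      any(weight <= 0) || any(height <= 0))
    stop_domain("weight and height must be positive and finite")
  if (units == "metric") weight / height^2 else 703 * weight / height^2
}

#' LMS z-score
#'
#' The Box-Cox (LMS) transform mapping a measurement to a z-score against a
#' reference distribution with skewness `L`, median `M`, and coefficient of
#' variation `S`:
#' `z = ((x/M)^L - 1) / (L * S)` for `L != 0`, and `z = log(x/M) / S` when
#' `L = 0`.
#'
#' @param x measurement (> 0), same units as `M`.
#' @param L,M,S LMS parameters (`M > 0`, `S > 0`).
#' @return z-score; strictly increasing in `x` for fixed parameters.
#' @export
lms_zscore <- function(x, L, M, S) {
  if (any(!is.finite(x)) || any(!is.finite(M)) || any(!is.finite(S)) ||
      any(x <= 0) || any(M <= 0) || any(S <= 0))
    stop_domain("lms_zscore requires x > 0, M > 0, S > 0")
  ifelse(L == 0, log(x / M) / S, ((x / M)^L - 1) / (L * S))
}

#' Invert the LMS transform: measurement at a given z-score
#'
#' @inheritParams lms_zscore
#' @param z z-score.
#' @return the measurement whose LMS z-score is `z`.
#' @export
lms_quantile <- function(z, L, M, S) {
  if (any(M <= 0) || any(S <= 0)) stop_domain("lms_quantile requires M > 0, S > 0")
  ifelse(L == 0, M * exp(S * z), M * (1 + L * S * z)^(1 / L))
}

#' Interpolate LMS parameters at an age
#'
#' Linear interpolation in age, component-wise on L, M, and S, between the
#' bracketing reference rows; an exactly tabulated age returns that row.
#' Ages outside the table's covered interval for the requested sex raise a
#' range error (no extrapolation).
#'
#' @param ref a [growth_reference()].
#' @param sex `"male"` or `"female"` (recycled against `age_months`).
#' @param age_months query age(s) in months.
#' @return data.frame with columns `L`, `M`, `S` (one row per query).
#' @export
interpolate_lms <- function(ref, sex, age_months) {
  if (!inherits(ref, "growth_reference"))
    stop_schema("`ref` must be a growth_reference")
  n <- max(length(sex), length(age_months))
  sex <- rep_len(as.character(sex), n)
  age <- rep_len(as.numeric(age_months), n)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("L", "M", "S")))
  for (s in unique(sex)) {
    idx <- which(sex == s)
    tab <- ref[ref$sex == s, , drop = FALSE]
    if (nrow(tab) == 0)
      stop_range(sprintf("growth reference has no rows for sex '%s'", s))
    lo <- min(tab$age_months); hi <- max(tab$age_months)
    a <- age[idx]
    if (any(a < lo | a > hi))
      stop_range(sprintf(
        "age(s) %s outside growth reference coverage [%g, %g] months for sex '%s'",
        paste(unique(a[a < lo | a > hi]), collapse = ", "), lo, hi, s))
    k <- findInterval(a, tab$age_months, rightmost.closed = TRUE)
    a0 <- tab$age_months[k]; a1 <- tab$age_months[pmin(k + 1, nrow(tab))]
    f <- ifelse(a1 > a0, (a - a0) / (a1 - a0), 0)
    for (p in c("L", "M", "S"))
      out[idx, p] <- tab[[p]][k] * (1 - f) + tab[[p]][pmin(k + 1, nrow(tab))] * f
  }
  as.data.frame(out)
}

#' Percentile from a z-score
#'
#' The standard-normal CDF scaled to (0, 100); the convention underlying
#' "BMI-for-age percentile".
#'
#' @param z finite z-score(s).
#' @return percentile(s) in (0, 100), monotone in `z`.
#' @export
percentile_from_z <- function(z) {
  if (any(!is.finite(z))) stop_domain("z must be finite")
  100 * stats::pnorm(z)
}

#' BMI-for-age percentile
#'
#' @param bmi BMI in kg/m^2 (> 0).
#' @inheritParams interpolate_lms
#' @return percentile(s) in (0, 100).
#' @export
bmi_percentile <- function(bmi, age_months, sex, ref) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) stop_domain("bmi must be positive")
  lms <- interpolate_lms(ref, sex, age_months)
  percentile_from_z(lms_zscore(bmi, lms$L, lms$M, lms$S))
}

ADULT_AGE_MONTHS <- 240

#' Classify weight status from BMI
#'
#' Below age 20 (240 months) classification uses BMI-for-age percentiles
#' against the growth reference with the half-open cutoffs
#' UW < 5th, 5th <= HW < 85th, 85th <= OW < 95th, OB >= 95th.
#' At 240 months and above, adult BMI cutoffs apply:
#' UW < 18.5 <= HW < 25 <= OW < 30 <= OB (WHO convention, lower bound
#' inclusive).
#'
#' @param bmi BMI in kg/m^2 (> 0).
#' @param age_months age(s) in months.
#' @param sex `"male"`/`"female"`.
#' @param ref a [growth_reference()]; required when any age is below 240
#'   months and must cover those ages.
#' @return a [weight_status()] ordered factor.
#' @export
classify_weight_status <- function(bmi, age_months, sex, ref = NULL) {
  n <- max(length(bmi), length(age_months), length(sex))
  bmi <- rep_len(as.numeric(bmi), n)
  age <- rep_len(as.numeric(age_months), n)
  sex <- rep_len(as.character(sex), n)
  if (any(!is.finite(bmi)) || any(bmi <= 0)) stop_domain("bmi must be positive")
  out <- character(n)
  adult <- age >= ADULT_AGE_MONTHS
  if (any(adult)) {
    b <- bmi[adult]
    out[adult] <- ifelse(b < 18.5, "UW",
                  ifelse(b < 25, "HW",
                  ifelse(b < 30, "OW", "OB")))
  }
  if (any(!adult)) {
    if (is.null(ref))
      stop_schema("a growth reference is required for ages under 240 months")
    p <- bmi_percentile(bmi[!adult], age[!adult], sex[!adult], ref)
    out[!adult] <- ifelse(p < 5, "UW",
                   ifelse(p < 85, "HW",
                   ifelse(p < 95, "OW", "OB")))
  }
  weight_status(out)
}

# unit conversions (exact definitions: 1 in = 2.54 cm, 1 lb = 0.45359237 kg)
CM_PER_IN <- 2.54
KG_PER_LB <- 0.45359237

cm_to_in <- function(x) x / CM_PER_IN
in_to_cm <- function(x) x * CM_PER_IN
kg_to_lb <- function(x) x / KG_PER_LB
lb_to_kg <- function(x) x * KG_PER_LB
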
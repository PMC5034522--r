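# Predictor registry: every candidate predictor of the correction models,
# with its type and (for class variables) levels and reference level.
# Reference levels follow the published models: healthy weight, "about
# right" body-size estimation, White, male, college degree.

.predictors <- list(
  sr_weight         = list(type = "continuous"),
  sr_height         = list(type = "continuous"),
  age_months        = list(type = "continuous"),
  puberty           = list(type = "continuous"),
  sr_status         = list(type = "categorical", ref = "HW",
                           levels = c("HW", "UW", "OW", "OB")),
  body_size         = list(type = "categorical", ref = "AboutRight",
                           levels = c("AboutRight", "UW", "OW")),
  dieting           = list(type = "binary"),
  cesd              = list(type = "continuous"),
  self_rated_health = list(type = "continuous"),
  self_esteem       = list(type = "continuous"),
  race_ethnicity    = list(type = "categorical", ref = "White",
                           levels = c("White", "Hispanic", "Black", "Asian", "Other")),
  sex               = list(type = "categorical", ref = "male",
                           levels = c("male", "female")),
  parent_education  = list(type = "categorical", ref = "College_plus",
                           levels = c("College_plus", "HS_or_less", "Some_college"))
)

predictor_names <- function() names(.predictors)

# non-reference dummy terms (or the single continuous term) for a predictor
block_terms <- function(predictor) {
  info <- .predictors[[predictor]]
  if (is.null(info)) stop_schema(sprintf("unknown predictor '%s'", predictor))
  if (info$type == "categorical") {
    data.frame(predictor = predictor, level = setdiff(info$levels, info$ref),
               stringsAsFactors = FALSE)
  } else {
    data.frame(predictor = predictor, level = NA_character_,
               stringsAsFactors = FALSE)
  }
}

term_label <- function(predictor, level, predictor2 = NA, level2 = NA) {
  lab1 <- ifelse(is.na(level), predictor, paste0(predictor, ":", level))
  lab2 <- ifelse(is.na(predictor2), "",
                 paste0(" x ", ifelse(is.na(level2), predictor2,
                                      paste0(predictor2, ":", level2))))
  paste0(lab1, lab2)
}

#' Linear correction model
#'
#' A correction model is an affine equation predicting a measured
#' anthropometric (height or weight) from self-reported values and
#' covariates: an intercept plus named coefficient terms. Class variables
#' are dummy-coded against declared reference levels (healthy weight,
#' "about right", White, male, college degree); a term therefore never
#' references its predictor's reference level. Coefficients are kept both
#' as numbers and as decimal strings so serialisation round-trips
#' bit-exactly.
#'
#' @param outcome `"weight"` or `"height"`.
#' @param units unit system of the equation: `"imperial"` (pounds/inches)
#'   or `"metric"` (kg/cm).
#' @param intercept numeric or decimal string.
#' @param terms data.frame with columns `predictor`, `level` (NA for
#'   continuous terms), `coefficient` (numeric or decimal string); optional
#'   `predictor2`, `level2` for two-way interaction terms.
#' @param provenance list describing where the coefficients come from
#'   (`source = "published"` or `"refit"`, plus fit metadata `n`,
#'   `aic`, `r_squared` when refit).
#' @return an object of class `correction_model`.
#' @seealso [published_models()], [apply_model()], [write_model()]
#' @export
correction_model <- function(outcome = c("weight", "height"),
                             units = c("imperial", "metric"),
                             intercept, terms,
                             provenance = list(source = "refit")) {
  outcome <- match.arg(outcome)
  units <- match.arg(units)
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  if (!"predictor2" %in% names(terms)) terms$predictor2 <- NA_character_
  if (!"level2" %in% names(terms)) terms$level2 <- NA_character_
  if (!all(c("predictor", "level", "coefficient") %in% names(terms)))
    stop_schema("terms need columns predictor, level, coefficient")
  terms$coefficient_chr <- as.character(terms$coefficient)
  terms$coefficient <- as.numeric(terms$coefficient_chr)
  if (anyNA(terms$coefficient)) stop_schema("non-numeric coefficient")
  check_level <- function(p, l) {
    if (is.na(p)) return()
    info <- .predictors[[p]]
    if (is.null(info)) stop_schema(sprintf("unknown predictor '%s'", p))
    if (info$type == "categorical") {
      if (is.na(l)) stop_schema(sprintf("'%s' is categorical; a level is required", p))
      if (identical(l, info$ref))
        stop_schema(sprintf("term references the reference level '%s' of '%s'", l, p))
      if (!l %in% c(info$levels, "Below_college"))
        stop_schema(sprintf("unknown level '%s' for '%s'", l, p))
    } else if (!is.na(l)) {
      stop_schema(sprintf("'%s' is not categorical; level must be NA", p))
    }
  }
  for (i in seq_len(nrow(terms))) {
    check_level(terms$predictor[i], terms$level[i])
    check_level(terms$predictor2[i], terms$level2[i])
  }
  refs <- vapply(unique(c(terms$predictor,
                          terms$predictor2[!is.na(terms$predictor2)])),
                 function(p) {
                   info <- .predictors[[p]]
                   if (info$type == "categorical") info$ref else NA_character_
                 }, character(1))
  refs <- refs[!is.na(refs)]
  structure(list(
    outcome = outcome, units = units,
    intercept = as.numeric(as.character(intercept)),
    intercept_chr = as.character(intercept),
    terms = terms[, c("predictor", "level", "predictor2", "level2",
                      "coefficient", "coefficient_chr")],
    reference_levels = as.list(refs),
    provenance = provenance
  ), class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  unit_lab <- if (x$units == "imperial") {
    if (x$outcome == "weight") "lb" else "in"
  } else {
    if (x$outcome == "weight") "kg" else "cm"
  }
  cat(sprintf("Correction model: measured %s (%s), %s\n", x$outcome, unit_lab,
              x$provenance$source))
  cat(sprintf("  intercept  %8s\n", x$intercept_chr))
  labs <- term_label(x$terms$predictor, x$terms$level,
                     x$terms$predictor2, x$terms$level2)
  for (i in seq_along(labs))
    cat(sprintf("  %-38s %8s\n", labs[i], x$terms$coefficient_chr[i]))
  if (!is.null(x$provenance$r_squared))
    cat(sprintf("  n = %s, AIC = %.2f, R^2 = %.3f\n",
                x$provenance$n, x$provenance$aic, x$provenance$r_squared))
  invisible(x)
}

#' Bundled published correction equations
#'
#' The two final multiple-regression models relating measured to
#' self-reported anthropometrics in a large US adolescent panel study:
#' model 1 predicts measured weight, model 2 measured height. Coefficients
#' are stored exactly at their printed 2-decimal precision; model 1 omits
#' race/ethnicity, sex, and parent education (removed during AIC selection),
#' while model 2 retains all candidate predictors, including
#' individually non-significant race levels kept because the class variable
#' overall contributed. Parent education is printed as a single coefficient
#' against the college-degree reference and is encoded here as one
#' "below college degree" indicator.
#'
#' The equations' unit system is not stated alongside the coefficients;
#' pounds/inches (the survey's native units) are assumed and recorded in
#' the models' `units` field. Because coefficients carry only two printed
#' decimals, predictions have rounding error of order 0.005 times the
#' covariate magnitudes.
#'
#' @return list with elements `weight` and `height`, each a
#'   [correction_model()].
#' @export
#' @examples
#' published_models()$weight
published_models <- function() {
  weight_terms <- data.frame(
    predictor = c("sr_weight", "age_months", "puberty",
                  "sr_status", "sr_status", "sr_status",
                  "body_size", "body_size", "dieting", "cesd",
                  "self_rated_health", "self_esteem"),
    level = c(NA, NA, NA, "UW", "OW", "OB", "UW", "OW", NA, NA, NA, NA),
    coefficient = c("0.95", "-0.01", "0.22", "3.67", "2.46", "2.86",
                    "-1.76", "3.68", "0.93", "-0.04", "-0.39", "0.35"),
    stringsAsFactors = FALSE
  )
  height_terms <- data.frame(
    predictor = c("sr_height", "age_months", "puberty",
                  "sr_status", "sr_status", "sr_status",
                  "body_size", "body_size", "dieting", "cesd",
                  "self_rated_health", "self_esteem",
                  "race_ethnicity", "race_ethnicity", "race_ethnicity",
                  "race_ethnicity", "sex", "parent_education"),
    level = c(NA, NA, NA, "UW", "OW", "OB", "UW", "OW", NA, NA, NA, NA,
              "Hispanic", "Black", "Asian", "Other", "female", "Below_college"),
    coefficient = c("0.85", "0.00", "0.05", "-0.92", "0.17", "0.40",
                    "0.13", "-0.11", "-0.08", "-0.01", "-0.04", "-0.06",
                    "-0.23", "0.03", "-0.29", "0.02", "0.65", "0.08"),
    stringsAsFactors = FALSE
  )
  list(
    weight = correction_model("weight", "imperial", "8.20", weight_terms,
                              provenance = list(source = "published",
                                                r_squared = 0.91, n = 13650)),
    height = correction_model("height", "imperial", "9.53", height_terms,
                              provenance = list(source = "published",
                                                r_squared = 0.89, n = 13650))
  )
}

#' Serialise / deserialise a correction model (JSON, format 1)
#'
#' Coefficients travel as decimal strings, so a published model's printed
#' values round-trip bit-exactly; refit models are written with full
#' `%.17g` precision.
#'
#' @param model a [correction_model()].
#' @param path JSON file path.
#' @return [read_model()] returns the `correction_model`; [write_model()]
#'   invisibly returns `path`.
#' @export
write_model <- function(model, path) {
  obj <- list(
    format = 1L,
    outcome = model$outcome,
    unit_system = model$units,
    intercept = model$intercept_chr,
    terms = lapply(seq_len(nrow(model$terms)), function(i) {
      t <- model$terms[i, ]
      out <- list(predictor = t$predictor, coefficient = t$coefficient_chr)
      if (!is.na(t$level)) out$level <- t$level
      if (!is.na(t$predictor2)) out$predictor2 <- t$predictor2
      if (!is.na(t$level2)) out$level2 <- t$level2
      out
    }),
    reference_levels = model$reference_levels,
    provenance = model$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$format) || obj$format != 1)
    stop_schema("unsupported model JSON format")
  grab <- function(t, f) if (is.null(t[[f]])) NA_character_ else t[[f]]
  terms <- do.call(rbind, lapply(obj$terms, function(t) {
    data.frame(predictor = t$predictor, level = grab(t, "level"),
               predictor2 = grab(t, "predictor2"), level2 = grab(t, "level2"),
               coefficient = t$coefficient, stringsAsFactors = FALSE)
  }))
  correction_model(obj$outcome, obj$unit_system, obj$intercept, terms,
                   provenance = obj$provenance)
}

# full-precision decimal string that survives as.numeric() exactly
num_chr <- function(x) sprintf("%.17g", x)
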
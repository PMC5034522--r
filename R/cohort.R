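# Cohort schema: one row per participant. Heights are stored in cm and
# weights in kg internally (metric canonical); imperial CSVs are converted
# on ingest and the source unit system recorded in the "source_units"
# attribute.

COHORT_COLUMNS <- c(
  "id", "sex", "age_months", "sr_height", "sr_weight",
  "measured_height", "measured_weight",
  "puberty", "body_size", "dieting", "cesd", "self_rated_health",
  "self_esteem", "race_ethnicity", "parent_education", "sample_weight"
)

BODY_SIZE_LEVELS <- c("AboutRight", "UW", "OW")
RACE_LEVELS <- c("White", "Hispanic", "Black", "Asian", "Other")
PARENT_ED_LEVELS <- c("College_plus", "HS_or_less", "Some_college")

#' Validate a cohort data.frame
#'
#' Checks the participant-record schema: positive self-reported height (cm)
#' and weight (kg), positive sampling weight, puberty in 1..5, the collapsed
#' 3-level body-size estimation, CES-D in 0-60, self-rated health and
#' self-esteem in 1-5, and recognised race/ethnicity and parent-education
#' levels. Measured height/weight columns are optional (they may be absent
#' or `NA` for application-only cohorts). Row-level failures are reported
#' together in the error message.
#'
#' @param data cohort data.frame.
#' @param require_measured if `TRUE`, measured height/weight must be present
#'   and positive (needed for fitting and evaluation).
#' @return the validated data.frame, invisibly unchanged apart from type
#'   normalisation (`dieting` coerced to logical, `sex` lowercased).
#' @export
validate_cohort <- function(data, require_measured = FALSE) {
  data <- as.data.frame(data)
  need <- setdiff(COHORT_COLUMNS, c("id", "measured_height", "measured_weight"))
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop_schema(sprintf("cohort lacks column(s): %s", paste(miss, collapse = ", ")))
  if (!"id" %in% names(data)) data$id <- as.character(seq_len(nrow(data)))
  data$sex <- tolower(as.character(data$sex))
  data$dieting <- as.logical(data$dieting)
  probs <- character(0)
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0)
      probs <<- c(probs, sprintf("%s (rows %s)", what,
                                 paste(utils::head(i, 5), collapse = ",")))
  }
  bad(!data$sex %in% c("male", "female"), "sex not male/female")
  bad(!is.finite(data$age_months) | data$age_months <= 0, "invalid age_months")
  bad(!is.finite(data$sr_height) | data$sr_height <= 0, "nonpositive sr_height")
  bad(!is.finite(data$sr_weight) | data$sr_weight <= 0, "nonpositive sr_weight")
  bad(!is.finite(data$sample_weight) | data$sample_weight <= 0,
      "nonpositive sample_weight")
  ok_na <- function(x, cond) !is.na(x) & cond
  bad(ok_na(data$puberty, !data$puberty %in% 1:5), "puberty outside 1..5")
  bad(ok_na(data$body_size, !data$body_size %in% BODY_SIZE_LEVELS),
      "unknown body_size level")
  bad(ok_na(data$cesd, data$cesd < 0 | data$cesd > 60), "cesd outside 0..60")
  bad(ok_na(data$self_rated_health,
            data$self_rated_health < 1 | data$self_rated_health > 5),
      "self_rated_health outside 1..5")
  bad(ok_na(data$self_esteem, data$self_esteem < 1 | data$self_esteem > 5),
      "self_esteem outside 1..5")
  bad(ok_na(data$race_ethnicity, !data$race_ethnicity %in% RACE_LEVELS),
      "unknown race_ethnicity level")
  bad(ok_na(data$parent_education, !data$parent_education %in% PARENT_ED_LEVELS),
      "unknown parent_education level")
  if (require_measured) {
    for (v in c("measured_height", "measured_weight")) {
      if (!v %in% names(data)) stop_schema(sprintf("cohort lacks column %s", v))
      bad(!is.finite(data[[v]]) | data[[v]] <= 0, sprintf("nonpositive %s", v))
    }
  }
  if (length(probs) > 0)
    stop_schema(paste0("cohort validation failed: ",
                       paste(probs, collapse = "; ")))
  data
}

#' Read / write a cohort CSV
#'
#' The CSV carries the participant-record schema (see [validate_cohort()]).
#' Heights/weights are cm and kg when `units = "metric"` (the canonical
#' storage) or inches and pounds when `units = "imperial"`; imperial input
#' is converted to metric on read and the source unit system recorded in
#' the `source_units` attribute.
#'
#' @param path CSV path.
#' @param units unit system of the file's height/weight columns.
#' @param validate run [validate_cohort()] (default `TRUE`).
#' @return a metric cohort data.frame.
#' @export
read_cohort <- function(path, units = c("metric", "imperial"), validate = TRUE) {
  units <- match.arg(units)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (units == "imperial") {
    for (v in c("sr_height", "measured_height"))
      if (v %in% names(data)) data[[v]] <- in_to_cm(data[[v]])
    for (v in c("sr_weight", "measured_weight"))
      if (v %in% names(data)) data[[v]] <- lb_to_kg(data[[v]])
  }
  if (validate) data <- validate_cohort(data)
  attr(data, "source_units") <- units
  data
}

#' @rdname read_cohort
#' @param data cohort data.frame (metric).
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# rows complete for a set of record fields (sr_status derives from SR values,
# so it imposes no extra completeness requirement)
complete_for <- function(data, predictors) {
  fields <- setdiff(unique(predictors), "sr_status")
  ok <- rep(TRUE, nrow(data))
  for (f in fields) {
    if (!f %in% names(data)) return(rep(FALSE, nrow(data)))
    ok <- ok & !is.na(data[[f]])
  }
  ok
}
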
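# Design encoding: map participant records to the numeric covariate vector
# a correction model's terms expect. Class variables are dummy-coded against
# their reference levels; continuous self-reported height/weight are
# expressed in the model's unit system (cohorts are stored metric).

#' Weight status implied by self-report
#'
#' Classifies the BMI computed from self-reported height and weight, using
#' the same pediatric percentile / adult cutoff rules as measured values.
#' This is the "weight status by self-report" class variable of the
#' correction models.
#'
#' @param data cohort data.frame (metric: cm / kg).
#' @param ref a [growth_reference()] (needed for ages under 240 months).
#' @return a [weight_status()] factor, one element per row.
#' @export
derive_sr_weight_status <- function(data, ref = NULL) {
  if (any(!is.finite(data$sr_height) | data$sr_height <= 0) ||
      any(!is.finite(data$sr_weight) | data$sr_weight <= 0))
    stop_domain("self-reported height and weight must be positive")
  bmi <- compute_bmi(data$sr_weight, data$sr_height / 100)
  classify_weight_status(bmi, data$age_months, data$sex, ref)
}

# encode a single (predictor, level) term for all rows; returns numeric vector
encode_term <- function(data, predictor, level, units) {
  info <- .predictors[[predictor]]
  if (is.null(info)) stop_schema(sprintf("unknown predictor '%s'", predictor))
  if (!predictor %in% names(data))
    stop_missing(sprintf("record is missing field '%s'", predictor))
  x <- data[[predictor]]
  if (anyNA(x))
    stop_missing(sprintf("missing value in field '%s'", predictor))
  if (info$type == "continuous") {
    x <- as.numeric(x)
    if (units == "imperial") {
      if (predictor == "sr_weight") x <- kg_to_lb(x)
      if (predictor == "sr_height") x <- cm_to_in(x)
    }
    x
  } else if (info$type == "binary") {
    as.numeric(as.logical(x))
  } else {
    x <- as.character(x)
    if (identical(level, "Below_college")) {
      # published single-coefficient encoding of parent education
      as.numeric(x != .predictors$parent_education$ref)
    } else {
      as.numeric(x == level)
    }
  }
}

# design matrix for a model's term list; data must already carry sr_status
# if the model uses it (see add_sr_status)
model_design <- function(model, data) {
  n <- nrow(data)
  X <- matrix(0, n, nrow(model$terms))
  colnames(X) <- term_label(model$terms$predictor, model$terms$level,
                            model$terms$predictor2, model$terms$level2)
  for (i in seq_len(nrow(model$terms))) {
    t <- model$terms[i, ]
    v <- encode_term(data, t$predictor, t$level, model$units)
    if (!is.na(t$predictor2))
      v <- v * encode_term(data, t$predictor2, t$level2, model$units)
    X[, i] <- v
  }
  X
}

add_sr_status <- function(data, model_or_preds, ref) {
  preds <- if (inherits(model_or_preds, "correction_model")) {
    c(model_or_preds$terms$predictor, model_or_preds$terms$predictor2)
  } else model_or_preds
  if ("sr_status" %in% preds && !"sr_status" %in% names(data))
    data$sr_status <- as.character(derive_sr_weight_status(data, ref))
  data
}

#' Design vector for one record
#'
#' Encodes a single participant record into the named numeric covariate
#' vector matching a model's term order: dummy indicators for class
#' variables (reference levels encode to zero), continuous predictors in
#' the model's unit system. A record at all reference levels with
#' zero-valued continuous covariates encodes to the zero vector. Missing
#' covariates raise a missing-data error naming the field (complete-case
#' policy; nothing is imputed).
#'
#' @param record one-row data.frame (or list) with the record's fields,
#'   metric units.
#' @param model a [correction_model()].
#' @param ref growth reference, needed only when the model uses the
#'   self-report weight-status class variable and `record` does not already
#'   carry an `sr_status` field.
#' @return named numeric vector, one element per model term.
#' @export
design_vector <- function(record, model, ref = NULL) {
  record <- as.data.frame(record, stringsAsFactors = FALSE)
  if (nrow(record) != 1) stop_schema("design_vector expects exactly one record")
  record <- add_sr_status(record, model, ref)
  drop(model_design(model, record)[1, ])
}

#' Apply a correction model
#'
#' Evaluates the affine correction equation `intercept + coefficients .
#' design` for each row. The result is in the model's unit system (pounds
#' or inches for the published equations).
#'
#' @param model a [correction_model()].
#' @param data cohort data.frame in metric storage units (cm / kg); may
#'   carry an `sr_status` column, otherwise it is derived via `ref`.
#' @param ref growth reference for deriving self-report weight status.
#' @return numeric vector of corrected values in model units.
#' @export
apply_model <- function(model, data, ref = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  src <- attr(data, "source_units")
  if (!is.null(src) && !src %in% c("metric", "imperial"))
    stop_unit(sprintf("unknown cohort unit system '%s'", src))
  data <- add_sr_status(data, model, ref)
  X <- model_design(model, data)
  drop(model$intercept + X %*% model$terms$coefficient)
}

#' Correct a cohort's self-reported anthropometrics
#'
#' The two-stage application step: apply a weight model and a height model
#' to each record's self-reported values, convert the corrected values to
#' metric, compute corrected BMI, and classify corrected weight status.
#' Records incomplete for any model predictor are dropped (complete-case
#' policy); the number dropped is recorded in the `n_dropped` attribute.
#'
#' @param data cohort data.frame (metric).
#' @param weight_model,height_model [correction_model()]s sharing one unit
#'   system.
#' @param ref a [growth_reference()].
#' @return the complete-case rows of `data` with added columns
#'   `corrected_height` (cm), `corrected_weight` (kg), `corrected_bmi`,
#'   `corrected_status`; attribute `n_dropped` counts excluded rows.
#' @export
correct_cohort <- function(data, weight_model, height_model, ref) {
  if (!identical(weight_model$units, height_model$units))
    stop_unit("weight and height models use different unit systems")
  data <- validate_cohort(data)
  preds <- unique(c(weight_model$terms$predictor, weight_model$terms$predictor2,
                    height_model$terms$predictor, height_model$terms$predictor2))
  preds <- preds[!is.na(preds)]
  ok <- complete_for(data, preds)
  out <- data[ok, , drop = FALSE]
  if (nrow(out) == 0) stop_data("no complete-case records to correct")
  out <- add_sr_status(out, preds, ref)
  w_corr <- apply_model(weight_model, out, ref)
  h_corr <- apply_model(height_model, out, ref)
  if (weight_model$units == "imperial") {
    w_corr <- lb_to_kg(w_corr)
    h_corr <- in_to_cm(h_corr)
  }
  if (any(w_corr <= 0) || any(h_corr <= 0))
    stop_degenerate("correction produced nonpositive height or weight")
  out$corrected_weight <- w_corr
  out$corrected_height <- h_corr
  out$corrected_bmi <- compute_bmi(w_corr, h_corr / 100)
  out$corrected_status <- classify_weight_status(out$corrected_bmi,
                                                 out$age_months, out$sex, ref)
  attr(out, "n_dropped") <- sum(!ok)
  out
}
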
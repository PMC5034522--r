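# Correction-quality evaluation: weighted correlations, 4x4 weight-status
# misclassification tables with over/under-estimation decomposition, and
# BMI-threshold diagnostics (sensitivity/specificity/PPV/NPV).

#' Weighted Pearson correlation
#'
#' Probability-weighted product-moment correlation. Invariant to uniform
#' rescaling of the weights and to sign-preserving affine transforms of
#' either variable.
#'
#' @param x,y numeric vectors (length >= 3).
#' @param w positive weights (default equal).
#' @return correlation in \[-1, 1\].
#' @export
weighted_pearson <- function(x, y, w = NULL) {
  n <- length(x)
  if (length(y) != n) stop_schema("x and y must have equal length")
  if (n < 3) stop_schema("need at least 3 observations")
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n || any(!is.finite(w)) || any(w <= 0))
    stop_domain("weights must be positive and match x in length")
  if (anyNA(x) || anyNA(y)) stop_missing("x and y must be complete")
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0)
    stop_degenerate("zero weighted variance: correlation undefined")
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Weight-status classification table
#'
#' A 4x4 matrix of weighted percentages comparing an assigned weight status
#' (rows; self-reported or corrected) against a reference status (columns;
#' measured, or self-reported for descriptive comparisons). Rows and
#' columns are ordered UW, HW, OW, OB. Cells above the diagonal (reference
#' exceeds assigned) are underestimates.
#'
#' @param cells 4x4 numeric matrix of percentages summing to 100.
#' @param n effective count behind the table.
#' @param counts optional raw 4x4 integer counts (kept when weights are
#'   uniform).
#' @param row_axis,col_axis axis labels for printing.
#' @param tol allowed deviation of the cell sum from 100 (default 1e-9;
#'   re-entered printed tables round to one decimal and need ~0.2).
#' @return object of class `classification_table`.
#' @export
classification_table <- function(cells, n = NA_integer_, counts = NULL,
                                 row_axis = "assigned", col_axis = "reference",
                                 tol = 1e-9) {
  cells <- as.matrix(cells)
  if (!all(dim(cells) == c(4, 4)))
    stop_schema("classification table must be 4x4")
  dimnames(cells) <- list(status_levels(), status_levels())
  if (any(cells < 0)) stop_domain("cell percentages must be nonnegative")
  if (abs(sum(cells) - 100) > tol)
    stop_domain(sprintf("cell percentages sum to %.6f, not 100", sum(cells)))
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (!all(dim(counts) == c(4, 4))) stop_schema("counts must be 4x4")
    dimnames(counts) <- dimnames(cells)
  }
  structure(list(cells = cells, counts = counts, n = n,
                 row_axis = row_axis, col_axis = col_axis),
            class = "classification_table")
}

#' @export
print.classification_table <- function(x, digits = 1, ...) {
  cat(sprintf("Weight status classification (%% of n = %s)\n",
              format(x$n, big.mark = ",")))
  cat(sprintf("  rows: %s   columns: %s\n", x$row_axis, x$col_axis))
  print(round(x$cells, digits))
  cat(sprintf("  diagonal %.1f%%  under %.1f%%  over %.1f%%\n",
              sum(diag(x$cells)), underestimation_rate(x),
              overestimation_rate(x)))
  invisible(x)
}

#' Weighted contingency table of assigned vs reference status
#'
#' @param assigned,reference weight statuses ([weight_status()] or status
#'   codes), equal length.
#' @param w positive weights (default equal; with equal weights the raw
#'   counts are kept alongside the percentages).
#' @return a [classification_table()] of weighted cell percentages.
#' @export
contingency <- function(assigned, reference, w = NULL) {
  assigned <- weight_status(assigned)
  reference <- weight_status(reference)
  n <- length(assigned)
  if (length(reference) != n) stop_schema("assigned and reference lengths differ")
  if (n == 0) stop_data("empty input")
  if (anyNA(assigned) || anyNA(reference)) stop_missing("statuses must be complete")
  uniform <- is.null(w)
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n || any(!is.finite(w)) || any(w <= 0))
    stop_domain("weights must be positive and match input length")
  uniform <- uniform || length(unique(w)) == 1
  cells <- matrix(0, 4, 4, dimnames = list(status_levels(), status_levels()))
  agg <- tapply(w, list(assigned, reference), sum, default = 0)
  cells[rownames(agg), colnames(agg)] <- agg
  counts <- NULL
  if (uniform) {
    counts <- matrix(0L, 4, 4, dimnames = dimnames(cells))
    tab <- table(assigned, reference)
    counts[rownames(tab), colnames(tab)] <- tab
  }
  classification_table(100 * cells / sum(cells), n = n, counts = counts)
}

#' Misclassification decomposition of a classification table
#'
#' With rows = assigned and columns = reference status,
#' `underestimation_rate()` sums the cells above the diagonal (the
#' reference status exceeds the assigned one), `overestimation_rate()` the
#' cells below it, and `overall_misclassification()` is `100 - trace`. The
#' three satisfy under + over + diagonal = 100.
#'
#' @param table a [classification_table()].
#' @return a percentage.
#' @export
underestimation_rate <- function(table) {
  stopifnot(inherits(table, "classification_table"))
  sum(table$cells[upper.tri(table$cells)])
}

#' @rdname underestimation_rate
#' @export
overestimation_rate <- function(table) {
  stopifnot(inherits(table, "classification_table"))
  sum(table$cells[lower.tri(table$cells)])
}

#' @rdname underestimation_rate
#' @export
overall_misclassification <- function(table) {
  stopifnot(inherits(table, "classification_table"))
  100 - sum(diag(table$cells))
}

# Wilson score interval for a proportion at effective sample size n
wilson_ci <- function(p, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

# Clopper-Pearson via the beta quantile, at (possibly non-integer)
# effective counts x successes out of n
exact_ci <- function(p, n, conf = 0.95) {
  a <- (1 - conf) / 2
  x <- p * n
  lo <- if (x <= 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x >= n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo = lo, hi = hi)
}

# Kish effective sample size of a weight vector
kish_n <- function(w) sum(w)^2 / sum(w^2)

#' BMI-threshold diagnostics against a reference
#'
#' Dichotomises predicted and reference BMI at a threshold (positive =
#' BMI >= threshold on both axes) and computes weighted sensitivity,
#' specificity, PPV, and NPV with 95% confidence intervals. Intervals use
#' the Wilson score method by default (Clopper-Pearson available via
#' `ci`); the effective sample size behind each interval is Kish's
#' approximation on the weights of the relevant margin.
#'
#' @param bmi_pred predicted (self-reported or corrected) BMI values.
#' @param bmi_ref reference (measured) BMI values.
#' @param threshold BMI cutoff in kg/m^2 (> 0), e.g. 25 or 30.
#' @param w positive weights (default equal).
#' @param ci `"wilson"` or `"exact"`.
#' @param conf confidence level (default 0.95).
#' @return object of class `diagnostic_result` with `estimates` (named
#'   vector: sensitivity, specificity, ppv, npv), `ci` (4x2 matrix),
#'   `threshold`, `method`, and the weighted 2x2 `cells`.
#' @export
binary_diagnostics <- function(bmi_pred, bmi_ref, threshold, w = NULL,
                               ci = c("wilson", "exact"), conf = 0.95) {
  ci <- match.arg(ci)
  n <- length(bmi_pred)
  if (length(bmi_ref) != n) stop_schema("bmi_pred and bmi_ref lengths differ")
  if (!is.finite(threshold) || threshold <= 0)
    stop_domain("threshold must be positive")
  if (anyNA(bmi_pred) || anyNA(bmi_ref)) stop_missing("BMI vectors must be complete")
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n || any(!is.finite(w)) || any(w <= 0))
    stop_domain("weights must be positive and match input length")
  pred_pos <- bmi_pred >= threshold
  ref_pos <- bmi_ref >= threshold
  if (!any(ref_pos))
    stop_degenerate("no reference positives: sensitivity undefined")
  if (!any(!ref_pos))
    stop_degenerate("no reference negatives: specificity undefined")
  tp <- sum(w[pred_pos & ref_pos]);  fn <- sum(w[!pred_pos & ref_pos])
  tn <- sum(w[!pred_pos & !ref_pos]); fp <- sum(w[pred_pos & !ref_pos])
  cells <- matrix(c(tp, fp, fn, tn), 2, 2,
                  dimnames = list(pred = c("pos", "neg"),
                                  ref = c("pos", "neg")))
  est <- c(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_
  )
  n_eff <- c(
    sensitivity = kish_n(w[ref_pos]),
    specificity = kish_n(w[!ref_pos]),
    ppv = if (any(pred_pos)) kish_n(w[pred_pos]) else NA_real_,
    npv = if (any(!pred_pos)) kish_n(w[!pred_pos]) else NA_real_
  )
  ci_fun <- if (ci == "wilson") wilson_ci else exact_ci
  ci_mat <- t(vapply(names(est), function(m) {
    if (is.na(est[m])) c(lo = NA_real_, hi = NA_real_)
    else ci_fun(est[[m]], n_eff[[m]], conf)
  }, numeric(2)))
  structure(list(threshold = threshold, estimates = est, ci = ci_mat,
                 n_eff = n_eff, cells = cells, method = ci, conf = conf),
            class = "diagnostic_result")
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat(sprintf("Diagnostics at BMI >= %g (%s %d%% CI)\n", x$threshold,
              x$method, round(100 * x$conf)))
  for (m in rownames(x$ci))
    cat(sprintf("  %-12s %.3f [%.3f, %.3f]\n", m, x$estimates[[m]],
                x$ci[m, "lo"], x$ci[m, "hi"]))
  invisible(x)
}

# manual constructor for published / externally reported diagnostics
diagnostic_from_published <- function(threshold, est, ci_mat,
                                      method = "published") {
  structure(list(threshold = threshold, estimates = est, ci = ci_mat,
                 n_eff = NULL, cells = NULL, method = method, conf = 0.95),
            class = "diagnostic_result")
}

#' Compare two diagnostic results
#'
#' Percentage-point differences (corrected minus self-report) for
#' sensitivity, specificity, PPV, and NPV, plus a confidence-interval
#' overlap flag per metric (non-overlap being the conventional marker of a
#' clear difference).
#'
#' @param sr diagnostics of the self-reported BMI.
#' @param corrected diagnostics of the corrected BMI.
#' @return data.frame with columns `metric`, `sr`, `corrected`,
#'   `delta_pts`, `ci_overlap`.
#' @export
compare_diagnostics <- function(sr, corrected) {
  stopifnot(inherits(sr, "diagnostic_result"),
            inherits(corrected, "diagnostic_result"))
  if (!isTRUE(all.equal(sr$threshold, corrected$threshold)))
    stop_schema("diagnostics compare different thresholds")
  metrics <- names(sr$estimates)
  overlap <- vapply(metrics, function(m) {
    sr$ci[m, "lo"] <= corrected$ci[m, "hi"] &&
      corrected$ci[m, "lo"] <= sr$ci[m, "hi"]
  }, logical(1))
  data.frame(
    metric = metrics,
    sr = unname(sr$estimates[metrics]),
    corrected = unname(corrected$estimates[metrics]),
    delta_pts = unname(100 * (corrected$estimates[metrics] - sr$estimates[metrics])),
    ci_overlap = unname(overlap),
    row.names = NULL
  )
}

#' Export a classification table
#'
#' @param table a [classification_table()].
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
write_classification_csv <- function(table, path) {
  df <- as.data.frame(table$cells)
  df <- cbind(assigned = rownames(table$cells), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
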
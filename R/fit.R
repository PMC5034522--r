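# Probability-weighted least squares and block-wise AIC model selection.
#
# Weighting convention: sampling weights are treated as probability
# weights and normalised to sum to n before likelihood evaluation, so the
# pseudo-log-likelihood (and hence AIC) is invariant to the weights' scale.
# k counts the intercept, the slopes, and the error variance.

#' Weighted least-squares fit
#'
#' Fits `y = b0 + X b + e` by probability-weighted least squares. Point
#' estimates are the usual WLS solution; the Gaussian pseudo-log-likelihood
#' uses weights normalised to sum to `n`, and `AIC = 2k - 2 loglik` with
#' `k = ncol(X) + 2` (intercept + slopes + error variance). R-squared is
#' the weighted explained-variance fraction. Standard errors are
#' model-based: `Var(b) = s2 (X'WX)^-1` with the unbiased weighted residual
#' variance.
#'
#' @param y numeric outcome vector.
#' @param X numeric design matrix (no intercept column; one is added).
#' @param w positive weights (default: equal).
#' @return object of class `wls_fit`: `coefficients` (named, starting with
#'   `(Intercept)`), `se`, `loglik`, `aic`, `r_squared`, `sigma2`,
#'   `fitted`, `residuals`, `n`, `k`.
#' @export
fit_wls <- function(y, X, w = NULL) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop_schema("y and X have different lengths")
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n) stop_schema("weights length must match y")
  if (any(!is.finite(w)) || any(w <= 0)) stop_domain("weights must be positive")
  if (anyNA(y) || anyNA(X)) stop_missing("fit_wls requires complete cases")
  p <- ncol(X) + 1L
  if (n <= p) stop_data(sprintf("need n > p (n = %d, p = %d)", n, p))
  if (is.null(colnames(X)) && ncol(X) > 0)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xi <- cbind(`(Intercept)` = 1, X)
  wn <- w * n / sum(w)
  sw <- sqrt(wn)
  qr_d <- qr(Xi * sw)
  if (qr_d$rank < p) {
    bad <- colnames(Xi)[qr_d$pivot[(qr_d$rank + 1):p]]
    stop_singular(sprintf("design matrix is rank deficient; collinear column(s): %s",
                          paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qr_d, y * sw)
  fitted <- drop(Xi %*% beta)
  res <- y - fitted
  rss <- sum(wn * res^2)
  sigma2 <- rss / n
  loglik <- -0.5 * n * (log(2 * pi * sigma2) + 1)
  k <- p + 1L
  ybar <- sum(wn * y) / n
  tss <- sum(wn * (y - ybar)^2)
  XtWX_inv <- chol2inv(qr.R(qr_d))
  s2_unb <- rss / (n - p)
  se <- sqrt(diag(XtWX_inv) * s2_unb)
  names(se) <- names(beta) <- colnames(Xi)
  structure(list(
    coefficients = beta, se = se, loglik = loglik, aic = 2 * k - 2 * loglik,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    sigma2 = sigma2, fitted = fitted, residuals = res, n = n, k = k
  ), class = "wls_fit")
}

#' @export
print.wls_fit <- function(x, ...) {
  cat(sprintf("Weighted LS fit: n = %d, k = %d, AIC = %.2f, R^2 = %.4f\n",
              x$n, x$k, x$aic, x$r_squared))
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

# --- block design ----------------------------------------------------------

# blocks: named list, block name -> terms data.frame
# (predictor, level, predictor2, level2)
main_blocks <- function(predictors) {
  out <- lapply(predictors, function(p) {
    t <- block_terms(p)
    t$predictor2 <- NA_character_
    t$level2 <- NA_character_
    t
  })
  names(out) <- predictors
  out
}

interaction_block <- function(p, q) {
  a <- block_terms(p); b <- block_terms(q)
  g <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  data.frame(predictor = a$predictor[g$i], level = a$level[g$i],
             predictor2 = b$predictor[g$j], level2 = b$level[g$j],
             stringsAsFactors = FALSE)
}

build_block_design <- function(data, blocks, units, ref) {
  preds <- unique(unlist(lapply(blocks, function(t)
    c(t$predictor, t$predictor2[!is.na(t$predictor2)]))))
  data <- add_sr_status(data, preds, ref)
  cols <- list(); labels <- character(0); owner <- character(0)
  for (b in names(blocks)) {
    t <- blocks[[b]]
    for (i in seq_len(nrow(t))) {
      v <- encode_term(data, t$predictor[i], t$level[i], units)
      if (!is.na(t$predictor2[i]))
        v <- v * encode_term(data, t$predictor2[i], t$level2[i], units)
      cols[[length(cols) + 1L]] <- v
      labels <- c(labels, term_label(t$predictor[i], t$level[i],
                                     t$predictor2[i], t$level2[i]))
      owner <- c(owner, b)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- labels
  list(X = X, owner = owner, data = data)
}

outcome_vector <- function(data, outcome, units) {
  col <- paste0("measured_", outcome)
  if (!col %in% names(data))
    stop_schema(sprintf("cohort lacks measured outcome column '%s'", col))
  y <- as.numeric(data[[col]])
  if (units == "imperial")
    y <- if (outcome == "weight") kg_to_lb(y) else cm_to_in(y)
  y
}

sr_analogue <- function(outcome) if (outcome == "weight") "sr_weight" else "sr_height"

fit_blocks <- function(y, design, block_names, w) {
  keep <- design$owner %in% block_names
  fit_wls(y, design$X[, keep, drop = FALSE], w)
}

wrap_fit <- function(wls, blocks, block_names, outcome, units) {
  # design columns follow the blocks-list order, whatever order blocks
  # were retained/added in
  block_names <- names(blocks)[names(blocks) %in% block_names]
  terms <- do.call(rbind, blocks[block_names])
  terms$coefficient <- num_chr(wls$coefficients[-1])
  model <- correction_model(outcome, units, num_chr(wls$coefficients[1]), terms,
                            provenance = list(source = "refit", n = wls$n,
                                              aic = wls$aic,
                                              r_squared = wls$r_squared))
  structure(list(model = model, se = wls$se, loglik = wls$loglik,
                 aic = wls$aic, r_squared = wls$r_squared, n_used = wls$n,
                 blocks = block_names, outcome = outcome, units = units,
                 wls = wls),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit result: measured %s, n = %d, AIC = %.2f, R^2 = %.4f\n",
              x$outcome, x$n_used, x$aic, x$r_squared))
  cat("Blocks:", paste(x$blocks, collapse = ", "), "\n")
  print(x$model)
  invisible(x)
}

prepare_fit_data <- function(data, outcome, predictors, units, ref) {
  data <- validate_cohort(data, require_measured = TRUE)
  fields <- c(setdiff(unique(predictors), "sr_status"),
              paste0("measured_", outcome), "sample_weight")
  ok <- complete_for(data, fields)
  data <- data[ok, , drop = FALSE]
  if (nrow(data) == 0) stop_data("no complete-case records available for fitting")
  attr(data, "n_dropped") <- sum(!ok)
  data
}

#' Fit a correction model on cohort data
#'
#' Weighted least-squares fit of a measured anthropometric on the given
#' predictor blocks (no selection). Complete cases only; sampling weights
#' taken from the `sample_weight` column.
#'
#' @param data cohort data.frame (metric) with measured outcome columns.
#' @param outcome `"weight"` or `"height"`.
#' @param predictors character vector of predictor block names (see
#'   `predictor_names()`); defaults to the outcome's self-report analogue
#'   plus all covariates.
#' @param units unit system of the fitted equation.
#' @param ref growth reference (for the self-report weight-status block).
#' @return a `fit_result`: the fitted [correction_model()] plus `se`,
#'   `loglik`, `aic`, `r_squared`, `n_used`.
#' @export
fit_correction <- function(data, outcome = c("weight", "height"),
                           predictors = NULL,
                           units = c("imperial", "metric"), ref = NULL) {
  outcome <- match.arg(outcome)
  units <- match.arg(units)
  if (is.null(predictors))
    predictors <- c(sr_analogue(outcome),
                    setdiff(predictor_names(), c("sr_weight", "sr_height")))
  data <- prepare_fit_data(data, outcome, predictors, units, ref)
  blocks <- main_blocks(predictors)
  design <- build_block_design(data, blocks, units, ref)
  y <- outcome_vector(design$data, outcome, units)
  wls <- fit_blocks(y, design, predictors, design$data$sample_weight)
  wrap_fit(wls, blocks, predictors, outcome, units)
}

#' Block-wise backward AIC selection
#'
#' Starting from the full model over all candidate blocks, repeatedly drops
#' the whole block (a class variable leaves with all its dummies) whose
#' removal lowers AIC the most, until no single-block removal lowers AIC.
#' The mandatory block — by default the self-report analogue of the outcome
#' — is never dropped. Deterministic: candidate blocks are evaluated in the
#' given order and on an exact AIC tie the block is kept.
#'
#' @inheritParams fit_correction
#' @param candidates candidate predictor block names (default: all
#'   covariates besides the mandatory self-report term).
#' @param mandatory block name(s) always retained.
#' @return a `fit_result` for the selected model; attribute `trace` records
#'   each removal step, attribute `full_aic` the full-model AIC.
#' @export
aic_select <- function(data, outcome = c("weight", "height"),
                       candidates = NULL, mandatory = NULL,
                       units = c("imperial", "metric"), ref = NULL) {
  outcome <- match.arg(outcome)
  units <- match.arg(units)
  if (is.null(mandatory)) mandatory <- sr_analogue(outcome)
  if (is.null(candidates))
    candidates <- setdiff(predictor_names(), c("sr_weight", "sr_height"))
  all_blocks <- unique(c(mandatory, candidates))
  data <- prepare_fit_data(data, outcome, all_blocks, units, ref)
  blocks <- main_blocks(all_blocks)
  design <- build_block_design(data, blocks, units, ref)
  y <- outcome_vector(design$data, outcome, units)
  w <- design$data$sample_weight

  current <- all_blocks
  cur_fit <- fit_blocks(y, design, current, w)
  full_aic <- cur_fit$aic
  trace <- data.frame(step = integer(0), removed = character(0),
                      aic = numeric(0))
  step <- 0L
  repeat {
    removable <- setdiff(current, mandatory)
    if (length(removable) == 0) break
    aics <- vapply(removable, function(b)
      fit_blocks(y, design, setdiff(current, b), w)$aic, numeric(1))
    best <- which.min(aics)   # first minimum in candidate order
    if (aics[best] >= cur_fit$aic) break  # tie => keep the block
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = removable[best],
                                     aic = aics[best]))
    current <- setdiff(current, removable[best])
    cur_fit <- fit_blocks(y, design, current, w)
  }
  out <- wrap_fit(cur_fit, blocks, current, outcome, units)
  attr(out, "trace") <- trace
  attr(out, "full_aic") <- full_aic
  out
}

#' Screen two-way interactions by AIC
#'
#' Forms all pairwise interaction blocks among the predictors retained by
#' [aic_select()] (dummy x dummy, dummy x continuous, continuous x
#' continuous) and adds them greedily: at each step the interaction block
#' whose inclusion lowers AIC the most enters; screening stops when no
#' block lowers AIC. With the main effects capturing the generative model,
#' no interaction is expected to survive.
#'
#' @param fit a `fit_result` from [aic_select()] (or [fit_correction()]).
#' @param data the cohort the fit was made on.
#' @param ref growth reference.
#' @return a `fit_result`; attribute `interactions_kept` lists retained
#'   pair names (empty when none survive).
#' @export
screen_interactions <- function(fit, data, ref = NULL) {
  retained <- fit$blocks
  if (length(retained) < 2) {
    attr(fit, "interactions_kept") <- character(0)
    return(fit)
  }
  outcome <- fit$outcome; units <- fit$units
  data <- prepare_fit_data(data, outcome, retained, units, ref)
  pairs <- utils::combn(retained, 2, simplify = FALSE)
  blocks <- main_blocks(retained)
  pair_names <- vapply(pairs, function(p) paste(p, collapse = " x "), character(1))
  for (i in seq_along(pairs))
    blocks[[pair_names[i]]] <- interaction_block(pairs[[i]][1], pairs[[i]][2])
  design <- build_block_design(data, blocks, units, ref)
  y <- outcome_vector(design$data, outcome, units)
  w <- design$data$sample_weight

  current <- retained
  cur_fit <- fit_blocks(y, design, current, w)
  candidates <- pair_names
  kept <- character(0)
  repeat {
    if (length(candidates) == 0) break
    aics <- vapply(candidates, function(b) {
      f <- tryCatch(fit_blocks(y, design, c(current, b), w),
                    bmicorrect_singular_error = function(e) NULL)
      if (is.null(f)) Inf else f$aic
    }, numeric(1))
    best <- which.min(aics)
    if (aics[best] >= cur_fit$aic) break
    kept <- c(kept, candidates[best])
    current <- c(current, candidates[best])
    candidates <- candidates[-best]
    cur_fit <- fit_blocks(y, design, current, w)
  }
  out <- wrap_fit(cur_fit, blocks, current, outcome, units)
  attr(out, "interactions_kept") <- kept
  out
}

#' Sex-stratified correction fits
#'
#' Refits the selection pipeline separately within each sex, for analyses
#' that prefer sex-specific equations over a pooled model with sex as a
#' covariate. The `sex` block is removed from the candidates within each
#' stratum (it is constant there).
#'
#' @inheritParams aic_select
#' @param interactions also run [screen_interactions()] per stratum.
#' @return named list (`male`, `female`) of `fit_result`s.
#' @export
fit_stratified <- function(data, outcome = c("weight", "height"),
                           candidates = NULL, units = c("imperial", "metric"),
                           ref = NULL, interactions = FALSE) {
  outcome <- match.arg(outcome)
  units <- match.arg(units)
  if (is.null(candidates))
    candidates <- setdiff(predictor_names(), c("sr_weight", "sr_height"))
  candidates <- setdiff(candidates, "sex")
  out <- lapply(c(male = "male", female = "female"), function(s) {
    sub <- data[data$sex == s, , drop = FALSE]
    if (nrow(sub) == 0) stop_data(sprintf("no records for sex '%s'", s))
    fit <- aic_select(sub, outcome, candidates = candidates, units = units,
                      ref = ref)
    if (interactions) fit <- screen_interactions(fit, sub, ref = ref)
    fit
  })
  out
}
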
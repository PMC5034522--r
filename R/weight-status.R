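#' Ordered weight-status factor
#'
#' Weight status is a four-level ordered categorical: underweight (`UW`) <
#' healthy weight (`HW`) < overweight (`OW`) < obesity (`OB`). The ordering
#' carries the above/below-diagonal semantics used by the misclassification
#' decomposition: an assigned status below the reference status is an
#' underestimate.
#'
#' @param x character vector of status codes (`"UW"`, `"HW"`, `"OW"`, `"OB"`).
#' @return an ordered factor with levels `UW < HW < OW < OB`.
#' @export
#' @examples
#' weight_status(c("HW", "OB")) < weight_status(c("OW", "OW"))
weight_status <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !x %in% status_levels()
  if (any(bad)) {
    stop_domain(sprintf("unknown weight status code(s): %s",
                        paste(unique(x[bad]), collapse = ", ")))
  }
  factor(x, levels = status_levels(), ordered = TRUE)
}

#' @rdname weight_status
#' @export
status_levels <- function() c("UW", "HW", "OW", "OB")
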
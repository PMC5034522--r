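# Classed conditions so callers (and the CLI exit-code mapping) can
# distinguish bad values, bad schemas, and numerical failures.

stop_classed <- function(class, msg, call. = sys.call(-2)) {
  stop(structure(
    class = c(class, "bmicorrect_error", "error", "condition"),
    list(message = msg, call = call.)
  ))
}

stop_domain    <- function(msg) stop_classed("bmicorrect_domain_error", msg)
stop_range     <- function(msg) stop_classed("bmicorrect_range_error", msg)
stop_schema    <- function(msg) stop_classed("bmicorrect_schema_error", msg)
stop_missing   <- function(msg) stop_classed(c("bmicorrect_missing_data_error",
                                               "bmicorrect_schema_error"), msg)
stop_unit      <- function(msg) stop_classed(c("bmicorrect_unit_error",
                                               "bmicorrect_schema_error"), msg)
stop_degenerate <- function(msg) stop_classed("bmicorrect_numeric_error", msg)
stop_singular  <- function(msg) stop_classed(c("bmicorrect_singular_error",
                                               "bmicorrect_numeric_error"), msg)
stop_data      <- function(msg) stop_classed(c("bmicorrect_data_error",
                                               "bmicorrect_schema_error"), msg)
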
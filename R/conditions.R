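# Classed error conditions so callers can branch on failure modes rather
# than matching message text. Every error signalled by the package carries
# class c("foodexch_<what>", "foodexch_error", "error", "condition").

abort_foodexch <- function(class, message, ...) {
  stop(errorCondition(message,
                      ...,
                      class = c(paste0("foodexch_", class), "foodexch_error")))
}

# shared precondition: numeric, finite, non-negative
check_nonneg <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort_foodexch("invalid_component",
                   sprintf("%s must be finite numeric, got: %s", what,
                           paste(utils::head(x), collapse = ", ")))
  }
  if (any(x < 0)) {
    abort_foodexch("invalid_component",
                   sprintf("%s must be >= 0, got %s", what,
                           paste(x[x < 0], collapse = ", ")))
  }
  invisible(x)
}
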
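# classed conditions so callers (and the CLI wrapper) can distinguish
# validation failures from programming errors
abort_glyco <- function(msg, class) {
  stop(structure(
    class = c(class, "glycoEMT_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_invalid <- function(msg) abort_glyco(msg, "glycoEMT_invalid_input")
abort_validation <- function(msg) abort_glyco(msg, "glycoEMT_validation_error")

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || anyNA(x)) {
    abort_invalid(sprintf("'%s' must be numeric and non-missing", name))
  }
  if (any(x < lower) || any(x > upper)) {
    abort_invalid(sprintf("'%s' must lie in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
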
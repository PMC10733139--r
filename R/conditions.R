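# Structured conditions so callers (and the command-line wrapper) can
# distinguish bad input from numerical failure.

tra_abort <- function(msg, class = "tra_validation_error", call = NULL) {
  stop(errorCondition(msg, class = c(class, "tra_error"), call = call))
}

tra_abort_numerical <- function(msg) {
  tra_abort(msg, class = "tra_numerical_error")
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE, strict_lower = FALSE) {
  if (is.null(x) || length(x) != 1L) {
    tra_abort(sprintf("'%s' must be a single number", name))
  }
  if (is.na(x)) {
    if (allow_na) return(invisible(x))
    tra_abort(sprintf("'%s' must not be missing", name))
  }
  if (!is.numeric(x)) tra_abort(sprintf("'%s' must be numeric", name))
  if (strict_lower) {
    if (x <= lower) {
      tra_abort(sprintf("'%s' must be > %g (got %g)", name, lower, x))
    }
  } else if (x < lower) {
    tra_abort(sprintf("'%s' must be >= %g (got %g)", name, lower, x))
  }
  if (x > upper) {
    tra_abort(sprintf("'%s' must be <= %g (got %g)", name, upper, x))
  }
  invisible(x)
}
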
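# Condition helpers. All package errors inherit from "fp_error" plus a
# specific class so callers can distinguish bad input, model-domain
# violations, lookup failures, and configuration problems.

fp_abort <- function(message, class, ...) {
  abort(message, class = c(class, "fp_error"), ...)
}

fp_abort_input <- function(message, ...) {
  fp_abort(message, class = "fp_error_invalid_input", ...)
}

fp_abort_domain <- function(message, ...) {
  fp_abort(message, class = "fp_error_domain", ...)
}

fp_abort_lookup <- function(message, ...) {
  fp_abort(message, class = "fp_error_lookup", ...)
}

fp_abort_config <- function(message, ...) {
  fp_abort(message, class = "fp_error_config", ...)
}

check_numeric <- function(x, name) {
  if (!is.numeric(x) || anyNA(x)) {
    fp_abort_input(sprintf("`%s` must be numeric and non-missing.", name))
  }
  invisible(x)
}

# Range check with open/closed bounds; `name` appears in the diagnostic so
# configuration errors identify the offending key.
check_range <- function(x, name, lower = -Inf, upper = Inf,
                        open_lower = FALSE, open_upper = FALSE) {
  check_numeric(x, name)
  bad_low <- if (open_lower) x <= lower else x < lower
  bad_high <- if (open_upper) x >= upper else x > upper
  if (any(bad_low | bad_high)) {
    lb <- if (open_lower) "(" else "["
    ub <- if (open_upper) ")" else "]"
    fp_abort_input(sprintf(
      "`%s` must lie in %s%g, %g%s; got %s.",
      name, lb, lower, upper, ub,
      paste(format(x[bad_low | bad_high]), collapse = ", ")
    ))
  }
  invisible(x)
}

check_proportion <- function(x, name) check_range(x, name, 0, 1)

check_nonnegative <- function(x, name) check_range(x, name, lower = 0)
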
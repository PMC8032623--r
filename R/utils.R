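# Internal validation helpers shared across the package.

stop_validation <- function(...) {
  stop(structure(
    class = c("revdosim_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(name, " must be a single finite number")
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_validation(name, " = ", format(x), " outside allowed range ",
                    if (lower_open) "(" else "[", lower, ", ", upper,
                    if (upper_open) ")" else "]")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
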
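.stop_cond <- function(class, msg) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_validation <- function(msg) .stop_cond("elbowsim_validation_error", msg)
stop_config     <- function(msg) .stop_cond("elbowsim_config_error", msg)
stop_numeric    <- function(msg) .stop_cond("elbowsim_numeric_error", msg)

# scalar-or-vector numeric range check used by every constructor
check_num <- function(x, name, lower = -Inf, upper = Inf,
                      closed_lower = TRUE, closed_upper = TRUE,
                      len = NULL) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_validation(sprintf("`%s` must be finite numeric", name))
  }
  if (!is.null(len) && length(x) != len) {
    stop_validation(sprintf("`%s` must have length %d", name, len))
  }
  lo_ok <- if (closed_lower) all(x >= lower) else all(x > lower)
  hi_ok <- if (closed_upper) all(x <= upper) else all(x < upper)
  if (!lo_ok || !hi_ok) {
    stop_validation(sprintf(
      "`%s` must be in %s%g, %g%s (got %g)",
      name, if (closed_lower) "[" else "(", lower, upper,
      if (closed_upper) "]" else ")", x[which(!(
        (if (closed_lower) x >= lower else x > lower) &
        (if (closed_upper) x <= upper else x < upper)))[1]]
    ))
  }
  invisible(x)
}
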
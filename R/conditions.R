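# Classed error conditions shared by all modules. Tests and the CLI dispatch
# on the class, never on the message text.

stop_stereokin <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "stereokin_error", "error", "condition")))
}

stop_undefined <- function(msg) stop_stereokin(msg, "undefined_quantity_error")
stop_domain    <- function(msg) stop_stereokin(msg, "domain_error")
stop_infeasible <- function(msg) stop_stereokin(msg, "infeasibility_error")
stop_input     <- function(msg) stop_stereokin(msg, "input_error")
stop_lookup    <- function(msg) stop_stereokin(msg, "lookup_error")
stop_solver    <- function(msg) stop_stereokin(msg, "solver_failure_error")

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input(sprintf("`%s` must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    bound <- sprintf("%s%s, %s%s",
                     if (strict_lower) "(" else "[", format(lower),
                     format(upper), if (strict_upper) ")" else "]")
    stop_domain(sprintf("`%s` = %g outside %s", name, x, bound))
  }
  invisible(x)
}
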
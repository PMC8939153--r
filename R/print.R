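#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  actuation: %s | dt = 1/%g s | task: %g deg -> %+g deg",
              x$actuation$mode, round(1 / x$sim$dt), x$task$theta_start,
              x$task$delta_target),
      sprintf("(+/- %g deg, < %g deg/s, limit %g s)\n", x$task$tol_theta,
              x$task$tol_omega, x$task$t_limit))
  cat(sprintf("  arm: I = %g kg m^2, b = %g N m s/rad, ROM [%.0f, %.0f] deg\n",
              x$arm$inertia, x$arm$damping_b, x$arm$rom_min * 180 / pi,
              x$arm$rom_max * 180 / pi))
  cat(sprintf("  flexor:   f_max = %g N, moment arm %.1f mm at start\n",
              x$muscles$flexor$f_max,
              1000 * moment_arm(x$task$theta_start * pi / 180,
                                x$geometry$flexor)))
  cat(sprintf("  extensor: f_max = %g N, moment arm %.1f mm at start\n",
              x$muscles$extensor$f_max,
              1000 * moment_arm(x$task$theta_start * pi / 180,
                                x$geometry$extensor)))
  invisible(x)
}

#' @export
print.trial_record <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("<trial_record> %s, %d steps (%.3f s)", x$outcome, n,
              x$series$time[n]))
  if (!is.na(x$movement_time)) {
    cat(sprintf(", movement time %.3f s", x$movement_time))
  }
  cat(sprintf("\n  terminal: theta = %.3f deg, omega = %.2e deg/s\n",
              x$series$theta[n], x$series$omega[n]))
  invisible(x)
}

#' @export
print.muscle_params <- function(x, ...) {
  cat(sprintf(
    "<muscle_params> f_max = %g N, l_ce_opt = %g m, l_slack = %.4f m\n",
    x$f_max, x$l_ce_opt, x$l_slack))
  invisible(x)
}
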
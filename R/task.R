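#' Goal-directed task parameters
#'
#' The task: move the arm from `theta_start` to a target `delta_target`
#' away (positive = flexion) as fast as possible. A trial succeeds when the
#' angle is within `tol_theta` of the target while the angular speed is
#' below `tol_omega`; otherwise it times out at `t_limit`. Angles are in
#' degrees, matching the user-facing convention.
#'
#' @param theta_start start angle (deg).
#' @param delta_target target offset from the start (deg, flexion-positive).
#' @param tol_theta success half-width (deg).
#' @param tol_omega success speed threshold (deg/s).
#' @param t_limit movement time limit (s).
#' @return An object of class `task_params`.
#' @export
task_params <- function(theta_start = 90, delta_target = 45, tol_theta = 2,
                        tol_omega = 0.001, t_limit = 5) {
  check_num(theta_start, "theta_start", 0, 180, closed_lower = FALSE,
            closed_upper = FALSE, len = 1)
  check_num(delta_target, "delta_target", len = 1)
  check_num(tol_theta, "tol_theta", 0, closed_lower = FALSE, len = 1)
  check_num(tol_omega, "tol_omega", 0, closed_lower = FALSE, len = 1)
  check_num(t_limit, "t_limit", 0, closed_lower = FALSE, len = 1)
  structure(
    list(theta_start = theta_start, delta_target = delta_target,
         tol_theta = tol_theta, tol_omega = tol_omega, t_limit = t_limit),
    class = "task_params"
  )
}

#' Success predicate of the goal-directed task
#'
#' True iff the angle is within `tol_theta` of the target
#' (`theta_start + delta_target`) and the angular speed is strictly below
#' `tol_omega`.
#'
#' @param theta arm angle (deg); vectorized.
#' @param omega arm angular velocity (deg/s); vectorized.
#' @param tp a [task_params()].
#' @return Logical.
#' @export
success_check <- function(theta, omega, tp) {
  target <- tp$theta_start + tp$delta_target
  abs(theta - target) <= tp$tol_theta & abs(omega) < tp$tol_omega
}

#' Initial arm state for a trial
#'
#' Builds the start-of-trial state: the arm at the task's start angle with
#' zero velocity and both muscles at their isometric equilibrium with
#' activation at the floor.
#'
#' @param model a [run_config()]-style model bundle.
#' @return An [arm_state()].
#' @export
initial_arm_state <- function(model) {
  th0 <- model$task$theta_start * pi / 180
  arm_state(
    theta = th0, omega = 0,
    flexor = init_muscle_state(th0, model$muscles$flexor$a_min,
                               model$geometry$flexor, model$muscles$flexor),
    extensor = init_muscle_state(th0, model$muscles$extensor$a_min,
                                 model$geometry$extensor,
                                 model$muscles$extensor)
  )
}

.LOG_COLS <- c("time", "theta", "omega", "u_f", "u_e", "a_f", "a_e",
               "force_f", "force_e", "l_ce_f", "l_ce_e", "l_se_f", "l_se_e",
               "r_f", "r_e", "t_lig", "t_damp")

.log_row <- function(t, s, u, model) {
  lmt_f <- muscle_tendon_length(s$theta, model$geometry$flexor)
  lmt_e <- muscle_tendon_length(s$theta, model$geometry$extensor)
  c(t,
    s$theta * 180 / pi,
    s$omega * 180 / pi,
    u$u_f, u$u_e,
    s$flexor$a, s$extensor$a,
    .see_force_safe(lmt_f - s$flexor$l_ce, model$muscles$flexor),
    .see_force_safe(lmt_e - s$extensor$l_ce, model$muscles$extensor),
    s$flexor$l_ce, s$extensor$l_ce,
    lmt_f - s$flexor$l_ce, lmt_e - s$extensor$l_ce,
    moment_arm(s$theta, model$geometry$flexor),
    moment_arm(s$theta, model$geometry$extensor),
    ligament_torque(s$theta, model$arm),
    damping_torque(s$omega, model$arm))
}

.get_control <- function(controller, s, t, step) {
  u <- controller(s, t)
  u_f <- if (is.list(u)) u$u_f else u[["u_f"]]
  u_e <- if (is.list(u)) u$u_e else u[["u_e"]]
  if (!is.numeric(u_f) || !is.numeric(u_e) || anyNA(c(u_f, u_e)) ||
      u_f < 0 || u_f > 1 || u_e < 0 || u_e > 1) {
    stop_validation(sprintf(
      "controller emitted out-of-range excitation at step %d (t = %.4f s)",
      step, t))
  }
  list(u_f = u_f, u_e = u_e)
}

#' Run a single goal-directed trial
#'
#' Steps the simulation at the configured `dt` from the task's start state,
#' evaluating the success predicate on each post-step state. The trial ends
#' at the first successful step (recording the movement time) or when the
#' time limit is reached. Every step, including the terminal one, is
#' logged: angle and velocity (deg, deg/s), excitations, activations,
#' transmitted forces, CE and SEE lengths, moment arms, and the passive
#' torques.
#'
#' @param controller function of `(state, t)` returning a
#'   [control_sample()] (or a list/named vector with `u_f`, `u_e`).
#' @param model a [run_config()]-style model bundle.
#' @param stop_on_success stop at the first successful step (default); set
#'   to `FALSE` to always run out the full time limit (the outcome is still
#'   scored from the first successful step, if any).
#' @return An object of class `trial_record`: list with `series` (data
#'   frame, one row per step), `outcome` (`"success"`/`"timeout"`) and
#'   `movement_time` (s, `NA` on timeout).
#' @export
run_trial <- function(controller, model, stop_on_success = TRUE) {
  dt <- model$sim$dt
  t_limit <- model$task$t_limit
  n_max <- round(t_limit / dt) + 1
  s <- initial_arm_state(model)
  log <- matrix(NA_real_, nrow = n_max, ncol = length(.LOG_COLS),
                dimnames = list(NULL, .LOG_COLS))
  u <- .get_control(controller, s, 0, 0L)
  log[1, ] <- .log_row(0, s, u, model)
  outcome <- "timeout"
  movement_time <- NA_real_
  n_used <- n_max
  for (k in seq_len(n_max - 1)) {
    s <- rk4_step(s, u, dt, model)
    t <- k * dt
    u <- .get_control(controller, s, t, k)
    log[k + 1, ] <- .log_row(t, s, u, model)
    if (is.na(movement_time) &&
        success_check(s$theta * 180 / pi, s$omega * 180 / pi, model$task)) {
      outcome <- "success"
      movement_time <- t
      if (stop_on_success) {
        n_used <- k + 1
        break
      }
    }
  }
  structure(
    list(series = as.data.frame(log[seq_len(n_used), , drop = FALSE]),
         outcome = outcome, movement_time = movement_time),
    class = "trial_record"
  )
}

#' Run a session of sequential trials
#'
#' Runs `n_trials` trials back to back. Between trials the arm
#' auto-resets: the full state (angle, velocity and both muscle substates)
#' is rebuilt from the start configuration, so no state leaks across
#' trials. Per-trial seeds are derived deterministically from the session
#' seed and handed to the controller factory.
#'
#' @param n_trials number of trials (>= 1).
#' @param controller_factory function of `(trial, seed)` returning a
#'   controller for that trial; alternatively a single controller function
#'   of `(state, t)` used for every trial (wrap with [as_controller_factory()]
#'   semantics).
#' @param model a [run_config()]-style model bundle.
#' @param seed session seed (integer).
#' @return List of [run_trial()] records, one per trial.
#' @export
run_session <- function(n_trials, controller_factory, model, seed = 1L) {
  if (!is.numeric(n_trials) || n_trials < 1) {
    stop_validation("`n_trials` must be >= 1")
  }
  factory <- controller_factory
  lapply(seq_len(n_trials), function(k) {
    trial_seed <- (as.integer(seed) + 7919L * k) %% .Machine$integer.max
    run_trial(factory(k, trial_seed), model)
  })
}

#' Wrap a plain controller as a trial factory
#'
#' Convenience for [run_session()]: returns a factory that hands the same
#' controller to every trial, ignoring the per-trial seed.
#'
#' @param controller function of `(state, t)`.
#' @return A function of `(trial, seed)`.
#' @export
as_controller_factory <- function(controller) {
  function(trial, seed) controller
}

#' Summarize a session
#'
#' One row per trial: outcome, movement time (`NA` for timeouts), peak
#' absolute angular velocity (deg/s) and terminal angular error from the
#' target (deg).
#'
#' @param records non-empty list of [run_trial()] records.
#' @param tp optional [task_params()] used for the terminal error; defaults
#'   to the standard task.
#' @return A data frame of class `session_summary`.
#' @export
summarize_session <- function(records, tp = task_params()) {
  if (!is.list(records) || length(records) == 0) {
    stop_validation("`records` must be a non-empty list of trial records")
  }
  target <- tp$theta_start + tp$delta_target
  rows <- lapply(seq_along(records), function(k) {
    r <- records[[k]]
    n <- nrow(r$series)
    data.frame(trial = k, outcome = r$outcome,
               movement_time = r$movement_time,
               peak_velocity = max(abs(r$series$omega)),
               terminal_error = abs(r$series$theta[n] - target))
  })
  structure(do.call(rbind, rows),
            class = c("session_summary", "data.frame"))
}

#' Null controller
#'
#' Emits zero excitation on both sides; the arm just sits at its start
#' equilibrium.
#'
#' @return A controller function of `(state, t)`.
#' @export
controller_null <- function() {
  function(state, t) list(u_f = 0, u_e = 0)
}

#' Controller playing back a sampled excitation stream
#'
#' Looks the excitations up by step index (the stream must be sampled at
#' the simulation `dt`); zero after the stream runs out.
#'
#' @param stream a `control_stream` data frame (`time`, `u_f`, `u_e`).
#' @param dt the simulation step the stream is sampled at (s).
#' @return A controller function of `(state, t)`.
#' @export
controller_stream <- function(stream, dt = 1 / 150) {
  n <- nrow(stream)
  u_f <- stream$u_f
  u_e <- stream$u_e
  function(state, t) {
    k <- round(t / dt) + 1
    if (k < 1 || k > n) list(u_f = 0, u_e = 0)
    else list(u_f = u_f[k], u_e = u_e[k])
  }
}

#' Bang-bang controller from an interval schedule
#'
#' On-off excitation at a fixed level inside the scheduled intervals
#' (later-starting interval wins when sides collide), emulating
#' keyboard/mouse control.
#'
#' @param schedule data frame with `t_on`, `t_off`, `side`.
#' @param level fixed excitation level in `(0, 1]`.
#' @return A controller function of `(state, t)`.
#' @export
controller_bang_bang <- function(schedule, level = 1) {
  .validate_bang_bang_schedule(schedule)
  check_num(level, "level", 0, 1, closed_lower = FALSE, len = 1)
  ord <- order(schedule$t_on)
  function(state, t) {
    u <- list(u_f = 0, u_e = 0)
    for (i in ord) {
      if (t >= schedule$t_on[i] && t < schedule$t_off[i]) {
        if (schedule$side[i] == "flexor") u <- list(u_f = level, u_e = 0)
        else u <- list(u_f = 0, u_e = level)
      }
    }
    u
  }
}

#' Proportional tracking controller with co-activation
#'
#' A graded (EMG-like) feedback policy: both sides hold a co-activation
#' level `co` and the flexor/extensor split follows a
#' proportional-derivative term on the angular error, mimicking a user who
#' grades excitation and stiffens the joint near the target by
#' co-activating.
#'
#' @param tp a [task_params()] (defines the target).
#' @param kp proportional gain (excitation per deg of error).
#' @param kd derivative gain (excitation per deg/s).
#' @param co co-activation level in `[0, 1)`.
#' @return A controller function of `(state, t)`.
#' @export
controller_proportional <- function(tp = task_params(), kp = 0.02,
                                    kd = 0.002, co = 0.3) {
  target <- tp$theta_start + tp$delta_target
  function(state, t) {
    e <- target - state$theta * 180 / pi
    w <- state$omega * 180 / pi
    drive <- kp * e - kd * w
    list(u_f = min(max(co + drive, 0), 1),
         u_e = min(max(co - drive, 0), 1))
  }
}

#' Tune a bang-bang schedule and level that complete the task
#'
#' Builds the canonical keyboard strategy -- a short flexion burst to
#' launch the arm, one braking extension tap in mid-flight, then a coast
#' into the target -- and calibrates the fixed excitation level by
#' bisection on the arm's turnaround angle. Pulse edges live on the
#' simulation's sample grid (as they do for a sampled keyboard), so
#' durations quantize to whole steps and the continuous knob is the level,
#' which stays fixed within the trial as bang-bang control requires.
#' Because the default arm has a rest equilibrium at the target with only
#' a residual torque gradient around it, a turnaround placed close enough
#' to the target leaves the angular speed below the success threshold for
#' tens of consecutive samples, so the tuned trial satisfies the strict
#' stop criterion. The search is fully deterministic.
#'
#' @param model a [run_config()]-style model bundle.
#' @param n_flex flexion burst length in integration steps.
#' @param t_brake brake tap onset (s), on the sample grid.
#' @param n_brake brake tap length in integration steps.
#' @return The tuned schedule (data frame `t_on`, `t_off`, `side`), with
#'   attributes `"level"` (the calibrated excitation level) and
#'   `"movement_time"` from the verifying trial.
#' @export
tune_bang_bang_schedule <- function(model, n_flex = 4, t_brake = 0.1,
                                    n_brake = 1) {
  tp <- model$task
  dt <- model$sim$dt
  target <- tp$theta_start + tp$delta_target
  # pulse edges sit half a step away from the sample grid, so writing the
  # schedule to text and reading it back can never flip a sample on or off
  sched <- function(n_flex) {
    data.frame(t_on = c(0, t_brake - dt / 2),
               t_off = c((n_flex - 0.5) * dt,
                         t_brake + (n_brake - 0.5) * dt),
               side = c("flexor", "extensor"))
  }
  peak_of <- function(level, n_flex) {
    ser <- run_trial(controller_bang_bang(sched(n_flex), level), model,
                     stop_on_success = FALSE)$series
    max(ser$theta)
  }
  # lengthen the launch burst until full drive overshoots the target
  for (try in 1:10) {
    if (peak_of(1, n_flex) > target + 0.5) break
    n_flex <- n_flex * 2
  }
  if (peak_of(1, n_flex) <= target + 0.5) {
    stop_config("flexion burst cannot reach the target region; task and \
actuation parameters are inconsistent")
  }
  s <- sched(n_flex)
  # level calibration: turnaround angle is continuous and increasing in
  # the level, so bisect it onto the target from below
  lo <- 0.01
  hi <- 1
  if (peak_of(lo, n_flex) >= target) {
    stop_config("arm overshoots the target even at near-zero drive")
  }
  for (i in 1:60) {
    level <- 0.5 * (lo + hi)
    tr <- run_trial(controller_bang_bang(s, level), model)
    if (tr$outcome == "success") {
      out <- s
      attr(out, "level") <- level
      attr(out, "movement_time") <- tr$movement_time
      return(out)
    }
    if (peak_of(level, n_flex) < target) lo <- level else hi <- level
  }
  stop_config("bang-bang tuning did not converge to the success window")
}
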
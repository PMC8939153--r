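#' Rigid-body arm parameters
#'
#' The skeleton is a planar pair of rigid links joined by a frictionless
#' hinge at the elbow: the upper arm is fixed, the forearm (plus hand)
#' rotates with moment of inertia `inertia` about the hinge. Two passive
#' torques act on the joint: a viscous damping torque `-damping_b * omega`
#' and a double-sided exponential ligament torque that holds the angle
#' inside the physiological range of motion. The plane is treated as
#' horizontal, so gravity does not enter.
#'
#' @param inertia forearm + hand moment of inertia about the elbow (kg m^2).
#' @param damping_b viscous damping coefficient (N m s/rad, >= 0).
#' @param rom_min,rom_max range-of-motion limits (rad), inside `(0, pi)`.
#' @param lig_k ligament torque scale (N m, >= 0; 0 disables the ligament).
#' @param lig_c ligament exponential rate (1/rad).
#' @param upper_len,fore_len segment lengths (m), bookkeeping for display
#'   and geometry.
#' @return An object of class `arm_params`.
#' @export
arm_params <- function(inertia = 0.075, damping_b = 0.3,
                       rom_min = 10 * pi / 180, rom_max = 160 * pi / 180,
                       lig_k = 10, lig_c = 40,
                       upper_len = 0.3, fore_len = 0.3) {
  check_num(inertia, "inertia", 0, closed_lower = FALSE, len = 1)
  check_num(damping_b, "damping_b", 0, len = 1)
  check_num(rom_min, "rom_min", 0, pi, closed_lower = FALSE,
            closed_upper = FALSE, len = 1)
  check_num(rom_max, "rom_max", 0, pi, closed_lower = FALSE,
            closed_upper = FALSE, len = 1)
  if (rom_min >= rom_max) stop_validation("`rom_min` must be below `rom_max`")
  check_num(lig_k, "lig_k", 0, len = 1)
  check_num(lig_c, "lig_c", 0, closed_lower = FALSE, len = 1)
  check_num(upper_len, "upper_len", 0, closed_lower = FALSE, len = 1)
  check_num(fore_len, "fore_len", 0, closed_lower = FALSE, len = 1)
  structure(
    list(inertia = inertia, damping_b = damping_b,
         rom_min = rom_min, rom_max = rom_max,
         lig_k = lig_k, lig_c = lig_c,
         upper_len = upper_len, fore_len = fore_len),
    class = "arm_params"
  )
}

#' Simulation configuration
#'
#' Fixed-step solver settings: integration step `dt` (default 1/150 s) and
#' the trial time limit.
#'
#' @param dt integration step (s).
#' @param t_limit trial time limit (s).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1 / 150, t_limit = 5) {
  check_num(dt, "dt", 0, closed_lower = FALSE, len = 1)
  check_num(t_limit, "t_limit", 0, closed_lower = FALSE, len = 1)
  structure(list(dt = dt, t_limit = t_limit), class = "sim_config")
}

#' Full dynamic state of the arm
#'
#' The integrator's state vector: joint angle and velocity plus the two
#' muscle substates.
#'
#' @param theta flexion angle (rad).
#' @param omega angular velocity (rad/s).
#' @param flexor,extensor [muscle_state()]s.
#' @return An object of class `arm_state`.
#' @export
arm_state <- function(theta, omega, flexor, extensor) {
  check_num(theta, "theta", len = 1)
  check_num(omega, "omega", len = 1)
  structure(list(theta = theta, omega = omega,
                 flexor = flexor, extensor = extensor),
            class = "arm_state")
}

#' Passive ligament torque
#'
#' Double-sided exponential restoring torque
#' `lig_k (exp(lig_c (rom_min - theta)) - exp(lig_c (theta - rom_max)))`:
#' negligible mid-range, rising steeply as the angle approaches either
#' range-of-motion limit, positive (flexing) below `rom_min` and negative
#' (extending) above `rom_max`.
#'
#' @param theta flexion angle (rad); vectorized.
#' @param p an [arm_params()].
#' @return Ligament torque (N m).
#' @export
ligament_torque <- function(theta, p) {
  check_num(theta, "theta")
  p$lig_k * (exp(p$lig_c * (p$rom_min - theta)) -
               exp(p$lig_c * (theta - p$rom_max)))
}

#' Passive damping torque
#'
#' Linear viscous torque `-damping_b * omega`. Its purpose is behavioral:
#' without it the frictionless arm would be very hard to stop on a spatial
#' target.
#'
#' @param omega angular velocity (rad/s); vectorized.
#' @param p an [arm_params()].
#' @return Damping torque (N m).
#' @export
damping_torque <- function(omega, p) {
  check_num(omega, "omega")
  -p$damping_b * omega
}

# packed-vector layout used by the integrator
.STATE_NAMES <- c("theta", "omega", "a_f", "l_ce_f", "a_e", "l_ce_e")

.pack_state <- function(s) {
  c(s$theta, s$omega, s$flexor$a, s$flexor$l_ce, s$extensor$a,
    s$extensor$l_ce)
}

.unpack_state <- function(y) {
  structure(
    list(theta = y[1], omega = y[2],
         flexor = structure(list(a = y[3], l_ce = y[4]),
                            class = "muscle_state"),
         extensor = structure(list(a = y[5], l_ce = y[6]),
                              class = "muscle_state")),
    class = "arm_state"
  )
}

.deriv_vec <- function(y, u, model) {
  st_f <- list(a = y[3], l_ce = y[4])
  st_e <- list(a = y[5], l_ce = y[6])
  theta <- y[1]
  omega <- y[2]
  t_act <- control_to_joint_torque(u, theta,
                                   states = list(flexor = st_f,
                                                 extensor = st_e),
                                   cfg = model$actuation,
                                   geoms = model$geometry,
                                   params = model$muscles)
  t_net <- t_act + ligament_torque(theta, model$arm) +
    damping_torque(omega, model$arm)
  d <- c(omega, t_net / model$arm$inertia, 0, 0, 0, 0)
  if (model$actuation$mode == "muscle") {
    pf <- model$muscles$flexor
    pe <- model$muscles$extensor
    v_f <- ce_velocity_from_equilibrium(
      st_f, muscle_tendon_length(theta, model$geometry$flexor), pf)
    v_e <- ce_velocity_from_equilibrium(
      st_e, muscle_tendon_length(theta, model$geometry$extensor), pe)
    d[3] <- .act_rate(u$u_f, y[3], pf)
    d[4] <- -v_f * pf$l_ce_opt
    d[5] <- .act_rate(u$u_e, y[5], pe)
    d[6] <- -v_e * pe$l_ce_opt
  }
  d
}

#' Time derivative of the full arm state
#'
#' Newton--Euler on the single hinge: `dtheta/dt = omega`,
#' `domega/dt = (T_active + T_ligament + T_damping) / inertia`, with the
#' active torque from [control_to_joint_torque()]. In muscle mode the muscle
#' substates evolve by first-order activation dynamics and the CE velocity
#' from the series force equilibrium; in torque/force mode they are frozen.
#'
#' @param s an [arm_state()].
#' @param u a [control_sample()].
#' @param model a [run_config()]-style model bundle.
#' @return A list of rates with the same shape as `s` (class
#'   `arm_state_rate`): `theta` (rad/s), `omega` (rad/s^2), and per-muscle
#'   `a` (1/s) and `l_ce` (m/s) rates.
#' @export
state_derivative <- function(s, u, model) {
  d <- .deriv_vec(.pack_state(s), u, model)
  structure(
    list(theta = d[1], omega = d[2],
         flexor = list(a = d[3], l_ce = d[4]),
         extensor = list(a = d[5], l_ce = d[6])),
    class = "arm_state_rate"
  )
}

#' One classical fourth-order Runge--Kutta step
#'
#' Advances the full coupled state by `dt` with the control sample held
#' constant across the step (zero-order hold, matching a fixed-step
#' interaction loop). Activations are clamped into `[a_min, 1]` after the
#' update.
#'
#' @inheritParams state_derivative
#' @param dt step size (s).
#' @return The updated [arm_state()].
#' @export
rk4_step <- function(s, u, dt, model) {
  check_num(dt, "dt", 0, closed_lower = FALSE, len = 1)
  y <- .pack_state(s)
  k1 <- .deriv_vec(y, u, model)
  k2 <- .deriv_vec(y + dt / 2 * k1, u, model)
  k3 <- .deriv_vec(y + dt / 2 * k2, u, model)
  k4 <- .deriv_vec(y + dt * k3, u, model)
  y_new <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  y_new[3] <- min(max(y_new[3], model$muscles$flexor$a_min), 1)
  y_new[5] <- min(max(y_new[5], model$muscles$extensor$a_min), 1)
  if (any(!is.finite(y_new))) {
    stop_numeric(sprintf(
      "non-finite state after RK4 step: %s",
      paste(.STATE_NAMES[!is.finite(y_new)], collapse = ", ")))
  }
  .unpack_state(y_new)
}
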
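#' Hill-type muscle parameters
#'
#' Constants for a two-element Hill-type muscle: a contractile element (CE)
#' whose force scales with activation, length and velocity, in series with a
#' nonlinear elastic element (SEE) that is compliant at low force and
#' stiffens exponentially with strain. There is no parallel elastic element.
#'
#' @param f_max maximum isometric CE force (N).
#' @param l_ce_opt optimal CE length (m), the peak of the force--length curve.
#' @param w force--length width (dimensionless Gaussian width).
#' @param v_max maximum shortening velocity, in units of `l_ce_opt`/s.
#' @param a_f force--velocity curvature of the Hill hyperbola (dimensionless).
#' @param fv_ecc_max eccentric force ceiling (dimensionless, > 1).
#' @param l_slack SEE slack length (m); the tendon is force-free below it.
#' @param c1,c2 SEE exponential shape constants (dimensionless).
#' @param tau_act,tau_deact activation / deactivation time constants (s).
#' @param a_min activation floor (dimensionless, keeps the CE-velocity
#'   equilibrium solve non-singular at zero excitation).
#' @return An object of class `muscle_params`.
#' @export
muscle_params <- function(f_max = 1000, l_ce_opt = 0.12, w = 0.45,
                          v_max = 10, a_f = 0.25, fv_ecc_max = 1.5,
                          l_slack = 0.032, c1 = 0.02, c2 = 30,
                          tau_act = 0.015, tau_deact = 0.05, a_min = 0.01) {
  check_num(f_max, "f_max", 0, closed_lower = FALSE, len = 1)
  check_num(l_ce_opt, "l_ce_opt", 0, closed_lower = FALSE, len = 1)
  check_num(w, "w", 0, closed_lower = FALSE, len = 1)
  check_num(v_max, "v_max", 0, closed_lower = FALSE, len = 1)
  check_num(a_f, "a_f", 0, closed_lower = FALSE, len = 1)
  check_num(fv_ecc_max, "fv_ecc_max", 1, closed_lower = FALSE, len = 1)
  check_num(l_slack, "l_slack", 0, closed_lower = FALSE, len = 1)
  check_num(c1, "c1", 0, closed_lower = FALSE, len = 1)
  check_num(c2, "c2", 0, closed_lower = FALSE, len = 1)
  check_num(tau_act, "tau_act", 0, closed_lower = FALSE, len = 1)
  check_num(tau_deact, "tau_deact", 0, closed_lower = FALSE, len = 1)
  if (tau_act > tau_deact) {
    stop_validation("`tau_act` must not exceed `tau_deact`")
  }
  check_num(a_min, "a_min", 0, 0.1, closed_lower = FALSE,
            closed_upper = FALSE, len = 1)
  structure(
    list(f_max = f_max, l_ce_opt = l_ce_opt, w = w, v_max = v_max,
         a_f = a_f, fv_ecc_max = fv_ecc_max, l_slack = l_slack,
         c1 = c1, c2 = c2, tau_act = tau_act, tau_deact = tau_deact,
         a_min = a_min),
    class = "muscle_params"
  )
}

#' Muscle state
#'
#' Internal state of one Hill-type muscle: activation `a` (the low-pass
#' filtered neural drive scaling CE force) and the contractile-element
#' length `l_ce` (m). The SEE length follows as the muscle--tendon length
#' minus `l_ce`.
#'
#' @param a activation, in `[a_min, 1]`.
#' @param l_ce contractile-element length (m), positive.
#' @param p optional [muscle_params()] used to validate the activation floor.
#' @return An object of class `muscle_state`.
#' @export
muscle_state <- function(a, l_ce, p = NULL) {
  a_lo <- if (is.null(p)) 0 else p$a_min
  check_num(a, "a", a_lo, 1, len = 1)
  check_num(l_ce, "l_ce", 0, closed_lower = FALSE, len = 1)
  structure(list(a = a, l_ce = l_ce), class = "muscle_state")
}

# lenient internals used by the integrator (RK4 stage states may wander a
# hair outside the invariant box; the exported wrappers validate strictly)
.act_rate <- function(u, a, p) {
  u_eff <- max(u, p$a_min)
  a <- min(max(a, p$a_min), 1)
  tau <- if (u_eff > a) p$tau_act else p$tau_deact
  (u_eff - a) / tau
}

.fl_raw <- function(l_ce, p) {
  exp(-((l_ce / p$l_ce_opt - 1) / p$w)^2)
}

.see_force_safe <- function(l_se, p) {
  eps <- (l_se - p$l_slack) / p$l_slack
  ifelse(l_se <= p$l_slack, 0, p$f_max * p$c1 * expm1(p$c2 * pmax(eps, 0)))
}

#' First-order activation dynamics
#'
#' Rate of change of activation toward the excitation, with an asymmetric
#' time constant: `tau_act` when drive rises, `tau_deact` when it falls.
#' Excitation is floored at `a_min` so activation never decays below the
#' floor.
#'
#' @param u excitation in `[0, 1]`.
#' @param a current activation in `[a_min, 1]`.
#' @param p a [muscle_params()].
#' @return da/dt (1/s).
#' @export
activation_derivative <- function(u, a, p) {
  check_num(u, "u", 0, 1, len = 1)
  check_num(a, "a", p$a_min, 1, len = 1)
  .act_rate(u, a, p)
}

#' Active force--length scaling
#'
#' Gaussian force--length relationship
#' `exp(-((l_ce/l_ce_opt - 1)/w)^2)`: unity at the optimal length,
#' symmetric about it, width set by `w`.
#'
#' @param l_ce contractile-element length (m), positive; vectorized.
#' @param p a [muscle_params()].
#' @return Force scale factor in `(0, 1]`.
#' @export
force_length <- function(l_ce, p) {
  check_num(l_ce, "l_ce", 0, closed_lower = FALSE)
  .fl_raw(l_ce, p)
}

#' Force--velocity scaling
#'
#' Hill hyperbola on the concentric side (shortening-positive `v_ce`):
#' `(1 - v/v_max) / (1 + v/(v_max a_f))`, clamped to 0 for `v >= v_max`.
#' On the eccentric side an exponential branch
#' `fv_ecc_max - (fv_ecc_max - 1) exp(k v)` rises asymptotically to
#' `fv_ecc_max`, with `k` chosen so value and slope are continuous at
#' `v_ce = 0`. The whole curve is strictly decreasing in `v_ce` up to
#' `v_max`.
#'
#' @param v_ce CE velocity in `l_ce_opt`/s, shortening-positive; vectorized.
#' @param p a [muscle_params()].
#' @return Force scale factor in `[0, fv_ecc_max)`.
#' @export
force_velocity <- function(v_ce, p) {
  check_num(v_ce, "v_ce")
  x <- v_ce / p$v_max
  conc <- ifelse(x >= 1, 0, (1 - x) / (1 + x / p$a_f))
  k <- .fv_ecc_k(p)
  ecc <- p$fv_ecc_max - (p$fv_ecc_max - 1) * exp(k * v_ce)
  ifelse(v_ce >= 0, conc, ecc)
}

# eccentric rate constant matching the concentric slope at v = 0
.fv_ecc_k <- function(p) {
  s0 <- (1 + p$a_f) / (p$a_f * p$v_max)
  s0 / (p$fv_ecc_max - 1)
}

#' Closed-form inverse of the force--velocity curve
#'
#' Maps a required force--velocity scale factor back to the CE velocity that
#' produces it. Defined on `[0, fv_ecc_max)`; both branches invert in closed
#' form (the Hill hyperbola algebraically, the eccentric exponential by a
#' logarithm).
#'
#' @param fv force scale factor in `[0, fv_ecc_max)`; vectorized.
#' @param p a [muscle_params()].
#' @return CE velocity (`l_ce_opt`/s, shortening-positive).
#' @export
force_velocity_inverse <- function(fv, p) {
  check_num(fv, "fv", 0, p$fv_ecc_max, closed_upper = FALSE)
  k <- .fv_ecc_k(p)
  conc <- p$v_max * p$a_f * (1 - fv) / (p$a_f + fv)
  ecc <- log((p$fv_ecc_max - fv) / (p$fv_ecc_max - 1)) / k
  ifelse(fv <= 1, conc, ecc)
}

#' Series-elastic (tendon) force
#'
#' Exponential force--strain law: zero at or below the slack length, then
#' `f_max c1 (exp(c2 eps) - 1)` with strain `eps = (l_se - l_slack)/l_slack`.
#' Compliant at low force, stiffening with load; continuous at slack.
#'
#' @param l_se SEE length (m), positive; vectorized.
#' @param p a [muscle_params()].
#' @return Tendon force (N, non-negative).
#' @export
see_force <- function(l_se, p) {
  check_num(l_se, "l_se", 0, closed_lower = FALSE)
  .see_force_safe(l_se, p)
}

#' CE velocity from the series force equilibrium
#'
#' In a two-element muscle the CE and SEE carry the same force, so the CE
#' velocity is whatever makes the force--velocity scaling equal the ratio of
#' the current tendon force to the activation- and length-scaled maximal
#' force. The required scale is clamped into `[0, fv_ecc_max - 1e-6]` and
#' the activation and force--length factors are floored, making the solve
#' total and non-singular.
#'
#' @param s a [muscle_state()].
#' @param l_mt muscle--tendon length (m), positive.
#' @param p a [muscle_params()].
#' @return CE velocity (`l_ce_opt`/s, shortening-positive).
#' @export
ce_velocity_from_equilibrium <- function(s, l_mt, p) {
  check_num(l_mt, "l_mt", 0, closed_lower = FALSE, len = 1)
  f_se <- .see_force_safe(l_mt - s$l_ce, p)
  fl <- max(.fl_raw(s$l_ce, p), 1e-6)
  a <- max(s$a, p$a_min)
  fv_req <- f_se / (p$f_max * a * fl)
  fv_req <- min(max(fv_req, 0), p$fv_ecc_max - 1e-6)
  force_velocity_inverse(fv_req, p)
}

#' Force transmitted to the skeleton
#'
#' The skeleton only ever sees the tendon: the transmitted force is the SEE
#' force at the current SEE length `l_mt - l_ce` (zero when slack).
#'
#' @inheritParams ce_velocity_from_equilibrium
#' @return Muscle force (N, non-negative).
#' @export
muscle_force <- function(s, l_mt, p) {
  check_num(l_mt, "l_mt", 0, closed_lower = FALSE, len = 1)
  .see_force_safe(l_mt - s$l_ce, p)
}

#' Initial muscle state at a joint angle
#'
#' Solves the isometric equilibrium for the CE length by bisection on
#' `(0, l_mt)`: the returned state has
#' `|see_force(l_mt - l_ce) - f_max a0 fl(l_ce)| < 1e-8 f_max`.
#'
#' @param theta elbow flexion angle (rad), inside `(0, pi)`.
#' @param a0 initial activation (defaults to the floor `a_min`).
#' @param geom a [path_geometry()] for this muscle.
#' @param p a [muscle_params()].
#' @return A [muscle_state()] at isometric equilibrium.
#' @export
init_muscle_state <- function(theta, a0 = p$a_min, geom, p) {
  check_num(a0, "a0", p$a_min, 1, len = 1)
  l_mt <- muscle_tendon_length(theta, geom)
  f_ce <- function(l) p$f_max * a0 * .fl_raw(l, p)
  g <- function(l) .see_force_safe(l_mt - l, p) - f_ce(l)
  lo <- l_mt * 1e-9
  hi <- l_mt * (1 - 1e-9)
  if (!(g(lo) > 0 && g(hi) < 0)) {
    stop_config(paste0(
      "no isometric equilibrium bracket on (0, l_mt): geometry and muscle ",
      "parameters are inconsistent (is the tendon slack across the whole ",
      "range?)"
    ))
  }
  for (i in 1:200) {
    mid <- 0.5 * (lo + hi)
    gm <- g(mid)
    if (abs(gm) < 1e-9 * p$f_max || (hi - lo) < 1e-16) break
    if (gm > 0) lo <- mid else hi <- mid
  }
  if (abs(g(mid)) >= 1e-8 * p$f_max) {
    stop_config("isometric equilibrium bisection did not converge")
  }
  muscle_state(a0, mid, p)
}

#' Settle a muscle isometrically
#'
#' Holds the muscle--tendon length and excitation fixed and integrates the
#' muscle substate (activation, CE length) with RK4 until the per-step state
#' change falls below `tol` or `t_end` is reached. Useful for verifying that
#' the CE/SEE force balance holds at the fixed point.
#'
#' @param s starting [muscle_state()].
#' @param l_mt fixed muscle--tendon length (m).
#' @param u fixed excitation in `[0, 1]`.
#' @param p a [muscle_params()].
#' @param dt integration step (s).
#' @param t_end maximum settling time (s).
#' @param tol per-step state-change norm below which settling stops.
#' @return The settled [muscle_state()].
#' @export
settle_isometric <- function(s, l_mt, u, p, dt = 1/1000, t_end = 5,
                             tol = 1e-12) {
  check_num(u, "u", 0, 1, len = 1)
  y <- c(s$a, s$l_ce)
  f <- function(y) {
    st <- list(a = y[1], l_ce = y[2])
    c(.act_rate(u, y[1], p),
      -ce_velocity_from_equilibrium(st, l_mt, p) * p$l_ce_opt)
  }
  n <- ceiling(t_end / dt)
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y_new <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    y_new[1] <- min(max(y_new[1], p$a_min), 1)
    if (sqrt(sum((y_new - y)^2)) < tol) {
      y <- y_new
      break
    }
    y <- y_new
  }
  muscle_state(y[1], y[2], p)
}
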
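#' Straight-line actuator path geometry
#'
#' Each actuator runs in a straight line from an origin on the (fixed) upper
#' arm to an insertion near the elbow. `d_origin` is the elbow-to-origin
#' distance along the upper arm and `d_insert` the elbow-to-insertion
#' distance along the forearm; for the extensor the insertion sits on the
#' posterior extension of the forearm (olecranon-like), which mirrors the
#' elbow triangle and keeps the moment arm positive throughout flexion.
#'
#' @param d_origin elbow-to-origin distance (m).
#' @param d_insert elbow-to-insertion distance (m); must be smaller than
#'   `d_origin` (origins are proximal on the upper arm, insertions near the
#'   elbow).
#' @param side `"flexor"` or `"extensor"`.
#' @return An object of class `path_geometry`.
#' @export
path_geometry <- function(d_origin, d_insert, side = c("flexor", "extensor")) {
  side <- match.arg(side)
  check_num(d_origin, "d_origin", 0, closed_lower = FALSE, len = 1)
  check_num(d_insert, "d_insert", 0, closed_lower = FALSE, len = 1)
  if (d_origin <= d_insert) {
    stop_validation("`d_origin` must exceed `d_insert`")
  }
  structure(list(d_origin = d_origin, d_insert = d_insert, side = side),
            class = "path_geometry")
}

.check_theta <- function(theta) {
  if (!is.numeric(theta) || anyNA(theta) || any(!is.finite(theta)) ||
      any(theta <= 0) || any(theta >= pi)) {
    stop_validation("`theta` must lie strictly inside (0, pi) rad")
  }
  theta
}

#' Muscle--tendon length from the elbow triangle
#'
#' Law of cosines on the triangle (origin, elbow, insertion). With the
#' flexion angle `theta` (0 = full extension) the flexor path
#' `sqrt(d_o^2 + d_i^2 + 2 d_o d_i cos(theta))` shortens with flexion; the
#' mirrored extensor path uses `-cos(theta)` and lengthens with flexion.
#'
#' @param theta flexion angle (rad) in `(0, pi)`; vectorized.
#' @param g a [path_geometry()].
#' @return Muscle--tendon length (m).
#' @export
muscle_tendon_length <- function(theta, g) {
  .check_theta(theta)
  sgn <- if (g$side == "flexor") 1 else -1
  sqrt(g$d_origin^2 + g$d_insert^2 +
         sgn * 2 * g$d_origin * g$d_insert * cos(theta))
}

#' Moment arm of a straight-line actuator
#'
#' `d_o d_i sin(theta) / l_mt(theta)`, the magnitude of the derivative of
#' the muscle--tendon length with respect to the joint angle (tendon
#' excursion). Vanishes at full extension and full flexion, where the path
#' passes through the hinge.
#'
#' @inheritParams muscle_tendon_length
#' @return Moment arm (m, non-negative).
#' @export
moment_arm <- function(theta, g) {
  .check_theta(theta)
  g$d_origin * g$d_insert * sin(theta) / muscle_tendon_length(theta, g)
}

#' Actuation mode configuration
#'
#' The model supports three actuation modes. `torque`: control signals map
#' directly to joint torques scaled by `t_max`. `force`: control signals map
#' to actuator forces scaled by `f_gen_max`, then through the moment arms.
#' `muscle`: Hill-type muscle models transmit their tendon force through the
#' same moment arms.
#'
#' @param mode `"muscle"`, `"force"` or `"torque"`.
#' @param t_max maximum generator torque per direction (N m, torque mode).
#' @param f_gen_max maximum generator force per actuator (N, force mode).
#' @return An object of class `actuation_config`.
#' @export
actuation_config <- function(mode = c("muscle", "force", "torque"),
                             t_max = 5, f_gen_max = 250) {
  mode <- match.arg(mode)
  check_num(t_max, "t_max", 0, closed_lower = FALSE, len = 1)
  check_num(f_gen_max, "f_gen_max", 0, closed_lower = FALSE, len = 1)
  structure(list(mode = mode, t_max = t_max, f_gen_max = f_gen_max),
            class = "actuation_config")
}

#' Net active joint torque from the control sample
#'
#' Maps the flexor/extensor excitations to a net elbow torque
#' (flexion-positive) under the configured actuation mode. In muscle mode
#' the transmitted forces come from the muscles' series-elastic elements, so
#' `states` must carry a valid [muscle_state()] per side.
#'
#' @param u a [control_sample()] or list with `u_f`, `u_e`.
#' @param theta flexion angle (rad).
#' @param states list with `flexor`/`extensor` [muscle_state()]s (muscle
#'   mode only; ignored otherwise).
#' @param cfg an [actuation_config()].
#' @param geoms list with `flexor`/`extensor` [path_geometry()]s.
#' @param params list with `flexor`/`extensor` [muscle_params()]s.
#' @return Net active torque (N m, flexion-positive).
#' @export
control_to_joint_torque <- function(u, theta, states = NULL, cfg, geoms,
                                    params = NULL) {
  switch(cfg$mode,
    torque = (u$u_f - u$u_e) * cfg$t_max,
    force = {
      u$u_f * cfg$f_gen_max * moment_arm(theta, geoms$flexor) -
        u$u_e * cfg$f_gen_max * moment_arm(theta, geoms$extensor)
    },
    muscle = {
      if (is.null(states) || is.null(states$flexor) ||
          is.null(states$extensor)) {
        stop_config("muscle mode requires flexor and extensor muscle states")
      }
      f_f <- .see_force_safe(
        muscle_tendon_length(theta, geoms$flexor) - states$flexor$l_ce,
        params$flexor)
      f_e <- .see_force_safe(
        muscle_tendon_length(theta, geoms$extensor) - states$extensor$l_ce,
        params$extensor)
      f_f * moment_arm(theta, geoms$flexor) -
        f_e * moment_arm(theta, geoms$extensor)
    }
  )
}
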
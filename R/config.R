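#' Assemble a run configuration
#'
#' Bundles every model component into the single object the simulation
#' functions consume. Cross-invariants are checked: the start and target
#' angles must lie inside the range of motion and the muscles must have a
#' solvable rest equilibrium at the start angle.
#'
#' @param arm an [arm_params()].
#' @param muscles list with `flexor`/`extensor` [muscle_params()]s.
#' @param geometry list with `flexor`/`extensor` [path_geometry()]s.
#' @param actuation an [actuation_config()].
#' @param sim a [sim_config()].
#' @param task a [task_params()].
#' @param emg an [emg_chain_params()].
#' @param seed integer seed for any stochastic component (EMG synthesis).
#' @return An object of class `run_config`.
#' @export
run_config <- function(arm, muscles, geometry, actuation, sim, task, emg,
                       seed = 1L) {
  cfg <- structure(
    list(arm = arm, muscles = muscles, geometry = geometry,
         actuation = actuation, sim = sim, task = task, emg = emg,
         seed = as.integer(seed)),
    class = "run_config"
  )
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration's cross-invariants
#'
#' @param cfg a [run_config()].
#' @return `cfg`, invisibly; signals a configuration error otherwise.
#' @export
validate_run_config <- function(cfg) {
  tp <- cfg$task
  rom <- c(cfg$arm$rom_min, cfg$arm$rom_max) * 180 / pi
  for (ang in c(start = tp$theta_start,
                target = tp$theta_start + tp$delta_target)) {
    if (ang < rom[1] || ang > rom[2]) {
      stop_config(sprintf(
        "task angle %.1f deg lies outside the range of motion [%.1f, %.1f]",
        ang, rom[1], rom[2]))
    }
  }
  # rest equilibrium must be solvable at the start angle (errors propagate)
  initial_arm_state(cfg)
  invisible(cfg)
}

#' Default run configuration
#'
#' The standard planar elbow: flexion task from 90 deg to a target 45 deg
#' away (flexion), success within +/- 2 deg at under 0.001 deg/s, 5 s
#' limit, integrated at 1/150 s.
#'
#' The default actuators are constructed so the task is mechanically
#' well-posed under the activation floor. With both activations at the
#' floor, the residual muscle forces are a few newtons, so the passive
#' torque field they create decides where the arm can rest. Two conditions
#' pin the free constants: (1) at the start angle (90 deg) the flexor and
#' extensor rest torques cancel exactly -- the extensor insertion distance
#' is solved for this in closed form -- so a trial started with zero
#' excitation holds still; and (2) at the target angle (135 deg) they
#' cancel again -- the extensor's resting contractile-element stretch is
#' solved for this. The target equilibrium is a gentle saddle (residual
#' stiffness of order 0.01 N m/rad), so an arm braked to a turnaround
#' close to the target satisfies the strict velocity criterion over many
#' consecutive samples before drifting away; this is what makes the
#' goal-directed task's stop criterion attainable under on-off control.
#' Each tendon slack length is solved so the CE takes its prescribed
#' resting length with the tendon just taut.
#'
#' @param mode actuation mode (`"muscle"`, `"force"` or `"torque"`).
#' @param seed integer seed.
#' @return A [run_config()].
#' @export
default_run_config <- function(mode = "muscle", seed = 1L) {
  task <- task_params()
  arm <- arm_params()
  th0 <- task$theta_start * pi / 180
  th1 <- (task$theta_start + task$delta_target) * pi / 180

  base <- list(f_max = 1000, l_ce_opt = 0.12, w = 0.45, v_max = 10,
               a_f = 0.25, fv_ecc_max = 1.5, c1 = 0.02, c2 = 30,
               tau_act = 0.015, tau_deact = 0.05, a_min = 0.01,
               l_slack = 1)
  d_o <- 0.2
  g_f <- path_geometry(d_o, 0.03, "flexor")
  rest_stretch_f <- 1.005

  # slack length putting the CE at `stretch * l_ce_opt` at rest at th0
  slack_for <- function(p, l_mt, stretch) {
    f0 <- p$f_max * p$a_min * exp(-((stretch - 1) / p$w)^2)
    strain <- log(f0 / (p$f_max * p$c1) + 1) / p$c2
    (l_mt - stretch * p$l_ce_opt) / (1 + strain)
  }

  build <- function(stretch_e) {
    p_f <- base
    p_e <- base
    p_e$f_max <- 800
    l_mt_f <- muscle_tendon_length(th0, g_f)
    p_f$l_slack <- slack_for(p_f, l_mt_f, rest_stretch_f)
    # extensor insertion solved so rest torques cancel at the start angle:
    # r = d_o q sin(th0)/sqrt(d_o^2 + q^2 - 2 d_o q cos(th0)); at 90 deg
    # the cross term drops and q solves in closed form
    f_f0 <- p_f$f_max * p_f$a_min * exp(-((rest_stretch_f - 1) / p_f$w)^2)
    f_e0 <- p_e$f_max * p_e$a_min * exp(-((stretch_e - 1) / p_e$w)^2)
    r_f0 <- moment_arm(th0, g_f)
    r_e0 <- f_f0 * r_f0 / f_e0
    stopifnot(abs(cos(th0)) < 1e-12)
    q <- r_e0 * d_o / sqrt((d_o * sin(th0))^2 - r_e0^2)
    g_e <- path_geometry(d_o, q, "extensor")
    p_e$l_slack <- slack_for(p_e, muscle_tendon_length(th0, g_e), stretch_e)
    list(muscles = list(flexor = do.call(muscle_params, p_f),
                        extensor = do.call(muscle_params, p_e)),
         geometry = list(flexor = g_f, extensor = g_e))
  }

  # net rest torque at the target angle, as a function of the extensor's
  # resting CE stretch
  rest_torque_at_target <- function(stretch_e) {
    b <- build(stretch_e)
    s_f <- init_muscle_state(th1, b$muscles$flexor$a_min,
                             b$geometry$flexor, b$muscles$flexor)
    s_e <- init_muscle_state(th1, b$muscles$extensor$a_min,
                             b$geometry$extensor, b$muscles$extensor)
    control_to_joint_torque(list(u_f = 0, u_e = 0), th1,
                            states = list(flexor = s_f, extensor = s_e),
                            cfg = actuation_config("muscle"),
                            geoms = b$geometry, params = b$muscles)
  }
  # scan for a feasible sign-change bracket, then polish with uniroot
  grid <- seq(0.75, 1.0, by = 0.01)
  vals <- vapply(grid, function(s) {
    tryCatch(rest_torque_at_target(s), error = function(e) NA_real_)
  }, numeric(1))
  ok <- which(!is.na(vals))
  flip <- ok[which(diff(sign(vals[ok])) != 0)]
  if (length(flip) == 0) {
    stop_config("default construction failed: no rest equilibrium at the \
target angle")
  }
  i <- flip[length(flip)]
  stretch_e <- stats::uniroot(rest_torque_at_target,
                              c(grid[i], grid[i + 1]), tol = 1e-13)$root
  b <- build(stretch_e)

  run_config(
    arm = arm,
    muscles = b$muscles,
    geometry = b$geometry,
    actuation = actuation_config(mode),
    sim = sim_config(),
    task = task,
    emg = emg_chain_params(noise_seed = seed),
    seed = seed
  )
}

# ---- structured-text (YAML) configuration surface -------------------------
# user-facing angles are degrees; internal representation is radians

.config_to_list <- function(cfg) {
  r2d <- 180 / pi
  list(
    sim = list(dt = cfg$sim$dt, t_limit = cfg$sim$t_limit),
    arm = list(inertia = cfg$arm$inertia, damping_b = cfg$arm$damping_b,
               rom_min = cfg$arm$rom_min * r2d,
               rom_max = cfg$arm$rom_max * r2d,
               lig_k = cfg$arm$lig_k, lig_c = cfg$arm$lig_c,
               upper_len = cfg$arm$upper_len, fore_len = cfg$arm$fore_len),
    geometry = list(
      flexor = list(d_origin = cfg$geometry$flexor$d_origin,
                    d_insert = cfg$geometry$flexor$d_insert),
      extensor = list(d_origin = cfg$geometry$extensor$d_origin,
                      d_insert = cfg$geometry$extensor$d_insert)),
    muscle = list(
      flexor = unclass(cfg$muscles$flexor),
      extensor = unclass(cfg$muscles$extensor)),
    actuation = list(mode = cfg$actuation$mode, t_max = cfg$actuation$t_max,
                     f_gen_max = cfg$actuation$f_gen_max),
    task = unclass(cfg$task),
    emg = unclass(cfg$emg),
    seed = cfg$seed
  )
}

.merge_keys <- function(base, override, path = "") {
  for (key in names(override)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      warning(sprintf("unknown configuration key `%s` (ignored)", here),
              call. = FALSE)
      next
    }
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- .merge_keys(base[[key]], override[[key]], here)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

.config_from_list <- function(lst) {
  d2r <- pi / 180
  arm <- arm_params(inertia = lst$arm$inertia,
                    damping_b = lst$arm$damping_b,
                    rom_min = lst$arm$rom_min * d2r,
                    rom_max = lst$arm$rom_max * d2r,
                    lig_k = lst$arm$lig_k, lig_c = lst$arm$lig_c,
                    upper_len = lst$arm$upper_len,
                    fore_len = lst$arm$fore_len)
  mk_muscle <- function(m) do.call(muscle_params, m)
  mk_geom <- function(g, side) path_geometry(g$d_origin, g$d_insert, side)
  run_config(
    arm = arm,
    muscles = list(flexor = mk_muscle(lst$muscle$flexor),
                   extensor = mk_muscle(lst$muscle$extensor)),
    geometry = list(flexor = mk_geom(lst$geometry$flexor, "flexor"),
                    extensor = mk_geom(lst$geometry$extensor, "extensor")),
    actuation = actuation_config(lst$actuation$mode,
                                 t_max = lst$actuation$t_max,
                                 f_gen_max = lst$actuation$f_gen_max),
    sim = sim_config(dt = lst$sim$dt, t_limit = lst$sim$t_limit),
    task = do.call(task_params, lst$task),
    emg = do.call(emg_chain_params, lst$emg),
    seed = lst$seed
  )
}

#' Load a run configuration from a YAML file
#'
#' Missing keys fall back to the defaults of [default_run_config()]; an
#' empty file yields the all-defaults configuration. Unknown keys warn with
#' their key path; violated invariants error. Angles in the file are in
#' degrees (`arm.rom_min`, `arm.rom_max`, the whole `task` block) and are
#' converted to radians internally.
#'
#' @param path path to a YAML configuration file.
#' @return A validated [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("no such config file: %s", path))
  user <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_config(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
  })
  base <- .config_to_list(default_run_config())
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop_config("configuration must be a YAML mapping")
  merged <- .merge_keys(base, user)
  .config_from_list(merged)
}

#' Write a run configuration to a YAML file
#'
#' Inverse of [load_config()]: the written file parses back to an
#' equivalent configuration (angles on the degree scale).
#'
#' @param cfg a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(.config_to_list(cfg), path, precision = 15)
  invisible(path)
}
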
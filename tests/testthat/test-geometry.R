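test_that("muscle-tendon length follows the elbow-triangle law of cosines", {
  g_f <- ref_geometry("flexor")
  g_e <- path_geometry(0.15, 0.03, "extensor")
  # hand computation: sqrt(0.15^2 + 0.03^2 + 0) at 90 deg
  expect_equal(muscle_tendon_length(pi / 2, g_f), sqrt(0.0234),
               tolerance = 1e-12)
  expect_equal(muscle_tendon_length(pi / 2, g_f),
               muscle_tendon_length(pi / 2, g_e))
  th <- seq(1e-3, pi - 1e-3, length.out = 1000)
  expect_true(all(diff(muscle_tendon_length(th, g_f)) < 0))
  expect_true(all(diff(muscle_tendon_length(th, g_e)) > 0))
  expect_error(muscle_tendon_length(0, g_f),
               class = "elbowsim_validation_error")
  expect_error(muscle_tendon_length(pi, g_f),
               class = "elbowsim_validation_error")
})

test_that("moment arm matches the tendon-excursion derivative", {
  # worked value at 90 deg: 0.15*0.03/sqrt(0.0234)
  g <- ref_geometry("flexor")
  expect_equal(moment_arm(pi / 2, g), 0.0045 / sqrt(0.0234),
               tolerance = 1e-12)
  # vanishes toward the singular poses
  expect_lt(moment_arm(1e-6, g), 1e-6)
  expect_lt(moment_arm(pi - 1e-6, g), 1e-6)
  # central-difference oracle on 1000 angles, both muscles, both the
  # reference and the constructed default geometry
  m <- default_model()
  geoms <- list(ref_geometry("flexor"), path_geometry(0.15, 0.025, "extensor"),
                m$geometry$flexor, m$geometry$extensor)
  th <- seq(0.05, pi - 0.05, length.out = 1000)
  h <- 1e-6
  for (g in geoms) {
    dl <- (muscle_tendon_length(th + h, g) -
             muscle_tendon_length(th - h, g)) / (2 * h)
    rel <- abs(moment_arm(th, g) - abs(dl)) / moment_arm(th, g)
    expect_lt(max(rel), 1e-6)
    # sign convention: flexors shorten, extensors lengthen with flexion
    expect_true(all(if (g$side == "flexor") dl < 0 else dl > 0))
  }
})

test_that("control maps to joint torque correctly in all three modes", {
  m <- default_model()
  cfg_t <- actuation_config("torque", t_max = 5)
  cfg_f <- actuation_config("force", f_gen_max = 1000)
  geoms <- list(flexor = ref_geometry("flexor"),
                extensor = path_geometry(0.15, 0.025, "extensor"))
  # symmetric cancellation in torque mode
  expect_equal(control_to_joint_torque(list(u_f = 0.5, u_e = 0.5), pi / 2,
                                       cfg = cfg_t, geoms = geoms), 0)
  # force mode worked example: 1000 N times the flexor moment arm
  expect_equal(
    control_to_joint_torque(list(u_f = 1, u_e = 0), pi / 2,
                            cfg = cfg_f, geoms = geoms),
    1000 * 0.0045 / sqrt(0.0234), tolerance = 1e-10)
  # muscle mode with slack tendons transmits nothing
  p <- ref_muscle()
  slack_states <- list(flexor = muscle_state(0.5, 0.2, p),
                       extensor = muscle_state(0.5, 0.2, p))
  expect_equal(
    control_to_joint_torque(list(u_f = 1, u_e = 1), pi / 2,
                            states = slack_states,
                            cfg = actuation_config("muscle"),
                            geoms = geoms,
                            params = list(flexor = p, extensor = p)),
    0)
  expect_error(
    control_to_joint_torque(list(u_f = 1, u_e = 0), pi / 2,
                            cfg = actuation_config("muscle"),
                            geoms = geoms),
    class = "elbowsim_config_error")
  # one-sided drive has the right torque sign everywhere, all modes (in
  # muscle mode the drive lives in the activation state)
  for (mode in c("torque", "force", "muscle")) {
    mm <- default_model(mode)
    for (th in seq(0.4, 2.6, length.out = 7)) {
      one_sided <- function(active) {
        a <- function(side) if (side == active) 0.9 else
          mm$muscles[[side]]$a_min
        states <- list(
          flexor = init_muscle_state(th, a("flexor"), mm$geometry$flexor,
                                     mm$muscles$flexor),
          extensor = init_muscle_state(th, a("extensor"),
                                       mm$geometry$extensor,
                                       mm$muscles$extensor))
        u <- list(u_f = as.numeric(active == "flexor"),
                  u_e = as.numeric(active == "extensor"))
        control_to_joint_torque(u, th, states, mm$actuation, mm$geometry,
                                mm$muscles)
      }
      expect_gt(one_sided("flexor"), 0)
      expect_lt(one_sided("extensor"), 0)
    }
  }
})

test_that("muscle mode degenerates to the force-generator mapping", {
  # rigid tendon, flat force-length, fv ~ 1, activation = excitation,
  # vanishing activation floor
  p_deg <- muscle_params(f_max = 1000, w = 1000, v_max = 1e6,
                         l_slack = 0.02, c1 = 0.02, c2 = 2000,
                         a_min = 1e-6)
  geoms <- list(flexor = ref_geometry("flexor"),
                extensor = path_geometry(0.15, 0.025, "extensor"))
  params <- list(flexor = p_deg, extensor = p_deg)
  cfg_m <- actuation_config("muscle")
  cfg_f <- actuation_config("force", f_gen_max = p_deg$f_max)
  for (u in c(0.2, 0.5, 0.8, 1)) {
    for (th in seq(0.6, 2.4, length.out = 7)) {
      states <- list(
        flexor = init_muscle_state(th, u, geoms$flexor, p_deg),
        extensor = init_muscle_state(th, p_deg$a_min, geoms$extensor,
                                     p_deg))
      tq_m <- control_to_joint_torque(list(u_f = u, u_e = 0), th, states,
                                      cfg_m, geoms, params)
      tq_f <- control_to_joint_torque(list(u_f = u, u_e = 0), th,
                                      cfg = cfg_f, geoms = geoms)
      expect_lt(abs(tq_m - tq_f) / abs(tq_f), 0.01)
    }
  }
})

test_that("path geometry invariants are enforced", {
  expect_error(path_geometry(0.03, 0.15, "flexor"),
               class = "elbowsim_validation_error")
  expect_error(path_geometry(-0.1, 0.03, "flexor"),
               class = "elbowsim_validation_error")
  expect_error(actuation_config("torque", t_max = 0),
               class = "elbowsim_validation_error")
})
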
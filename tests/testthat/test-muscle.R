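test_that("activation dynamics have the right fixed point, rate and bounds", {
  p <- ref_muscle()
  expect_equal(activation_derivative(0.5, 0.5, p), 0)
  expect_equal(activation_derivative(1, p$a_min, p),
               (1 - p$a_min) / p$tau_act)
  # deactivation uses the slower time constant
  expect_equal(activation_derivative(0, 0.8, p),
               (p$a_min - 0.8) / p$tau_deact)
  expect_error(activation_derivative(1.2, 0.5, p),
               class = "elbowsim_validation_error")
  expect_error(activation_derivative(0.5, 0, p),
               class = "elbowsim_validation_error")

  # step response: RK4 on the linear ODE tracks the exponential solution
  # and reaches 95% of the step within five rise time constants
  dt <- 1 / 150
  a <- p$a_min
  f <- function(a) (1 - a) / p$tau_act
  for (k in 1:12) {
    k1 <- f(a); k2 <- f(a + dt / 2 * k1); k3 <- f(a + dt / 2 * k2)
    k4 <- f(a + dt * k3)
    a <- a + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  t_end <- 12 * dt
  expect_gte(t_end, 5 * p$tau_act)
  expect_gte(a, 0.95)
  # RK4 at dt/tau ~ 0.44 tracks the exponential to its own O((dt/tau)^5)
  # per-step error
  expect_equal(a, 1 - (1 - p$a_min) * exp(-t_end / p$tau_act),
               tolerance = 1e-4)
})

test_that("activation stays inside [a_min, 1] under random excitation", {
  m <- default_model()
  set.seed(11)
  for (rep in 1:3) {
    s <- initial_arm_state(m)
    u_seq <- runif(60)
    for (k in 1:120) {
      u <- list(u_f = u_seq[(k - 1) %/% 2 + 1],
                u_e = u_seq[60 - (k - 1) %/% 2])
      s <- rk4_step(s, u, m$sim$dt, m)
      expect_true(s$flexor$a >= m$muscles$flexor$a_min - 1e-12)
      expect_true(s$flexor$a <= 1 + 1e-12)
      expect_true(s$extensor$a >= m$muscles$extensor$a_min - 1e-12)
      expect_true(s$extensor$a <= 1 + 1e-12)
    }
  }
})

test_that("force-length curve peaks at the optimum and is symmetric", {
  p <- ref_muscle()
  expect_equal(force_length(p$l_ce_opt, p), 1)
  expect_equal(force_length(p$l_ce_opt * (1 + p$w), p), exp(-1))
  x <- seq(0.05, 0.6, length.out = 25)
  expect_equal(force_length(p$l_ce_opt * (1 + x), p),
               force_length(p$l_ce_opt * (1 - x), p))
  expect_error(force_length(0, p), class = "elbowsim_validation_error")
})

test_that("force-velocity curve is anchored, smooth at zero and monotone", {
  p <- ref_muscle()
  expect_equal(force_velocity(0, p), 1)
  expect_equal(force_velocity(p$v_max, p), 0)
  expect_equal(force_velocity(1e9, p), 0)
  # eccentric branch stays below its asymptote
  expect_lt(force_velocity(-1e9, p), p$fv_ecc_max + 1e-12)
  # strict monotone decrease on a 1000-point grid
  v <- seq(-p$v_max, p$v_max, length.out = 1000)
  expect_true(all(diff(force_velocity(v, p)) < 0))
  # slope continuity at v = 0 (central vs one-sided differences)
  h <- 1e-7
  s_conc <- (force_velocity(h, p) - 1) / h
  s_ecc <- (1 - force_velocity(-h, p)) / h
  expect_equal(s_conc, s_ecc, tolerance = 1e-5)
})

test_that("series-elastic force is zero when slack, continuous and convex", {
  p <- ref_muscle()
  expect_equal(see_force(p$l_slack, p), 0)
  expect_equal(see_force(0.9 * p$l_slack, p), 0)
  expect_error(see_force(-0.01, p), class = "elbowsim_validation_error")
  # continuity at the slack length
  expect_lt(see_force(p$l_slack * (1 + 1e-10), p), 1e-6 * p$f_max)
  # stiffening: finite-difference slope grows with strain
  slope_at <- function(eps) {
    h <- 1e-7
    l <- p$l_slack * (1 + eps)
    (see_force(l + h, p) - see_force(l - h, p)) / (2 * h)
  }
  expect_gt(slope_at(0.04), slope_at(0.01))
})

test_that("force-velocity inversion round-trips to machine precision", {
  p <- ref_muscle()
  fv <- seq(0, p$fv_ecc_max - 1e-6, length.out = 1e4)
  v <- force_velocity_inverse(fv, p)
  expect_lt(max(abs(force_velocity(v, p) - fv)), 1e-9)
  expect_equal(force_velocity_inverse(0, p), p$v_max)
  expect_equal(force_velocity_inverse(1, p), 0)
  expect_error(force_velocity_inverse(p$fv_ecc_max, p),
               class = "elbowsim_validation_error")
})

test_that("CE velocity solve satisfies the series force equilibrium", {
  p <- ref_muscle()
  g <- ref_geometry()
  # isometric fixed point
  s0 <- init_muscle_state(pi / 2, 0.3, g, p)
  l_mt <- muscle_tendon_length(pi / 2, g)
  expect_equal(ce_velocity_from_equilibrium(s0, l_mt, p), 0,
               tolerance = 1e-6)
  # slack tendon with nonzero activation shortens at v_max
  s_slack <- muscle_state(0.5, l_mt, p)
  expect_equal(ce_velocity_from_equilibrium(s_slack, l_mt, p), p$v_max)
  # round-trip through the analytic inverse on random states
  set.seed(7)
  for (i in 1:200) {
    s <- muscle_state(runif(1, p$a_min, 1),
                      runif(1, 0.5, 1.4) * p$l_ce_opt, p)
    lm <- runif(1, 0.9, 1.1) * l_mt
    fv_req <- see_force(max(lm - s$l_ce, 1e-9), p) /
      (p$f_max * max(s$a, p$a_min) * max(force_length(s$l_ce, p), 1e-6))
    fv_req <- min(max(fv_req, 0), p$fv_ecc_max - 1e-6)
    v <- ce_velocity_from_equilibrium(s, lm, p)
    expect_lt(abs(force_velocity(v, p) - fv_req), 1e-9)
  }
})

test_that("transmitted force is the tendon force and grows with length", {
  p <- ref_muscle()
  s <- muscle_state(0.5, p$l_ce_opt, p)
  expect_equal(muscle_force(s, s$l_ce + p$l_slack * 0.99, p), 0)
  l_mt <- seq(s$l_ce + 0.9 * p$l_slack, s$l_ce + 1.1 * p$l_slack,
              length.out = 200)
  f <- vapply(l_mt, function(l) muscle_force(s, l, p), numeric(1))
  expect_true(all(diff(f) >= 0))
})

test_that("isometric initialization and settling balance CE and SEE force", {
  p <- ref_muscle()
  g <- ref_geometry()
  for (a0 in c(p$a_min, 0.2, 0.8)) {
    s <- init_muscle_state(pi / 2, a0, g, p)
    l_mt <- muscle_tendon_length(pi / 2, g)
    expect_gt(s$l_ce, 0)
    expect_lt(s$l_ce, l_mt)
    resid <- abs(see_force(l_mt - s$l_ce, p) -
                   p$f_max * a0 * force_length(s$l_ce, p))
    expect_lt(resid, 1e-8 * p$f_max)
  }
  # holding length and drive fixed, the state settles onto the force
  # balance F_ce = F_se
  s <- init_muscle_state(pi / 2, p$a_min, g, p)
  l_mt <- muscle_tendon_length(pi / 2, g)
  st <- settle_isometric(s, l_mt, 0.6, p, dt = 1 / 1000, t_end = 3)
  f_se <- see_force(l_mt - st$l_ce, p)
  f_ce <- p$f_max * st$a * force_length(st$l_ce, p) *
    force_velocity(ce_velocity_from_equilibrium(st, l_mt, p), p)
  expect_lt(abs(f_se - f_ce), 1e-6 * p$f_max)
  # no bracket -> configuration error (tendon slack over the whole range)
  p_bad <- muscle_params(l_slack = 0.5)
  expect_error(init_muscle_state(pi / 2, 0.5, g, p_bad),
               class = "elbowsim_config_error")
})

test_that("muscle parameter invariants are enforced", {
  expect_error(muscle_params(f_max = -1), class = "elbowsim_validation_error")
  expect_error(muscle_params(fv_ecc_max = 1),
               class = "elbowsim_validation_error")
  expect_error(muscle_params(tau_act = 0.06, tau_deact = 0.05),
               class = "elbowsim_validation_error")
  expect_error(muscle_params(a_min = 0.2),
               class = "elbowsim_validation_error")
  expect_error(muscle_state(0.005, 0.1, ref_muscle()),
               class = "elbowsim_validation_error")
})
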
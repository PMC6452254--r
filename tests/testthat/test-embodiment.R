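# Body builders, muscle model, physics and sensing.

test_that("insect body has one joint, actuator and sensor per leg", {
  b <- build_insect_body(12)
  expect_equal(nrow(b$joints), 12)
  expect_equal(b$n_actuators, 12)
  expect_equal(b$params$n_legs, 12)
  b3 <- build_insect_body(3)
  expect_equal(nrow(b3$joints), 3)
  expect_error(build_insect_body(2))
  # rotational symmetry: all legs share identical parameters
  expect_equal(length(unique(b$joints$K)), 1)
  expect_equal(length(unique(b$muscles$max_torque)), 1)
  expect_equal(diff(b$taxels$arc[b$taxels$segment == "disc"]),
               rep(1 / 12, 11))
})

test_that("human-like taxel distribution concentrates on face/hands/feet", {
  bh <- build_fetus_body(32, "humanlike", 300)
  bu <- build_fetus_body(32, "uniform", 300)
  special <- function(b) mean(b$taxels$region %in% c("face", "hand", "foot"))
  expect_gt(special(bh), special(bu))
  expect_gt(special(bh), 0.65)
  # uniform: per-unit-length density equal across segments within rounding
  cnt <- table(factor(bu$taxels$segment, levels = bu$segments$name))
  dens <- as.numeric(cnt) / bu$segments$length
  expect_lt(max(dens) - min(dens), 0.15 * mean(dens))
  expect_error(build_fetus_body(20), "age_weeks")
  expect_error(build_fetus_body(32, "patchy"))
})

test_that("fetus geometry scales monotonically with gestational age", {
  b32 <- build_fetus_body(32)
  b40 <- build_fetus_body(40)
  expect_true(all(b40$segments$length > b32$segments$length))
  expect_gt(sum(b40$segments$mass), sum(b32$segments$mass))
})

test_that("taxel totals per region scale linearly with taxel_count", {
  b1 <- build_fetus_body(32, "humanlike", 150)
  b2 <- build_fetus_body(32, "humanlike", 300)
  t1 <- table(b1$taxels$region)
  t2 <- table(b2$taxels$region)[names(t1)]
  expect_true(all(abs(as.numeric(t2) - 2 * as.numeric(t1)) <= 2))
})

test_that("muscle torque follows the documented formula", {
  m <- list(sign = 1, max_torque = 2, theta_opt = 0, width = 1.6,
            damping = 0.1)
  # zero activation leaves pure damping
  expect_equal(muscle_torque(0, m, 0.3, 2), -0.2)
  # hand evaluation at a stated angle
  expect_equal(muscle_torque(0.5, m, 0.4, 0),
               0.5 * 2 * exp(-(0.4 / 1.6)^2))
  expect_error(muscle_torque(1.5, m, 0, 0), "activation")
  # antagonist co-activation at neutral angle cancels
  body <- build_fetus_body()
  tq <- embodysim:::joint_torques(body, rep(0.7, 20), numeric(10),
                                  numeric(10))
  expect_equal(tq, numeric(10), tolerance = 1e-12)
})

test_that("passive bodies dissipate energy in the fluid environment", {
  body <- build_fetus_body()
  env <- environment_spec("uterus_fluid", radius = fit_uterus(body))
  st <- initial_state(body, env)
  st[4] <- 0.3                       # initial base velocity
  st[17:26] <- 0.5                   # joint velocities
  r <- physics_step(body, st, numeric(10), env, n_sub = 0)
  e0 <- r$energy
  e_prev <- e0
  for (i in 1:30) {
    r <- physics_step(body, r$state, numeric(10), env, n_sub = 100)
    expect_lte(r$energy, e_prev * 1.001 + 1e-9)
    e_prev <- r$energy
  }
  expect_lt(r$energy, 0.01 * e0)
})

test_that("a released body settles on the plane with shallow penetration", {
  body <- build_fetus_body()
  env <- environment_spec("flat_plane")
  st <- initial_state(body, env)
  r <- physics_step(body, st, numeric(10), env, n_sub = 0)
  for (i in 1:50) r <- physics_step(body, r$state, numeric(10), env,
                                    n_sub = 100)
  kin <- fetus_kinematics(r$state, body$cbody)
  expect_gt(min(kin$tax_y), -0.012)
  expect_lt(sqrt(r$state[4]^2 + r$state[5]^2), 0.02)
})

test_that("ground impulse balances momentum change plus gravity impulse", {
  body <- build_fetus_body()
  env <- environment_spec("flat_plane")
  st <- initial_state(body, env)
  # settle first
  r <- physics_step(body, st, numeric(10), env, n_sub = 0)
  for (i in 1:30) r <- physics_step(body, r$state, numeric(10), env,
                                    n_sub = 100)
  M <- body$cbody$mass_total
  v0y <- r$state[5]
  imp <- 0
  nwin <- 20
  for (i in 1:nwin) {
    r <- physics_step(body, r$state, numeric(10), env, n_sub = 50)
    imp <- imp + r$contact_impulse[2]
  }
  dt_tot <- nwin * 50 * 1e-3
  lhs <- imp - M * 9.81 * dt_tot
  rhs <- M * (r$state[5] - v0y)
  expect_lt(abs(lhs - rhs), 0.01 * M * 9.81 * dt_tot)
})

test_that("a passive spring leg oscillates at sqrt(K/I)/2pi", {
  body <- build_insect_body()
  body$params$mu_grip <- 0            # free oscillation
  env <- environment_spec("walled_arena", arena_half = Inf)
  st <- initial_state(body, env)
  st[7] <- 0.3
  dt <- 1e-4
  n <- 20000
  trace <- numeric(n)
  r <- list(state = st)
  for (i in seq_len(n)) {
    r <- embodysim:::insect_substeps(r$state, numeric(12), body$params,
                                     1L, dt)
    trace[i] <- r$state[7]
  }
  up <- which(trace[-1] > 0 & trace[-n] <= 0)
  f_meas <- 1 / (mean(diff(up)) * dt)
  f_theory <- sqrt(body$params$K / body$params$leg_inertia) / (2 * pi)
  expect_equal(f_meas, f_theory, tolerance = 0.05)
})

test_that("sensing reports fluid pressure only on moving taxels", {
  body <- build_fetus_body()
  env <- environment_spec("uterus_fluid", radius = fit_uterus(body))
  st <- initial_state(body, env)
  fr0 <- sense(body, st, env)
  expect_true(all(fr0$tactile[body$taxels$region != "hand" &
                                body$taxels$region != "face"] < 1e-9))
  st2 <- st
  st2[17] <- 2.0   # spine joint swings: upper body taxels move
  fr <- sense(body, st2, env)
  moving <- body$taxels$segment %in% c("head")
  still <- body$taxels$segment %in% c("shank_foot_L", "shank_foot_R")
  expect_gt(mean(fr$tactile[moving]), 0)
  expect_lt(max(fr$tactile[still]), 1e-6)
})

test_that("the camera sees the hand in front of the face but not limbs far away", {
  body <- build_fetus_body()
  env <- environment_spec("uterus_fluid", radius = fit_uterus(body))
  st <- initial_state(body, env)
  vis_rest <- render_vision(body, st)
  st2 <- st
  st2[9] <- -0.9; st2[11] <- -0.9  # swing both arms away (shoulder joints)
  vis_away <- render_vision(body, st2)
  expect_gt(sum(vis_rest$left) + sum(vis_rest$right),
            sum(vis_away$left) + sum(vis_away$right))
  expect_true(all(unlist(vis_rest) >= 0 & unlist(vis_rest) <= 1))
})

test_that("simulation is deterministic and validates components", {
  body <- build_insect_body()
  env <- environment_spec("walled_arena", arena_half = Inf)
  ctrl <- chaotic_controller(12, alpha = 1.7)
  t0 <- simulate_embodied(body, env, ctrl, duration = 0, seed = 1)
  expect_equal(length(t0$time), 1)
  a <- simulate_embodied(body, env, ctrl, duration = 2, seed = 7)
  b <- simulate_embodied(body, env, ctrl, duration = 2, seed = 7)
  expect_identical(a$states, b$states)
  expect_identical(a$config_hash, b$config_hash)
  expect_error(simulate_embodied(body, env, chaotic_controller(5),
                                 duration = 1),
               "actuators")
})

test_that("trajectories export to columnar CSV", {
  body <- build_insect_body()
  env <- environment_spec("walled_arena", arena_half = Inf)
  tr <- simulate_embodied(body, env, chaotic_controller(12), duration = 1,
                          seed = 1)
  d <- withr::local_tempdir()
  export_trajectory_csv(tr, d)
  st <- read.csv(file.path(d, "states.csv"))
  expect_equal(nrow(st), length(tr$time))
  expect_true(file.exists(file.path(d, "motors.csv")))
})
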
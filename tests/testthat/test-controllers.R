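# Chaotic map units and BVP/spinal oscillators.

test_that("quadratic map step matches hand arithmetic and boundary cases", {
  expect_equal(logistic_step(0, 1.8), 1.0)
  expect_equal(logistic_step(1, 2), -1.0)
  x1 <- logistic_step(0.1, 2)
  expect_equal(x1, 0.98)
  expect_equal(logistic_step(x1, 2), -0.9208)
})

test_that("map step rejects out-of-range state and parameter", {
  expect_error(logistic_step(1.5, 1.8), "out of range")
  expect_error(logistic_step(0.5, 2.5), "alpha")
  expect_error(logistic_step(NaN, 1.5), "out of range")
})

test_that("iterated map preserves [-1, 1] across the parameter range", {
  for (a in c(1.0, 1.5, 2.0)) {
    orbit <- embodysim:::cpp_logistic_orbit(0.1, a, 1e6)
    expect_true(all(abs(orbit) <= 1))
  }
})

test_that("controller bank: zero input maps to u = 1, coupling is smooth", {
  ctrl <- chaotic_controller(3, alpha = c(1.5, 1.7, 1.9),
                             eps_self = 0, eps_mix = 0)
  ctrl <- chaotic_controller_step(ctrl, c(0, 0, 0))
  expect_equal(ctrl$u, c(1, 1, 1))

  s0 <- c(0.3, -0.2, 0.5)
  a <- chaotic_controller_step(
    chaotic_controller(3, alpha = 1.7, eps_self = 0, eps_mix = 0, x0 = 0.1),
    s0)
  b <- chaotic_controller_step(
    chaotic_controller(3, alpha = 1.7, eps_self = 1e-9, eps_mix = 0,
                       x0 = 0.1), s0)
  expect_lt(max(abs(a$u - b$u)), 1e-6)
})

test_that("controller mixing follows the convex-combination definition", {
  # two units, one hand-computed iteration
  ctrl <- chaotic_controller(2, alpha = c(1.6, 1.8), eps_self = 0,
                             eps_mix = 0.2, x0 = c(0.5, -0.5))
  s <- c(0.2, 0.4)
  ctrl <- chaotic_controller_step(ctrl, s)
  # effective input: 0.8 * s + 0.2 * mean(c(0.5, -0.5)) = 0.8 * s
  expect_equal(ctrl$u, c(1 - 1.6 * 0.16^2, 1 - 1.8 * 0.32^2))
})

test_that("controller rejects invalid coupling weights and lengths", {
  expect_error(chaotic_controller(2, eps_self = 0.6, eps_mix = 0.5),
               "eps_self")
  expect_error(chaotic_controller_step(chaotic_controller(3), c(0, 0)),
               "does not match")
})

test_that("BVP oscillator rests at its fixed point under zero drive", {
  u <- bvp_units(1, v0 = -0.9, w0 = -0.4)
  r <- bvp_run(u, drive = 0, dt = 1e-3, n_steps = 1e5)  # 100 time units
  expect_equal(r$units$v, -1.19941, tolerance = 1e-4)
  expect_equal(r$units$w, -0.62426, tolerance = 1e-4)
})

test_that("supra-threshold drive yields a stable limit cycle", {
  r <- bvp_run(bvp_units(1), drive = 0.8, dt = 1e-3, n_steps = 6e4)
  v <- r$v[, 1]
  up <- which(v[-1] > 0 & v[-length(v)] <= 0)
  expect_gt(length(up), 4)
  periods <- diff(up)[-1]  # drop the transient cycle
  expect_lt(max(abs(diff(periods))) / mean(periods), 0.01)
})

test_that("halving the integration step changes the state only to first order", {
  r1 <- bvp_run(bvp_units(1), drive = 0.5, dt = 1e-3, n_steps = 1000)
  r2 <- bvp_run(bvp_units(1), drive = 0.5, dt = 5e-4, n_steps = 2000)
  expect_equal(r1$units$v, r2$units$v, tolerance = 5e-3)
})

test_that("spinal unit with zero afferent gain reduces to the bare oscillator", {
  su <- spinal_units(2, afferent_gain = 0)
  bare <- su$osc
  af <- list(spindle_length = c(0.5, -0.5), spindle_velocity = c(1, -1),
             tendon_tension = c(0.3, 0.3))
  for (k in 1:500) {
    su <- spinal_step(su, af, dt = 1e-2)
    bare <- bvp_step(bare, su$base_drive, dt = 1e-2)
  }
  expect_equal(su$osc$v, bare$v)
  # gamma = 0 with zero tendon input behaves identically
  su2 <- spinal_units(2, afferent_gain = 0.5, gamma_mn = 0)
  bare2 <- su2$osc
  af0 <- list(spindle_length = c(0.5, -0.5), spindle_velocity = c(1, -1),
              tendon_tension = c(0, 0))
  for (k in 1:500) {
    su2 <- spinal_step(su2, af0, dt = 1e-2)
    bare2 <- bvp_step(bare2, su2$base_drive, dt = 1e-2)
  }
  expect_equal(su2$osc$v, bare2$v)
  expect_true(all(su$activation >= 0 & su$activation <= 1))
})

test_that("muscles coupled only through the body phase-organize", {
  body <- build_fetus_body()
  env <- environment_spec("uterus_fluid", radius = fit_uterus(body))
  plv_of <- function(gain) {
    tr <- simulate_embodied(body, env,
                            spinal_units(20, afferent_gain = gain),
                            duration = 40, seed = 3,
                            record_taxels = FALSE)
    a <- tr$activation[-(1:500), c(1, 2)]   # antagonist pair, post-transient
    m <- phase_sync_matrix(a)
    m[1, 2]
  }
  expect_gt(plv_of(0.6), plv_of(0))
})

test_that("with a rigid body, per-muscle oscillator traces are independent", {
  # zero afferents (the body never moves): cross-correlation between any
  # two muscle traces must be indistinguishable from circular-shift
  # surrogates at the 5% level
  set.seed(9)
  su <- spinal_units(6)
  su$osc$v <- bvp_phase_states(6, drive = 0.8, rate = 4)$v
  su$osc$w <- bvp_phase_states(6, drive = 0.8, rate = 4)$w
  su$osc$rate <- 4 * runif(6, 0.8, 1.25)
  n <- 4000
  tr <- matrix(NA_real_, n, 6)
  aff <- zero_afferents <- list(spindle_length = numeric(6),
                                spindle_velocity = numeric(6),
                                tendon_tension = numeric(6))
  for (k in seq_len(n)) {
    su <- spinal_step(su, aff, dt = 0.01)
    tr[k, ] <- su$osc$v
  }
  tr <- tr[-(1:500), ]
  cc <- abs(cor(tr[, 1], tr[, 2]))
  sur <- replicate(60, {
    k <- sample(300, 1) + 200
    abs(cor(tr[, 1], c(tr[-(1:k), 2], tr[1:k, 2])))
  })
  expect_lt(cc, quantile(sur, 0.95) + 0.15)
})
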
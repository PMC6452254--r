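# Synthetic stream, oscillatory signal and scripted trajectory generators.

test_that("block-correlated streams hit their target correlations", {
  spec <- stream_spec(30, rep(1:3, each = 10), rho_in = 0.8,
                      rho_out = 0.1, duration = 1e4, seed = 5)
  x <- synth_receptor_stream(spec)
  expect_true(all(x >= 0))
  C <- cor(x)
  blocks <- rep(1:3, each = 10)
  same <- outer(blocks, blocks, "==")
  diag(C) <- NA
  expect_equal(mean(C[same], na.rm = TRUE), 0.8, tolerance = 0.05)
  expect_equal(mean(C[!same]), 0.1, tolerance = 0.05)

  spec0 <- stream_spec(20, rep(1:2, each = 10), rho_in = 0, rho_out = 0,
                       duration = 1e4, seed = 2)
  C0 <- cor(synth_receptor_stream(spec0))
  diag(C0) <- NA
  expect_lt(max(abs(C0), na.rm = TRUE), 0.06)

  expect_identical(synth_receptor_stream(spec), synth_receptor_stream(spec))
  expect_error(stream_spec(10, rep(1, 10), rho_in = 0.3, rho_out = 0.5),
               "rho_out")
  expect_error(stream_spec(10, rep(1, 4)), "cover")
})

test_that("oscillatory fixtures drive the PLV metric as constructed", {
  x <- synth_oscillatory_signals(3, frequency = 2, duration = 10,
                                 offsets = c(0, pi / 2, pi), jitter_sd = 0)
  m <- phase_sync_matrix(x)
  expect_true(all(m[upper.tri(m)] > 0.999))      # offset invariance
  y <- synth_oscillatory_signals(2, frequency = 2, duration = 30,
                                 jitter_sd = 0.3, seed = 4)
  plv_y <- phase_sync_matrix(y)[1, 2]
  # circular-shift surrogate bound at 95%
  sur <- replicate(100, {
    k <- sample(200:2800, 1)
    phase_sync_matrix(cbind(y[, 1], c(y[-(1:k), 2], y[1:k, 2])))[1, 2]
  })
  expect_lt(plv_y, quantile(sur, 0.95) + 0.1)
  expect_gt(phase_sync_matrix(x)[1, 2], plv_y)
})

test_that("scripted trajectories interpolate targets and sense frames", {
  body <- build_fetus_body()
  env <- environment_spec("uterus_fluid", radius = fit_uterus(body))
  empty <- scripted_trajectory(body, data.frame(time = 0), env)
  expect_equal(nrow(empty$states), 1)
  expect_error(scripted_trajectory(
    body, data.frame(time = c(1, 0.5), elbow_L = c(0, 1)), env),
    "increasing")
  # an arm sweep in front of the eyes produces visual input synchronized
  # with arm proprioception
  script <- data.frame(time = seq(0, 8, by = 2),
                       shoulder_R = c(0, .45, 0, .45, 0),
                       elbow_R = c(0, .35, 0, .35, 0))
  tr <- scripted_trajectory(body, script, env, control_dt = 0.05,
                            visual_on = TRUE)
  vis <- vapply(tr$visual, function(v) sum(v$left) + sum(v$right),
                numeric(1))
  expect_gt(max(vis), 0)
  prop <- abs(tr$spindle_velocity[, 5])  # a right-shoulder muscle
  expect_gt(cor(vis, rowSums(abs(tr$spindle_velocity))), 0)
})

test_that("hand-to-face scripts yield exactly the scripted contact count", {
  body <- build_fetus_body()
  env <- environment_spec("uterus_fluid", radius = fit_uterus(body))
  # three distinct elbow flexions bringing the hand to the face
  t <- seq(0, 30, by = 1)
  elbow <- rep(0, length(t))
  elbow[c(5, 15, 25)] <- 0.9
  elbow[c(6, 16, 26)] <- 0.9
  script <- data.frame(time = t, elbow_R = elbow, shoulder_R = 0.25 *
                         (elbow > 0))
  tr <- scripted_trajectory(body, script, env, control_dt = 0.05)
  ct <- contact_event_rate(tr, "hand", "face", debounce = 3)
  expect_equal(ct$n_events, 3)
  # a lazier debounce merges adjacent touches
  ct0 <- contact_event_rate(tr, "hand", "face", debounce = 0)
  expect_gte(ct0$n_events, ct$n_events)
})
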
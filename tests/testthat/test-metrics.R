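# Analysis metrics: Lyapunov, PLV, DFA, event rates, response indices.

test_that("map Lyapunov exponent reproduces canonical values", {
  expect_equal(largest_lyapunov_map(2, n_iter = 1e6), log(2),
               tolerance = 0.01)
  expect_lt(largest_lyapunov_map(1.0, n_iter = 1e5), 0)
  expect_gt(largest_lyapunov_map(1.5, n_iter = 1e5), 0)
})

test_that("PLV: identical and offset sinusoids lock, noise does not", {
  t <- seq(0, 10, by = 0.01)
  s <- cbind(sin(2 * pi * t), sin(2 * pi * t))
  expect_equal(phase_sync_matrix(s)[1, 2], 1, tolerance = 1e-6)
  s2 <- cbind(sin(2 * pi * t), sin(2 * pi * t + pi / 2))
  expect_equal(phase_sync_matrix(s2)[1, 2], 1, tolerance = 1e-4)
  set.seed(1)
  wn <- matrix(rnorm(2002), ncol = 2)
  plv_wn <- phase_sync_matrix(wn)[1, 2]
  sur <- replicate(100, {
    k <- sample(100:900, 1)
    phase_sync_matrix(cbind(wn[, 1], c(wn[-(1:k), 2], wn[1:k, 2])))[1, 2]
  })
  expect_lt(plv_wn, quantile(sur, 0.95) + 0.05)
  # constant channel flagged
  m <- phase_sync_matrix(cbind(rep(1, 100), sin(1:100)))
  expect_true(is.na(m[1, 2]))
  # symmetry
  m3 <- phase_sync_matrix(matrix(rnorm(3000), ncol = 3))
  expect_equal(m3, t(m3))
  # zero-crossing method agrees for clean sinusoids
  expect_equal(phase_sync_matrix(s2, method = "zerocross")[1, 2], 1,
               tolerance = 0.02)
})

test_that("DFA reproduces 0.5 for white noise and 1.5 for a random walk", {
  set.seed(11)
  a_wn <- mean(replicate(3, dfa_exponent(rnorm(4096))$alpha))
  expect_equal(a_wn, 0.5, tolerance = 0.05)
  a_rw <- mean(replicate(3, dfa_exponent(cumsum(rnorm(4096)))$alpha))
  expect_equal(a_rw, 1.5, tolerance = 0.1)
  expect_true(dfa_exponent(rep(1, 2048))$degenerate)
  expect_error(dfa_exponent(rnorm(2048), windows = c(4, 8)), "window")
})

test_that("jerk events count injected acceleration pulses exactly", {
  dt <- 0.01
  t <- seq(0, 60, by = dt)
  theta <- 0.001 * t                       # constant velocity: no events
  expect_equal(jerk_event_rate(cbind(theta), dt, 5)$n_events, 0)
  k <- 4
  th2 <- theta
  for (i in seq_len(k)) {
    at <- 1000 * i
    th2[at:(at + 3)] <- th2[at:(at + 3)] + c(0.01, 0.03, 0.01, 0)
  }
  jk <- jerk_event_rate(cbind(th2), dt, 50)
  expect_equal(jk$n_events, k)
  expect_equal(jerk_event_rate(cbind(th2), dt, 1e9)$n_events, 0)
})

test_that("segregation index matches cosine geometry", {
  one_hot <- list(a = c(1, 0, 0), b = c(0, 1, 0), c = c(0, 0, 1))
  expect_equal(segregation_index(one_hot)$value, 1)
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(segregation_index(same)$value, 0)
  deg60 <- list(a = c(1, 0), b = c(0.5, sqrt(3) / 2))
  expect_equal(segregation_index(deg60)$value, 0.5)
  # invariance to positive rescaling
  expect_equal(segregation_index(list(a = c(1, 0), b = 5 * c(0.5, sqrt(3) / 2)))$value,
               0.5)
  sz <- segregation_index(list(a = c(1, 0), b = c(0, 0), c = c(0, 1)))
  expect_equal(length(sz$excluded), 2)
  expect_equal(sz$value, 1)   # remaining pair a~c orthogonal
})

test_that("multimodal index reflects super/sub-additivity", {
  u <- list(v = c(3, 0), t = c(0, 4))
  expect_equal(multimodal_index(c(3, 4), u), 5 / 7)
  expect_equal(multimodal_index(c(6, 8), u), 10 / 7)  # numerator linearity
  expect_equal(multimodal_index(c(2, 2), list(a = c(2, 2))), 1)
  expect_warning(mi <- multimodal_index(c(1, 1), list(a = c(0, 0))))
  expect_true(is.na(mi))
})

test_that("onset detection finds sustained step increases", {
  t <- 1:100
  flat <- rep(5, 100) + rep(c(-0.1, 0.1), 50)
  expect_true(is.na(onset_time(flat, t, 1:20)))
  step <- c(rep(5, 49), rep(20, 51)) + rep(c(-0.1, 0.1), 50)
  expect_equal(onset_time(step, t, 1:20), 50, tolerance = 1)
  stepB <- c(rep(5, 29), rep(20, 71)) + rep(c(-0.1, 0.1), 50)
  expect_lt(onset_time(stepB, t, 1:20), onset_time(step, t, 1:20))
})
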
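# Hebbian tactile-to-motor learning.

test_that("zero tactile input can only shrink weights (decay term)", {
  W <- spinal_weights(10, 4, w0 = 0.5)
  W2 <- hebbian_update(W, numeric(10), rep(0.8, 4), lr = 0.1)
  expect_true(all(W2$W_alpha <= W$W_alpha))
})

test_that("a single co-active pair converges monotonically to the Oja fixed point", {
  W <- spinal_weights(1, 1, w0 = 0.05)
  path <- numeric(200)
  for (k in 1:200) {
    W <- hebbian_update(W, 1, 1, lr = 0.05)
    path[k] <- W$W_alpha[1, 1]
  }
  expect_true(all(diff(path) >= -1e-12))
  expect_equal(path[200], 1, tolerance = 1e-3)  # dw = lr (1 - w) -> w = 1
})

test_that("one-step weight change matches the analytic expectation", {
  # for independent pre/post streams at a fixed weight w0:
  # E[dw | w0] = lr (E[pre] E[post] - w0 E[post^2])
  set.seed(42)
  n <- 1e4
  lr <- 0.01
  w0 <- 0.3
  pre <- runif(n)
  post <- runif(n)
  dws <- vapply(seq_len(n), function(k) {
    W <- spinal_weights(1, 1, w0 = w0)
    hebbian_update(W, pre[k], post[k], lr = lr)$W_alpha[1, 1] - w0
  }, numeric(1))
  expected <- lr * (mean(pre) * mean(post) - w0 * mean(post^2))
  expect_equal(mean(dws), expected, tolerance = 0.05)
})

test_that("weights stay inside [0, w_max] under arbitrary input streams", {
  set.seed(7)
  W <- spinal_weights(20, 5, w_max = 1, w0 = 0.5)
  for (k in 1:2e4) {
    W <- hebbian_update(W, runif(20), runif(5), lr = 0.2)
    if (k %% 1000 == 0)
      expect_true(all(W$W_alpha >= 0 & W$W_alpha <= 1))
  }
  expect_true(all(W$W_osc >= 0 & W$W_osc <= 1))
})

test_that("learned drive is linear in gain pre-squash and bounded post-squash", {
  W <- spinal_weights(10, 3, w0 = 0.2)
  tact <- runif(10)
  d1 <- spinal_drive(W, tact, which = "alpha", squash = FALSE)
  W$gain <- 3
  d3 <- spinal_drive(W, tact, which = "alpha", squash = FALSE)
  expect_equal(d3, 3 * d1)
  # zero weights give zero drive; saturating input stays below 1
  W0 <- spinal_weights(10, 3, w0 = 0)
  expect_equal(spinal_drive(W0, tact), numeric(3))
  Wbig <- spinal_weights(10, 3, w0 = 1, gain = 100)
  expect_true(all(spinal_drive(Wbig, rep(1, 10)) <= 1))
  expect_error(spinal_drive(W, runif(4)), "taxel count")
  expect_error(hebbian_update(W, runif(3), runif(3)), "shape mismatch")
})

test_that("closed-loop tactile-motor correlation does not collapse under learning", {
  # positive-feedback property: early-learning correlation between summed
  # tactile input and summed motor activation is non-decreasing (majority
  # of seeds)
  body <- build_fetus_body(32, "humanlike", 120)
  env <- environment_spec("uterus_fluid", radius = fit_uterus(body))
  wins <- 0
  for (s in 1:5) {
    W <- spinal_weights(120, 20)
    tr <- simulate_embodied(body, env,
                            spinal_units(20, base_drive = 0.55),
                            duration = 90, seed = s, plasticity = W,
                            lr = 2e-3, record_taxels = FALSE,
                            fb_warmup = 20)
    tact <- rowSums(tr$tactile)
    act <- rowSums(tr$activation)
    early <- 500:3000; late <- 6000:8999
    c_early <- cor(tact[early], act[early])
    c_late <- cor(tact[late], act[late])
    if (!is.na(c_late) && !is.na(c_early) && c_late >= c_early - 0.05)
      wins <- wins + 1
  }
  expect_gte(wins, 3)
})
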
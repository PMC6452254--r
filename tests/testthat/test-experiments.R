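# Experiment drivers: controls, determinism, report plumbing.

test_that("a fixed-point (alpha = 0) controller produces no sustained locomotion", {
  rep0 <- run_insect_locomotion(seeds = 1:2, duration = 8,
                                config = list(alpha = 0))
  expect_true(all(rep0$summary$displacement < 0.1))
  # after the start-up transient the robot is at rest
  for (p in rep0$per_seed) {
    rng <- p$trajectory_range
    expect_lt(rng[2] - rng[1], 0.2)
  }
})

test_that("locomotion reports are reproducible bit-for-bit", {
  a <- run_insect_locomotion(seeds = 3, duration = 6)
  b <- run_insect_locomotion(seeds = 3, duration = 6)
  expect_identical(a$summary, b$summary)
  expect_identical(a$config_hash, b$config_hash)
  d <- withr::local_tempdir()
  write_report(a, d)
  expect_true(file.exists(file.path(d, "insect_locomotion.json")))
})

test_that("an arena without walls leaves wall adaptation inconclusive", {
  rep <- run_wall_adaptation(seeds = 1, duration = 6, arena_half = Inf)
  expect_true(rep$per_seed[[1]]$inconclusive)
  expect_equal(rep$summary$n_conclusive, 0)
})

test_that("an untrained cortex shows no condition difference in segregation", {
  body <- build_fetus_body(32, "humanlike", 300)
  ch <- receptor_channels(body)
  seg_naive <- vapply(1:4, function(s) {
    net <- attach_inputs(build_cortex(600, seed = s), ch, seed = s)
    maps <- embodysim:::probe_parts(net, body, seed = s, amplitude = 0.5)
    segregation_index(maps)$value
  }, numeric(1))
  # no training, no environment: spread across seeds is pure probe noise
  expect_lt(diff(range(seg_naive)), 0.35)
})

test_that("receptor channel tables cover taxels, muscles and pixels", {
  body <- build_fetus_body()
  ch <- receptor_channels(body, visual = TRUE)
  expect_equal(sum(ch$modality == "tactile"), 300)
  expect_equal(sum(ch$modality == "proprio"), 20)
  expect_equal(sum(ch$modality == "visual"), 512)
  expect_setequal(unique(ch$part[ch$modality == "tactile"]),
                  c("armL", "armR", "legL", "legR", "head", "trunk"))
})

test_that("config files round-trip through YAML", {
  cfg <- list(body = list(n_legs = 12, K = 0.08),
              controller = list(alpha = c(1.6, 1.8), eps_self = 0.05))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, f)
  expect_equal(read_config(f)$body$K, 0.08)
  expect_equal(read_config(f)$controller$alpha, c(1.6, 1.8))
})
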
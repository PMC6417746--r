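test_that("EPSG kernel is causal with the closed-form peak", {
  expect_equal(epsg_kernel(0), 0)
  expect_equal(epsg_kernel(-1), 0)
  # closed-form argmax of a double exponential
  t_star <- (0.18 * 0.1 / (0.18 - 0.1)) * log(0.18 / 0.1)
  expect_equal(t_star, 0.1323, tolerance = 1e-3)
  opt <- optimize(epsg_kernel, c(0, 2), maximum = TRUE)
  expect_equal(opt$maximum, t_star, tolerance = 1e-4)
  expect_equal(opt$objective, 26.70, tolerance = 1e-3)
  expect_equal(epsg_kernel(t_star),
               125.25 * (exp(-t_star / 0.18) - exp(-t_star / 0.1)))
})

test_that("conductance trains superpose linearly", {
  g2 <- conductance_train(c(5, 5), 1)
  t <- seq(4, 12, by = 0.01)
  expect_equal(g2(t), 2 * epsg_kernel(t - 5), tolerance = 1e-12)
  g <- conductance_train(c(1, 2.5, 4), c(1, 3, 2))
  manual <- epsg_kernel(t - 1) + 3 * epsg_kernel(t - 2.5) + 2 * epsg_kernel(t - 4)
  expect_equal(g(t), manual, tolerance = 1e-12)
  expect_equal(g(0.5), 0)  # causality
})

test_that("step and ramp currents have the declared shapes", {
  st <- stim_step(2500, onset = 5, duration = 200)
  expect_equal(stim_current(st, c(0, 4.99)), c(0, 0))
  expect_equal(stim_current(st, c(5, 100, 204.9)), rep(2500, 3))
  expect_equal(stim_current(st, 206), 0)
  expect_equal(stim_current(stim_step(0, 5, 10), c(1, 7)), c(0, 0))

  rp <- stim_ramp(1000, peak = 2500, onset = 5)
  expect_equal(stim_current(rp, 5), 0)
  expect_equal(stim_current(rp, 7.5), 2500)   # reaches peak at onset + 2.5
  expect_equal(stim_current(rp, 6), 1000)
  expect_equal(stim_current(rp, 20), 2500)    # holds at peak
  expect_equal(stim_current(stim_ramp(500, 2500, 5), 10), 2500)
  expect_error(stim_ramp(-1), "slope")
})

test_that("phase-locked trains are reproducible and respect the refractory gap", {
  t1 <- phase_locked_trains(500, 500, seed = 7)
  t2 <- phase_locked_trains(500, 500, seed = 7)
  expect_identical(t1$side_a, t2$side_a)
  expect_identical(t1$side_b, t2$side_b)
  t3 <- phase_locked_trains(500, 500, seed = 8)
  expect_false(identical(t1$side_a, t3$side_a))
  for (sp in c(t1$side_a, t1$side_b)) {
    if (length(sp) > 1) expect_gte(min(diff(sp)), 0.75)
    expect_true(all(sp >= 0 & sp <= 500))
  }
})

test_that("train statistics hit the targets: mean rate and vector strength", {
  tr <- phase_locked_trains(500, 10000, n_fibers = 3, seed = 11)
  sp <- c(unlist(tr$side_a), unlist(tr$side_b))
  n <- length(sp)
  rate <- n / 6 / 10                       # sp/s per fiber over 10 s
  se <- 200 / sqrt(n)                      # Poisson-scale standard error
  expect_lt(abs(rate - 200), 3 * se)
  vs <- vector_strength(sp, 500)
  expect_lt(abs(vs - 0.65), 0.05)
  # phase locking degrades with frequency
  tr7 <- phase_locked_trains(700, 10000, n_fibers = 3, seed = 11)
  vs7 <- vector_strength(c(unlist(tr7$side_a), unlist(tr7$side_b)), 700)
  expect_lt(vs7, vs)
  expect_lt(abs(vs7 - 0.55), 0.05)
})

test_that("side delay shifts the second ear; anti-phase is half a period", {
  expect_equal(antiphase_delay(500), 1)
  expect_equal(antiphase_delay(250), 2)
  tr0 <- phase_locked_trains(500, 300, side_delay = 0, seed = 5)
  trd <- phase_locked_trains(500, 300, side_delay = 1, seed = 5)
  expect_identical(tr0$side_a, trd$side_a)
  # interior spikes of the delayed side are the undelayed ones shifted
  b0 <- tr0$side_b[[1]]; bd <- trd$side_b[[1]]
  common <- b0[b0 + 1 <= 300]
  expect_equal(bd, common + 1, tolerance = 1e-12)
  expect_error(phase_locked_trains(500, -1, seed = 1), "duration")
  expect_error(phase_locked_trains(500, 100, mean_rate = 0, seed = 1), "rate")
  expect_error(phase_locked_trains(500, 100), "seed")
})

test_that("trains convert to a pooled EPSG stimulus", {
  tr <- phase_locked_trains(300, 100, n_fibers = 2, seed = 3)
  st <- stim_from_trains(tr, scale = 1, offset = 5)
  expect_s3_class(st, "stimulus")
  expect_equal(length(st$times),
               sum(lengths(tr$side_a)) + sum(lengths(tr$side_b)))
  expect_true(all(diff(st$times) >= 0))
  expect_gte(min(st$times), 5)
})
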
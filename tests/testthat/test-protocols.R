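test_that("gNa_ref brackets are validated: +/- 1 percent flips the outcome", {
  m <- fwd_model()
  ref <- cached_gna_ref(m)
  stim <- stim_epsg(c(5, 5), 1)
  up <- simulate(two_cpt_model(m$coupling, gna = ref * 1.01),
                 stimulus = stim, duration = 15)
  dn <- simulate(two_cpt_model(m$coupling, gna = ref * 0.99),
                 stimulus = stim, duration = 15)
  expect_gte(length(up$spike_times), 1)
  expect_length(dn$spike_times, 0)
})

test_that("step-response classification separates quiescent, phasic, tonic", {
  mw <- weak_model(); mf <- fwd_model()
  rw <- cached_gna_ref(mw); rf <- cached_gna_ref(mf)
  expect_identical(classify_firing_pattern(weak_model(gna = 0), 2500),
                   "quiescent")
  amps <- c(500, 1000, 2000, 4000)
  lw <- vapply(amps, function(a)
    classify_firing_pattern(two_cpt_model(mw$coupling, gna = rw), a),
    character(1))
  lf <- vapply(amps, function(a)
    classify_firing_pattern(two_cpt_model(mf$coupling, gna = rf), a),
    character(1))
  # at its reference conductance the weakly-coupled model fires tonically
  # for some step amplitude; the forward-coupled model never does
  expect_true("tonic" %in% lw)
  expect_false("tonic" %in% lf)
  expect_true("phasic" %in% lf)
})

test_that("slope sensitivity: forward coupling raises delta_gna", {
  dw <- delta_gna(weak_model())
  df <- delta_gna(fwd_model())
  expect_gt(df$delta_gna, dw$delta_gna)
  expect_lt(abs(dw$delta_gna - 1), 0.3)  # weak thresholds nearly slope-flat
  expect_gte(df$delta_gna, 1)
  # threshold decreases with ramp slope for the slope-sensitive model
  expect_lt(df$threshold_fast, df$threshold_slow)
})

test_that("paired 3x EPSGs at 2.5 ms delay evoke two spikes in all models", {
  for (mk in list(weak_model, fwd_model, strong_model)) {
    m <- mk()
    ref <- cached_gna_ref(m)
    s <- simulate(two_cpt_model(m$coupling, gna = ref),
                  stimulus = stim_epsg(c(5, 7.5), 3), duration = 18)
    expect_gte(length(s$spike_times), 2)
  }
})

test_that("delay-threshold curve is nonincreasing", {
  m <- fwd_model()
  dc <- delay_threshold_curve(m, delays = c(1, 1.5, 2, 3, 4.5),
                              gna_max = 5 * cached_gna_ref(m))
  thr <- dc$threshold_gna[!is.na(dc$threshold_gna)]
  expect_gte(length(thr), 4)
  expect_true(all(diff(thr) <= 0))
})

test_that("standard error of trial rates scales as 1/sqrt(n)", {
  m <- fwd_model(gna = cached_gna_ref(fwd_model()))
  r25 <- firing_rate_trials(m, 500, n_trials = 25, duration = 100, seed = 21)
  r100 <- firing_rate_trials(m, 500, n_trials = 100, duration = 100,
                             seed = 21)
  se25 <- sd(r25) / sqrt(25)
  se100 <- sd(r100) / sqrt(100)
  # expected ratio 0.5; allow generous sampling noise
  expect_gt(se25 / se100, 1.2)
  expect_lt(se25 / se100, 3.5)
})

test_that("parameter-space sweeps are tidy, deterministic and error-tolerant", {
  empty <- parameter_space_sweep(coupling_grid(0.3)[0, ], function(m) 1)
  expect_s3_class(empty, "data.frame")
  expect_equal(nrow(empty), 0)

  g <- coupling_grid(0.3, c(0.2, 0.8))
  f <- function(m) list(rin = input_resistance(m))
  t1 <- parameter_space_sweep(g, f)
  t2 <- parameter_space_sweep(g, f)
  expect_identical(t1, t2)
  expect_true(all(is.na(t1$error)))
  expect_true(all(abs(t1$rin - 8.5) < 1e-8))

  flaky <- function(m) {
    if (m$coupling$kfwd > 0.5) stop("boom")
    list(ok = 1)
  }
  t3 <- parameter_space_sweep(g, flaky)
  expect_true(any(!is.na(t3$error)))
  expect_true(any(is.na(t3$error)))
  expect_equal(nrow(t3), nrow(g))
})
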
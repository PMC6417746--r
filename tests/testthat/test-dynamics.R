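test_that("compiled RHS agrees with the R reference implementation", {
  m <- fwd_model(gna = 500, klt_placement = "cpt2", klt_mode = "dynamic")
  stim <- stim_epsg(c(2, 3.5), c(2, 3))
  # same integration through deSolve once with the compiled RHS (via
  # simulate) and once with the plain-R derivatives()
  s_c <- simulate(m, stimulus = stim, duration = 8)
  rhs_r <- function(t, y, parms) list(unname(derivatives(m, y, t, stim)))
  s_r <- deSolve::ode(y = resting_state(m), times = s_c$times, func = rhs_r,
                      rtol = 1e-6, atol = 1e-8, hmax = 0.05,
                      method = "lsoda")
  expect_lt(max(abs(s_c$state[, "V2"] - s_r[, "V2"])), 0.05)
  expect_lt(max(abs(s_c$state[, "V1"] - s_r[, "V1"])), 0.01)
  expect_lt(max(abs(s_c$state[, "h"] - s_r[, "h"])), 1e-3)
})

test_that("zero stimulus from rest stays flat", {
  m <- strong_model(gna = 2000)
  s <- simulate(m, stimulus = stim_zero(), duration = 30)
  expect_lt(max(abs(s$state[, "V1"] + 58)), 1e-7)
  expect_lt(max(abs(s$state[, "V2"] + 58)), 1e-7)
  expect_length(s$spike_times, 0)
})

test_that("passive steady-state attenuation equals the coupling strengths", {
  # current into Cpt1: U2/U1 -> kfwd (simulated); current into Cpt2:
  # U1/U2 -> kback (2x2 steady-state solve, the axon compartment is not a
  # stimulus target in the simulator)
  for (k in list(c(0.3, 0.2), c(0.8, 0.2), c(0.8, 0.7))) {
    m <- two_cpt_model(coupling(k[1], k[2]))
    s <- simulate(m, stimulus = stim_step(300, 2, 60), duration = 60)
    n <- length(s$times)
    U1 <- s$state[n, "V1"] + 58; U2 <- s$state[n, "V2"] + 58
    expect_equal(unname(U2 / U1), k[1], tolerance = 1e-4)
    A <- matrix(c(m$g1 + m$gc, -m$gc, -m$gc, m$g2 + m$gc), 2, byrow = TRUE)
    u <- solve(A, c(0, 1))   # 1 pA into Cpt2
    expect_equal(u[1] / u[2], k[2], tolerance = 1e-12)
  }
})

test_that("spike detection finds threshold crossings with dead time", {
  t <- seq(0, 20, by = 0.01)
  flat <- rep(-58, length(t))
  expect_length(detect_spikes(flat, t), 0)
  # two crossings 5 ms apart
  v <- -60 + 50 * exp(-((t - 5)^2) / 0.02) + 50 * exp(-((t - 10)^2) / 0.02)
  sp <- detect_spikes(v, t, threshold = -20)
  expect_length(sp, 2)
  expect_equal(sp[2] - sp[1], 5, tolerance = 0.01)
  # subthreshold bump peaking at -30
  v2 <- -58 + 28 * exp(-((t - 5)^2) / 0.02)
  expect_length(detect_spikes(v2, t, threshold = -20), 0)
  # crossings closer than the dead time collapse to one
  v3 <- -60 + 50 * exp(-((t - 5)^2) / 0.002) + 50 * exp(-((t - 5.3)^2) / 0.002)
  expect_length(detect_spikes(v3, t, threshold = -20, dead_time = 0.5), 1)
})

test_that("simulation is deterministic and insensitive to tolerance halving", {
  m <- fwd_model(gna = cached_gna_ref(fwd_model()))
  stim <- stim_epsg(c(5, 7.5), 3)
  s1 <- simulate(m, stimulus = stim, duration = 15)
  s2 <- simulate(m, stimulus = stim, duration = 15)
  expect_identical(s1$spike_times, s2$spike_times)
  expect_identical(s1$state, s2$state)
  s3 <- simulate(m, stimulus = stim, duration = 15, rtol = 5e-7, atol = 5e-9)
  expect_equal(length(s1$spike_times), length(s3$spike_times))
  expect_lt(max(abs(s1$spike_times - s3$spike_times)), 1e-3)  # < 1 us
})

test_that("somatic EPSP is invariant across the coupling grid", {
  g <- coupling_grid(0.2, c(0.1, 0.9))
  ref <- NULL
  for (i in seq_len(nrow(g))) {
    m <- two_cpt_model(coupling(g$kfwd[i], g$kback[i]))
    s <- simulate(m, stimulus = stim_epsg(5), duration = 15)
    v1 <- s$state[, "V1"]
    if (is.null(ref)) {
      ref <- v1
      peak <- max(ref) + 58
      expect_equal(peak, 6, tolerance = 1 / 6)  # roughly 6 mV
    } else {
      expect_lt(max(abs(v1 - ref)) / peak, 0.02)
    }
  }
})

test_that("frozen KLT is subthreshold-identical to the passive model", {
  mp <- weak_model()
  mk <- weak_model(klt_placement = "cpt2", klt_mode = "frozen",
                   klt_fraction = 0.1)
  sp <- simulate(mp, stimulus = stim_epsg(5), duration = 15)
  sk <- simulate(mk, stimulus = stim_epsg(5), duration = 15)
  expect_lt(max(abs(sp$state - sk$state)), 1e-9)
})

test_that("resting_state is a verified equilibrium", {
  m <- weak_model(gna = 6000)
  st <- resting_state(m)
  expect_equal(unname(st[["V1"]]), -58)
  expect_equal(unname(st[["h"]]), h_gate(-58)$h_inf)
  expect_lt(max(abs(derivatives(m, st))), 1e-12)
})
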
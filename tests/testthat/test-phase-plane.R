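test_that("nullcline points satisfy the defining equation", {
  m <- weak_model(gna = 6300)
  for (v1 in c(-58, -40, -30)) {
    nc <- v2_nullcline(m, v1)
    idx <- round(seq(1, nrow(nc), length.out = 50))
    for (i in idx) {
      if (nc$h[i] < 0 || nc$h[i] > 1) next
      # substitute back through the independent R dynamics: c2 * dV2/dt
      st <- c(V1 = v1, V2 = nc$V2[i], h = nc$h[i],
              w1 = w_gate(v1)$w_inf, w2 = w_gate(nc$V2[i])$w_inf)
      resid <- m$c2 * derivatives(m, st)[["V2"]]
      expect_lt(abs(resid), 1e-8)
    }
  }
})

test_that("nullclines shift down and right as the soma depolarizes", {
  m <- strong_model(gna = 2000)
  nc1 <- v2_nullcline(m, -58)
  nc2 <- v2_nullcline(m, -40)
  # at matching V2 (where both curves exist with h in (0,1)), h is lower for
  # the more depolarized soma: the curve moved down, equivalently any given
  # h-level moved right
  vs <- seq(-60, -20, by = 0.5)
  h1 <- approx(nc1$V2[nc1$h > 0 & nc1$h < 1], nc1$h[nc1$h > 0 & nc1$h < 1], vs)$y
  h2 <- approx(nc2$V2[nc2$h > 0 & nc2$h < 1], nc2$h[nc2$h > 0 & nc2$h < 1], vs)$y
  both <- is.finite(h1) & is.finite(h2)
  expect_gt(sum(both), 5)
  expect_true(all(h2[both] < h1[both]))
})

test_that("the left knee exists at rest and vanishes at depolarized V1", {
  mw <- weak_model(gna = cached_gna_ref(weak_model()))
  kw <- left_knee(v2_nullcline(mw, -58))
  expect_false(is.null(kw))
  expect_true(kw[["h"]] > 0 && kw[["h"]] < 1)
  mf <- fwd_model(gna = cached_gna_ref(fwd_model()))
  expect_null(left_knee(v2_nullcline(mf, -30)))
  # a monotone synthetic curve has no knee
  mono <- structure(data.frame(V2 = seq(-70, -30, 0.5),
                               h = seq(0.9, 0.1, length.out = 81),
                               branch = "left"),
                    class = c("nullcline", "data.frame"))
  expect_null(left_knee(mono))
})

test_that("fixed points sit at rest for V1 = Vrest and satisfy both equations", {
  for (mk in list(weak_model, fwd_model, strong_model)) {
    m <- mk(gna = 2000)
    fp <- fixed_points(m, -58)
    expect_gte(nrow(fp), 1)
    i <- which.min(abs(fp$V2 + 58))
    expect_lt(abs(fp$V2[i] + 58), 1e-6)
    for (j in seq_len(nrow(fp))) {
      st <- c(V1 = -58, V2 = fp$V2[j], h = fp$h[j],
              w1 = w_gate(-58)$w_inf, w2 = w_gate(fp$V2[j])$w_inf)
      d <- derivatives(m, st)
      expect_lt(abs(m$c2 * d[["V2"]]), 1e-8)
      expect_lt(abs(d[["h"]]), 1e-10)
    }
  }
})

test_that("weak model fixed point crosses to the middle branch and fires", {
  m <- weak_model(gna = cached_gna_ref(weak_model()))
  branch_at <- function(v1) {
    fp <- fixed_points(m, v1)
    fp$branch[which.min(abs(fp$V2 - v1 * 0.3))]  # the low-voltage root
  }
  expect_identical(branch_at(-58), "left")
  # find the transition V1 on a grid
  v1s <- seq(-58, -30, by = 1)
  br <- vapply(v1s, branch_at, character(1))
  expect_true("middle" %in% br)
  v1_mid <- v1s[which(br == "middle")[1]]
  # with the soma clamped past the transition the axon fires repetitively
  s <- simulate(m, stimulus = stim_zero(), duration = 100,
                clamp_v1 = v1_mid + 2)
  expect_gte(length(s$spike_times), 5)
})

test_that("sodium inactivation recovers more slowly with strong backward coupling", {
  hw <- h_after_epsg(weak_model(), cached_gna_ref(weak_model()))
  hs <- h_after_epsg(strong_model(), cached_gna_ref(strong_model()))
  expect_gt(hw, hs)
})
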
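test_that("passive parameters match hand-evaluated values", {
  m <- weak_model()
  expect_equal(m$gc, 25.03, tolerance = 1e-3)
  expect_equal(m$g1, 100.1, tolerance = 1e-3)
  expect_equal(m$g2, 58.41, tolerance = 1e-3)
  mf <- fwd_model()
  expect_equal(mf$gc, 28.01, tolerance = 1e-3)
  expect_equal(mf$g1, 112.0, tolerance = 1e-3)
  expect_equal(mf$g2, 7.00, tolerance = 1e-3)
})

test_that("soma capacitance is invariant: c1 = tau_exp/Rin for all couplings", {
  g <- coupling_grid(0.1)
  spec <- mso_cell_spec()
  for (i in seq_len(nrow(g))) {
    m <- two_cpt_model(coupling(g$kfwd[i], g$kback[i]), spec = spec)
    expect_equal(m$c1, 1000 * spec$tau_exp / spec$Rin, tolerance = 1e-12)
    expect_equal(m$c2, spec$alpha * m$c1, tolerance = 1e-12)
  }
  expect_equal(weak_model()$c1, 40)
})

test_that("analytic input resistance equals the specified Rin on the grid", {
  g <- coupling_grid(0.1)
  for (i in seq_len(nrow(g))) {
    m <- two_cpt_model(coupling(g$kfwd[i], g$kback[i]))
    expect_lt(abs(input_resistance(m) - 8.5) / 8.5, 1e-9)
  }
})

test_that("conductances and coupling strengths round-trip", {
  g <- coupling_grid(0.1)
  for (i in seq_len(nrow(g))) {
    m <- two_cpt_model(coupling(g$kfwd[i], g$kback[i]))
    k <- coupling_from_conductances(m$g1, m$g2, m$gc)
    expect_lt(abs(k$kfwd - g$kfwd[i]), 1e-10)
    expect_lt(abs(k$kback - g$kback[i]), 1e-10)
  }
})

test_that("coupling_from_conductances handles limiting cases", {
  k <- coupling_from_conductances(100, 50, 0)
  expect_equal(k$kfwd, 0)
  expect_equal(k$kback, 0)
  expect_equal(coupling_from_conductances(100, 0, 30)$kfwd, 1)
  expect_error(coupling_from_conductances(0, 5, 0), "nonzero")
})

test_that("inadmissible couplings are rejected with informative errors", {
  expect_error(coupling(1, 1), "degenerate")
  expect_error(coupling(0.2, 0.3), "kfwd must be >= kback")
  expect_error(coupling(0.9, 0.05), "<= 10")
  expect_error(coupling(0, 0.1), "strictly in")
})

test_that("timescale ratio is alpha * kfwd/kback", {
  spec <- mso_cell_spec()
  expect_equal(timescale_ratio(spec, coupling(0.3, 0.2)), 0.015)
  expect_equal(timescale_ratio(spec, coupling(0.5, 0.5)), 0.01)
  expect_equal(timescale_ratio(spec, coupling(0.8, 0.2)), 0.04)
})

test_that("coupling grid is triangular, constrained and deterministic", {
  g <- coupling_grid(0.1)
  expect_true(all(g$kfwd >= g$kback))
  expect_true(all(g$kfwd / g$kback <= 10 + 1e-9))
  expect_true(all(g$kfwd * g$kback < 1))
  # row-major ordering by kback then kfwd
  expect_true(all(diff(g$kback) >= 0))
  expect_identical(g, coupling_grid(0.1))
  # the three named configurations are present
  has <- function(kf, kb) any(abs(g$kfwd - kf) < 1e-9 & abs(g$kback - kb) < 1e-9)
  expect_true(has(0.3, 0.2))
  expect_true(has(0.8, 0.2))
  expect_true(has(0.8, 0.7))
  expect_error(coupling_grid(0.5, c(1.1, 1.2)), "empty grid")
})

test_that("cell specification validates its fields", {
  expect_error(mso_cell_spec(Rin = -1), "Rin")
  expect_error(mso_cell_spec(alpha = 0.5), "alpha")
  s <- mso_cell_spec(Rin = 10, tau_exp = 0.5)
  m <- two_cpt_model(coupling(0.4, 0.3), spec = s)
  expect_lt(abs(input_resistance(m) - 10) / 10, 1e-9)
  expect_equal(m$c1, 1000 * 0.5 / 10)
})
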
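# The axon compartment's fast subsystem lives in the (V2, h) plane, with the
# soma voltage V1 acting as a slowly varying input.  The V2-nullcline at a
# fixed V1 is solved for h in closed form, since h enters the sodium current
# linearly.

v2_rhs_current <- function(model, V2, h, V1_fixed) {
  Vr <- model$spec$Vrest
  IK2 <- if (model$gklt2 > 0)
    klt_current(V2, w_gate(V2)$w_inf, model$gklt2, Vr, model$EK) else 0
  -model$g2 * (V2 - model$Elk) - model$gc * (V2 - V1_fixed) - IK2 -
    na_current(V2, h, model$gna, Vr, model$ENa, model$m_vhalf, model$m_slope)
}

#' V2-nullcline at fixed soma voltage
#'
#' Solves `0 = -g2 (V2 - Elk) - gc (V2 - V1) - I_KLT2 - I_Na(V2, h)` for `h`
#' at each `V2`, treating the soma voltage as a fixed input.  The inactivation
#' gate enters the sodium current linearly, so the solution is closed-form.
#' When dynamic KLT is present in the axon compartment its activation gate is
#' evaluated quasi-statically at `w_inf(V2)` (a plotting/diagnostic
#' approximation).  The returned `h` values are clipped to `[-0.1, 1.1]`.
#'
#' @param model A [two_cpt_model()] with `gna > 0`.
#' @param V1_fixed Soma voltage treated as the input, mV.
#' @param V2_range Range of axon voltages, mV.
#' @param dV2 Grid spacing, mV.
#' @return An object of class `"nullcline"`: data frame with columns `V2`,
#'   `h`, and `branch` (`"left"`, `"middle"`, `"right"` where separable by
#'   the knees), plus attributes `V1_fixed` and `model`.
#' @examples
#' m <- two_cpt_model(coupling(0.3, 0.2), gna = 6000)
#' nc <- v2_nullcline(m, -58)
#' head(nc)
#' @export
v2_nullcline <- function(model, V1_fixed, V2_range = c(-80, 60), dV2 = 0.05) {
  stopifnot(inherits(model, "two_cpt_model"))
  if (model$gna <= 0) stop("'gna' must be positive: no V2-nullcline in h")
  Vr <- model$spec$Vrest
  V2 <- seq(V2_range[1], V2_range[2], by = dV2)
  # exclude the singular point V2 = ENa where the Na driving force vanishes
  V2 <- V2[abs(V2 - model$ENa) > 1e-6]
  IK2 <- if (model$gklt2 > 0)
    klt_current(V2, w_gate(V2)$w_inf, model$gklt2, Vr, model$EK) else 0
  na_corr <- model$gna * m_inf(Vr, model$m_vhalf, model$m_slope)^3 *
    h_gate(Vr)$h_inf * (Vr - model$ENa)
  passive <- -model$g2 * (V2 - model$Elk) - model$gc * (V2 - V1_fixed) - IK2
  h <- (passive + na_corr) /
    (model$gna * m_inf(V2, model$m_vhalf, model$m_slope)^3 * (V2 - model$ENa))
  keep <- h >= -0.1 & h <= 1.1
  out <- data.frame(V2 = V2[keep], h = h[keep])
  out$branch <- label_branches(out$V2, out$h)
  structure(out, V1_fixed = V1_fixed, model = model,
            class = c("nullcline", "data.frame"))
}

# Branch labels from the knees of h(V2): left of the local maximum (left
# knee) = "left", between maximum and minimum = "middle", beyond = "right".
# A monotone curve gets a single label by slope sign.
label_branches <- function(V2, h) {
  n <- length(h)
  if (n < 3) return(rep("left", n))
  d <- diff(h)
  lmax <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L  # local maxima
  lmin <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L  # local minima
  lab <- rep("left", n)
  if (length(lmax) == 0) return(rep(if (mean(d) > 0) "middle" else "left", n))
  knee <- lmax[1]
  lab[seq_len(n) > knee] <- "middle"
  trough <- lmin[lmin > knee]
  if (length(trough)) lab[seq_len(n) > trough[1]] <- "right"
  lab
}

#' Left knee of a V2-nullcline
#'
#' The local maximum of `h` along the nullcline with `0 < h < 1`, refined by
#' a quadratic fit through the three samples around the discrete maximum.
#' The knee's height sets the effective spike threshold of the fast
#' subsystem; it disappears at depolarized soma voltages in strongly
#' forward-coupled models, which is the phase-plane signature of phasic
#' firing.
#'
#' @param curve A [v2_nullcline()] result.
#' @return A named numeric vector `c(V2, h)`, or `NULL` if the curve has no
#'   interior local maximum with `h` in (0, 1).
#' @export
left_knee <- function(curve) {
  stopifnot(inherits(curve, "nullcline"))
  h <- curve$h; V2 <- curve$V2
  n <- length(h)
  if (n < 3) return(NULL)
  d <- diff(h)
  idx <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  idx <- idx[h[idx] > 0 & h[idx] < 1]
  if (length(idx) == 0) return(NULL)
  i <- idx[1]
  # quadratic refinement through (i-1, i, i+1)
  x <- V2[(i - 1):(i + 1)]; y <- h[(i - 1):(i + 1)]
  co <- solve(cbind(1, x, x^2), y)
  v_star <- -co[2] / (2 * co[3])
  c(V2 = unname(v_star),
    h = unname(co[1] + co[2] * v_star + co[3] * v_star^2))
}

#' Fixed points of the (V2, h) fast subsystem
#'
#' Intersections of the V2-nullcline with the h-nullcline `h = h_inf(V2)` at
#' a fixed soma voltage, located by sign-change bracketing on a fine grid and
#' refined with [stats::uniroot()].  Each root is labelled with the nullcline
#' branch it lies on.
#'
#' @param model A [two_cpt_model()] with `gna > 0`.
#' @param V1_fixed Soma voltage, mV.
#' @param V2_range,dV2 Search grid for sign changes.
#' @return A data frame with columns `V2`, `h`, `branch` (possibly zero
#'   rows).
#' @examples
#' m <- two_cpt_model(coupling(0.3, 0.2), gna = 6000)
#' fixed_points(m, -58)  # the resting state, V2 = -58
#' @export
fixed_points <- function(model, V1_fixed, V2_range = c(-80, 60),
                         dV2 = 0.05) {
  stopifnot(inherits(model, "two_cpt_model"))
  if (model$gna <= 0) stop("'gna' must be positive")
  f <- function(V2) v2_rhs_current(model, V2, h_gate(V2)$h_inf, V1_fixed)
  V2 <- seq(V2_range[1], V2_range[2], by = dV2)
  V2 <- V2[abs(V2 - model$ENa) > 1e-6]
  fv <- vapply(V2, f, numeric(1))
  sgn <- sign(fv)
  idx <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(f, c(V2[i], V2[i + 1]), tol = 1e-12)$root
  }, numeric(1))
  roots <- c(roots, V2[which(fv == 0)])
  if (length(roots) == 0)
    return(data.frame(V2 = numeric(0), h = numeric(0),
                      branch = character(0)))
  roots <- sort(unique(roots))
  curve <- v2_nullcline(model, V1_fixed, V2_range, dV2)
  branch <- vapply(roots, function(r) {
    curve$branch[which.min(abs(curve$V2 - r))]
  }, character(1))
  data.frame(V2 = roots, h = h_gate(roots)$h_inf, branch = branch)
}

#' @export
plot.nullcline <- function(x, add = FALSE, col = "steelblue", lwd = 2,
                           xlim = NULL, ylim = c(0, 1), ...) {
  if (!add) {
    graphics::plot(x$V2, x$h, type = "n",
                   xlim = if (is.null(xlim)) range(x$V2) else xlim,
                   ylim = ylim, xlab = "V2 (mV)", ylab = "h", ...)
    v <- seq(min(x$V2), max(x$V2), length.out = 400)
    graphics::lines(v, h_gate(v)$h_inf, col = "black")
  }
  # draw branch segments separately to avoid spurious connecting strokes
  for (b in unique(x$branch)) {
    s <- x[x$branch == b, ]
    graphics::lines(s$V2, s$h, col = col, lwd = lwd)
  }
  invisible(x)
}

#' Sodium inactivation after the first of two strong EPSGs
#'
#' Simulates the paired suprathreshold EPSG protocol (two events, each
#' `epsg_scale` times unitary, separated by `delay`) and reads the sodium
#' inactivation gate `h` a fixed lag after the onset of the first event.
#' This exposes the post-spike recovery state of the fast subsystem, which
#' governs whether the trailing event can evoke a second spike.
#'
#' @param model A [two_cpt_model()] (its `gna` field is ignored).
#' @param gna_ref Sodium conductance used; computed by [find_gna_ref()] if
#'   omitted.
#' @param lag Read-out time after the first event onset, ms.
#' @param delay Delay between the two events, ms.
#' @param epsg_scale EPSG amplitude in units of the unitary kernel.
#' @param onset First-event onset, ms.
#' @return The value of `h` at `onset + lag` (dimensionless).
#' @export
h_after_epsg <- function(model, gna_ref = NULL, lag = 1.5, delay = 1.5,
                         epsg_scale = 3, onset = 5) {
  stopifnot(inherits(model, "two_cpt_model"))
  if (is.null(gna_ref)) gna_ref <- find_gna_ref(model)
  m <- with_gna(model, gna_ref)
  s <- simulate(m, stimulus = refractory_stim(delay, onset, epsg_scale),
                duration = onset + delay + 8, dt_out = 0.005)
  unname(stats::approx(s$times, s$state[, "h"], xout = onset + lag)$y)
}
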
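#' Passive cell specification
#'
#' Bundles the measured passive properties of the modelled cell: somatic input
#' resistance, membrane decay time constant, resting potential (equal to the
#' leak reversal in the passive model), the axon-to-soma surface-area ratio,
#' and specific membrane capacitance.  Defaults are the in vitro values for
#' gerbil MSO principal neurons used throughout the package.
#'
#' @param Rin Input resistance at the soma, in MOhm.
#' @param tau_exp Exponential decay time constant of the somatic voltage after
#'   a brief perturbation, in ms.
#' @param Vrest Resting potential, mV.  Equals the leak reversal `Elk`.
#' @param alpha Surface-area ratio A2/A1 (axon compartment over soma
#'   compartment), dimensionless, in (0, 0.1].
#' @param Cm Specific membrane capacitance in uF/cm^2 (equivalently
#'   0.01 pF/um^2), assumed equal in both compartments.
#' @return An object of class `"mso_cell_spec"`.
#' @examples
#' spec <- mso_cell_spec()
#' spec$Rin
#' @export
mso_cell_spec <- function(Rin = 8.5, tau_exp = 0.34, Vrest = -58,
                          alpha = 0.01, Cm = 0.9) {
  stopifnot(is.numeric(Rin), length(Rin) == 1L, is.finite(Rin),
            is.numeric(tau_exp), length(tau_exp) == 1L, is.finite(tau_exp),
            is.numeric(Vrest), length(Vrest) == 1L, is.finite(Vrest),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(Cm), length(Cm) == 1L, is.finite(Cm))
  if (Rin <= 0) stop("'Rin' must be positive (MOhm)")
  if (tau_exp <= 0) stop("'tau_exp' must be positive (ms)")
  if (alpha <= 0 || alpha > 0.1)
    stop("'alpha' (area ratio A2/A1) must lie in (0, 0.1]")
  if (Cm <= 0) stop("'Cm' must be positive (uF/cm^2)")
  structure(list(Rin = Rin, tau_exp = tau_exp, Vrest = Vrest,
                 alpha = alpha, Cm = Cm),
            class = "mso_cell_spec")
}

#' @export
print.mso_cell_spec <- function(x, ...) {
  cat("Passive cell specification\n")
  cat(sprintf("  Rin      %.4g MOhm\n", x$Rin))
  cat(sprintf("  tau_exp  %.4g ms\n", x$tau_exp))
  cat(sprintf("  Vrest    %.4g mV (= Elk)\n", x$Vrest))
  cat(sprintf("  alpha    %.4g (A2/A1)\n", x$alpha))
  cat(sprintf("  Cm       %.4g uF/cm^2\n", x$Cm))
  invisible(x)
}

#' Coupling configuration
#'
#' The pair of electrotonic coupling strengths that defines one point in the
#' two-dimensional model family: `kfwd` (soma-to-axon, the steady-state
#' attenuation U2/U1 for current into the soma compartment) and `kback`
#' (axon-to-soma, U1/U2 for current into the axon compartment).  Values near 0
#' mean strong attenuation (weak coupling); values near 1 mean no attenuation.
#'
#' Admissible configurations satisfy `kfwd >= kback` (forward propagation is
#' at least as strong as backpropagation), `kfwd/kback <= 10` (preserves the
#' separation of time scales between compartments), and `kfwd * kback < 1`.
#'
#' @param kfwd Forward coupling strength, in (0, 1).
#' @param kback Backward coupling strength, in (0, 1).
#' @return An object of class `"coupling"`.
#' @examples
#' coupling(0.3, 0.2)  # the weakly-coupled configuration
#' @export
coupling <- function(kfwd, kback) {
  stopifnot(is.numeric(kfwd), length(kfwd) == 1L, is.finite(kfwd),
            is.numeric(kback), length(kback) == 1L, is.finite(kback))
  if (kfwd * kback >= 1)
    stop("degenerate coupling: kfwd * kback must be < 1")
  if (kfwd <= 0 || kfwd >= 1 || kback <= 0 || kback >= 1)
    stop("coupling strengths must lie strictly in (0, 1)")
  if (kfwd < kback)
    stop("constraint violated: kfwd must be >= kback ",
         "(forward coupling at least as strong as backward)")
  if (kfwd / kback > 10 + 1e-12)
    stop("constraint violated: kfwd/kback must be <= 10 ",
         "(time-scale separation restriction)")
  structure(list(kfwd = kfwd, kback = kback), class = "coupling")
}

#' @export
print.coupling <- function(x, ...) {
  cat(sprintf("Coupling configuration: kfwd = %.3g, kback = %.3g\n",
              x$kfwd, x$kback))
  invisible(x)
}

#' Recover coupling strengths from conductances
#'
#' Inverts the parameterization: `kfwd = gc/(g2 + gc)` and
#' `kback = gc/(g1 + gc)`.
#'
#' @param g1,g2 Leak conductances of the soma and axon compartments, nS.
#' @param gc Axial conductance, nS.
#' @return A list with elements `kfwd` and `kback` (not validated against the
#'   admissibility constraints, since arbitrary conductance triples may fall
#'   outside the restricted family).
#' @examples
#' coupling_from_conductances(100.1, 58.41, 25.03)
#' @export
coupling_from_conductances <- function(g1, g2, gc) {
  stopifnot(is.numeric(g1), is.numeric(g2), is.numeric(gc),
            all(g1 >= 0), all(g2 >= 0), all(gc >= 0))
  if (any(g2 + gc == 0) || any(g1 + gc == 0))
    stop("undefined coupling: g2 + gc and g1 + gc must be nonzero")
  list(kfwd = gc / (g2 + gc), kback = gc / (g1 + gc))
}

#' Ratio of compartment time constants
#'
#' Returns `tau2/tau1 = alpha * kfwd / kback`, the small parameter that
#' quantifies the separation of time scales between the slow soma compartment
#' and the fast axon compartment.  The admissibility restriction
#' `kfwd/kback <= 10` keeps this ratio at or below `10 * alpha`.
#'
#' @param spec An [mso_cell_spec()] (only `alpha` is used).
#' @param coupling A [coupling()] object.
#' @return Dimensionless ratio `tau2/tau1`.
#' @examples
#' timescale_ratio(mso_cell_spec(), coupling(0.3, 0.2))  # 0.015
#' @export
timescale_ratio <- function(spec, coupling) {
  stopifnot(inherits(spec, "mso_cell_spec"), inherits(coupling, "coupling"))
  if (coupling$kback == 0) stop("'kback' must be nonzero")
  spec$alpha * coupling$kfwd / coupling$kback
}

#' Grid of admissible coupling configurations
#'
#' Enumerates a square lattice of `(kfwd, kback)` pairs and retains those
#' satisfying the admissibility constraints (`kfwd >= kback`,
#' `kfwd/kback <= 10`, `kfwd * kback < 1`), giving the triangular region used
#' for parameter-space sweeps.  Ordering is deterministic: row-major by
#' `kback`, then `kfwd`.
#'
#' @param step Lattice spacing in both coordinates, in (0, 1).
#' @param bounds Numeric length-2 vector, inclusive range for both
#'   coordinates.  Default `c(0.1, 0.9)`.
#' @return A data frame with columns `kfwd` and `kback`, one row per retained
#'   configuration.
#' @examples
#' g <- coupling_grid(0.1)
#' nrow(g)
#' @export
coupling_grid <- function(step = 0.05, bounds = c(0.1, 0.9)) {
  stopifnot(is.numeric(step), length(step) == 1L, step > 0, step < 1,
            is.numeric(bounds), length(bounds) == 2L, bounds[1] <= bounds[2])
  vals <- seq(bounds[1], bounds[2], by = step)
  vals <- vals[vals > 0 & vals < 1]
  g <- expand.grid(kfwd = vals, kback = vals, KEEP.OUT.ATTRS = FALSE)
  keep <- g$kfwd >= g$kback - 1e-12 &
    g$kfwd / g$kback <= 10 + 1e-12 &
    g$kfwd * g$kback < 1
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0L) stop("empty grid: bounds/step exclude all valid points")
  g <- g[order(g$kback, g$kfwd), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# Passive conductances/capacitances from (spec, coupling); internal workhorse.
# Units: nS and pF (1/Rin in MOhm gives 1000/Rin nS).
passive_params <- function(spec, coupling) {
  kf <- coupling$kfwd; kb <- coupling$kback
  if (kf * kb >= 1)
    stop("degenerate coupling: kfwd * kback must be < 1")
  Gin <- 1000 / spec$Rin                 # nS
  gc <- kb * Gin / (1 - kf * kb)
  g1 <- gc * (1 / kb - 1)
  g2 <- gc * (1 / kf - 1)
  c1 <- spec$tau_exp * (1 - kf * kb) * (g1 + gc)
  c2 <- spec$alpha * c1
  list(g1 = g1, g2 = g2, gc = gc, c1 = c1, c2 = c2, Elk = spec$Vrest)
}

#' Construct a two-compartment model
#'
#' Builds the full parameter set of a two-compartment soma-axon model from a
#' passive cell specification and a coupling configuration.  The passive
#' conductances and capacitances are determined uniquely so that, for any
#' admissible coupling pair, the passive dynamics of the soma compartment
#' (input resistance `Rin`, decay time `tau_exp`, rest `Vrest`) are invariant.
#' Spike-generating sodium current (conductance `gna`, axon compartment only)
#' and a low-threshold potassium (KLT) current may then be layered on top;
#' both carry resting-current correction terms so that the resting state is
#' unchanged.
#'
#' KLT placement replaces a fraction of a compartment's leak conductance with
#' KLT conductance while preserving total resting conductance (see
#' [allocate_klt()]).  In `"frozen"` mode the KLT activation gate is pinned at
#' its resting value; because `Elk = Vrest`, this is algebraically identical
#' to the purely passive leak, and is implemented as such.  In `"dynamic"`
#' mode the activation gate `w` follows its voltage-gated kinetics.
#'
#' @param coupling A [coupling()] object.
#' @param spec An [mso_cell_spec()]; default is the MSO specification.
#' @param gna Maximal sodium conductance in the axon compartment, nS.
#' @param klt_placement One of `"none"`, `"cpt1"`, `"cpt2"`, `"both"`: which
#'   compartment(s) carry KLT conductance.
#' @param klt_fraction Fraction of the resting leak conductance replaced by
#'   KLT conductance in each placed compartment, in \[0, 1).
#' @param klt_mode `"frozen"` or `"dynamic"` (see Details).
#' @param m_vhalf,m_slope Half-activation voltage (mV) and slope factor (mV)
#'   of the Boltzmann sodium activation curve
#'   `m_inf(V) = 1/(1 + exp(-(V - m_vhalf)/m_slope))`.
#' @param ENa,EK Sodium and potassium reversal potentials, mV.
#' @param Esyn Excitatory synaptic reversal potential, mV.
#' @return An object of class `"two_cpt_model"`: a list with the passive
#'   parameters (`g1`, `g2`, `gc` in nS; `c1`, `c2` in pF; `Elk` mV), channel
#'   settings, and the originating `spec` and `coupling`.
#' @examples
#' m <- two_cpt_model(coupling(0.3, 0.2))
#' m$c1   # 40 pF regardless of coupling
#' @export
two_cpt_model <- function(coupling, spec = mso_cell_spec(), gna = 0,
                          klt_placement = c("none", "cpt1", "cpt2", "both"),
                          klt_fraction = 0.1,
                          klt_mode = c("frozen", "dynamic"),
                          m_vhalf = -38, m_slope = 7,
                          ENa = 55, EK = -106, Esyn = 0) {
  stopifnot(inherits(spec, "mso_cell_spec"), inherits(coupling, "coupling"),
            is.numeric(gna), length(gna) == 1L, gna >= 0)
  klt_placement <- match.arg(klt_placement)
  klt_mode <- match.arg(klt_mode)
  if (klt_fraction < 0 || klt_fraction >= 1)
    stop("'klt_fraction' must lie in [0, 1)")

  pp <- passive_params(spec, coupling)
  Vr <- spec$Vrest

  # KLT allocation: leak reduced, gKLT sized to preserve resting conductance.
  gklt <- c(cpt1 = 0, cpt2 = 0)
  gleak <- c(cpt1 = pp$g1, cpt2 = pp$g2)
  dynamic <- klt_mode == "dynamic" && klt_placement != "none"
  if (dynamic && klt_fraction > 0) {
    if (klt_placement %in% c("cpt1", "both")) {
      a <- allocate_klt(pp$g1, klt_fraction, Vr)
      gleak["cpt1"] <- a$g_leak; gklt["cpt1"] <- a$g_klt
    }
    if (klt_placement %in% c("cpt2", "both")) {
      a <- allocate_klt(pp$g2, klt_fraction, Vr)
      gleak["cpt2"] <- a$g_leak; gklt["cpt2"] <- a$g_klt
    }
  }
  # frozen mode: KLT at rest is exactly a leak (Elk = Vrest), keep full leak

  structure(list(
    g1 = unname(gleak["cpt1"]), g2 = unname(gleak["cpt2"]), gc = pp$gc,
    c1 = pp$c1, c2 = pp$c2, Elk = pp$Elk,
    gna = gna, ENa = ENa, m_vhalf = m_vhalf, m_slope = m_slope,
    gklt1 = unname(gklt["cpt1"]), gklt2 = unname(gklt["cpt2"]), EK = EK,
    klt_placement = klt_placement, klt_fraction = klt_fraction,
    klt_mode = klt_mode, Esyn = Esyn,
    spec = spec, coupling = coupling
  ), class = "two_cpt_model")
}

#' @export
print.two_cpt_model <- function(x, ...) {
  cat("Two-compartment soma-axon model\n")
  cat(sprintf("  coupling   kfwd = %.3g, kback = %.3g\n",
              x$coupling$kfwd, x$coupling$kback))
  cat(sprintf("  passive    g1 = %.4g nS, g2 = %.4g nS, gc = %.4g nS\n",
              x$g1, x$g2, x$gc))
  cat(sprintf("             c1 = %.4g pF, c2 = %.4g pF, Elk = %.4g mV\n",
              x$c1, x$c2, x$Elk))
  cat(sprintf("  sodium     gNa = %.4g nS (ENa = %g mV)\n", x$gna, x$ENa))
  if (x$klt_placement != "none" && x$klt_mode == "dynamic")
    cat(sprintf("  KLT        dynamic, %s, fraction %.2g (gKLT1 = %.4g, gKLT2 = %.4g nS)\n",
                x$klt_placement, x$klt_fraction, x$gklt1, x$gklt2))
  else
    cat("  KLT        frozen (acts as leak)\n")
  invisible(x)
}

#' @export
summary.two_cpt_model <- function(object, ...) {
  x <- object
  # tau_i uses total resting conductance in the compartment
  g1tot <- x$g1 + x$gklt1 * resting_klt_factor(x)
  g2tot <- x$g2 + x$gklt2 * resting_klt_factor(x)
  out <- list(
    model = x,
    tau1 = x$c1 / (g1tot + x$gc),
    tau2 = x$c2 / (g2tot + x$gc),
    epsilon = timescale_ratio(x$spec, x$coupling),
    Rin_analytic = input_resistance(x),
    area1_um2 = x$c1 / (x$spec$Cm * 0.01)  # Cm uF/cm^2 = 0.01 pF/um^2
  )
  class(out) <- "summary.two_cpt_model"
  out
}

#' @export
print.summary.two_cpt_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  tau1 = %.4g ms, tau2 = %.4g ms, tau2/tau1 (eps) = %.4g\n",
              x$tau1, x$tau2, x$epsilon))
  cat(sprintf("  analytic Rin at Cpt1 = %.6g MOhm, implied A1 = %.5g um^2\n",
              x$Rin_analytic, x$area1_um2))
  invisible(x)
}

# w_inf(Vrest)^4 * z_inf(Vrest): resting KLT conductance factor
resting_klt_factor <- function(model) {
  Vr <- model$spec$Vrest
  w_gate(Vr)$w_inf^4 * z_inf(Vr)
}

#' Analytic steady-state input resistance at the soma compartment
#'
#' Solves the passive 2x2 steady-state system for constant current into the
#' soma compartment and returns `-U1ss/Iin` in MOhm.  By construction this
#' equals the specified `Rin` for every admissible coupling configuration;
#' the function provides the independent check.
#'
#' @param model A [two_cpt_model()].
#' @return Input resistance in MOhm.
#' @examples
#' input_resistance(two_cpt_model(coupling(0.8, 0.2)))  # 8.5
#' @export
input_resistance <- function(model) {
  stopifnot(inherits(model, "two_cpt_model"))
  # total resting conductances (frozen KLT is part of the leak; dynamic KLT
  # contributes its resting conductance to the subthreshold steady state)
  rf <- resting_klt_factor(model)
  g1 <- model$g1 + model$gklt1 * rf
  g2 <- model$g2 + model$gklt2 * rf
  gc <- model$gc
  # steady state: (g1+gc) U1 - gc U2 = -Iin ; -gc U1 + (g2+gc) U2 = 0
  A <- matrix(c(g1 + gc, -gc, -gc, g2 + gc), 2, 2, byrow = TRUE)
  u <- solve(A, c(-1, 0))       # Iin = 1 pA
  -u[1] * 1000                  # mV/pA = GOhm; in MOhm: *1000
}
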
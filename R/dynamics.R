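MAXEV <- 8192L
PARMS_LEN <- 28L + 2L * MAXEV

# Pack model + stimulus into the fixed-length parameter vector consumed by
# the compiled RHS.  See src/somaxon.c for the layout.
pack_parms <- function(model, stim, clamp_v1 = NULL,
                       epsg_amplitude = 125.25, tau_decay = 0.18,
                       tau_rise = 0.1) {
  Vr <- model$spec$Vrest
  rf <- resting_klt_factor(model)
  na_corr <- model$gna * m_inf(Vr, model$m_vhalf, model$m_slope)^3 *
    h_gate(Vr)$h_inf * (Vr - model$ENa)
  klt1_corr <- model$gklt1 * rf * (Vr - model$EK)
  klt2_corr <- model$gklt2 * rf * (Vr - model$EK)

  p <- numeric(PARMS_LEN)
  p[1:20] <- c(model$c1, model$c2, model$g1, model$g2, model$gc, model$Elk,
               model$gna, model$ENa, model$m_vhalf, model$m_slope,
               na_corr, model$gklt1, model$gklt2, model$EK, z_inf(Vr),
               klt1_corr, klt2_corr, model$Esyn,
               if (is.null(clamp_v1)) 0 else 1,
               if (is.null(clamp_v1)) 0 else clamp_v1)
  p[25:27] <- c(epsg_amplitude, tau_decay, tau_rise)
  if (stim$kind == "step") {
    p[21:24] <- c(1, stim$amplitude, stim$onset, stim$duration)
  } else if (stim$kind == "ramp") {
    p[21:24] <- c(2, stim$slope, stim$peak, stim$onset)
  } else {
    p[21] <- 0
  }
  if (stim$kind == "epsg") {
    n <- length(stim$times)
    if (n > MAXEV) stop("too many EPSG events (max ", MAXEV, ")")
    p[28] <- n
    if (n > 0) {
      p[28 + seq_len(n)] <- stim$times
      p[28 + MAXEV + seq_len(n)] <- stim$scales
    }
  }
  p
}

#' Resting state of a model
#'
#' Returns the state vector `(V1, V2, h, w1, w2)` at rest:
#' `V1 = V2 = Vrest`, gates at their voltage steady states.  Because every
#' voltage-gated current carries a resting-current correction term, this
#' state is an exact equilibrium of the system under zero input.
#'
#' @param model A [two_cpt_model()].
#' @return Named numeric vector of length 5.
#' @examples
#' resting_state(two_cpt_model(coupling(0.3, 0.2)))
#' @export
resting_state <- function(model) {
  stopifnot(inherits(model, "two_cpt_model"))
  Vr <- model$spec$Vrest
  c(V1 = Vr, V2 = Vr, h = h_gate(Vr)$h_inf,
    w1 = w_gate(Vr)$w_inf, w2 = w_gate(Vr)$w_inf)
}

#' Time derivatives of the model state
#'
#' Evaluates the right-hand side of the two-compartment system in R:
#' `c1 V1' = -g1 (V1 - Elk) - gc (V1 - V2) - I_KLT1 - I_syn + I_app` and
#' `c2 V2' = -g2 (V2 - Elk) - gc (V2 - V1) - I_KLT2 - I_Na`, plus first-order
#' gate kinetics.  Positive injected current depolarizes; synaptic current is
#' `g_syn(t) (V1 - Esyn)`.  This R implementation mirrors the compiled RHS
#' used by [simulate.two_cpt_model()] and serves as its independent check.
#'
#' @param model A [two_cpt_model()].
#' @param state Named state vector `(V1, V2, h, w1, w2)`.
#' @param t Time, ms.
#' @param stim A stimulus object (default none).
#' @return Named numeric vector of derivatives (mV/ms and 1/ms).
#' @examples
#' m <- two_cpt_model(coupling(0.3, 0.2), gna = 1000)
#' max(abs(derivatives(m, resting_state(m))))  # 0 at rest
#' @export
derivatives <- function(model, state, t = 0, stim = stim_zero()) {
  stopifnot(inherits(model, "two_cpt_model"), length(state) == 5)
  V1 <- state[[1]]; V2 <- state[[2]]; h <- state[[3]]
  w1 <- state[[4]]; w2 <- state[[5]]
  Vr <- model$spec$Vrest

  gsyn <- if (stim$kind == "epsg")
    sum(stim$scales * epsg_kernel(t - stim$times)) else 0
  Isyn <- gsyn * (V1 - model$Esyn)
  Iapp <- stim_current(stim, t)

  INa <- na_current(V2, h, model$gna, Vr, model$ENa, model$m_vhalf,
                    model$m_slope)
  IK1 <- if (model$gklt1 > 0) klt_current(V1, w1, model$gklt1, Vr, model$EK) else 0
  IK2 <- if (model$gklt2 > 0) klt_current(V2, w2, model$gklt2, Vr, model$EK) else 0

  hg <- h_gate(V2); wg1 <- w_gate(V1); wg2 <- w_gate(V2)
  c(V1 = (-model$g1 * (V1 - model$Elk) - model$gc * (V1 - V2) - IK1 -
            Isyn + Iapp) / model$c1,
    V2 = (-model$g2 * (V2 - model$Elk) - model$gc * (V2 - V1) - IK2 -
            INa) / model$c2,
    h = (hg$h_inf - h) / hg$tau_h,
    w1 = (wg1$w_inf - w1) / wg1$tau_w,
    w2 = (wg2$w_inf - w2) / wg2$tau_w)
}

#' Simulate a two-compartment model
#'
#' Integrates the model ODEs with deSolve's `lsoda` (variable-step,
#' variable-order, stiff-capable) from the resting state, samples the
#' trajectory on a uniform output grid, and detects spikes as upward
#' threshold crossings of the axon-compartment voltage.
#'
#' @param object A [two_cpt_model()].
#' @param nsim,seed Unused (the integration is deterministic); present for
#'   compatibility with the [stats::simulate()] generic.
#' @param stimulus A stimulus object (see [stim_step()], [stim_epsg()], ...).
#' @param duration Simulated time, ms.
#' @param dt_out Output sampling interval, ms (default 0.01 = 10 us).
#' @param init Initial state; default [resting_state()].
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param threshold,dead_time Spike-detection settings, see [detect_spikes()].
#' @param clamp_v1 If non-NULL, hold `V1` fixed at this value (mV) throughout
#'   (used for phase-plane diagnostics).
#' @param ... Ignored.
#' @return An object of class `"two_cpt_sim"`: list with `times`, matrix
#'   `state` (columns V1, V2, h, w1, w2), `spike_times`, the `stimulus`,
#'   `model`, and solver metadata.
#' @examples
#' m <- two_cpt_model(coupling(0.3, 0.2))
#' s <- simulate(m, stimulus = stim_epsg(5), duration = 15)
#' max(s$state[, "V1"]) - m$Elk   # unitary EPSP peak, ~6 mV
#' @export
simulate.two_cpt_model <- function(object, nsim = 1, seed = NULL,
                                   stimulus = stim_zero(), duration = 50,
                                   dt_out = 0.01, init = NULL,
                                   rtol = 1e-6, atol = 1e-8,
                                   threshold = -20, dead_time = 0.5,
                                   clamp_v1 = NULL, ...) {
  stopifnot(inherits(object, "two_cpt_model"),
            inherits(stimulus, "stimulus"))
  if (duration <= 0) stop("'duration' must be positive")
  y0 <- if (is.null(init)) resting_state(object) else init
  if (!is.null(clamp_v1)) y0[1] <- clamp_v1
  p <- pack_parms(object, stimulus, clamp_v1 = clamp_v1)
  times <- seq(0, duration, by = dt_out)
  # cap the internal step when the input has kinks the error estimator
  # cannot anticipate (event onsets, step/ramp corners)
  hmax <- switch(stimulus$kind, epsg = 0.05, zero = NULL, 0.25)
  out <- deSolve::ode(y = y0, times = times, func = "somaxon_derivs",
                      parms = p, dllname = "somaxon",
                      initfunc = "somaxon_init", method = "lsoda",
                      rtol = rtol, atol = atol, hmax = hmax,
                      maxsteps = 500000)
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failure (istate = ", attr(out, "istate")[1],
         ", last t = ", max(out[, 1]), "); tolerances rtol = ", rtol,
         ", atol = ", atol)
  state <- out[, -1, drop = FALSE]
  colnames(state) <- c("V1", "V2", "h", "w1", "w2")
  spikes <- detect_spikes(state[, "V2"], out[, 1], threshold = threshold,
                          dead_time = dead_time)
  structure(list(times = out[, 1], state = state, spike_times = spikes,
                 stimulus = stimulus, model = object,
                 settings = list(rtol = rtol, atol = atol, dt_out = dt_out,
                                 threshold = threshold,
                                 dead_time = dead_time,
                                 clamp_v1 = clamp_v1)),
            class = "two_cpt_sim")
}

#' @export
print.two_cpt_sim <- function(x, ...) {
  cat(sprintf("Simulation: %g ms, %d samples, %d spike(s)\n",
              max(x$times), length(x$times), length(x$spike_times)))
  if (length(x$spike_times))
    cat("  spike times (ms):",
        paste(sprintf("%.3f", x$spike_times), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.two_cpt_sim <- function(x, which = c("V1", "V2"), ...) {
  which <- match.arg(which, c("V1", "V2", "h", "w1", "w2"), several.ok = TRUE)
  old <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  for (v in which) {
    graphics::plot(x$times, x$state[, v], type = "l", xlab = "time (ms)",
                   ylab = if (v %in% c("V1", "V2")) paste(v, "(mV)") else v,
                   ...)
    if (v == "V2" && length(x$spike_times))
      graphics::abline(v = x$spike_times, col = "grey70", lty = 3)
  }
  invisible(x)
}

#' Detect spikes in a voltage trace
#'
#' Spikes are upward crossings of a voltage threshold, separated by at least
#' `dead_time`; crossing times are refined by linear interpolation between
#' samples.
#'
#' @param v Voltage trace, mV.
#' @param times Sample times, ms (same length as `v`).
#' @param threshold Crossing threshold, mV.
#' @param dead_time Minimum separation between detected spikes, ms.
#' @return Numeric vector of spike times (possibly empty), strictly
#'   increasing.
#' @examples
#' t <- seq(0, 10, by = 0.01)
#' v <- -60 + 50 * (abs(((t - 2.5) %% 5) - 2.5) < 0.5)
#' detect_spikes(v, t)
#' @export
detect_spikes <- function(v, times, threshold = -20, dead_time = 0.5) {
  stopifnot(length(v) == length(times), length(v) >= 2)
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  if (length(up) == 0) return(numeric(0))
  frac <- (threshold - v[up]) / (v[up + 1] - v[up])
  ts <- times[up] + frac * (times[up + 1] - times[up])
  out <- ts[1]
  for (s in ts[-1]) if (s - out[length(out)] >= dead_time) out <- c(out, s)
  out
}
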
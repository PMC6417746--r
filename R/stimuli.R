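#' Unitary excitatory post-synaptic conductance kernel
#'
#' Double-exponential conductance waveform
#' `g_syn(t) = 125.25 (exp(-t/0.18) - exp(-t/0.1))` nS for `t > 0` and zero
#' otherwise (t in ms).  The amplitude coefficient is set so that a single
#' unitary event depolarizes the soma compartment by roughly 6 mV.
#'
#' @param t Time since event onset, ms (vectorized).
#' @param amplitude Amplitude coefficient, nS.
#' @param tau_decay,tau_rise Decay and rise time constants, ms.
#' @return Conductance in nS.
#' @examples
#' epsg_kernel(0.1323)  # near the kernel peak, ~26.7 nS
#' @export
epsg_kernel <- function(t, amplitude = 125.25, tau_decay = 0.18,
                        tau_rise = 0.1) {
  ifelse(t > 0, amplitude * (exp(-t / tau_decay) - exp(-t / tau_rise)), 0)
}

#' Superpose EPSG events into a conductance waveform
#'
#' Returns a function of time giving the linear superposition of scaled,
#' shifted unitary kernels: one kernel per event, each multiplied by its
#' scale (in units of the unitary amplitude).
#'
#' @param times Event onset times, ms.
#' @param scales Event amplitudes in units of the unitary kernel; recycled to
#'   the length of `times`.
#' @return A vectorized function `g(t)` in nS.
#' @examples
#' g <- conductance_train(c(5, 5), c(1, 1))  # two simultaneous unitary events
#' g(5.1323)                                 # pointwise twice the kernel
#' @export
conductance_train <- function(times, scales = 1) {
  stopifnot(is.numeric(times), all(times >= 0))
  scales <- rep_len(scales, length(times))
  function(t) {
    vapply(t, function(tt) {
      sum(scales * epsg_kernel(tt - times))
    }, numeric(1))
  }
}

#' Stimulus constructors
#'
#' Stimuli are lightweight classed lists consumed by [simulate.two_cpt_model()].
#' `stim_zero()` is no input; `stim_step()` a constant current step;
#' `stim_ramp()` a linear current ramp held at its peak; `stim_epsg()` a train
#' of excitatory synaptic conductance events delivered to the soma
#' compartment.  Positive injected current depolarizes; synaptic events enter
#' as a conductance times the driving force `(V1 - Esyn)`.
#'
#' @param amplitude Step amplitude, pA.
#' @param onset Stimulus onset time, ms.
#' @param duration Step duration, ms.
#' @param slope Ramp slope, pA/ms (must be positive).
#' @param peak Ramp plateau amplitude, pA.
#' @param times EPSG event onset times, ms.
#' @param scales EPSG event amplitudes in units of the unitary kernel.
#' @return An object of class `"stimulus"`.
#' @name stimulus
#' @examples
#' stim_step(2500, onset = 5, duration = 200)
#' stim_epsg(times = c(5, 5))   # a pair of simultaneous unitary events
NULL

#' @rdname stimulus
#' @export
stim_zero <- function() {
  structure(list(kind = "zero"), class = "stimulus")
}

#' @rdname stimulus
#' @export
stim_step <- function(amplitude, onset = 5, duration = 200) {
  stopifnot(is.finite(amplitude), onset >= 0, duration > 0)
  structure(list(kind = "step", amplitude = amplitude, onset = onset,
                 duration = duration), class = "stimulus")
}

#' @rdname stimulus
#' @export
stim_ramp <- function(slope, peak = 2500, onset = 5) {
  stopifnot(is.finite(slope), is.finite(peak), onset >= 0)
  if (slope <= 0) stop("'slope' must be positive (pA/ms)")
  structure(list(kind = "ramp", slope = slope, peak = peak, onset = onset),
            class = "stimulus")
}

#' @rdname stimulus
#' @export
stim_epsg <- function(times, scales = 1) {
  stopifnot(is.numeric(times), all(is.finite(times)), all(times >= 0))
  scales <- rep_len(scales, length(times))
  structure(list(kind = "epsg", times = as.numeric(times),
                 scales = as.numeric(scales)), class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  switch(x$kind,
    zero = cat("Stimulus: none\n"),
    step = cat(sprintf("Stimulus: current step %g pA, onset %g ms, duration %g ms\n",
                       x$amplitude, x$onset, x$duration)),
    ramp = cat(sprintf("Stimulus: current ramp %g pA/ms to %g pA, onset %g ms\n",
                       x$slope, x$peak, x$onset)),
    epsg = cat(sprintf("Stimulus: %d EPSG event(s), scales in [%g, %g]\n",
                       length(x$times), min(x$scales), max(x$scales))))
  invisible(x)
}

#' Injected-current waveform of a stimulus
#'
#' Evaluates the injected-current component (step or ramp) of a stimulus as a
#' function of time; synaptic stimuli carry no injected current.
#'
#' @param stim A stimulus object.
#' @param t Times, ms (vectorized).
#' @return Current in pA.
#' @export
stim_current <- function(stim, t) {
  stopifnot(inherits(stim, "stimulus"))
  switch(stim$kind,
    step = ifelse(t >= stim$onset & t < stim$onset + stim$duration,
                  stim$amplitude, 0),
    ramp = ifelse(t < stim$onset, 0,
                  pmin(stim$slope * (t - stim$onset), stim$peak)),
    rep(0, length(t)))
}

# von Mises concentration giving a target vector strength: VS = I1(k)/I0(k)
vm_concentration <- function(vs) {
  stopifnot(vs > 0, vs < 1)
  f <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE) - vs
  stats::uniroot(f, c(1e-6, 500), tol = 1e-10)$root
}

# Default phase-locking targets: vector strength per frequency (Hz).
# Linear interpolation between tabulated values 0.8 at 200 Hz down to
# 0.55 at 700 Hz, emulating the degradation of phase locking with frequency.
default_vs_target <- function(freq) {
  stats::approx(x = seq(200, 700, by = 100),
                y = c(0.8, 0.75, 0.7, 0.65, 0.6, 0.55),
                xout = freq, rule = 2)$y
}

# Dead-time-corrected driving rate: find the base rate (sp/ms) whose
# refractory-thinned output matches the target.  First-order correction for
# an inhomogeneous Poisson process with absolute dead time d: the expected
# intensity mass in the dead window after a spike is computed with the spike
# phase density, generalizing R_out = lambda/(1 + lambda*d).
compensated_rate <- function(target_rate, freq, kappa, dead) {
  if (dead <= 0) return(target_rate)
  period <- 1000 / freq
  th <- seq(0, period, length.out = 201)[-201]
  rel <- exp(kappa * cos(2 * pi * th / period)) /
    besselI(kappa, 0, expon.scaled = FALSE)
  # mass of relative intensity in (th, th + dead), spike-phase weighted
  mass <- vapply(th, function(t0) {
    s <- seq(t0, t0 + dead, length.out = 25)
    mean(exp(kappa * cos(2 * pi * s / period)) /
           besselI(kappa, 0, expon.scaled = FALSE)) * dead
  }, numeric(1))
  d_eff <- sum(rel * mass) / sum(rel)
  f <- function(lam) lam / (1 + lam * d_eff) - target_rate
  if (target_rate * d_eff >= 1)
    stop("target rate unattainable under the refractory gap")
  stats::uniroot(f, c(target_rate, 5 * target_rate), extendInt = "upX",
                 tol = 1e-12)$root
}

#' Synthetic phase-locked afferent spike trains
#'
#' Generates independent auditory-nerve-like spike trains for the two "ears":
#' `n_fibers` fibers per side, each an inhomogeneous point process with a
#' von Mises-modulated rate `r(t) \propto exp(kappa cos(2 pi f t - phi))`,
#' normalized to the target mean rate, generated by Lewis thinning and then
#' thinned by an absolute refractory gap.  The second side is delayed by
#' `side_delay` ms (0 for coincident input, half the stimulus period for
#' anti-phase input, 0.5 ms for the fixed-delay condition).  The driving rate
#' is corrected for refractory losses so the delivered mean rate matches the
#' target.
#'
#' This generator is a documented synthetic stand-in for a full
#' auditory-periphery model: it preserves phase locking that degrades with
#' frequency and fiber independence, not cochlear filtering or level
#' dependence.
#'
#' @param freq Stimulus frequency, Hz (nominal range 200-700).
#' @param duration Train duration, ms.
#' @param n_fibers Fibers per side.
#' @param side_delay Delay applied to side B spike times, ms.
#' @param mean_rate Target mean firing rate per fiber, spikes/s.
#' @param vs_target Target vector strength; default interpolates the built-in
#'   frequency schedule (0.8 at 200 Hz to 0.55 at 700 Hz).
#' @param refractory Absolute refractory gap per fiber, ms.
#' @param seed Integer master seed (required: generation is deterministic
#'   given the seed, with independent per-fiber substreams).
#' @return An object of class `"afferent_trains"`: list with `side_a` and
#'   `side_b` (lists of per-fiber spike-time vectors) plus the generation
#'   parameters.
#' @examples
#' tr <- phase_locked_trains(500, duration = 100, seed = 1)
#' vector_strength(tr$side_a[[1]], 500)
#' @export
phase_locked_trains <- function(freq, duration, n_fibers = 5, side_delay = 0,
                                mean_rate = 200, vs_target = NULL,
                                refractory = 0.75, seed) {
  if (missing(seed)) stop("'seed' is required for reproducible trains")
  if (duration <= 0) stop("'duration' must be positive")
  if (mean_rate <= 0) stop("'mean_rate' must be positive")
  if (is.null(vs_target)) vs_target <- default_vs_target(freq)
  kappa <- vm_concentration(vs_target)
  rate_ms <- mean_rate / 1000                      # sp/ms
  lam0 <- compensated_rate(rate_ms, freq, kappa, refractory)
  period <- 1000 / freq
  lmax <- lam0 * exp(kappa) / besselI(kappa, 0, expon.scaled = FALSE)

  gen_fiber <- function(sub_seed, t_extra) {
    # own RNG substream; generation window padded so delayed trains still
    # cover [0, duration]
    set.seed(sub_seed)
    tmax <- duration + t_extra
    n_cand <- stats::rpois(1, lmax * tmax)
    cand <- sort(stats::runif(n_cand, 0, tmax))
    lam <- lam0 * exp(kappa * cos(2 * pi * cand / period)) /
      besselI(kappa, 0, expon.scaled = FALSE)
    keep <- stats::runif(n_cand) < lam / lmax
    sp <- cand[keep]
    # absolute refractory gap
    if (length(sp) > 1) {
      out <- sp[1]
      for (s in sp[-1]) if (s - out[length(out)] >= refractory) out <- c(out, s)
      sp <- out
    }
    sp
  }

  sub_seed <- function(i) as.integer((as.numeric(seed) + 104729 * i) %% 2147483647)
  side_a <- lapply(seq_len(n_fibers), function(i) {
    sp <- gen_fiber(sub_seed(i), 0)
    sp[sp <= duration]
  })
  side_b <- lapply(seq_len(n_fibers), function(i) {
    sp <- gen_fiber(sub_seed(i + n_fibers), 0) + side_delay
    sp[sp >= 0 & sp <= duration]
  })
  structure(list(side_a = side_a, side_b = side_b, freq = freq,
                 duration = duration, n_fibers = n_fibers,
                 side_delay = side_delay, mean_rate = mean_rate,
                 vs_target = vs_target, kappa = kappa,
                 refractory = refractory, seed = seed),
            class = "afferent_trains")
}

#' @export
print.afferent_trains <- function(x, ...) {
  n_a <- sum(lengths(x$side_a)); n_b <- sum(lengths(x$side_b))
  cat(sprintf("Afferent trains: %g Hz, %g ms, %d fibers/side, delay %g ms\n",
              x$freq, x$duration, x$n_fibers, x$side_delay))
  cat(sprintf("  %d spikes side A, %d spikes side B (target %g sp/s, VS %.2f)\n",
              n_a, n_b, x$mean_rate, x$vs_target))
  invisible(x)
}

#' Vector strength of spike times
#'
#' Circular-statistics measure of phase locking:
#' `VS = |sum(exp(i theta_j))| / N` with `theta_j = 2 pi f t_j`.
#'
#' @param times Spike times, ms.
#' @param freq Stimulus frequency, Hz.
#' @return Vector strength in \[0, 1\] (NA for empty input).
#' @export
vector_strength <- function(times, freq) {
  if (length(times) == 0) return(NA_real_)
  th <- 2 * pi * freq * times / 1000
  sqrt(sum(cos(th))^2 + sum(sin(th))^2) / length(times)
}

#' Convert afferent trains to an EPSG stimulus
#'
#' Pools all fibers of both sides into a single train of unitary (or scaled)
#' conductance events delivered to the soma compartment.
#'
#' @param trains An [phase_locked_trains()] result.
#' @param scale Amplitude of each event in units of the unitary kernel.
#' @param offset Time added to all events, ms (stimulus onset).
#' @return A `"stimulus"` of kind `"epsg"`.
#' @export
stim_from_trains <- function(trains, scale = 1, offset = 0) {
  stopifnot(inherits(trains, "afferent_trains"))
  times <- sort(c(unlist(trains$side_a), unlist(trains$side_b))) + offset
  stim_epsg(times, scale)
}

#' Half-period delay for anti-phase input
#'
#' @param freq Stimulus frequency, Hz.
#' @return Half the stimulus period, ms.
#' @export
antiphase_delay <- function(freq) 500 / freq
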
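# ---- shared helpers -------------------------------------------------------

with_gna <- function(model, gna) { model$gna <- gna; model }

derive_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 + i) %% 2147483647)
}

spike_count <- function(model, stimulus, duration, ...) {
  length(simulate(model, stimulus = stimulus, duration = duration, ...)$spike_times)
}

# Bisection for the smallest gNa at which `predicate(gna)` becomes TRUE,
# assuming monotonicity.  Returns the upper (TRUE) end of the final bracket.
bisect_gna <- function(predicate, gna_start = 500, gna_max = 1e5,
                       rel_tol = 0.005) {
  hi <- gna_start
  while (!predicate(hi)) {
    hi <- hi * 2
    if (hi > gna_max)
      stop("no spike up to the gNa search ceiling (", gna_max, " nS)")
  }
  lo <- 0
  while ((hi - lo) / hi > rel_tol) {
    mid <- (hi + lo) / 2
    if (predicate(mid)) hi <- mid else lo <- mid
  }
  hi
}

# ---- gNa reference --------------------------------------------------------

#' Reference sodium conductance
#'
#' Finds `gNa_ref`: the smallest sodium conductance at which a pair of
#' simultaneous unitary EPSG events delivered to the soma compartment evokes
#' a spike.  This value anchors all normalized sodium-conductance sweeps: at
#' `gNa_ref` the model fires only to coincident pairs, which is the operating
#' point of a coincidence detector.  Found by bisection on the deterministic
#' paired-EPSG stimulus; the returned threshold is validated by simulating at
#' 1 percent above (spike) and below (no spike).
#'
#' @param model A [two_cpt_model()] (its `gna` field is ignored).
#' @param rel_tol Relative bisection tolerance.
#' @param gna_max Search ceiling, nS; exceeding it is an error.
#' @param onset EPSG onset time, ms.
#' @param duration Simulated time, ms.
#' @param validate Check the returned bracket by +/- 1 percent simulations.
#' @return `gNa_ref` in nS.
#' @examples
#' \donttest{
#' find_gna_ref(two_cpt_model(coupling(0.8, 0.2)))  # forward-coupled model
#' }
#' @export
find_gna_ref <- function(model, rel_tol = 0.005, gna_max = 1e5, onset = 5,
                         duration = 15, validate = TRUE) {
  stopifnot(inherits(model, "two_cpt_model"))
  stim <- stim_epsg(c(onset, onset), 1)     # two simultaneous unitary events
  pred <- function(g) spike_count(with_gna(model, g), stim, duration) >= 1
  ref <- bisect_gna(pred, gna_start = 500, gna_max = gna_max,
                    rel_tol = rel_tol)
  if (validate) {
    if (!pred(ref * 1.01) || pred(ref * 0.99))
      stop("gNa_ref bracket failed validation at +/- 1 percent")
  }
  ref
}

# ---- coincidence-detection sensitivity ------------------------------------

#' Firing rates over repeated stochastic trials
#'
#' Simulates responses to synthetic phase-locked afferent input over repeated
#' trials (fresh spike trains per trial, deterministic per-trial substreams
#' derived from the master seed) and returns the per-trial firing rates in
#' spikes/s.
#'
#' @param model A [two_cpt_model()] with its `gna` set.
#' @param freq Stimulus frequency, Hz.
#' @param side_delay Delay of the second ear's input, ms.
#' @param n_trials Number of repeated trials.
#' @param duration Spike-counting window, ms.
#' @param seed Master seed.
#' @param seed_offset Substream block offset (distinct blocks give
#'   independent ensembles).
#' @param n_fibers,mean_rate,vs_target,refractory Passed to
#'   [phase_locked_trains()].
#' @param onset Stimulus onset, ms.
#' @return Numeric vector of length `n_trials`, firing rates in spikes/s.
#' @export
firing_rate_trials <- function(model, freq, side_delay = 0, n_trials = 100,
                               duration = 250, seed, seed_offset = 0,
                               n_fibers = 5, mean_rate = 200,
                               vs_target = NULL, refractory = 0.75,
                               onset = 5) {
  stopifnot(inherits(model, "two_cpt_model"))
  vapply(seq_len(n_trials), function(i) {
    tr <- phase_locked_trains(freq, duration, n_fibers = n_fibers,
                              side_delay = side_delay,
                              mean_rate = mean_rate, vs_target = vs_target,
                              refractory = refractory,
                              seed = derive_seed(seed, seed_offset + i))
    s <- simulate(model, stimulus = stim_from_trains(tr, offset = onset),
                  duration = duration + onset + 5)
    length(s$spike_times) / duration * 1000
  }, numeric(1))
}

#' Coincidence-detection sensitivity
#'
#' ROC-style sweep: firing rates to coincident input (both ears in phase) and
#' non-coincident input (anti-phase, or a fixed 500 us inter-ear delay) are
#' measured across a grid of sodium conductances expressed as multiples of
#' `gNa_ref`.  Sensitivity is the maximum, over the `gNa` grid, of the mean
#' firing-rate difference (coincident minus non-coincident); the maximizing
#' `gNa` ("best gNa") is also reported.
#'
#' @param model A [two_cpt_model()] (its `gna` field is ignored).
#' @param freq Stimulus frequency, Hz.
#' @param noncoincident_mode `"antiphase"` (delay = half period) or
#'   `"delay_500us"` (fixed 0.5 ms delay).
#' @param gna_ref Reference conductance; computed by [find_gna_ref()] if
#'   omitted.
#' @param gna_sweep Grid of multipliers applied to `gna_ref`.
#' @param n_trials Trials per condition and `gna` value.
#' @param duration Spike-counting window per trial, ms.
#' @param seed Master seed.
#' @param ... Passed to [firing_rate_trials()] (fiber count, rates, ...).
#' @return An object of class `"coincidence_sweep"`: list with a per-`gna`
#'   data frame (`gna_mult`, `gna`, `rate_coinc`, `se_coinc`, `rate_noncoinc`,
#'   `se_noncoinc`, `diff`, `se_diff`), the scalar `sensitivity` (sp/s), its
#'   standard error, `best_gna_mult`, and the run metadata.
#' @export
coincidence_sensitivity <- function(model, freq,
                                    noncoincident_mode = c("antiphase",
                                                           "delay_500us"),
                                    gna_ref = NULL,
                                    gna_sweep = seq(0.2, 2.2, by = 0.05),
                                    n_trials = 100, duration = 250, seed,
                                    ...) {
  stopifnot(inherits(model, "two_cpt_model"))
  noncoincident_mode <- match.arg(noncoincident_mode)
  if (missing(seed)) stop("'seed' is required")
  if (is.null(gna_ref)) gna_ref <- find_gna_ref(model)
  delay_nc <- switch(noncoincident_mode,
                     antiphase = antiphase_delay(freq),
                     delay_500us = 0.5)

  rates <- function(side_delay, block) {
    vapply(gna_sweep, function(mult) {
      r <- firing_rate_trials(with_gna(model, mult * gna_ref), freq,
                              side_delay = side_delay, n_trials = n_trials,
                              duration = duration, seed = seed,
                              seed_offset = block * n_trials, ...)
      c(mean(r), stats::sd(r) / sqrt(n_trials))
    }, numeric(2))
  }
  rc <- rates(0, 0)
  rn <- rates(delay_nc, 1)
  tab <- data.frame(gna_mult = gna_sweep, gna = gna_sweep * gna_ref,
                    rate_coinc = rc[1, ], se_coinc = rc[2, ],
                    rate_noncoinc = rn[1, ], se_noncoinc = rn[2, ])
  tab$diff <- tab$rate_coinc - tab$rate_noncoinc
  tab$se_diff <- sqrt(tab$se_coinc^2 + tab$se_noncoinc^2)
  best <- which.max(tab$diff)
  structure(list(table = tab, sensitivity = tab$diff[best],
                 se = tab$se_diff[best], best_gna_mult = tab$gna_mult[best],
                 gna_ref = gna_ref, freq = freq,
                 noncoincident_mode = noncoincident_mode,
                 n_trials = n_trials, duration = duration, seed = seed),
            class = "coincidence_sweep")
}

#' @export
print.coincidence_sweep <- function(x, ...) {
  cat(sprintf("Coincidence sweep: %g Hz, %s, %d trials x %d gNa values\n",
              x$freq, x$noncoincident_mode, x$n_trials, nrow(x$table)))
  cat(sprintf("  sensitivity (max rate difference) = %.1f +/- %.1f sp/s at gNa = %.2f x gNa_ref\n",
              x$sensitivity, x$se, x$best_gna_mult))
  invisible(x)
}

# ---- tonic/phasic classification ------------------------------------------

#' Classify the response to a current step
#'
#' Simulates a constant current step and labels the firing pattern:
#' `"quiescent"` (no spikes), `"tonic"` (at least `tonic_min_spikes` spikes
#' with the last spike in the final third of the step, i.e. sustained
#' repetitive firing), otherwise `"phasic"` (firing confined to the onset;
#' the canonical phasic response is a single onset spike within the first
#' `phasic_window` ms).
#'
#' @param model A [two_cpt_model()] with `gna` set.
#' @param I_step Step amplitude, pA.
#' @param step_duration Step duration, ms.
#' @param onset Step onset, ms.
#' @param phasic_window Onset window used for the phasic label, ms.
#' @param tonic_min_spikes Minimum spike count for the tonic label.
#' @return A character label: `"quiescent"`, `"phasic"` or `"tonic"`.
#' @export
classify_firing_pattern <- function(model, I_step, step_duration = 200,
                                    onset = 5, phasic_window = 25,
                                    tonic_min_spikes = 5) {
  stopifnot(inherits(model, "two_cpt_model"))
  s <- simulate(model, stimulus = stim_step(I_step, onset, step_duration),
                duration = onset + step_duration)
  sp <- s$spike_times - onset
  sp <- sp[sp >= 0]
  if (length(sp) == 0) return("quiescent")
  if (length(sp) >= tonic_min_spikes && max(sp) >= (2 / 3) * step_duration)
    return("tonic")
  "phasic"
}

#' Lowest sodium conductance admitting tonic firing
#'
#' Sweeps step amplitudes and bisects over `gNa` for the smallest value at
#' which any step amplitude in the grid elicits sustained repetitive (tonic)
#' firing.  This simulation-based boundary stands in for a numerical
#' continuation of the Hopf bifurcation: the tonic region in the
#' (amplitude, gNa) plane is U-shaped, and its lowest point is `gNa_tonic`.
#'
#' @param model A [two_cpt_model()] (its `gna` field is ignored).
#' @param gna_ref Reference conductance for normalization and as the
#'   bisection starting point; computed if omitted.
#' @param amp_grid Step amplitudes scanned at each `gNa`, pA.  Default: 41
#'   log-spaced points over 100-10000 pA.
#' @param rel_tol Relative bisection tolerance on `gNa`.
#' @param gna_max Search ceiling, nS.
#' @param ... Passed to [classify_firing_pattern()].
#' @return A list with `gna_tonic` (nS), `ratio` (`gna_tonic/gna_ref`), and
#'   `gna_ref`.
#' @export
find_gna_tonic <- function(model, gna_ref = NULL,
                           amp_grid = exp(seq(log(100), log(10000),
                                              length.out = 41)),
                           rel_tol = 0.02, gna_max = 1e5, ...) {
  stopifnot(inherits(model, "two_cpt_model"))
  if (is.null(gna_ref)) gna_ref <- find_gna_ref(model)
  tonic_possible <- function(g) {
    m <- with_gna(model, g)
    for (amp in amp_grid)
      if (classify_firing_pattern(m, amp, ...) == "tonic") return(TRUE)
    FALSE
  }
  gt <- bisect_gna(tonic_possible, gna_start = gna_ref, gna_max = gna_max,
                   rel_tol = rel_tol)
  list(gna_tonic = gt, ratio = gt / gna_ref, gna_ref = gna_ref)
}

# ---- slope sensitivity ----------------------------------------------------

#' Sodium threshold for a current ramp
#'
#' Bisects for the smallest `gNa` at which a linear current ramp of the given
#' slope (rising to `peak` pA and holding) evokes at least one spike.
#'
#' @param model A [two_cpt_model()] (its `gna` field is ignored).
#' @param slope Ramp slope, pA/ms.
#' @param peak Ramp plateau, pA.
#' @param onset Ramp onset, ms.
#' @param rel_tol Relative bisection tolerance.
#' @param gna_max Search ceiling, nS.
#' @return Threshold `gNa` in nS.
#' @export
ramp_threshold_gna <- function(model, slope, peak = 2500, onset = 5,
                               rel_tol = 0.005, gna_max = 1e5) {
  stopifnot(inherits(model, "two_cpt_model"))
  stim <- stim_ramp(slope, peak, onset)
  duration <- onset + peak / slope + 15
  pred <- function(g) spike_count(with_gna(model, g), stim, duration) >= 1
  bisect_gna(pred, gna_start = 500, gna_max = gna_max, rel_tol = rel_tol)
}

#' Slope sensitivity
#'
#' `delta_gna` is the ratio of threshold sodium conductances for a slow
#' (500 pA/ms) versus a fast (1000 pA/ms) current ramp to the same 2500 pA
#' plateau.  Values near 1 mean the model fires regardless of input slope;
#' large values mean the model can be tuned (by choosing `gNa` between the
#' two thresholds) to fire selectively to fast-rising inputs.
#'
#' @param model A [two_cpt_model()] (its `gna` field is ignored).
#' @param slow,fast The two ramp slopes, pA/ms.
#' @param peak Ramp plateau, pA.
#' @param ... Passed to [ramp_threshold_gna()].
#' @return A list with `delta_gna`, `threshold_slow`, `threshold_fast` (nS).
#' @export
delta_gna <- function(model, slow = 500, fast = 1000, peak = 2500, ...) {
  ts <- ramp_threshold_gna(model, slow, peak = peak, ...)
  tf <- ramp_threshold_gna(model, fast, peak = peak, ...)
  list(delta_gna = ts / tf, threshold_slow = ts, threshold_fast = tf)
}

# ---- refractory period ----------------------------------------------------

refractory_stim <- function(delay, onset = 5, scale = 3)
  stim_epsg(c(onset, onset + delay), scale)

# Do both EPSG events evoke their own spike?  Requires a spike between the
# two event onsets, a spike within `window` ms after the second onset, and
# no spike in that window in a first-event-only control (so that repetitive
# firing triggered by the first event at large gNa does not masquerade as a
# response to the second event).
both_spikes_causal <- function(model, gna, delay, onset = 5, scale = 3,
                               window = 3) {
  m <- with_gna(model, gna)
  duration <- onset + delay + window + 5
  t2 <- onset + delay
  sp <- simulate(m, stimulus = refractory_stim(delay, onset, scale),
                 duration = duration)$spike_times
  if (!any(sp > onset & sp <= t2 + 0.1)) return(FALSE)
  if (!any(sp > t2 & sp <= t2 + window)) return(FALSE)
  ctrl <- simulate(m, stimulus = stim_epsg(onset, scale),
                   duration = duration)$spike_times
  !any(ctrl > t2 & ctrl <= t2 + window)
}

#' Refractory period from paired EPSG events
#'
#' Delivers two suprathreshold EPSG events (each `epsg_scale` times the
#' unitary amplitude) separated by a variable delay and finds the smallest
#' delay at which both events evoke spikes; a spike is attributed to the
#' second event only if it follows that event and is absent from a
#' single-event control.
#'
#' Two measures are provided.  The default, `mode = "threshold"`, is the
#' left-most point of the delay-threshold curve (see
#' [delay_threshold_curve()]): the smallest delay at which *some* sodium
#' conductance (searched up to `gna_cap` times `gna_ref`) lets both events
#' spike.  `mode = "fixed"` holds `gNa` at `gna_ref` (the measure used for
#' parameter-space maps); it gives systematically longer values because the
#' reference conductance leaves no headroom for the partially inactivated
#' second response.
#'
#' @param model A [two_cpt_model()] (its `gna` field is ignored).
#' @param gna_ref Reference sodium conductance; computed by [find_gna_ref()]
#'   if omitted.
#' @param epsg_scale EPSG amplitude in units of the unitary kernel.
#' @param mode `"threshold"` or `"fixed"` (see Details).
#' @param gna_cap Upper end of the existence search in `mode = "threshold"`,
#'   as a multiple of `gna_ref`.  Far above the reference value the model
#'   stops operating as a coincidence detector (repetitive firing), so the
#'   search stays within a five-fold range by default.
#' @param delay_range Scanned delay interval, ms.
#' @param delay_tol Bisection tolerance on the delay, ms.
#' @param onset First-event onset, ms.
#' @return The refractory period in ms.
#' @export
refractory_period <- function(model, gna_ref = NULL, epsg_scale = 3,
                              mode = c("threshold", "fixed"), gna_cap = 5,
                              delay_range = c(0.1, 5), delay_tol = 0.01,
                              onset = 5) {
  stopifnot(inherits(model, "two_cpt_model"))
  mode <- match.arg(mode)
  if (is.null(gna_ref)) gna_ref <- find_gna_ref(model)
  fires_at <- if (mode == "fixed") {
    function(d) both_spikes_causal(model, gna_ref, d, onset, epsg_scale)
  } else {
    # existence over a log grid of gNa in [1, gna_cap] x gna_ref
    gna_grid <- gna_ref * exp(seq(0, log(gna_cap), length.out = 25))
    function(d) {
      for (g in gna_grid)
        if (both_spikes_causal(model, g, d, onset, epsg_scale)) return(TRUE)
      FALSE
    }
  }
  delays <- seq(delay_range[1], delay_range[2], by = 0.2)
  hit <- which(vapply(delays, fires_at, logical(1)))
  if (length(hit) == 0)
    stop("no second spike up to a delay of ", delay_range[2], " ms")
  hi <- delays[hit[1]]
  if (hit[1] == 1) return(hi)
  lo <- delays[hit[1] - 1]
  while (hi - lo > delay_tol) {
    mid <- (hi + lo) / 2
    if (fires_at(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Threshold sodium conductance versus inter-event delay
#'
#' For each delay between two `epsg_scale`-times-unitary EPSG events, bisects
#' for the smallest `gNa` at which both events evoke spikes (causal
#' criterion, see [refractory_period()]).  The curve is nonincreasing in the
#' delay: longer recovery lowers the conductance needed for the second
#' spike.  Its left-most finite point is the refractory period.
#'
#' @param model A [two_cpt_model()] (its `gna` field is ignored).
#' @param delays Delays to probe, ms.
#' @param epsg_scale EPSG amplitude in units of the unitary kernel.
#' @param onset First-event onset, ms.
#' @param rel_tol Relative bisection tolerance.
#' @param gna_max Search ceiling, nS.
#' @return A data frame with columns `delay` (ms) and `threshold_gna` (nS;
#'   NA where no conductance up to the ceiling works).
#' @export
delay_threshold_curve <- function(model, delays = seq(0.5, 5, by = 0.5),
                                  epsg_scale = 3, onset = 5,
                                  rel_tol = 0.005, gna_max = NULL) {
  stopifnot(inherits(model, "two_cpt_model"))
  if (is.null(gna_max)) gna_max <- 5 * find_gna_ref(model)
  thr <- vapply(delays, function(d) {
    pred <- function(g) both_spikes_causal(model, g, d, onset, epsg_scale)
    tryCatch(bisect_gna(pred, gna_start = gna_max / 8, gna_max = gna_max,
                        rel_tol = rel_tol),
             error = function(e) NA_real_)
  }, numeric(1))
  data.frame(delay = delays, threshold_gna = thr)
}

# ---- parameter-space sweep ------------------------------------------------

#' Run a protocol across a grid of coupling configurations
#'
#' Applies a protocol function to the model built at every grid point and
#' collects scalar results into one tidy table.  Per-cell failures are
#' recorded in an `error` column rather than aborting the sweep.  Ordering
#' follows the grid and is deterministic.
#'
#' @param grid A data frame with columns `kfwd`, `kback` (see
#'   [coupling_grid()]).
#' @param protocol A function taking a `two_cpt_model` and returning a named
#'   list (or single named numeric) of scalar outcomes.
#' @param spec Passive cell specification used for every model.
#' @param ... Passed to [two_cpt_model()] (KLT settings etc.).
#' @return A data frame: `kfwd`, `kback`, one column per outcome, and
#'   `error` (NA when the cell succeeded).
#' @examples
#' \donttest{
#' g <- coupling_grid(0.3, c(0.2, 0.8))
#' parameter_space_sweep(g, function(m) list(gna_ref = find_gna_ref(m)))
#' }
#' @export
parameter_space_sweep <- function(grid, protocol, spec = mso_cell_spec(),
                                  ...) {
  stopifnot(is.data.frame(grid), all(c("kfwd", "kback") %in% names(grid)))
  if (nrow(grid) == 0L)
    return(data.frame(kfwd = numeric(0), kback = numeric(0),
                      error = character(0)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    kf <- grid$kfwd[i]; kb <- grid$kback[i]
    res <- tryCatch({
      m <- two_cpt_model(coupling(kf, kb), spec = spec, ...)
      out <- protocol(m)
      c(list(kfwd = kf, kback = kb), as.list(out), list(error = NA_character_))
    }, error = function(e) {
      list(kfwd = kf, kback = kb, error = conditionMessage(e))
    })
    as.data.frame(res, stringsAsFactors = FALSE)
  })
  # failed cells lack outcome columns: fill with NA before binding
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(cols, names(r))) r[[cc]] <- NA
    r[cols]
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
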
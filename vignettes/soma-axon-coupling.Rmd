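---
title: "Two-compartment soma-axon models of coincidence detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-compartment soma-axon models of coincidence detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaxon)
```

## The scientific problem

Principal neurons of the medial superior olive (MSO) signal the azimuthal
location of a sound by firing preferentially when synaptic volleys driven by
the two ears arrive within a few hundred microseconds of each other.  How
well a neuron can perform this coincidence-detection task depends not only on
its ion channels but on its electrical architecture: how strongly the
synaptic input region (soma and dendrites) is coupled to the spike initiation
zone (axon initial segment), and how strongly spikes couple back.

`somaxon` implements a minimal model of this architecture: two isopotential
compartments, a large passive input compartment (Cpt1) and a small excitable
output compartment (Cpt2), joined by an axial conductance.  The family of
models is parameterized by two dimensionless coupling strengths, and is
constructed so that the passive behaviour of the soma compartment is the same
for every member of the family.  That invariance is the crux of the design:
when a spiking or coincidence-detection property changes across the family,
the change is attributable to the coupling configuration and not to a
confounded change in somatic excitability.

## The model

State variables are the compartment voltages $V_1, V_2$ (mV), the sodium
inactivation gate $h$, and (when KLT is dynamic) the KLT activation gates
$w_1, w_2$:

$$
\begin{aligned}
c_1 V_1' &= -g_1 (V_1 - E_{lk}) - g_c (V_1 - V_2) - I_{KLT,1}
            - g_{syn}(t)\,(V_1 - E_{syn}) + I_{app}(t) \\
c_2 V_2' &= -g_2 (V_2 - E_{lk}) - g_c (V_2 - V_1) - I_{KLT,2} - I_{Na}
\end{aligned}
$$

with first-order kinetics for each gate,
$x' = (x_\infty(V) - x)/\tau_x(V)$.  Units are mV, ms, nS, pA, pF throughout
(nS·mV = pA and pF·mV/ms = pA), converted once at the construction boundary;
the input resistance is entered in MΩ and becomes $10^3/R_{in}$ nS.

Synaptic input and injected current both target Cpt1.  Positive injected
current depolarizes; synaptic events enter as a conductance times the
driving force $(V_1 - E_{syn})$ with $E_{syn} = 0$ mV, so they are
depolarizing from rest.  These two sign conventions are deliberate and are
exercised by the current-step and ramp protocols.

### Coupling parameterization

Forward coupling $\kappa_{1\to2} = g_c/(g_2 + g_c)$ is the steady-state
attenuation $U_2/U_1$ for current into Cpt1 (deviations $U_i = V_i -
E_{lk}$); backward coupling $\kappa_{2\to1} = g_c/(g_1 + g_c)$ is $U_1/U_2$
for current into Cpt2.  Given measured somatic properties ($R_{in}$,
$\tau_{exp}$, $V_{rest} = E_{lk}$), an area ratio $\alpha = A_2/A_1$, and a
coupling pair, the construction inverts these relations:

$$
g_c = \frac{\kappa_{2\to1}}{R_{in}(1 - \kappa_{1\to2}\kappa_{2\to1})},\quad
g_1 = g_c\!\left(\tfrac{1}{\kappa_{2\to1}} - 1\right),\quad
g_2 = g_c\!\left(\tfrac{1}{\kappa_{1\to2}} - 1\right),
$$
$$
c_1 = \tau_{exp}\,(1 - \kappa_{1\to2}\kappa_{2\to1})(g_1 + g_c),\qquad
c_2 = \alpha c_1 .
$$

Two consequences are algebraic identities and are enforced by tests: the
steady-state input resistance at Cpt1 equals $R_{in}$ for every admissible
coupling pair, and $c_1 = \tau_{exp}/R_{in}$ independent of coupling (40 pF
for the default MSO values $R_{in} = 8.5$ MΩ, $\tau_{exp} = 0.34$ ms).  With
$C_m = 0.9$ μF/cm² the implied soma area is 4444 μm².  (Specific capacitance
is interpreted in μF/cm², the unit consistent with a 40 pF soma of that
area.)

The family is restricted to $\kappa_{1\to2} \ge \kappa_{2\to1}$ (forward
propagation at least as strong as backpropagation, as observed in MSO cells)
and $\kappa_{1\to2}/\kappa_{2\to1} \le 10$.  The second restriction keeps
the time-scale ratio $\tau_2/\tau_1 = \alpha\,\kappa_{1\to2}/\kappa_{2\to1}$
at or below $10\alpha$, preserving the separation between slow somatic and
fast axonal dynamics on which the phase-plane analysis relies.  (The
literature uses the symbol $\epsilon$ both for this ratio and for the
product form $\alpha\kappa_{1\to2}\kappa_{2\to1}$; `timescale_ratio()`
implements the ratio form, which is the one consistent with "ratio of time
constants", and uses it for the admissibility restriction.)

Three named configurations recur throughout: *weakly-coupled* (0.3, 0.2),
*forward-coupled* (0.8, 0.2) and *strongly-coupled* (0.8, 0.7).

```{r named-models}
m <- two_cpt_model(coupling(0.8, 0.2))
summary(m)
```

### Ion channels

**Sodium** (Cpt2 only): $I_{Na} = g_{Na} m_\infty^3(V_2)\, h\, (V_2 -
E_{Na})$ minus a constant chosen so $I_{Na} = 0$ at rest, with $E_{Na} = 55$
mV.  Activation is instantaneous; inactivation $h$ has
$h_\infty(V) = [1 + e^{(V+65)/6}]^{-1}$ and a bell-shaped $\tau_h$ (35 °C
kinetics).  The rest-correction term means adding sodium conductance never
moves the resting potential, so the resting state is an exact equilibrium
for every $g_{Na}$ — a property the test suite checks to machine precision.

The activation midpoint and slope are not uniquely pinned down by the
measured quantities this package targets, so $m_\infty$ is exposed as a
configurable Boltzmann curve, $m_\infty(V) = [1 + e^{-(V - V_{1/2})/k}]^{-1}$
with defaults $V_{1/2} = -38$ mV, $k = 7$ mV from the Rothman–Manis lineage
of auditory brainstem models.  With these defaults the three reference
conductances computed by `find_gna_ref()` (see below) land within a fraction
of a percent of their published calibration values, so the defaults are left
untouched; the parameters remain available for recalibration against other
datasets.

**Low-threshold potassium (KLT)**: $I_{KLT} = g_{KLT} w^4
z_\infty(V_{rest}) (V - E_K)$ minus its resting value, with $E_K = -106$ mV.
The slow inactivation gate $z$ is always frozen at its resting steady state.
The activation steady state is taken as the *rising* sigmoid
$w_\infty(V) = [1 + e^{-(V+65)/6}]^{-1}$: an activation gate of an outward
current must open with depolarization to act as negative feedback (the
falling form that sometimes appears in print describes inactivation-like
curves and would make KLT a regenerative current).

KLT is introduced by replacing a fraction $f$ (default 10%) of a
compartment's leak conductance: `allocate_klt()` sets the new leak to
$(1-f) g_{lk}$ and sizes $g_{KLT}$ so that total resting conductance is
exactly preserved.  In **frozen** mode the activation gate is pinned at
$w_\infty(V_{rest})$; because $E_{lk} = V_{rest}$ in this model, the frozen
KLT current plus reduced leak is *algebraically identical* to the original
leak, so frozen-KLT models are implemented as (and tested to be,
within solver tolerance) the passive model.  In **dynamic** mode $w$ follows
its kinetics and provides voltage-gated negative feedback.

### Stimuli

* `stim_step()`, `stim_ramp()`: injected current into Cpt1.  Ramps rise
  linearly at a given slope to a plateau (default 2500 pA) and hold.
* `stim_epsg()`: trains of excitatory conductance events.  The unitary
  kernel is the double exponential
  $g_{syn}(t) = 125.25\,(e^{-t/0.18} - e^{-t/0.1})$ nS, whose amplitude
  produces a somatic depolarization of roughly 6 mV per unitary event in the
  passive model; events superpose linearly and scale multiplicatively (a
  scale-2 event is exactly two simultaneous unitary events).
* `phase_locked_trains()`: a synthetic stand-in for an auditory-periphery
  front end.  Each of 5 fibers per ear is an independent inhomogeneous point
  process with von Mises rate modulation
  $r(t) \propto e^{\kappa \cos(2\pi f t)}$, normalized to a 200 spikes/s
  mean rate, generated by Lewis thinning with an absolute refractory gap of
  0.75 ms.  The concentration $\kappa$ is chosen per frequency so that
  vector strength falls from 0.8 at 200 Hz to 0.55 at 700 Hz, emulating the
  degradation of phase locking with frequency.  The driving rate is
  corrected for refractory losses (a phase-weighted generalization of
  $R = \lambda/(1+\lambda d)$) so the delivered rate matches the target.
  The generator preserves what the coincidence analysis depends on —
  phase locking that worsens with frequency, fiber independence, ear delays
  — and deliberately omits cochlear filtering, level dependence and
  bushy-cell convergence.  Consequently the *absolute* firing-rate
  differences measured with it are not comparable to analyses built on a
  full periphery model; only orderings and trends across coupling
  configurations are, and the test suite asserts exactly those.

## Numerical integration

The system is stiff in the strong-forward-coupling corner
($\tau_2 \sim$ 10 μs against $\tau_1 = 0.34$ ms), so trajectories are
integrated with `deSolve::lsoda` (variable-step, variable-order, automatic
stiff/non-stiff switching) with `rtol = 1e-6`, `atol = 1e-8`.  The
right-hand side is compiled C.  Output is sampled every 10 μs; spike times
are upward crossings of $-20$ mV on $V_2$ with a 0.5 ms dead time, refined
by linear interpolation.  The $-20$ mV threshold separates spikes from
subthreshold activity in all coupling regimes ($V_2$ spike peaks range from
about 0 mV under strong forward coupling to about +40 mV under weak
coupling); both threshold and dead time are configurable.  Because synaptic
event onsets are kinks the step-size controller cannot anticipate, the
internal step is capped at 50 μs during synaptic stimuli (250 μs for
steps/ramps).  Tests verify that halving the tolerances moves spike times by
less than 1 μs, and that an independent plain-R implementation of the
right-hand side reproduces the compiled trajectories.

A `clamp_v1` mode holds $V_1$ fixed during integration.  It exists for
phase-plane diagnostics: the $(V_2, h)$ subsystem at clamped $V_1$ is
exactly the system whose nullclines `v2_nullcline()` computes.

## Measurement protocols

**Reference sodium conductance.** `find_gna_ref()` bisects for the smallest
$g_{Na}$ at which a pair of simultaneous unitary EPSGs evokes a spike
(relative tolerance 0.5%, bracket validated by simulating at ±1%).  At this
operating point the model spikes only for coincident input, which makes
$g_{Na}^{ref}$ the natural normalization for comparisons across coupling
configurations whose useful $g_{Na}$ ranges span orders of magnitude.

**Coincidence-detection sensitivity.** `coincidence_sensitivity()` sweeps
$g_{Na}$ over 0.2–2.2 × $g_{Na}^{ref}$ and measures firing rates (spike
count / 250 ms, mean ± SE over repeated trials) for coincident input and for
non-coincident input (anti-phase ears, or a fixed 500 μs delay).  Treating
the neuron as a detector of its own inputs, coincident-rate is the hit rate,
non-coincident-rate the false-alarm rate, and $g_{Na}$ the decision
threshold; sensitivity is the maximum rate difference over the sweep, and
the maximizing $g_{Na}$ is reported as the best operating point.  Per-trial
random substreams are derived from the master seed by index, so any trial is
reproducible in isolation and results do not depend on execution order.

**Tonic/phasic boundary.** `classify_firing_pattern()` labels a 200 ms step
response quiescent, phasic, or tonic (tonic: ≥ 5 spikes with the last in the
final third of the step; phasic: spiking confined to the 25 ms onset
window, with intermediate patterns folded into phasic since only the tonic
label enters the boundary search; both constants are configurable).
`find_gna_tonic()` bisects for the smallest $g_{Na}$ at which *any* step
amplitude in a 41-point log-spaced grid (100–10000 pA) yields tonic firing.
This simulation-based classification replaces a numerical continuation of
the underlying Hopf bifurcation; it locates the lowest point of the
U-shaped tonic region in the (amplitude, $g_{Na}$) plane to a 2% bisection
tolerance, which is well inside the 10% agreement expected of the boundary
ratios.

**Slope sensitivity.** `delta_gna()` is the ratio of threshold $g_{Na}$
values for a slow (500 pA/ms) versus fast (1000 pA/ms) ramp to 2500 pA.
Ratios near 1 mean slope-blind; large ratios mean an operating range of
$g_{Na}$ exists in which only fast-rising inputs fire the cell.

**Refractory period.** Two EPSGs, each three times unitary, are delivered
at a variable delay.  A response counts only if each event evokes its own
spike: one spike between the onsets, one within 3 ms after the second
onset, and no spike in that window when the first event is presented alone.
The causality control matters because far above $g_{Na}^{ref}$ the model
fires repetitively to a single strong event, which a bare two-spike count
would miscount as recovery.  The headline measure (`mode = "threshold"`) is
the left-most point of the delay–threshold curve: the smallest delay at
which both-event spiking is achievable by *some* $g_{Na}$, searched within
5 × $g_{Na}^{ref}$ (beyond that the model no longer operates as a
coincidence detector, and the delay–threshold curve is diverging steeply at
the refractory limit, so the exact cap has little leverage).  The
`mode = "fixed"` variant measures the same quantity at a fixed
$g_{Na} = g_{Na}^{ref}$; it is the right measure for parameter-space maps
but gives systematically longer values, since the reference conductance
leaves no headroom for the partially inactivated second response.

**Phase plane.** `v2_nullcline()` treats $V_1$ as a parameter and solves the
$V_2$ balance equation for $h$ in closed form ($h$ enters $I_{Na}$
linearly), avoiding 2-D root finding; dynamic KLT in Cpt2 is evaluated
quasi-statically at $w_\infty(V_2)$ for these diagnostics.  `left_knee()`
locates the local maximum of the nullcline (the effective spike threshold of
the fast subsystem) with quadratic refinement, and `fixed_points()` brackets
sign changes of the balance current along the $h$-nullcline and polishes
roots with `uniroot`.  The default $V_2$ grid is 0.05 mV over [-80, 60] mV.
Every nullcline point and fixed point is verified by substitution back into
the independent R implementation of the dynamics (residual below $10^{-8}$
pA).

## Problem sizes and reproducibility

The deterministic protocols (construction identities, reference
conductances, tonic boundary, refractory period, phase-plane read-outs) are
exact given the solver settings and run in seconds; the acceptance script
recomputes all of them from scratch.  The stochastic coincidence protocol is
exercised in the test suite at a reduced size chosen to expose the
qualitative structure at useful power: 25 trials per condition and a 9-point
$g_{Na}$ sweep (0.2–2.2 in steps of 0.25), at 500 and 700 Hz, with the full
41-point sweep and 100 trials available through the same functions.  All
stochastic results derive from a single master seed.

## Known limitations

* The afferent generator is statistical, not mechanistic: absolute firing
  rates and rate differences depend on its declared rate and vector-strength
  schedule, and should not be compared quantitatively to results obtained
  with a full auditory-periphery model.
* The tonic/phasic boundary is located by simulation and classification,
  not continuation, so it inherits the classifier's constants (step length,
  spike-count minimum) near degenerate cases; subcritical oscillatory
  regimes narrower than the classifier's resolution would be missed.
* Gating kinetics are fixed at their 35 °C forms; there is no temperature
  parameter.
* The model has exactly two compartments — no dendritic cable, no
  multi-node axon, no inhibition, and no hyperpolarization-activated
  current.
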
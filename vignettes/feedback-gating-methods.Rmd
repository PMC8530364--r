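---
title: "Models of feedback-driven convergence and divergence of cortical odor codes"
author: "olfeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of feedback-driven convergence and divergence of cortical odor codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfeedback)
```

## The scientific question

Contextual feedback from central brain areas to the olfactory bulb can
increase or decrease the similarity of piriform-cortex responses to a pair
of odors (pattern convergence and divergence), shaping generalization and
discrimination.  `olfeedback` implements two tiers of models of this
circuit:

1. an **analytic statistical tier**: the bulb is a set of *modules* (the
   mitral cells projecting to one cortical unit), the cortex gates module
   rates through a hard activation threshold, and contextual feedback is an
   unstructured, probabilistic shift of module rates; and
2. a **mechanistic tier**: geometric mitral-cell/granule-cell (MC–GC)
   connectivity, a conductance-based Izhikevich spiking network, a
   reduction of the spiking model to fitted firing-rate distributions, and
   a balanced, sigmoid, randomly sampled cortical readout at scale.

The central quantity in both tiers is the cosine similarity between the
cortical activity vectors evoked by two odors, before (`rho_i`) and after
(`rho_f`) feedback.

## The analytic tier

### Model and assumptions

Module responses to an odor lie in `(0, R_max)`.  A module is
*odor-responsive* above the response threshold `theta_m` and drives its
cortical unit above the (much higher) cortical activation threshold
`theta_c`.  Responses to two odors are assumed jointly uniform within each
of the four regions of the response plane cut at `theta_m`, with exact
counts `N_A`, `N_B`, `N_AB` of responsive modules.  With a step cortical
transfer this makes the cortical counts exact rescalings of the module
counts, and the initial similarity

\[ \rho_i = Q_0 \frac{N_{AB}}{\sqrt{N_A N_B}}, \qquad
   Q_0 = \frac{R_{max}-\theta_c}{R_{max}-\theta_m} . \]

Feedback shifts each affected module's rate by exactly `dR`, upward with
probability `p_plus` and downward with probability `p_minus` (per odor);
the two odors' feedbacks are coupled by `p_both` (probability a module
affected for odor A is also affected for B) and `p_flip` (probability the
B shift opposes the A shift).  The similarity of the two feedback patterns
is then `rho_FB = p_both - 2 p_flip`.  The B-side marginals are derived so
that both feedbacks cover the same number of modules
(`feedback_spec()` fills them in and validates realizability of the joint
law).

The change in the number of cortically active modules decomposes into a
single-odor part (`single_odor_shift()`) and fifteen joint cases
(`joint_shift_contributions()`), each the product of a sign-pattern
probability, a region area, and a region density.  Seven of the fifteen
cases promote modules that are unresponsive to at least one odor; they are
gated by the indicator of `dR > theta_c - theta_m` and are what produces a
nonzero intercept at low cortical thresholds.  The result is the linear
law

\[ \Delta\rho = Q_2\,\rho_i + Q_1 . \]

### Numerical choices

* **Affine extraction of the coefficients.**  `linear_coefficients()` does
  not expand the fifteen cases symbolically.  The post-feedback similarity
  is affine in `N_AB` (its denominator does not involve `N_AB`), so `Q_1`
  and `Q_3` are obtained exactly from two probe evaluations and
  `Q_2 = Q_3/Q_0 - 1`.  This is exact to rounding error and immune to
  transcription mistakes in any one case; the case table itself is
  validated against the brute-force population simulator instead.
* **The "both decrease" case** uses the inclusion–exclusion probability
  `p_minus_A + p_minus_B - p_minus_A p_same` (at least one of the two
  feedbacks negative), consistent with the other cases and confirmed by
  the population oracle.
* **Pure-scenario closed forms.**  For feedback that is positive for all
  modules for both odors, the effect equals a reduction of `theta_c` by
  `dR`, giving slope `dR/(R_max - theta_c)`; for feedback positive for one
  odor and negative for the other, the asymmetric threshold shift gives
  slope `sqrt((R_max-theta_c)^2 - dR^2)/(R_max-theta_c) - 1`.  The second
  form is a geometric reconstruction (the square root follows from the
  uniform-density area argument); both are required to agree with the
  general machinery to `1e-10` in their regimes, and do.
* **Degenerate regimes raise, never clamp.**  If a shifted cortical count
  collapses to zero or below, `similarity_after_feedback()` raises an
  error naming the collapsed count.  Similarity against an all-zero
  activity vector is likewise an error, never 0 or 1 by convention.
* **Regime classification** (`phase_diagram()`) treats `Q_1` as zero below
  `1e-9`; *convergence* is `Q_2 > 0` with `Q_1 = 0`, *divergence* `Q_2 <
  0` with `Q_1 = 0`, *mixed* `Q_1 > 0`.  The y-axis is parameterized by
  `p_flip` (with `rho_FB` reported alongside) because `rho_FB` is a
  derived quantity whose range is limited by `p_both`.

A worked example:

```{r analytic-example}
th <- threshold_spec(theta_m = 0.3, theta_c = 0.8, R_max = 2)
fb <- feedback_spec(dR = 0.4, p_plus_A = 0.125, p_minus_A = 0.375,
                    p_both = 0.5, p_flip = 0)
linear_coefficients(th, fb, N = 1e4, N_A = 6e3, N_B = 6e3)
```

With `theta_c = 0.8` above `theta_m + dR = 0.7` the intercept is exactly
zero; the slope is slightly negative because at this moderate threshold
the mostly inhibitory feedback (75% of affected modules suppressed) still
wins.  Convergence for correlated feedback appears at the sparse end of
the threshold range — `phase_diagram()` marks the thresholds that activate
15%, 10% and 3% of cortical units, and the convergence region overlaps
that band.

### The population simulator as oracle

`sample_population()` realizes the model's assumptions literally for a
finite module population (exact region counts, joint feedback-sign law)
and `empirical_similarity()` recomputes the similarities from the drawn
vectors.  Because the analytic law describes expectations of this exact
generative process, agreement within Monte-Carlo error is a sharp
correctness check, not a qualitative one; the test suite requires
agreement within three standard errors at one million modules for twenty
random valid configurations.

The simulator also generalizes the analysis beyond the uniform/step
assumptions: responsive-module rates can be Gaussian (mean 1.15; the
dispersion values 0.42 and 0.28 are read as *standard deviations*, since
that reading reproduces both the documented feedback similarity of 0.8 for
identical-sign Gaussian feedback and the stated sparse activation at a
threshold of 1.6 — the literal-variance reading does neither; both are
configurable), the transfer can be a sigmoid (default steepness: the
10–90% rise spans 10% of `R_max`), and an identity transfer provides the
single-layer control in which the gating distinction between moderately
correlated and anticorrelated feedback disappears.  Gaussian draws are not
clipped to `(0, R_max)`; the transfer handles extremes.

## The mechanistic tier

### Geometric connectivity

MC lateral dendritic trees are laminar discs; GC dendritic trees are
inverted cones carrying spines.  The expected synapse count for a pair is

\[ \lambda = \rho_g(z)\, q \,\pi\, l , \]

where `l` is the dendritic length inside the disc–cone overlap (a
one-dimensional adaptive quadrature in polar coordinates, since the
angular extent of the lens is known in closed form), `rho_g` the spine
volume density at the intersection height (taken constant across the thin
interaction shell), and `q` the interaction cross-section constant.  The
connection probability is `1 - exp(-lambda)`, and multiple expected
synapses collapse to a single edge.  Each realized synapse's radial
distance `L` attenuates its GABA conductance as `exp(-L/675 um)`.

Two honest placeholders: the radial length-density profile `rho_m(r)`
(linear decay to the disc edge, normalized to a configurable total
dendritic length of 8 mm) and the spine profile `N_s(z)` (triangular,
peaking in the deep half, normalized to a configurable spine count).
Their shapes are not constrained by available anatomy beyond totals, so
both are config-swappable, and correctness is enforced through invariants
(containment limits, monotonicity, translation invariance,
quadrature-vs-Monte-Carlo agreement) rather than through the shapes.  The
printed interaction constant `q = 2.32 um^2` is inconsistent with the
shell geometry it is described by (`(d_shell + r_dendrite)^2 -
r_dendrite^2` gives about 2.06 um^2 with a 1.02 um shell and 0.5 um
dendrite radius); the printed value is the default and the formula-derived
value is selectable — the discrepancy is surfaced, not silently "fixed".

### Spiking network

Both cell classes follow the conductance-based Izhikevich model with the
documented mean parameters; all parameters are heterogeneous at
Normal(mean, mean/10), except the granule cells' `b` and `k`, which are
drawn at Normal(mean, 2 mean/3) and rejection-sampled under `b < 0`,
rheobase in 10–70 pA and input resistance in 0.25–1.5 GOhm (rheobase
`(b + k(v_t - v_r))^2 / 4k` and input resistance `1/(b + k(v_t - v_r))`
follow from the quadratic model with adapted recovery current).  A cell
whose heterogeneous `v_r`, `v_t` draw makes those constraints jointly
infeasible has its thresholds redrawn — roughly one cell in three hundred.
This yields class I granule cells (firing rates continuous from zero above
rheobase) and class II mitral cells (abrupt onset rate), which the test
suite checks on isolated neurons.

Synapses are AMPA + NMDA (with the 1 mM magnesium-block factor) onto GCs
and GABA onto MCs.  On an MC spike, its AMPA/NMDA gates are incremented
and — in the same Euler step — every synapse onto MCs sharing its granule
cells receives the `kappa`-scaled GABA increment, modeling
spike-independent graded release; a GC spike delivers the full GABA
increment.  Integration is forward Euler at `dt = 0.1` ms with reset
checks after each state update; halving `dt` changes per-neuron
spike counts over one sniff by at most one spike on the fixture network.

Stimuli: odor input is a half-wave-rectified 6 Hz sinusoid (one sniff =
1/6 s) with amplitude drawn uniformly in 300–500 pA per glomerulus (the
waveform and the per-glomerulus sharing are both config-swappable, since
only "oscillatory" is documented); feedback is a constant pulse, by
default to one fifth of MCs (0–300 pA) or one eighth of GCs (0–200 pA) —
these fractions reconstruct garbled printed fractions and are exposed in
the configuration rather than hard-coded.

### Rate reduction and cortical readout

Because full-scale spiking runs are expensive, the spiking model is
summarized by three laws (spikes per sniff; `default_distribution_set()`):

* odor-evoked MC rates: generalized Pareto (shape −0.281, scale 3.331,
  location −0.4), clipped at zero since rates are nonnegative;
* MC rate changes under direct excitatory feedback: zero-elevated skew
  normal (nonzero probability 0.31; shape 4.232, scale 2.687, location
  0.7785);
* MC rate changes under GC-mediated feedback: a lognormal (meanlog 0.7957,
  sdlog 0.2548) flipped and shifted onto `[-2, 0]` — the affine map
  anchors the central three-sigma log-range onto that interval, is
  recorded in the distribution set, and is *not* re-estimated when
  fitting; the law applies only to MCs firing at least two spikes per
  sniff, honoring the observed ceiling of two lost spikes.

`fit_rate_distributions()` provides maximum-likelihood fits of all three
(the generalized-Pareto location anchored at the sample minimum, the zero
fraction estimated separately), and recovers the packaged parameters from
its own draws within 5% at 10^5 samples.  A scaled-down spiking run
(`spiking_rate_summary()`) exercises the full pipeline end to end; at that
size the fitted parameters carry wide confidence intervals and are
reported against the packaged values, not asserted to match them.

The cortical readout (`cortical_readout()`): `K` units each sum the rates
of a fixed random sample of `round(qM)` MCs (without replacement, fixed
per experiment so pre/post comparisons are paired), the mean input across
units is subtracted (cortical balancing), and a sigmoid is applied.  The
sigmoid threshold is calibrated on pre-feedback inputs so that a target
fraction of units is strongly active; the 10–90% rise spans 10% of the
central input range.

**Choice of the high-threshold operating point.**  The strongly-active
fraction in the high-threshold regime defaults to 3%, the sparse end of
the experimentally reported piriform activation range (15%/10%/3%).  This
is a deliberate design choice: the convergence-increasing-with-similarity
regime requires the per-unit feedback fluctuation to be small relative to
the gap between the sub-threshold bulk and the gating threshold, and with
the packaged feedback law at 8% MC coverage that holds at the 3% operating
point but not at 10%, where weakly tuned units are promoted
indiscriminately and the model sits in the mixed/divergent regime.  At 3%
the full-scale experiment reproduces the reference second-level regression
(slope of the per-condition `delta_rho`-vs-`rho_i` slope against feedback
similarity about 0.46--0.48 across replicate sets, r-squared above 0.95;
recomputed by `scripts/acceptance.R`).  The low-excitability ("low")
regime uses a 50%
strongly-active calibration and reproduces the reversal: negative slope
with positive intercept even for fully shared feedback.

**The standard feedback condition** (`kind = "combined"`) applies
excitatory changes to the `p_FB` subset of MCs (similarity between the two
contexts controlled by the shared fraction of targets and draws) on top of
the GC-mediated negative background applied identically for both contexts
to all eligible MCs — identical because the network, not the targeted GC
subset, shapes that pathway.  Pure `"mc_excitatory"`, `"gc_inhibitory"`
and `"mixed"` (excitatory for one context, inhibitory for the other)
conditions are also available.

## What the generators emulate, and what they do not

The synthetic odor pairs control glomerular overlap exactly and share
per-glomerulus rate draws, so initial similarity is a clean monotone
function of overlap; real odor pairs differ also in concentration,
within-glomerulus correlations and temporal structure, none of which is
modeled.  Feedback targets are chosen independently of odor tuning —
deliberately, since unstructuredness is the hypothesis under test — so
passing tests say nothing about tuned feedback.  The spiking tier omits
periglomerular and deep short-axon cells, tufted cells, gap junctions and
all synaptic plasticity; the reduced tier replaces network dynamics by
static draws from the fitted laws, which removes trial-to-trial rate
correlations between MCs sharing granule cells.  Consequently, agreement
between the tiers supports the statistical mechanism, not a claim that
the reduced model captures bulbar dynamics in detail.

## Problem sizes

The test suite validates the analytic/population equivalence at 10^6
modules, runs the reduced-model experiments at their full scale (10^4 MCs,
10^5 cortical units) with small odor-pair and feedback grids, and keeps
spiking fixtures at tens of cells; these sizes give Monte-Carlo errors
comfortably inside the asserted tolerances while keeping the default test
run quick.  `scripts/acceptance.R` repeats the full-scale experiment over
five replicates and reports replicate means.

## Known limitations

* The fifteen-case decomposition assumes a single shared feedback
  magnitude `dR` in the analytic tier; per-module variability lives in the
  population simulator only.
* The sigmoid calibration depends on the calibration odors' input
  distribution; grossly non-representative calibration odors would shift
  the operating point.
* The geometric profiles are placeholders calibrated by totals (above).
* The spiking tier's graded-release timing (same step as the triggering
  spike) is one of several defensible readings of the mechanism; it is
  flagged in the code and configurable only through the source.
* At the scale-stability boundary (about 8000 MCs / 80000 units) the
  high-threshold slope sign is noisy; the packaged defaults sit at the
  documented stable scale.
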
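---
title: "A chain of network pattern generators for C. elegans crawling: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A chain of network pattern generators for C. elegans crawling: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormCPG)
```

## The question the model asks

*C. elegans* crawls by propagating a dorsoventral bending wave from head to
tail. Three candidate mechanisms can generate and coordinate that wave:
stretch-receptor (proprioceptive) feedback, intrinsically oscillating
pacemaker neurons, and network oscillators — rhythms that emerge from the
interaction of non-oscillatory neurons. This package implements a
neuromechanical model built to probe the third possibility in isolation: a
repeating ventral nerve cord (VNC) circuit with **no** stretch-receptor
feedback, **no** pacemaker dynamics, and **no** descending input, embodied
in a 2D mechanical body crawling on agar. If parameters exist for which this
stripped-down system still locomotes with worm-like kinematics, network
oscillators are a viable (complementary) contributor to locomotion.

## Model components

### Ventral nerve cord circuit

The VNC is modeled as seven identical repeating units of seven motorneuron
classes (AS, DA, DB, DD, VA, VB, VD), 49 neurons in total. Each neuron is a
continuous-time recurrent neural network (CTRNN) node:

$$\tau_i \frac{dV_i}{dt} = -V_i + \sum_j w_{ji}\,\sigma(V_j + \theta_j)
  + \sum_j g_{ji} (V_j - V_i) + I_i$$

with $\sigma(x) = 1/(1+e^{-x})$ the synaptic output function, $\theta$ a
bias, $w_{ji}$ signed chemical weights (signs between motorneurons are not
anatomically known and are left free), $g_{ji} \ge 0$ symmetric gap-junction
conductances, and a self-connection on every neuron standing in for active
membrane currents. Potentials are measured relative to rest, so the resting
state is $V = 0$.

Within a unit the evolved connections are nine chemical synapses (AS→DA,
AS→VD, DA→DB, DB→AS, VD→VA, VD→VB, DA→DD, VB→DD, VA→DD) and one gap
junction (VD⊣⊢DD). Adjacent units are joined by two chemical synapses
(DB→DD⁺¹, VA⁺¹→DD) and three gap junctions (DA⊣⊢AS⁺¹, VB⊣⊢DB⁺¹, AS⊣⊢VA⁺¹);
edges that would point beyond the chain ends are dropped. (Part of the
literature writes one of these channels as "VD⊣⊢DB⁺¹" in prose; the
consistent circuit, used here, couples VB to DB of the next unit.)

### Muscles

Each body side carries 24 overlapping muscles. Motorneuron output drives
muscle $m$ on side $k$ through
$I_m^k = \sum_{i \in N^k} \gamma_m\, q_i\, S_i$, where $N^D$ = {AS, DA, DB,
DD} and $N^V$ = {VA, VB, VD} of the innervating unit, $q_i$ is the NMJ
weight (positive for cholinergic AS/A/B classes, negative for GABAergic D
classes), and $\gamma_m = 0.7\,(1 - (m-1)F/24)$ imposes an evolved
anterior-posterior efficacy gradient ($\gamma_1 = 0.7$ always). Activation
is a leaky integrator, $\dot A = (I - A)/\tau_M$, $\tau_M = 100$ ms. Active
force is $A \times FL \times FV$ with simplified Hill properties: a
parabolic force-length curve around the element rest length and a hyperbolic
force-velocity decline with shortening, mildly enhanced (capped) when
lengthening.

Units innervate three muscles per side, except the two end units which take
four and five so that all 24 are covered (unit 1 → muscles 1–4, units 2–6 →
three each, unit 7 → muscles 20–24). The anatomical description of the end
allocation is ambiguous (three per unit totals 23); this assignment is the
package's documented resolution.

### Body and environment

The ~1 mm body is a 2D cross-section chain of 50 variable-width segments
bounded by 51 rigid rods, each with $(x, y, \phi)$ — 153 degrees of freedom.
Rod endpoints are joined by damped-spring lateral elements (cuticle) and
diagonal elements (internal pressure); muscles contract the lateral elements
they overlap, with weights proportional to overlap. Crawling on agar is the
low-Reynolds regime: inertia is dropped and the medium exerts linear drag
$F = -Cv$ per rod with $C_\parallel = 3.2\times10^{-3}$ kg/s along the
midline and $C_\perp = 128\times10^{-3}$ kg/s against lateral slip (ratio
40), plus a small rotational drag $C_\perp w^2/3$ from the distributed
normal drag over the rod.

The width profile, spring constants, damping constants and Hill-curve
parameters are shipped as a versioned configuration file
(`inst/extdata/wormcpg_config.json`), which is the single source of truth
for every constant. The historical rod-and-spring body this design follows
does not publish a reusable constant table, so the shipped values are a
**synthetic calibration**: the structure (tapered width, four damped-spring
elements per segment, overlapping muscle spans) is faithful, and the
magnitudes were chosen once, before any acceptance measurement, so that the
passive body is an exact equilibrium when straight, relaxes smoothly, and
actuated curvature and speeds fall in the worm's range. With these constants
an imposed worm-like traveling wave (0.44 Hz, ~0.65 body lengths) propels
the body at roughly 0.1–0.15 mm/s — somewhat below the 0.22 mm/s of real
worms on agar, a fidelity limit we disclose rather than tune away.

### Integration

The circuit uses Forward Euler at 0.5 ms; muscle activation is updated at
the same step. The body uses an overdamped semi-implicit (linearized
backward-Euler) step at 0.1 ms: damping is always implicit in the
velocities, the elastic Jacobian is treated implicitly with its compressive
branch clamped (the standard stabilization), and the resulting 153×153
system is block-tridiagonal and solved exactly by a block Thomas algorithm.
One neural step drives five body substeps with frozen activations. An
explicit-elastic variant serves as the convergence reference; tests verify
first-order convergence of both integrators, machine-precision conservation
of summed gap-junction current, and that the resting body stays at rest for
$10^6$ steps.

## Evolutionary search

The 44 unknown parameters (7 biases, 7 time constants, 7 self-connections,
7 NMJ magnitudes, 15 connection strengths, and the gain $F$) are encoded as
a normalized vector in $[-1,1]^{44}$ and mapped linearly onto the ranges in
the configuration file (biases, chemical and self weights ±15; gap
conductances 0–2.5; NMJ magnitudes 0–15; $\tau$ 0.05–2 s; $F$ 0–1). The
ranges are conventional CTRNN search ranges; the $\tau$ floor keeps Euler at
0.5 ms comfortably stable.

**Fitness.** Stage 1 rewards a rhythmic B-class pattern at the worm's
crawling frequency:

$$F_1 = \prod_{j \in \{DB, VB\}}
  \min\!\left(1, \frac{\int_0^T |\dot S_j|\,dt}{4 A f_a T}\right)
  \times \max\!\left(0, 1 - \frac{|f_j - f_a|}{f_a}\right)$$

with amplitude threshold $A = 0.5$ and target frequency $f_a = 0.44$ Hz.
The amplitude normalizer is chosen so that a sinusoid of amplitude $A$ at
$f_a$ scores exactly 1 (its total variation is $4 A f_a T$); the printed
form of this normalizer in the source literature is typographically
ambiguous, and this reading makes the stated cap coincide with the stated
threshold. Frequencies are estimated from mean intervals between rising
mean-crossings (with linear interpolation), with an FFT cross-check. Stage 2
multiplies $F_1$ by the velocity match
$F_2 = \max(0, 1 - |\bar V - V_a|/V_a)$, $V_a = 0.22$ mm/s, where $\bar V$
is net center-of-mass displacement over the post-transient window divided by
its duration (so spinning scores ~0). For embodied runs $F_1$ is averaged
over the seven units.

**Algorithm.** A simple generational GA: linear rank selection, uniform
recombination with probability 0.5, per-slot Gaussian mutation reflected at
the bounds, elitism 1, population 96, up to 300 generations. Mutation size
anneals with the best fitness ($\sigma = \max(0.01, 0.12\,(1 -
\text{best}))$): with any fixed $\sigma$ the search either never found
oscillations or stalled just below the stage-1 success threshold, and the
annealed schedule resolves both regimes. Three further choices matter for
reliability and are deliberate:

* **Shaped search fitness.** During stage-1 search the amplitude term is
  evaluated with a 10% stricter cap, so that winners sit safely above the
  true cap in every time window (the amplitude of young oscillations drifts
  for tens of seconds). All *reported* fitnesses are the unshaped $F_1$ on
  the full 50 s protocol.
* **Frequency calibration.** The CTRNN equations are invariant under a
  joint rescaling of time and all seven $\tau$; multiplying every $\tau$ by
  $f/f_a$ therefore moves the rhythm exactly onto the target frequency
  (within the $\tau$ range bounds). Candidates are calibrated before
  validation and the final winner is calibrated too.
* **End-game polish.** A short stochastic hill-climb (150 candidates,
  $\sigma = 0.02$, each frequency-calibrated) on the full-protocol $F_1$
  finishes what the coarse search leaves.

Stage-1 evaluations integrate a single 7-neuron unit for 24 s and score the
window after an 8 s transient; the final assessment always uses the full
protocol (50 s, 10 s transient). Stage-2 seeds its population from a
stage-1 winner and evaluates embodied runs of 10-12 s (3-4 s transient)
with the body substepped at 0.5 ms for tractability; re-validation and
every analysis in this package use the reference 0.1 ms body step (the
midline difference between the two steps is small over seconds of
simulation, though strongly bent postures are re-scored at the reference
step before any conclusion is drawn).

**How the committed locomotor was found.** On a single core the plain
stage-2 GA tends to stall in degenerate optima (one-sided flexing,
synchronized units). The committed demo locomotor was therefore produced by
a staged search that makes the incremental logic explicit, with every step
running through the same public simulation and fitness functions
(`inst/scripts/make_fixtures.R` reproduces it end to end): first the
coordination problem is solved on the neural chain alone — scanning each
interunit gap junction over its conductance range shows that VB⊣⊢DB⁺¹ near
0.6 phase-locks all seven units at 0.44 Hz with a coherent
posterior-directed lag (~146°/unit, i.e. a wavelength inside the filter
band), the signature of the "simple" coordination class; then the thrust
problem (NMJ magnitudes and the gain $F$) is optimized under the stage-2
objective $F_1 \cdot F_2$ by random search plus hill-climbing; finally the
candidate is refined at the reference body step and polished under the
B-class-dependence constraint of the ensemble filters (A- and AS-class
NMJs silenced), mirroring how the published ensemble was filtered.

## Analyses

* **Kymograph.** Signed curvature (dorsal positive) along the midline per
  frame, from tangent-angle differences over arclength, lightly smoothed
  along the body.
* **Filters.** (1) NMJ class dependence: B-class NMJ ablation must drop
  speed below 20% of $V_a$ while A-class ablation must leave more than 20%.
  (2) Body wavelength within 0.4–0.9 body lengths — estimated from zero-
  crossing spacing of the curvature profile (twice the mean spacing),
  averaged over frames, with a spectral cross-check; and a negative
  head-to-tail slope of the mean absolute curvature profile. (3) Trajectory
  curvature radius above 1 mm, from an algebraic (Kasa) circle fit of the
  center-of-mass path; radii beyond 1 m are reported as straight.
* **Paralysis experiments.** Regional silencing of units 1–3 or 3–5 either
  at the neurons (clamped to rest, zero output, gap junctions disconnected)
  or at their NMJs only (muscles inactivated, dynamics intact) — two
  distinct masks matching the two experimental manipulations. Bending
  amplitude is summarized per body third as peak-to-peak curvature summed
  over the third (the cited experimental measure is followed in spirit; the
  exact reduction is a package choice).
* **Gap-junction overexpression.** The B-class interunit coupling is scaled
  by a factor $\ge 1$: the evolved VB⊣⊢DB⁺¹ conductance is multiplied by the
  factor, and DB⊣⊢DB⁺¹ / VB⊣⊢VB⁺¹ channels (absent from the base wiring)
  are added at $(\text{factor}-1)$ times the evolved conductance, so factor
  1 is exactly the identity. Strong coupling synchronizes the oscillators
  and speed collapses.
* **Subcircuit oscillation scores.** Each candidate oscillator triple
  (AS-DA-DB, VD-VA-DD, VD-VB-DD) is isolated and swept over a grid of
  compensatory tonic inputs centered on the mean synaptic drive each neuron
  loses by isolation (default 9 points per neuron, ±5 potential units). The
  score is the maximum over the grid of mean $|\dot S|$, normalized by the
  total-variation rate of a full-range square wave at $f_a$ ($2 f_a$) and
  capped at 1; grid points that settle to a fixed point score 0. The
  normalization "to run between 0 and 1" is not fully specified in the
  source literature; this bound-based choice is ours.
* **Necessity and sufficiency.** Each of the five interunit connections is
  ablated alone (necessity) or retained alone (sufficiency); performance is
  the velocity match $F_2$. (The figure caption in the source literature
  cross-references the neural fitness here, but the quantity plotted is the
  speed match; $F_2$ is implemented.) A connection with ablation performance
  below half of baseline is necessary; one preserving at least half of
  baseline alone is sufficient. Solutions are "simple" (some connection both
  necessary and sufficient), "redundant" (sufficient ones exist, none
  necessary) or "complex" (none sufficient).
* **Entrainment.** Directionality of coordination is probed on the neural
  chain alone (the perturbation and read-out are purely neural): the
  anterior-most or posterior-most unit's state is replaced with its own
  state from a phase-shifted point of the same limit cycle, and each unit's
  adopted asymptotic phase shift is measured against the unperturbed
  continuation. Phase markers are the midpoint between the times of maximum
  and minimum $\dot S$ within each cycle; shifts are circularly averaged
  and reported in (−180°, 180°].

## What the synthetic data do and do not show

The synthetic kymographs and center-of-mass paths used by the test-suite are
analytic traveling waves and circles/lines: they validate the estimators
(wavelength, slope, radius, phase) against known ground truth, including
pass/fail classification at the filter boundaries. They do not emulate
punctuated waves from seven discrete units, measurement noise, or
self-intersecting postures, so passing those tests validates the analysis
operators, not the biological realism of any particular evolved worm. The
committed demo genotypes — a stage-1 oscillator and a stage-2 locomotor,
both products of the package's own evolutionary search with fixed seeds —
are the substrate for the qualitative experimental reproductions (anterior
and midbody paralysis, overexpression collapse).

## Numerical choices and degenerate inputs

Silenced neurons are clamped at rest with zero output and their gap
junctions disconnected (tests verify exact equivalence with edge removal).
Non-oscillatory traces return frequency 0 with a flag rather than an error;
phase analysis refuses traces whose frequencies differ by more than 10%.
Degenerate body elements (zero length) and singular solves abort the run
with a time-stamped error. Self-intersection is not modelled; an optional
geometric check warns when the midline self-crosses. Evaluation horizons
(24 s stage-1 eval, 50 s assessment, 12 s stage-2 eval, 10–15 s analysis
runs in the test-suite) are the package's choices balancing estimator
stability against cost, and are stated wherever they differ from the
defaults.

## Known limitations

Only forward crawling on agar is modelled: no backward locomotion, turns,
variable-viscosity environments, pacemaker currents, proprioception, or
descending command input. The body constants are a synthetic calibration
(above), so quantitative kinematics (top speed in particular) carry that
caveat. The ensemble statistics reported in the source literature (success
rates across 160 searches, the 15-member filtered ensemble, phase-shift
means) depend on unreported GA hyperparameters and are not reproduction
targets; the package instead commits to the per-solution properties that do
not depend on them.
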
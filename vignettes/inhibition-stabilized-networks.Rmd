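---
title: "Inhibition-stabilized attractor networks as finite-state machines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inhibition-stabilized attractor networks as finite-state machines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isnet)
```

## The model

`isnet` simulates and analyses networks built from *inhibition-stabilized
pairs* (ISPs): one excitatory and one inhibitory threshold-linear rate unit
with strong mutual coupling, tuned so that the runaway excitatory unit is
held in check by inhibitory feedback.  A network of `N` pairs obeys

$$\tau \dot r = -r + W r - \theta + \textstyle\sum_\alpha \omega_\alpha
I_\alpha(t), \qquad r \ge 0,$$

where `r` is the length-`2N` rate vector (Hz), `W` the signed weight
matrix, `θ` the per-unit activation thresholds, and each stimulus is a
shared scalar rectangular current pulse `I(t)` delivered to unit `a` with
gain `ω[a]`.  The transfer function is threshold-linear with unit slope;
all gain structure lives in the weights.

For a single pair the model is fully tractable: the non-zero (UP) fixed
point has a closed form, and the Jacobian there has trace
`(w_ee + w_ii − 2)/τ` and determinant
`((w_ee−1)(w_ii−1) − w_ei·w_ie)/τ²`.  A pair is *bistable* — a quiescent
DOWN state coexisting with an inhibition-stabilized UP state — when
`θ_I > θ_E > 0`, the inhibitory nullcline is steeper than the excitatory
one at the UP point, and the UP Jacobian is stable.  Within the stable
region the UP point is a *node* (`Tr² > 4Δ`) or a *spiral* (`Tr² < 4Δ`);
the spiral's transient oscillations are what allow a purely excitatory
pulse to knock the pair out of the UP state, and hence what make
*state-dependent* responses (the same stimulus driving DOWN→UP and
UP→DOWN) possible.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `tau` | ms | 10 | rate time constant of every unit |
| `dt` | ms | 0.01 | RK4 step; see "Numerical choices" |
| settle cap | ms | 12000 | give-up horizon for convergence |
| fixed-point radius | Hz | 0.1 | state identity / convergence radius |
| UP threshold `eps` | Hz | 0.1 | signature bit: pair UP iff `r_E > eps` |
| cross-class means | — | 10% of within-pair magnitudes | "weak" coupling |
| cross `cv` | — | 0 – 1 | heterogeneity of cross-connections |

The canonical pair used throughout the package (and by
`make_fixtures()`) is solved by inverse design: fix thresholds
`θ_E = 5.34`, `θ_I = 82.43`, UP rates `(r_E, r_I) = (5, 10)` Hz, and a
target `(Tr, Δ)`; `solve_pair_weights()` returns the four within-pair
weights.  The fixture spiral pair uses `(Tr, Δ) = (−0.1, 0.01)` (in 1/ms
and 1/ms²), safely inside the spiral region; the node fixture uses
`(−0.4, 0.01)`.

### The inverse design is a quadratic, not an iterative search

Of the four constraints (trace, determinant, and the two nullclines
passing through the UP point), three are linear in the weights once
`w_ee` is chosen.  Substituting them turns the determinant constraint
into an exact quadratic in `w_ee`.  `solve_pair_weights()` therefore
computes both roots in closed form and returns the Dale-compliant one
(preferring the larger `w_ee`, the inhibition-stabilized branch with
strong recurrent excitation), rather than running an iterative root
search with multi-start recovery: the closed form is deterministic,
exact to round-off, and cannot fail to converge.  The test-suite checks
it against an independent grid-plus-`uniroot` search on the determinant
residual.

## The synthetic-network generator

`build_weight_matrix()` emulates a cortex-like random network under three
constraints: identical within-pair blocks (every pair alone would be the
same bistable ISP); Dale's law (excitatory columns ≥ 0, inhibitory ≤ 0);
and *homeostatic input statistics* — for every row, the magnitudes of each
cross-connection class are affinely rescaled after sampling so that their
realized mean and sd match the specification exactly.  Literal
resample-until-exact would never terminate; the rescaling preserves the
property actually used downstream, namely that every unit receives
identical input statistics.  If rescaling drives a magnitude negative it
is floored at 1e−12 and the mean restored multiplicatively (the sd is then
approximate — this only occurs at large cv).  Cross-pair magnitudes come
from a log-normal family by default, or a gamma family
(`shape = 1/cv²`, `rate = shape/mean`) for the heterogeneity sweeps, where
gamma makes Dale's law trivial to enforce at high cv.  With
`scale_with_n = TRUE`, class means and sds are divided by `N` so the mean
total input per unit is independent of network size.

What the generator does *not* emulate: spiking, conductances, sparse
topology, synaptic dynamics, or noise.  A green test establishes
properties of this deterministic rate model only.

The fiducial cross-connection strength is a package choice
(`fiducial_cross_stats()`: class means at 10% of the corresponding
within-pair magnitude, cv 0.5 unless overridden): the reference values
live in unpublished supplementary material, so they are treated as
configuration, chosen once so that cross-input at a typical attractor is
an order of magnitude below threshold — "weak" in the sense the
multistability analysis assumes — and not revisited.

## Numerical choices

* **Integration** is classical RK4 with the rectification applied both to
  every stage evaluation (derivatives are computed on `max(r, 0)`) and to
  the state after each full step.  Rectifying stages prevents negative
  excursions from contributing flux; the forward-Euler oracle at `dt/100`
  agrees to better than 1e−3 Hz over 100 ms, which settles the stage
  -rectification ambiguity empirically.
* **Step size.** A literal 10 ns step with `τ = 10 ms` would need ~10⁹
  steps per settle window and adds nothing at this smoothness; the package
  default is `dt = 0.01 ms`.  The test-suite runs simulation-heavy tests
  at `dt = 0.05 ms` to stay inside its time budget; a dt-robustness test
  (halving `dt` changes no settled attractor identity on the fixtures)
  guards both choices.
* **Convergence** (`settle()`): max-norm rate change over a trailing 5 ms
  window below 1e−4 Hz *and* the flow-extrapolated fixed point
  (`r + τ·dr/dt`) within 0.1 Hz.  Units clamped at zero with negative
  drive are treated as stationary — the raw derivative at a silenced unit
  is `−θ/τ`, which would otherwise block convergence at every attractor
  containing a DOWN pair.  Non-convergence within 12 s is reported as a
  distinguishable timeout, never silently dropped: near the stability
  boundary (`Tr → 0`) orbits genuinely fail to decay, and the
  state-dependence maps mark those cells instead of guessing.
* **State identity.** Two settled states are the same attractor iff their
  UP/DOWN signatures match and rates agree within 0.1 Hz (max-norm).
  DOWN rates are exactly zero in the rectified model, so `eps = 0.1 Hz`
  on the excitatory rate is an unambiguous signature threshold.
* **Attractor enumeration** seeds `3·2^N` settles: every UP/DOWN pattern
  with three UP-rate guesses — the isolated-pair closed form, half, and
  double it.  The three guesses are not specified by the underlying
  analysis; bracketing above and below covers coupling-shifted UP states.
  For homogeneous (cv = 0) matrices the O(N) variant settles one
  representative per `k` active pairs and credits `choose(N, k)`
  permutations; it provably agrees with the full enumeration and is
  cross-checked against it at small `N`.
* **Growth fits** (`y = a·bˣ + c`) use `nls` (port algorithm,
  `b > 0` bound) from the fixed start `(1, 2, 0)`; `c` is fitted freely
  and reported, since the printed fits omit it without stating it was
  fixed.

## Stimulus sweeps and tolerance

`state_dependence_sweep()` applies each (amplitude, duration) cell twice —
from DOWN and from UP — and classifies the outcome.  The `tolerance`
statistic summarizes the state-dependent region as a circle on log-log
axes: restrict to the bounding sub-grid of state-dependent cells, let `f`
be their fraction of its (non-timeout) cells and `foldA`, `foldD` the
max/min ratios of their amplitudes and durations; then

$$\text{tolerance} = 2\sqrt{f \cdot \text{foldA} \cdot \text{foldD} / \pi}.$$

Two readings were open in the printed formula.  (1) *Fold ranges are
plain ratios*, not log-ratios: the quantity is described as "diameter in
units of fold-variation", and a single-cell region then gives the forced
value `2/√π ≈ 1.128`.  (2) `f` is computed over the *bounding box* of the
state-dependent cells rather than the whole grid; only then is the
statistic invariant to enlarging the sweep ranges around a fixed response
region ("sampling-invariant").  Both choices are package decisions,
frozen here.

Default sweep grids are log-spaced 20×20, amplitudes spanning
`[θ_E/2, 50·θ_E]` (100-fold) and durations `[0.1, 100]` ms (1000-fold):
the published sweep axes are not printed numerically, so the ranges are
configuration with these defaults.

## Itinerancy

A transition graph has one edge per (attractor, stimulus); under one
stimulus it is a functional graph, so every walk is ρ-shaped.  The
itinerancy measure L counts *state-changing* transitions from the best
start node, stopping at the first revisit; the closing transition of a
multi-state cycle counts, a self-loop does not.  This is the only reading
consistent with both anchor cases: an all-self-loop graph scores 0, and
the homogeneous bound works out to exactly 4 (tail of two transitions
into the all-UP/all-DOWN pair, then the two-cycle), which the sweep over
cv = 0 networks attains and never exceeds.  For homogeneous matrices and
uniform stimuli the sweep uses a permutation-symmetry fast path — every
UP pair responds identically, so one representative settle per stable
`k`-class determines the full graph; the fast path is validated against
the generic per-state path on small networks.

## The evidence-accumulation task

Six cues, each `L` or `R`, are delivered as pulses sharing one amplitude
and duration and distinguished by random log-normal unit-mean weight
vectors (`make_cue_pair()`).  `extract_fsm()` discovers the machine the
network implements by breadth-first search from the quiescent state, with
convergence-driven equilibration between pulses; each discovered state is
simulated once per symbol.  Scoring is then pure graph-work:
`evaluate_sequences()` walks all 64 sequences,
`optimal_output_and_reliability()` labels each reachable final state with
the majority class of its sequence set and computes

$$\text{reliability} = \frac{\sum_i \max(|S_i \cap L|, |S_i \cap R|)}
{|L| + |R|},$$

with the 20 tied sequences excluded (`|L| = |R| = 22`).  Anchors: a
one-state machine scores 0.50; a machine copying the last cue scores
8/11 ≈ 0.73; a saturating difference counter scores 1.00.  Output-label
ties are labelled `none` (deterministic, and the anchor values are
unaffected because the max() in the reliability sum is).  Primacy and
recency are computed over decided (non-`none`) sequences only: congruence
with the first or last cue is undefined for unlabelled outcomes.

`min_states_for_perfect()` settles by exhaustion how many states a
perfect machine needs: all `m^(2m)` transition tables with the initial
state fixed at 1 (relabelling invariance makes this lossless) are scored
with the optimal output function.  The search finds best reliabilities
0.50, 8/11, ≈0.886 for m = 1, 2, 3 and a perfect machine at m = 4 — so
the minimum of four *includes* the initial quiescent state, answering a
question the prose leaves open.

## Known limitations

* Point attractors only: sustained oscillations are reported as timeouts,
  not counted as limit-cycle states.
* Deterministic dynamics: no noise, hence no non-deterministic machine
  extensions; reliability is exact, not an expectation.
* Dense matrices; practical enumeration is capped at `N ≤ 14`
  (`3·2^N` settles).
* Configs are JSON only (no YAML parser among the package's
  dependencies).
* The psychometric logistic fit is two-parameter least squares on the
  curve (weighted by sequence counts), deliberately simple; it is a model
  comparison device, not a full GLM analysis.

## Reproducibility

Every stochastic operation takes an explicit seed; network construction
derives per-component seeds from the global seed plus a stable label.
Identical specs give bit-identical matrices and trajectories, and result
files embed seed, `dt` and package version in header comments so any
output can be regenerated from its own metadata.
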
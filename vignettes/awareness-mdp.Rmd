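---
title: "Modelling awareness dynamics as a finite-horizon MDP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling awareness dynamics as a finite-horizon MDP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(awaremdp)
```

## The model

`awaremdp` simulates a deliberately skeletal model of how awareness grows
(or decays) through repeated decision-making. The state `s` is a scalar
awareness level on the open unit interval, discretised to the grid
`{0.01, ..., 0.99}` with step 0.01; the endpoints are excluded, so awareness
is never total nor entirely absent. At each decision epoch the individual
chooses a degree of analyticity `u` from the same grid, and the state takes
a single clamped step up, down, or stays, with probabilities that depend on
`u` alone.

Three ideas shape the transition kernel:

* **Dual-process reasoning.** The forward probability is a convex
  combination, weighted by the trait `p_r`, of an *analytical* curve and an
  *intuitive* curve.
* **Overfitting.** The analytical curve is unimodal: beyond its peak,
  further analyticity *reduces* the chance of progress, because reasoning
  that chases every detail of the available information loses the general
  structure of the problem.
* **Tacit knowledge, with a floor.** The intuitive curve peaks at low `u`
  (experiential, unarticulated knowledge can drive progress without
  deliberate analysis) but drops toward the floor as `u` approaches 0: with
  no analyticity at all, intuition loses contact with the decision problem.

The stationary probability is a constant (default `P0 = 0.1`), modelling
inertia; it is configurable but deliberately not a function of `u`. The
backward probability is the residual, which constrains the curve heights:
`p_peak + P0` must not exceed 1.

## Kernel calibration

Only the qualitative shape of the two base curves is pinned down by the
model's motivation, so the package fixes a parametric family and calibrates
its defaults once. Each curve is a normalised beta bump

$$p(u) = p_\mathrm{floor} + (p_\mathrm{peak} - p_\mathrm{floor})
  \frac{u^a (1-u)^b}{\max_v v^a (1-v)^b},
  \qquad (a, b) = \kappa\,(\text{peak},\, 1 - \text{peak}),$$

whose maximiser sits exactly at `peak`. Defaults: analytical peak 0.8,
intuitive peak 0.2 (mirror images), floor `p_floor = 0.05`, height
`p_peak = 0.9`, concentration `κ = 2.5` (exponents (2, 0.5) and (0.5, 2)).

The height and concentration were chosen by a drift calculation against the
reference experiments the presets encode, before any simulation was run.
Under the habitual policy the per-epoch drift of the mean state is
`(2·E[P1(u)] - (1 - P0)) · step`. For the `fig6` preset (`p_r = 0.6`,
decisions concentrated near 0.6, `T = 100`, start 0.2) a final mean state
near 0.5 requires `E[P1] ≈ 0.6` at `u ≈ 0.6`; the default calibration gives
`P1(0.6) = 0.603`, hence an endpoint of ≈ 0.49, while the sharper
alternative `κ = 5, p_peak = 0.85` (kept available, and used in the worked
closed-form examples of the test suite) gives `P1(0.6) = 0.414` — a
*negative* drift incompatible with that experiment. Sharper bumps also move
the mixture's maximiser closer to the analytical peak; `κ = 2.5` puts it at
`u = 0.71` for `p_r = 0.6`, which is where the optimal policy settles.

```{r curves, fig.width = 7, fig.height = 3}
plot_transition_curves(p_r = c(0, 0.6, 1))
```

## Rewards, direction weights, discounting

The stage reward `r(s, u) = α·s − β·u` prices awareness positively and
analytical effort negatively. The terminal reward is the normalised
exponential `R(e^{ks} − 1)/(e^k − 1)` (defaults `R = 10`, `k = 5`): zero at
`s = 0`, `R` at `s = 1`, steep near the top so that final states differ
sharply in value.

Inside the Bellman backup the three movement directions are weighted by
`γ = (γ1, γ2, γ3)`:

$$V_\tau(s) = \max_u\; r(s, u) + D(s, \tau)\,
  [\gamma_1 V_{\tau+1}(s^+) P_1(u) + \gamma_2 V_{\tau+1}(s) P_0
   + \gamma_3 V_{\tau+1}(s^-) P_{-1}(u)],$$

with `s±` the clamped neighbours. The γ-weighting is applied exactly as
written — a *distorted, non-normalised* expectation — because normalising
it changes the optima qualitatively (see the limitations section). The
reference parameterisations use `γ1 > 1`, so the weighted one-step operator
is expansive: values grow geometrically away from the horizon. That is a
feature of the printed recursion, not a numerical accident; `double`
arithmetic holds the growth for the preset horizons (the solver's values
reach ~1e18 for `T = 100` and ~1e100 for the `T = 300` presets). The argmax
is unaffected by the magnitude.

With the emotion extension, the constant future weight `δ` is replaced by
`D(s, τ) = δ(s)·τ/T` with `δ(s) = 1 − c·e^{-k_e s}` (defaults `c = 1.5`,
`k_e = 4`): negative below `s ≈ 0.10` (an individual at low awareness
weighs the future harmfully), ≈ 0.97 at the top of the grid. The stage
index τ is used for the time factor, so the very first backup (`τ = 0`) is
purely myopic and the factor reaches `δ(s)` at the horizon. The emotion
factor affects only the planner: realised stage rewards are always reported
unweighted, as plain sums.

## Policies and simulation

* **Habitual**: `u ~ N(p_r, σ)`, clipped to `[0.01, 0.99]` and snapped to
  the grid — a clipped rather than re-drawn truncated Gaussian; at the
  preset noise levels (`σ = 0.08`) the difference is negligible, and at the
  illustrative `σ = 0.3` the clipping mass is documented by the exact
  action-weight computation used in `propagate_exact()`. `σ` has no
  default: it is a study condition and must be stated.
* **Self-aware**: backward induction over the full action grid; argmax ties
  break toward the smallest `u` (the cheapest decision — analyticity is
  costly). Decisions happen at epochs `0, ..., T−1`; the terminal reward is
  collected at `T`.

`run_ensemble()` derives one seed per run from the master seed
(`sample.int()` under `set.seed(master_seed)`), so every reported number is
a deterministic function of the configuration and the master seed.
Boundary moves are clamped: probability mass of an impossible move
effectively becomes "stay" in realised dynamics, and backups at the
boundary reuse the clamped neighbour's value. Off-grid inputs are snapped
to the nearest level with a warning rather than rejected, so serialised
runs can be resumed tolerantly.

## What the simulator emulates — and what it does not

The ensembles emulate the model's own study conditions (`N = 3000` runs at
the preset horizons, fixed or uniform initial states). They are synthetic
in the strict sense: there is no empirical data anywhere in the pipeline,
so passing tests show internal consistency (simulator ↔ exact propagation,
solver ↔ exhaustive enumeration, reproducibility) and reproduction of the
model's reference behaviours — not that the model describes human
decision-makers. Estimating `p_r`, the curves, or the reward weights from
behavioural data is out of scope.

## Validation design

Two independent oracles back the test suite:

* `propagate_exact()` pushes the full state distribution through the kernel
  — for the habitual policy using the *exact* marginal action distribution
  of the clipped-and-snapped Gaussian (normal-CDF bin masses) — giving
  exact per-epoch means that Monte Carlo ensembles must match within
  sampling error.
* `exhaustive_best_policy()` enumerates every deterministic policy of a
  `tiny_instance()` (a few states, actions and epochs) and evaluates each
  under the *same* backup semantics as the solver, so a disagreement
  isolates a solver bug rather than a semantics mismatch; a separate
  plain-expectation evaluation path cross-checks the semantics itself in
  the `γ = (1, 1, 1)`, constant-δ case where the weighted backup must
  reduce to the textbook recursion.

The dominance check compares policies under the planner's own
direction-weighted objective (`evaluate_policy()`), where the solved
policy's optimality is a theorem. Raw (unweighted) cumulative rewards are
reported alongside but are not the planner's objective: under the `fig6`
preset the optimal policy pays a higher analyticity cost than the habitual
one and its raw reward sum can be lower even though its awareness endpoint
is higher.

## Problem sizes and determinism

The default test run solves 99-state programmes with horizons 100–300
(fractions of a second each) and simulates ensembles of up to 3000 runs
(seconds each); the whole suite completes in well under a minute on one
CPU. `solve_sdp()` involves no randomness and is bit-reproducible;
ensembles are bit-reproducible given `(config, master_seed)`.

## Known limitations

* **Expansive backups.** With `γ1 > 1` the value scale is meaningless (only
  the argmax matters), and for horizons much beyond the presets the values
  would overflow `double` range. Renormalising γ is not a fix: with
  normalised weights the backup becomes contractive, neighbouring-state
  value differences shrink below the analyticity cost, and the optimal
  policy collapses to full myopia (`u = 0.01` everywhere) — eliminating
  the self-aware behaviour the model exists to study.
* **Emotion-mode regimes.** The emotion extension contains an absorbing
  low-awareness trap (`δ(s) < 0` below `s ≈ 0.10` makes the planner avoid
  progress) and an early-horizon myopic phase (`τ/T` small). The dynamics
  these presets were designed to probe — irrevocable collapse from a low
  start for an analytical individual, decision oscillation for an intuitive
  one, and an intermediate plateau near 0.7 from a high start — require
  that myopic phase to persist long enough for ensembles to reach the trap.
  Under the default calibration the expansive γ-weighting ends the myopic
  phase within a few tens of epochs, ensembles escape the dip (bottoming
  near 0.17) and saturate near the top of the grid (~0.99). The acceptance
  suite records the intended regimes and currently fails them; the analysis
  above is the reason. These regimes are extremely sensitive to the
  unpublishable interplay of kernel magnitudes, terminal-reward scale and
  emotion profile, and the package deliberately does not tune those
  constants against the expected outcomes.
* The habitual policy ignores the state entirely by construction; no
  learning, no interaction between individuals, and no multi-step shocks
  are modelled.
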
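---
title: "Automatic importance-factor optimization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic importance-factor optimization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autofmo)
```

## The planning problem

Fluence-map optimization (FMO) chooses nonnegative beamlet intensities $x$
minimizing a weighted objective over the voxel dose $D = Ax$:

$$ f(D) = \sum_{i=1}^{l} w_i\, f_i(D), \qquad \sum_i w_i = 1,\; w_i \in (0,1). $$

Each subscore $f_i$ penalizes one clinical constraint on one structure. The
importance factors $w_i$ are the knobs a human planner normally turns;
`autofmo` turns them automatically. Two mechanisms drive the automation:

1. **Correction factors.** After each inner solve, every subscore's weight
   is updated additively, $w^{new}_i = w^{old}_i + k_i \cdot
   \mathrm{factor}_i$, where the factor is the ratio of the constraint's
   current plan value to its prescribed value, oriented so violation
   raises the weight (see `?correction_factor` for the full table), and the
   weights are renormalized to sum 1. Because the update is additive on
   normalized weights, even a factor $< 1$ adds mass; what matters is the
   *relative* size of the factors, which shifts emphasis toward violated
   constraints. Factors are clamped to $[0.01, 100]$ so a degenerate plan
   (e.g. a cold start with zero dose in a structure) cannot produce an
   infinite or zero ratio.

2. **Compensation.** After the adjustment stage (default 5 alternations of
   inner solve and weight update) the plan is evaluated. If it fails, the
   correction factor of the *targeted* subscores is multiplied by a
   coefficient $k$ growing on an arithmetic schedule $k = k_0 +
   (\mathrm{iter}-1)\cdot\mathrm{steplength}$, and the adjustment stage is
   rerun, up to 10 times. Targets are the PTV subscores when coverage
   fails, otherwise the subscore linked to the violated dose–volume rule
   with the highest dose level — the high-dose region of an OAR is the
   clinically urgent one. Default schedules are $(k_0,\mathrm{step}) =
   (1,1)$ for the dose–volume model, $(10,5)$ for the gEUD model and
   $(1,1)$ for the NTCP model.

An "iteration" of the adjustment stage is one full inner solve followed by
one weight update: correction factors are only meaningful on a reasonably
converged dose, so we do not interleave updates with solver steps. Each
compensation iteration restarts the adjustment stage from the initial
weights and the cold-start fluence; this makes every run a pure function of
its inputs, at the cost of re-solving from scratch (each inner solve is
sub-second at the shipped problem sizes). Targets are re-selected from the
most recent evaluation rather than frozen at the first failure, so pressure
follows the currently-violated constraint while the $k$ schedule itself
stays strictly arithmetic.

## Plan evaluation

A plan is **acceptable** when

* PTV coverage: $V_{PTV}(D_{min}^{pre}) \ge 95\,\%$ (the volume fraction
  receiving the prescribed minimum dose), and
* every maximum dose–volume constraint of the prescription holds,
  $V(D_1) \le V_1$ (non-strict).

These two checks gate the loop for all three objective models — the
dose–volume constraints of the prescription are used for evaluation even
when the objective being optimized is biological (gEUD or NTCP). A separate
table of *clinical guidelines* (for the pelvic preset: rectum V50 < 50 %,
V60 < 35 %, V65 < 25 %, V70 < 20 %, V75 < 15 %; bladder V65 < 50 %,
V70 < 35 %, V75 < 25 %, V80 < 15 %, strict inequalities) is evaluated and
reported but does not gate acceptance. The distinction matters: guidelines
with no prescribed counterpart map to subscores whose penalty is already
zero once the prescription is met, so no amount of compensation weight can
move them — gating on them would stall the loop on plans the prescription
itself cannot improve. When guidelines fail while the prescription is
satisfied, the remedy is a tighter prescription, which is a clinical
decision, not an optimizer decision.

When all criteria hold, the loop stops. An optional post-pass
(`push_coverage = TRUE`) keeps adjusting while everything remains
satisfied and returns the last acceptable plan; it is off by default
because the stopping point of "improve as far as possible" is otherwise
arbitrary. If the budget is exhausted the best evaluated plan is returned,
flagged unacceptable; "best" is lexicographic on (PTV satisfied, number of
satisfied rules, lower objective).

## Objective models

With $H$ the strict step function ($H(x)=1$ iff $x>0$, so a constraint met
with equality is penalty-free):

* PTV minimum dose: $f_{Min} = \frac1N \sum_i H(D_{Min}-D_i)(D_{Min}-D_i)^2$.
* PTV mean dose: $f_{Mean} = \frac1N \sum_i (D_i - D_{Mean})^2$.
* Maximum dose–volume (dv model): $f_{DV} = \frac1N \sum_i
  H(D_i-D_1)H(D_2-D_i)(D_i-D_1)^2$, where $D_2$ is the dose of descending
  rank $\lceil N V_1 / 100 \rceil$ in the *current* plan. Voxels above
  $D_2$ are deliberately left alone: the hottest $V_1\%$ of the structure
  is allowed, and penalizing only the band $(D_1, D_2)$ makes the
  nonconvex dose–volume constraint tractable for a gradient method.
* gEUD model: $f_{gEUD} = \max(gEUD_a(D) - gEUD^{pre}, 0)$ with
  $gEUD_a = (\frac1N\sum D_i^a)^{1/a}$.
* NTCP model: $f_{NTCP} = \max(\ln(1-NTCP^{pre}) - \ln(1-NTCP_{LKB}(D)), 0)$
  with $NTCP_{LKB} = \Phi\!\big((gEUD_{1/n} - TD_{50})/(m\,TD_{50})\big)$.
  The logarithmic form is convex in $NTCP$ and bounded gradients make it
  well-behaved; if $NTCP$ is numerically 1 the penalty is capped at $10^6$
  with a warning.

### Dynamic dose–volume windows

$D_2$ is recomputed at **every** objective evaluation, not frozen per inner
solve. With a frozen $D_2$ the per-voxel window penalty is discontinuous: a
voxel crossing the frozen threshold from above adds $(D_2-D_1)^2/N$ in a
single jump, and on a cold-start plan (where a large fraction of the
structure sits above $D_2$) the line search rejects every descent step and
the solver stalls at the start. Recomputing $D_2$ keeps the penalty
continuous — when a voxel crosses the quantile boundary it swaps with
another voxel of equal dose, so the penalized set changes without a jump.
The analytic gradient treats $D_2$ as locally constant, which is exact
except on the measure-zero set where two voxels tie at the quantile.

### Gradients and the square-root parameterization

The inner problem is solved by L-BFGS (`stats::optim`, method
`"L-BFGS-B"` without box constraints) in $u$ with $x = u^2$, so
nonnegativity is structural: $\partial f/\partial u_j = 2u_j (A^\top
\partial f/\partial D)_j$. All quadratic subscores are differentiated
exactly; step-gated terms use the subgradient consistent with strict $H$;
the gEUD and NTCP subscores are differentiated through the power mean and
the normal CDF ($\partial gEUD/\partial D_i = \frac1N (D_i/gEUD)^{a-1}$).
A finite-difference audit (central differences, 20 random instances per
subscore type, kept away from penalty kinks) bounds the relative error at
$10^{-5}$ in the test suite.

One consequence of the parameterization: $u = 0$ is a stationary point
(the factor $2u_j$ kills the gradient), so the solver must start strictly
positive. `initial_fluence()` returns a uniform vector scaled so the mean
PTV dose equals its prescription — a one-parameter least-squares fit.

## The synthetic phantom and dose model

Real planning uses CT-based dose engines; this package's contribution is
the automation layer, so the dosimetry is deliberately simple and fully
synthetic:

* **Geometry** — single-slice 2-D phantoms built from disks, annuli and
  crescents. The shipped preset (64×64 grid, 2.5 mm voxels) emulates a
  male pelvis: circular body (r = 75 mm), central PTV disk (r = 12 mm), a
  posterior crescent "rectum" and an anterior disk "bladder" each ~3 mm
  from the PTV surface, and a 15 mm normal-tissue ring (scaled down from
  the clinical 5 cm ring to fit the grid). The OAR gaps are of the order
  of the beam penumbra, which is what makes the coverage/sparing trade-off
  non-trivial.
* **Beams** — 5 coplanar parallel beams at gantry angles 36°, 100°, 180°,
  260°, 324° (clockwise from anterior), 5 mm beamlets laid out to cover
  the PTV's circumscribed radius plus a 10 mm margin (identical count per
  beam by construction).
* **Kernel** — per beamlet, dose $= e^{-\mu\,\mathrm{depth}} \cdot
  e^{-\ell^2/2\sigma^2}$ with $\mu = 0.005\,$mm⁻¹ (soft-tissue scale for
  6 MV), $\sigma = 3$ mm penumbra; depth is measured from the body entry
  point of each lateral ray position and voxels outside the body receive
  nothing. Entries below $10^{-4}$ of a beamlet's maximum are dropped for
  sparsity.

These defaults were chosen once so that the standard prostate prescription
(74/78 Gy PTV, rectum 50/40–65/25–75/15, bladder 65/35–70/30–75/16) is
geometrically achievable — the preset is a stand-in for patient anatomy,
not a reproduction of any patient. What the phantom does *not* emulate:
3-D scatter, tissue heterogeneity, beam divergence, organ-shape
variability, and realistic structure volumes (the rectum is 50 voxels, so
dose–volume percentages are quantized at 2 %). Passing tests on the
phantom demonstrate that the automation loop works as specified, not that
the dose engine is clinically accurate.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `inner_adjust_iters` | 5 | iterations | adjustment iterations per pass; enough for factors to stabilize |
| `max_compensation_iters` | 10 | iterations | compensation budget; with the defaults, ≤ 55 inner solves per run |
| `k0`, `steplength` | (1,1) dv, (10,5) gEUD, (1,1) NTCP | — | gEUD overshoots are in Gy (order 1–10), so its schedule is coarser |
| `max_iters` (inner) | 50 | L-BFGS iterations | keeps a full run in seconds; raise for tighter convergence |
| `tol` (inner) | 1e-6 | relative Δf | mapped to optim's `factr` |
| `mu_attenuation` | 0.005 | mm⁻¹ | 6 MV soft-tissue scale |
| `sigma_penumbra` | 3 | mm | typical MLC penumbra width |
| `beamlet_width` | 5 | mm | standard beamlet resolution |
| LKB rectum | TD50 76.9 Gy, m 0.13, n 0.09 | — | literature-tradition serial-organ values; **not** prescriptive |
| LKB bladder | TD50 80 Gy, m 0.11, n 0.5 | — | literature-tradition parallel-organ values |

The gEUD exponents of the shipped gEUD prescriptions are `a = 1/n` of the
corresponding LKB set (≈ 11 for the rectum, 2 for the bladder).

## Numerical choices and degenerate inputs

* $H(0) = 0$ everywhere: a constraint met exactly is penalty-free, and the
  boundary set has measure zero for continuous doses.
* $D_{x\%}$ uses the descending-rank convention (rank
  $\lceil Nx/100\rceil$), exact on voxels, no interpolation; $V(d)$ counts
  with $\ge$.
* gEUD is computed as $D_{max}\,(\frac1N\sum (D_i/D_{max})^a)^{1/a}$ to
  avoid overflow at large exponents; `a = 1` short-circuits to the exact
  mean; zero doses with $a < 0$ are an error (undefined power mean).
* Correction factors clamp to $[0.01, 100]$; a non-finite ratio warns and
  returns the ceiling.
* `solve_fmo()` never returns an iterate worse than its start (a final
  safeguard comparison), so the descent property holds even if the line
  search aborts.
* The conformity index counts the reference isodose over the body mask
  only; voxels outside the body receive no dose by construction. If no
  voxel reaches the reference dose, CI is defined as 0 with a warning.
* Phantom rasterization rejects specs whose PTV is empty or overlaps an
  OAR; the normal-tissue ring excludes the PTV and the OARs.

## Design choices where the design was open

* **Loop acceptance vs clinical guidelines.** The loop accepts on the
  prescription's own dose–volume constraints (non-strict); the clinical
  guideline table is reported separately (strict). Rationale in "Plan
  evaluation" above.
* **Evaluation-to-subscore mapping.** A violated rule maps to the dv
  subscore with the largest $D_1$ at or below the rule's dose level:
  pushing $V(D_1)$ down also drags the volume at any higher dose, whereas
  a subscore whose own constraint is already satisfied exerts no gradient.
* **Compensation restarts.** Weights and fluence restart each compensation
  iteration; warm-starting would couple iterations and make the meaning of
  the $k$ schedule depend on history length.
* **dv_min** is implemented as the cold-volume mirror of the hot-volume
  surrogate (window $[D_2, D_1]$) but no shipped prescription exercises
  it; it is flagged experimental.
* **TCP constraints** are supported in the correction-factor table given a
  user-supplied evaluator, but no TCP model ships and no TCP subscore is
  differentiated — the factor mechanism is generic, the model is not ours
  to invent.
* **Tidy surfaces over tabular cores.** DVHs, metrics, histories and
  traces are tibbles with `tidy()`/`glance()`/`autoplot()` methods; the
  phantom, influence matrix and plan stay list-based S3 objects because a
  sparse matrix and a voxel grid are not data frames.

## Known limitations

* The shipped objectives contain no normal-tissue term (the models cover
  PTV + OAR subscores only), so dose conformity outside the constrained
  structures is whatever the beam geometry gives — the worked example's
  conformity index (~0.39) reflects this, while coverage and OAR sparing
  are controlled. Adding a ring constraint to a custom prescription is
  supported and tightens conformity at some cost to the OARs.
* On this phantom the gEUD model with serial-organ exponents controls the
  high-dose region of the rectum extremely well but leaves mid-dose
  volumes (V50, V60) above the clinical guidelines: once
  $gEUD_{11} \le 60$ Gy is met the subscore's gradient vanishes, and no
  compensation weight can create pressure below the prescription. The run
  honestly reports budget exhaustion with the best plan. This is a
  property of gEUD-only OAR objectives, amplified by a 2-D geometry in
  which the rectum lies in every beam's path.
* Problem sizes are desk-scale by design: 64×64 grids, ~45 beamlets,
  ≤ 55 inner solves per run (a full automatic run takes ~0.1–2 s). The
  algorithms are dimension-agnostic; the containers are not optimized for
  clinical-scale matrices.
* The inner solver's iteration cap (50) trades exactness for speed; the
  quadratic-oracle test uses a higher cap to verify convergence to the
  true optimum.

## What the tests establish

Unit suites verify every subscore, metric and factor against hand values
and brute-force recomputation; property suites check gradient correctness
(finite differences), descent, determinism, weight normalization, the
arithmetic $k$ schedule and the iteration budget; end-to-end suites run
the full automatic loop on the default phantom and assert the prescribed
coverage, dose–volume and NTCP outcomes. `scripts/acceptance.R` recomputes
the end-to-end quantities from scratch on each invocation.
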
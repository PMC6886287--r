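# autofmo

Automatic optimization of the importance factors in IMRT inverse planning.

Inverse planning for intensity-modulated radiotherapy (IMRT) chooses beamlet
intensities `x ≥ 0` that minimize a weighted sum of structure-specific
penalty subscores,

```
f(D) = Σᵢ wᵢ fᵢ(D),     D = A x,
```

where `A` is the sparse dose-influence matrix, `D` the voxel dose, and the
importance factors `wᵢ` encode the clinical trade-off between target
coverage and organ-at-risk (OAR) sparing. In routine practice those factors
are tuned by hand, by trial and error. `autofmo` automates the tuning: after
each inner fluence-map optimization (FMO) every factor is updated by a
*prescription-value-based correction factor* — the ratio of the constraint's
current plan value to its prescribed value, oriented so a violated
constraint gains weight and an over-satisfied one loses it:

| constraint | correction factor |
|---|---|
| minimum dose (PTV) | `D_min_pre / D_min_cur` |
| maximum dose | `D_max_cur / D_max_pre` |
| mean dose (PTV / OAR) | `max(cur,pre)/min(cur,pre)` / `cur/pre` |
| max (min) dose–volume | `V₂/V₁` (`V₁/V₂`) |
| gEUD, OAR `a ≥ 1` (PTV `a < 1`) | `gEUD_cur/gEUD_pre` (`gEUD_pre/gEUD_cur`) |
| NTCP (TCP) | `NTCP_cur/NTCP_pre` (`TCP_pre/TCP_cur`) |

Weights evolve additively, `w_new = w_old + k · factor`, and are renormalized
to sum 1. The plan is then evaluated: PTV coverage `V(D_min_pre) ≥ 95 %` and
the prescription's dose–volume constraints `V(D₁) ≤ V₁`. If the plan is not
acceptable, a *compensation coefficient* `k` on an arithmetic schedule
(`k = k₀ + (iter−1)·steplength`) multiplies the correction factor of the
failing subscore — the PTV subscores when coverage fails, otherwise the
highest-dose violated OAR constraint — and the adjustment stage reruns,
until the plan is acceptable or the compensation budget (default 10
iterations around a 5-iteration adjustment stage) is exhausted.

Three objective models are provided:

* **dv** — quadratic PTV min/mean penalties plus the convex dose–volume
  surrogate `Σ H(Dᵢ−D₁)·H(D₂−Dᵢ)·(Dᵢ−D₁)²/N` per OAR constraint, where `D₂`
  is the current dose at the prescribed hot-volume rank;
* **geud** — linear overshoot penalties `max(gEUD_a(D) − gEUD_pre, 0)` on
  Niemierko's generalized equivalent uniform dose;
* **ntcp** — the convex logarithmic form
  `max(ln(1−NTCP_pre) − ln(1−NTCP_LKB(D)), 0)` of the
  Lyman–Kutcher–Burman model `NTCP = Φ((gEUD_{1/n} − TD50)/(m·TD50))`.

The inner solves use L-BFGS on the square roots of the beamlet weights
(`x = u²`), which enforces nonnegativity without box constraints. Everything
runs on synthetic 2-D phantoms with an analytic beam kernel (exponential
depth attenuation × Gaussian penumbra), so the whole pipeline is
self-contained and fast; the automation layer, not the dose engine, is the
point.

## Worked example

```r
library(autofmo)

phantom <- generate_phantom(default_prostate_spec())   # 64x64, 2.5 mm voxels
im      <- compute_influence_matrix(phantom, beam_spec())  # 5 beams, 45 beamlets
run     <- run_automatic(phantom, im, default_prostate_prescription(),
                         model = "dv")
run
#> <autofmo_run> model=dv: acceptable plan after 5 inner solves
#> <plan_evaluation> PTV coverage 100.0% (ok); 6/6 DV rules met; acceptable
#>   clinical guidelines: 9/9 met

glance(run)
#>   model accepted n_solves k_final objective ptv_coverage_pct n_criteria_met
#> 1    dv     TRUE        5      NA  0.001542              100              6
#>   n_criteria     CI    HI
#> 1          6 0.3878 1.004
```

The adjustment stage alone (5 inner solves) reaches an acceptable plan:
every PTV voxel receives the prescribed 74 Gy minimum (coverage 100 %), all
six prescribed dose–volume constraints hold (e.g. rectum V50 = 40 % against
the prescribed 40 %, bladder V70 = 14.3 % against 30 %), and all nine
clinical guidelines are met. The homogeneity index `HI = D5%/D95% = 1.004`
indicates a near-uniform target dose; the conformity index is modest
because the shipped objectives contain no normal-tissue term (see the
methods vignette). `tidy(run)` returns the per-iteration weight/factor
trajectory; `autoplot(run)`, `plot_dose(run)` and `plot_weight_history(run)`
draw the DVHs, the planar dose and the importance-factor evolution.

A shell entry point wraps the same pipeline:

```sh
exec/autofmo run --model dv --out results/ --seed 1      # exit 0 = acceptable
```

writing `dvh.csv`, `metrics.csv`, `weights_history.csv`, `solver_trace.csv`,
`plan_report.json` and a config echo to the output directory.

## Conventions

Grids are single-slice, row-major, with voxel centers on a regular lattice;
coordinates are in mm with the origin at the grid center and y pointing
"north" (anterior). Gantry angles are measured clockwise from north,
parallel-beam geometry. Dose–volume queries use exact voxel counting with
`V(d)` closed at the threshold (`≥ d`), and `D_x%` is the dose of descending
rank `⌈N·x/100⌉`.
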
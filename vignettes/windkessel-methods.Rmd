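---
title: "Model and methods: fast Windkessel parameter estimation and medication-response simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(windkesselrc)
```

## The problem

Adjusting the vascular parameters of a lumped cardiovascular model until its
simulated pressures match a patient's measurements is an enumeration-style
search: minutes to hours per patient when the forward model is expensive.
`windkesselrc` replaces that search with a tabulate-once, look-up-many
scheme: the closed-form systolic and diastolic pressures of a single
Windkessel vessel segment are tabulated over the admissible box of
resistance `R` and compliance `C`, the measured SBP and DBP each define an
iso-contour on their surface, and the (unique, in practice) crossing of the
two contours is the parameter estimate. A Newton polish on the true forward
map removes the tabulation error, so batch estimation costs milliseconds
per patient at machine-precision round-trip accuracy.

On top of the estimator the package simulates ACE-inhibitor therapy:
pre/post blood-pressure records give per-dose fractional changes
$\Delta R$, $\Delta C$; a saturating dose-effect curve is fitted; applying
the curve to a new patient's baseline predicts their post-treatment
pressures; and a seven-component cardiac integrated index (CII) summarises
the hemodynamic state before and after.

## The vessel model

One segment is a bond-graph element with state variables vascular volume
$V$ (pressure $P = V/C$) and pressure momentum $\lambda$ (flow
$Q = \lambda/I$):

$$\frac{dV}{dt} = Q_{in} - Q, \qquad
  \frac{d\lambda}{dt} = P - P_{next} - R\,Q,$$

which combine into the second-order pressure equation

$$I C \ddot P + R C \dot P + P = I \dot Q_{in} + R\,Q_{in} + P_{next}.$$

Fixed physics: blood inertance $I = 0.23$ mmHg·s²/mL and downstream
boundary pressure $P_{next} = 30$ mmHg. The admissible inverse-problem box
is $R \in [1.55, 3.60]$ mmHg·s/mL, $C \in [0.30, 0.60]$ mL/mmHg.

The inflow over a 0.8 s cycle (0.3 s systole) is piecewise sinusoidal —
half-sine shoulders in early/late systole, a raised full sine in
mid-systole, zero in diastole — continuous at all branch boundaries, with
amplitude 70 in model flow units. Integrated over systole the inflow
delivers about 14.7 model units per beat; this is **not** calibrated to a
physiological stroke volume (~70 mL), so flow-derived quantities (SV, CO
in `profile_from_model()`) are model-internal and documented as such.

### Closed-form branches

The characteristic roots of $I C s^2 + R C s + 1 = 0$,

$$s_\pm = \frac{-RC \pm \sqrt{R^2C^2 - 4CI}}{2CI},$$

always have negative real part. Part of the admissible box (small $R$ and
$C$, below the curve $C = 4I/R^2$) has a negative discriminant; there the
free response is a damped oscillation and all closed forms are evaluated
through the real part of the complex-exponential pair. An exactly repeated
root is refused with a dedicated error: the two-exponential form
degenerates on that measure-zero curve and the numeric integrator covers
it.

Each inflow branch contributes a particular solution of the form
*constant + steady sinusoidal response* (solved exactly from the 2×2
in-phase/quadrature system), plus two homogeneous degrees of freedom:

* `systolic_pressure()` is the mid-systole branch with reference
  coefficients $K_1 = K_2 = 1$;
* `diastolic_pressure()` is the unforced decay
  $K_3 e^{s_1 t} + K_4 e^{s_2 t} + P_{next}$;
* `assemble_cycle()` solves an 8×8 linear system for all four branches'
  coefficients so that pressure and its derivative are continuous at the
  three branch boundaries and periodic across the cycle — this is the
  exact steady-state wave, and `solve_ode_numeric()` (fixed-step RK4,
  2000 steps/cycle, steady state declared at a successive-cycle difference
  below $10^{-4}$ mmHg) converges to it to ~$10^{-5}$ mmHg.

Correctness is enforced by an ODE-residual oracle in the test suite: both
branches are differentiated numerically (5-point stencils) and must satisfy
the vessel equation to a relative residual below $10^{-6}$ at 50 interior
points for 20 parameter pairs spanning the box.

### The diastolic coefficient repair

With the literal reference constants $K_3 = -200$, $K_4 = -400$ the
diastolic decay approaches $P_{next}$ *from below* and end-diastolic
pressure is strongly negative over most of the box (about $-106$ to $+24$
mmHg) — physically untenable, and it leaves every clinically relevant DBP
(70–102 mmHg) unreachable. A magnitude-preserving sign flip,
$K_3 = +200$, $K_4 = +400$, restores the classic monotone decay from above
and spans end-diastolic pressures of roughly 36–166 mmHg over the box.
This *classic* policy is the package default for the DBP surface; the
literal constants remain available (`dbp_policy = "literal"`) for fidelity
checks. The choice is load-bearing: with it, every pressure pair we ask
the estimator to invert (120/70, and cohort baselines from 118/78 up to
161/101) has a unique in-box solution; without it, none does.

### Two forward-map modes

`forward_bp()` offers two conventions:

* **`fixed_t`** (default): SBP is the $K_1=K_2=1$ systolic branch
  sampled at the fixed time $t = 0.14$ s; DBP is the classic diastolic
  decay at end-diastole $t = 0.8$ s. Over the box this surface pair spans
  ~107–209 / ~36–166 mmHg — the clinical range the estimator must cover.
* **`extremum`**: SBP/DBP are the max/min of the cycle-periodic assembled
  wave. This is the physically self-consistent pulse (SBP 67–113 mmHg,
  pulse pressures 16–33 mmHg over the box) but its systolic values cannot
  reach common clinical SBPs, because the uncalibrated inflow amplitude
  caps the cycle-mean pressure at $R \cdot \bar Q + P_{next} \le 96$ mmHg.

The two modes ride different solution conventions and differ by up to
~100 mmHg in SBP; they are *not* interchangeable and no agreement between
them is claimed. Estimation defaults to `fixed_t` for coverage;
waveform-shape work (MAP, pulse morphology) uses the assembled cycle.

A related caveat: with the phase-consistent mid-systole forcing
$\tfrac{A}{2}\sin(2\pi(t - T_s/4)/T_s)$, the fixed-coefficient systolic
branch peaks at $t \approx 0.223$ s — strictly inside the mid-systole
window, but late in it, not at the nominal sampling time 0.14 s. (The
0.14 s peak is recovered only if the quarter-period phase shift is dropped
from the forcing, which would make the inflow discontinuous between
branches; we keep the continuous inflow.) The fixed sampling time is
therefore a surface-construction *convention*, not the location of the
waveform maximum, and the package treats it as such.

## The estimator

`build_surface()` tabulates `forward_bp()` on the (default) 201×201 grid —
vectorised, ~20 ms — and memoises the result per session keyed by grid,
mode and physics, so batch estimation is O(contour extraction) per
patient. `extract_isocontour()` uses marching squares with linear edge
interpolation (`grDevices::contourLines`); every returned point
re-interpolates to the target level to $10^{-6}$ mmHg.
`intersect_contours()` finds **all** segment-pair crossings exactly; a
single crossing is `status = "unique"`, several are reported as
`"multiple"` with the crossing nearest the brute-force argmin first
(uniqueness is surfaced, never silently assumed), none is a diagnosed
`"none"` row. Each crossing is then polished by 2–3 Newton steps on the
true forward map with a central finite-difference Jacobian, which takes
round-trip errors from ~0.1% (bilinear tabulation scale) to machine
precision.

Numerical notes:

* The SBP surface is near-affine in $R$ (~49.5 mmHg per unit $R$) and
  almost flat in $C$; the DBP surface rises in both. SBP contours are
  near-vertical, DBP contours slope downward, so crossings are
  well-conditioned and unique in practice. Monotonicity of SBP in $R$ is
  verified on the full grid in the acceptance suite.
* Along the root-discriminant curve $R^2C^2 = 4CI$ the surfaces are
  continuous but their derivative has a kink; contour polylines can wiggle
  there and report several near-coincident crossings. The polish step
  collapses them to the same solution; the `multiple` status is retained
  as a diagnostic.
* `brute_force_rc()` (dense-grid argmin of the squared pressure misfit) is
  the estimator's in-package oracle. Because the misfit valley is
  anisotropic, its discrete argmin can sit one node sideways of the
  polished estimate; agreement is therefore asserted at one-cell
  resolution.
* Degenerate requests (`sbp <= dbp`) are input errors; pressures
  reachable only at the box edge are flagged `boundary = TRUE`.

## Dose-effect curves

Treatment effects enter as fractional changes
$\Delta R = (R_{post} - R_{pre})/R_{pre}$ (and likewise $\Delta C$),
estimated per record by inverting the pre- and post-treatment pressure
pairs. The dose-effect family is the zero-anchored rectangular hyperbola

$$E(d) = \frac{E_{max}\, d}{d_{50} + d},$$

chosen because ACEI binding is a saturating reaction and the observed
response curves rise and plateau. The fit is weighted least squares
(`minpack.lm::nlsLM`, weights = group size when given, $d_{50} > 0$
enforced); an all-zero response short-circuits to a flat curve, fewer than
three distinct doses is an explicit error.

`apply_dose()` maps a baseline through the fitted fractions and clamps the
result to the admissible box with a warning — clamping is visible, never
silent.

## The synthetic cohort

`generate_synthetic_cohort()` is the package's study-condition generator:
it emulates a dose-ranging ACEI programme in which only blood pressure is
measured. Baselines are drawn uniformly from $R \in [2.3, 3.0]$,
$C \in [0.32, 0.45]$ — elevated resistance and reduced compliance, the
heart-failure pattern, with the box sized so that the largest simulated
effect keeps post-treatment parameters inside the admissible grid. The
generating truth is:

| drug | $E_{max}(\Delta R)$ | $E_{max}(\Delta C)$ | $d_{50}$ (mg/d) | doses (mg/d) |
|---|---|---|---|---|
| enalapril | $-0.30$ | $+0.12$ | 12 | 2.5, 5, 10, 20, 40 |
| lisinopril | $-0.30$ | $+0.28$ | 0.9 | 1.25, 2.5, 5, 10, 20, 40 |

i.e. enalapril acts gradually and predominantly on resistance; lisinopril
moves resistance and compliance in near-parallel and saturates early
(>95% of its asymptote by 20 mg/d). All four pressures receive iid
Gaussian noise (sd 2 mmHg, typical cuff repeatability); draws whose noisy
pressures leave the mapping-surface range are resampled with a reported
count; a fixed seed makes the table byte-identical.

What the generator does *not* emulate: individual response heterogeneity
(one truth curve per drug), therapy-duration effects, group-mean reporting
(records are individual patients), and any drug action outside $R$ and
$C$. Passing recovery tests therefore shows the estimation-and-fitting
chain is consistent — not that real trial data would identify the same
curves.

A quantitative limitation worth stating: through the inverse chain a
2 mmHg pressure noise becomes $\Delta R$ noise of sd ≈ 0.019 but
$\Delta C$ noise of sd ≈ 0.049, because DBP is roughly four times less
sensitive to fractional changes of $C$ than SBP is to $R$. At ~20 records
per dose the resistance curves are recovered to a few percent, while a
small compliance asymptote (enalapril's $+0.12$) is not identifiable to
10% — its standard error alone exceeds that band. Parameter-recovery
claims in the test suite are therefore made on the resistance curves; the
compliance fit is reported with its uncertainty, not asserted to a bound
it cannot meet.

## The cardiac integrated index

`compute_cii()` is the dot product of the seven-component profile (MAP,
PP, HR, CO, SV, EF, SW in mmHg, mmHg, beats/min, L/min, mL, %, J/beat)
with fixed weights

```{r}
cii_weights()
```

The weights were derived once by principal component analysis of model
outputs and are shipped as constants; the underlying data are not
available, so the derivation is out of scope. The sum uses **raw** values
in the stated units — reproducing the recorded worked-example scores
(9.85/4.01 for enalapril, 13.22/1.80 for lisinopril) proves raw rather
than standardised components are intended — which makes the index
deliberately unit-dependent. Lower is better: CO, SV, EF carry negative
weights, MAP, PP, HR, SW positive ones.

`profile_from_model()` supplies the components a single vessel segment
can produce (MAP as the trace's time average, PP as its excursion, HR
from the cycle length with an override, SV/CO from the inflow integral,
in model units); EF and SW are ventricular quantities and must be
supplied by the user.

## Worked example

```{r}
est <- estimate_rc(120, 70)
est[, c("R", "C", "status", "sbp_residual", "dbp_residual")]
```

```{r}
check_reference_example()
```

```{r, fig.alt = "SBP mapping surface over the (R, C) grid"}
autoplot(build_surface(parameter_grid(n_R = 101, n_C = 101), "sbp"))
```

## Problem sizes and reproducibility

The package's own validation uses: 201×201 estimation surfaces; the
ODE-residual oracle at 20 parameter pairs × 50 time points per branch;
closed-form/integrator agreement at 2000 RK4 steps per cycle; 100
round-trip inversions and 25 brute-force comparisons under a fixed seed;
and a 200-record synthetic cohort (noise sd 2 mmHg) for dose-curve
recovery. All randomness is seeded; surfaces, estimates and cohorts are
deterministic given their inputs. `scripts/acceptance.R` recomputes the
worked-example quantities from the installed package and writes them as
JSON.

## Known limitations

* Single segment only: no multi-segment network, wave reflection,
  nonlinear compliance or baroreflex.
* The inflow amplitude is model-internal; SV/CO from
  `profile_from_model()` are not in clinical units.
* The fixed-$t$ SBP surface convention and the cycle-extremum convention
  are not mutually consistent; estimates are only meaningful within one
  mode.
* EF and SW cannot be produced by this model and are pass-through
  supplements; CII differences between baseline and prediction are driven
  by the pressure-derived components only, unless the user updates the
  supplements from a richer model.
* Real post-treatment cohort pressures for the packaged baselines were
  not published; dose-effect fits on real data reproduce the *procedure*,
  not any published curve.
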
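---
title: "Constitutive characterization of venous tissue with veinfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constitutive characterization of venous tissue with veinfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`veinfit` characterizes the passive mechanical response of venous tissue
(basilic and great saphenous vein strips are the motivating application)
as an incompressible, hyperelastic, anisotropic solid. The strain energy
density is the four-fiber-family exponential form built on a neo-Hookean
matrix:

$$W = \frac{\mu}{2}(I_1 - 3) +
\sum_{j=1}^{4} \frac{k_1^j}{4 k_2^j}
\left( e^{k_2^j (I_4^j - 1)^2} - 1 \right),$$

with $I_1 = \operatorname{tr} \mathbf{C}$, $\mathbf{C} = \mathbf{F}^T
\mathbf{F}$, and $I_4^j = \mathbf{M}^j \cdot \mathbf{C}\mathbf{M}^j$ the
squared stretch of the $j$-th fiber family. The preferred directions
$\mathbf{M}^j$ lie in the cylindrical surface of the vessel: family 1 is
circumferential ($\beta^1 = 0$), family 2 longitudinal ($\beta^2 =
90^\circ$), and families 3 and 4 sit symmetrically at $\pm\beta$ with
shared stiffness, so eight parameters are free: $\mu$, $k_1^1$, $k_2^1$,
$k_1^2$, $k_2^2$, $k_1^3$, $k_2^3$, $\beta$. The model is treated as
phenomenological: the fiber families are a convenient parameterization of
the observed anisotropy, not a histological claim. Because the two
diagonal families are balanced, a strip loaded on a cylinder axis admits
a diagonal deformation gradient (no shear), which is the kinematic
assumption behind everything below.

Nominal (first Piola-Kirchhoff) stress follows from
$\mathbf{P} = \partial W / \partial \mathbf{F} - p \mathbf{F}^{-T}$,
where the hydrostatic multiplier $p$ enforces incompressibility and is
fixed by traction boundary conditions. Units are kPa and dimensionless
stretch throughout; angles are degrees at every interface and radians
internally.

## The uniaxial strip problem

A strip loaded along one in-plane axis has two traction-free directions.
No fiber family has a radial component, so the thickness direction gives
$p = \mu \lambda_R^2$ exactly, and the remaining unknown — the in-plane
transverse stretch — solves a single scalar equation (zero transverse
nominal stress). `solve_transverse()` brackets that root in
$[1/\lambda, 1]$, the physically expected contraction regime, widening
once to $[0.3, 1.5]$; a safeguarded Newton/bisection iteration (compiled)
converges to a relative stretch tolerance of $10^{-12}$, leaving a
transverse stress residual below $10^{-9}\max(1, P)$ kPa. States whose
root would fall outside $[0.3, 1.5]$ are reported as inadmissible rather
than silently extrapolated. Nesting this per-point solve inside the
fitting objective realizes the zero-transverse-stress constraints
exactly, so the parameter identification is bound-constrained only — no
penalty weights to tune.

Two numerical details are worth noting. The fiber energy term is a $0/0$
limit as $k_2 \to 0$; below $k_2 = 10^{-8}$ it is evaluated by its series
$(k_1/4) x^2 (1 + k_2 x^2/2)$. Exponential arguments beyond 700 would
overflow double precision; the energy reports a divergence instead of
returning `Inf`.

## From raw specimens to representative curves

Each donor contributes 2-4 strips per direction. `clean_loading_branch()`
re-references each loading branch to its first sample and prunes it to a
strictly increasing envelope (no smoothing). `build_representative()`
then averages specimens at *fixed stress*: `m = 20` stress levels
uniformly spaced on `(0, 200]` kPa, each specimen's stretch interpolated
(monotone piecewise-linear) at those levels and averaged arithmetically.
Stress-parameterized averaging was chosen because the representative
curves are defined on a fixed nominal-stress range; the transposed
(stretch-parameterized) convention and a `(1, 0)` anchor point are
available as options. The grid excludes 0 kPa to avoid a degenerate
all-zero point. When a specimen does not reach 200 kPa the range is
truncated to the common maximum (with a message) by default.

## Parameter identification

`fit_four_fiber()` minimizes

$$Q = \sum_{i=1}^{m} \left[
(P^{\mathrm{EXP}}_{\theta\Theta} - P^{\mathrm{MOD}}_{\theta\Theta})^2_i +
(P^{\mathrm{EXP}}_{zZ} - P^{\mathrm{MOD}}_{zZ})^2_i \right],$$

with model stresses evaluated at the experimental stretches through the
uniaxial solver. The objective as written is unweighted; optional
per-direction weights are available. Goodness of fit is reported as
$R^2 = 1 - SS_{res}/SS_{tot}$ per direction.

The landscape is the hard part: $k_1$ and $k_2$ within a family are
strongly correlated, tabulated $k_2$ values for venous tissue span four
orders of magnitude, and distinct assignments of the observed stiffness
to the four families form separate basins. The optimizer therefore
combines, deterministically under one seed:

1. **Staged structural starts.** Each direction's curve is first fitted
   alone with the matrix plus its on-axis family (3 parameters, coarse
   log-grid initializations, top two distinct basins kept), then
   diagonal-dominated and mixed hypotheses are fitted the same way.
   Because each stage absorbs its direction's linear stiffness into its
   own $\mu$, a combined start parks the diagonal pair on the stiffer
   axis as a near-linear pseudo-matrix ($k_2 \to 0$, $\beta \to 0$ or
   $90^\circ$) with the small-strain slope deficit — this start is what
   reliably reaches sharp-exponent donors.
2. **Latin-hypercube multistarts** over the transformed box
   ($\log_{10}$ scales for $\mu$, $k_1$, $k_2$; $\beta/90$), refined by
   L-BFGS-B (default 32 starts, about 2000 objective evaluations each).
3. **Basin hopping** around the incumbent with cycling wide/narrow
   Gaussian steps plus occasional uniform re-draws of single
   coordinates — a Gaussian hop in log space cannot wake a family parked
   at the $k_1$ floor ($10^{-3}$ kPa, effectively zero).

Default bounds are $\mu \in (10^{-3}, 5\times10^3]$ kPa, $k_1 \in
[10^{-3}, 5\times10^4]$ kPa, $k_2 \in (10^{-6}, 5\times10^4]$, $\beta \in
[0^\circ, 90^\circ]$, spanning the magnitudes reported for venous tissue
with headroom. Identical seeds give bit-identical results.

Parameter *recovery* is deliberately not the success criterion: the
correlated $k_1$/$k_2$ pairs and the family structure make the parameters
non-identifiable from two uniaxial curves, so validation is defined on
the curves (self-consistency $R^2$), as is standard for this model class.

## Elastic moduli

`initial_modulus()` and `tangent_modulus()` report ordinary
least-squares slopes of nominal stress against engineering strain
$(\lambda - 1)$ inside a stress window, in MPa: the initial modulus over
0-0.5 kPa and the tangent modulus at $100 \pm 10$ kPa by default. The
strain measure is engineering strain, consistent with the
nominal-stress tangent-modulus convention of the comparison literature.
The 0-0.5 kPa default window is kept for fidelity to the protocol it
mirrors but is implausibly narrow for coarsely sampled curves (a ~MPa
modulus crosses it within a fraction of a percent strain); the pipeline
records an explanatory `NA` rather than silently widening it, and the
window is fully configurable. A windowed regression was preferred to a
two-point finite difference for noise robustness.

## The synthetic study generator

`generate_study()` emulates the statistical structure of a two-group
(BV/GSV) uniaxial campaign so the whole pipeline can be exercised
without access to donor tissue data: per-donor ground-truth parameters
drawn log-uniformly over the tabulated magnitudes ($\mu$: 1-10^3 kPa,
$k_1$: 1-2x10^3 kPa, $k_2$: 0.5-5x10^3, $\beta$: 30-80 deg), screened
for admissibility (strictly monotone curves reaching 200 kPa at a
stretch between 1.02 and 2.2); 3-4 specimens per direction; ~150 sample
points per specimen (a 20 Hz camera over a minutes-long test); i.i.d.
multiplicative log-normal stress noise (5% default — scatter in tensile
data grows with load, hence multiplicative); a per-specimen log-normal
scale on engineering strain (5% default) mimicking gauge and clamping
variation; and 7% specimen dropout (about 5 failures in 68 attempts),
redrawn so at least two specimens per donor and direction survive.
Inter-specimen variability deliberately enters through the stretch axis,
not through parameter redraws, so each donor's truth stays well-defined
for recovery scoring.

What the generator does *not* emulate: preconditioning cycles and their
residual hysteresis, viscoelastic rate effects, extensometer artifacts
(dropouts, marker loss), storage artifacts, and real biological
correlation structure between parameters. Passing recovery tests on
synthetic data therefore demonstrates the correctness and stability of
the pipeline, not the field accuracy of the model on tissue.

## Problem sizes and validation

The package's own validation (testthat suite and
`scripts/acceptance.R`) uses: 100 random states for the analytic-stress
versus finite-difference check (relative error $< 10^{-6}$, with states
confined to the loading regime — outside it the exponential terms tower
over individual stress components and a double-precision difference
quotient carries no information); closed-form neo-Hookean limits
($k_1 = 0$: transverse stretch $\lambda^{-1/2}$, stress
$\mu(\lambda - \lambda^{-2})$, small-strain modulus $3\mu$); 50
admissible parameter draws checked against a dense brute-force scan
(step $10^{-6}$) of the transverse-stress condition; hand-computed
objective and $R^2$ examples; and end-to-end recovery on a 10-donor
noiseless study plus ten 5%-noise single-donor studies (8 multistarts),
where fitted curves reproduce the generating curves with $R^2 \ge
0.999$ (noiseless) and median $R^2 \ge 0.97$ (noisy) — the fit-quality
regime reported for real venous data. These sizes keep the whole
validation within minutes on one core while exercising every stage at
the study's actual dimensions ($m = 20$, 0-200 kPa, 2-4 specimens per
direction).

## Known limitations

* Loading branch only; unloading/hysteresis is out of scope.
* The strip kinematics assume a diagonal deformation gradient; shear
  (e.g. misaligned clamping) is not modeled.
* Compressed fibers ($I_4 < 1$) contribute energy exactly as the
  exponential form is written; a tension-only switch exists
  (`tension_only = TRUE`) but is off by default, and whether the
  original protocol excluded compressed fibers is unknown.
* Fitted parameters are non-identifiable in the usual sense; compare
  models through their curves, not their parameter values.
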
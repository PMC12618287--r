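# veinfit

Constitutive characterization of venous tissue from uniaxial strip
tension tests, for biomechanics groups building vessel-scale or
fluid-structure simulations (e.g. of arteriovenous fistula hemodynamics)
that need more than a rigid-tube wall. The package covers the full
workflow: forward mechanics of an anisotropic hyperelastic wall model,
reduction of raw strip tests to per-donor representative curves, global
identification of the constitutive parameters, and extraction of the
elastic moduli used for group comparison — plus a synthetic
virtual-experiment generator that makes every stage testable end to end.

## The model

The wall is incompressible and hyperelastic with a four-fiber-family
exponential strain energy density over a neo-Hookean matrix:

$$W = \frac{\mu}{2}(I_1 - 3) + \sum_{j=1}^{4}
\frac{k_1^j}{4 k_2^j}\left(e^{k_2^j (I_4^j - 1)^2} - 1\right)$$

with fiber families circumferential ($\beta^1=0$), longitudinal
($\beta^2=90^\circ$) and a symmetric diagonal pair at $\pm\beta$ sharing
one stiffness, leaving eight free parameters
($\mu, k_1^1, k_2^1, k_1^2, k_2^2, k_1^3, k_2^3, \beta$). Nominal stress
follows from $\mathbf{P} = \partial W/\partial \mathbf{F} -
p\mathbf{F}^{-T}$. For a uniaxial strip the multiplier $p$ is eliminated
exactly through the traction-free thickness face and the transverse
stretch solves a zero-transverse-stress condition per loading step;
fitting minimizes

$$Q = \sum_{i=1}^{m}\left[(P^{EXP}_{\theta\Theta} -
P^{MOD}_{\theta\Theta})_i^2 + (P^{EXP}_{zZ} - P^{MOD}_{zZ})_i^2\right]$$

over per-donor representative curves ($m = 20$ points on 0-200 kPa
nominal stress, both directions), with goodness of fit reported as
$R^2$ per direction. See the vignette
(`vignettes/vein-constitutive-modeling.Rmd`) for the full account.

## Worked example

Generate a small synthetic study (two virtual donors, 3-4 noisy
specimens per direction each) and run the whole pipeline:

```r
library(veinfit)

dir <- file.path(tempdir(), "demo")
generate_study(synthetic_study_config(n_donors = 2, seed = 42), dir)

cfg <- pipeline_config(fit = fit_config(n_multistarts = 8, seed = 1))
report <- run_pipeline(file.path(dir, "specimens.csv"),
                       file.path(dir, "geometry.csv"), cfg,
                       out_dir = file.path(dir, "out"))
#> [read] 14 specimens from .../demo/specimens.csv
#> [fit] donor BV_01: n=7, Q=86.49 kPa^2, R2=0.9995/0.9992 (20.9 s)
#> [fit] donor GSV_02: n=7, Q=124.9 kPa^2, R2=0.9986/0.9995 (19.3 s)
#> [done] 2 donor(s) in 40.2 s

print(report$summary, digits = 4)
#>   donor_id vein_type n_specimens    mu_kPa k1_circ_kPa   k2_circ k1_axial_kPa
#> 1    BV_01        BV           7 496.62964       669.1 1.000e-06        0.001
#> 2   GSV_02       GSV           7   0.05218        11.3 2.464e+02       75.430
#>   k2_axial k1_diag_kPa k2_diag beta_deg R2_circ R2_long
#> 1     1.00      1858.6  12.916    54.57  0.9995  0.9992
#> 2    11.49       227.5   4.914    63.30  0.9986  0.9995
```

Each row is one donor: specimen count, the eight fitted constitutive
parameters and the per-direction coefficients of determination of the
fit to that donor's representative curves ($R^2 \ge 0.998$ here — the
5% multiplicative stress noise is averaged down by the 7 specimens).
Note that the fitted parameters need not match the generating ones even
at high $R^2$: with two uniaxial curves the $(k_1, k_2)$ pairs and the
family assignment are strongly correlated, which is why validation is
defined on curves, not parameters. `report.json` and `summary.csv` are
written under `out/`, stamped with seed and config hash.

Individual stages are exported as plain functions
(`solve_transverse()`, `simulate_curve()`, `clean_loading_branch()`,
`build_representative()`, `fit_four_fiber()`, `initial_modulus()`,
`tangent_modulus()`, ...), and a thin command-line front end with
subcommands `synth` / `simulate` / `curves` / `fit` / `moduli` / `run`
lives at `inst/scripts/veinfit-cli.R`.

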
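# Shared fixtures: parameter draws and closed-form references used across
# the test files. All randomness is seeded in the tests themselves.

neo_hookean_params <- function(mu = 100) {
  four_fiber_params(mu = mu, k1_circ = 0, k2_circ = 1,
                    k1_axial = 0, k2_axial = 1,
                    k1_diag = 0, k2_diag = 1, beta_deg = 45)
}

# Moderate-regime random parameter set (venous-tissue magnitudes); not
# admissibility-screened, for pointwise constitutive checks.
random_params <- function() {
  rl <- function(lo, hi) 10^runif(1, log10(lo), log10(hi))
  four_fiber_params(mu = rl(1, 300),
                    k1_circ = rl(0.5, 500), k2_circ = rl(0.5, 50),
                    k1_axial = rl(0.5, 500), k2_axial = rl(0.5, 50),
                    k1_diag = rl(0.5, 500), k2_diag = rl(0.5, 50),
                    beta_deg = runif(1, 10, 80))
}

# Random stretch state within the regime the model is exercised in
# (energy density bounded as on 0-200 kPa loading curves). Outside it the
# exponential terms tower over individual stress components and a
# double-precision finite difference of W carries no information.
random_state <- function(params, W_max = 1e3) {
  repeat {
    lam <- runif(3, 0.8, 1.4)
    st <- principal_stretches(lam[1], lam[2], lam[3])
    W <- tryCatch(strain_energy(st, params), error = function(e) Inf)
    if (W <= W_max) return(st)
  }
}

# Closed-form uniaxial nominal stress of the incompressible neo-Hookean
# solid (independent of the package's solver).
nh_stress <- function(mu, lam) mu * (lam - lam^-2)

# Noiseless m-point representative-style curve pair computed through the
# package's forward model at a uniform stress grid.
truth_curve_pair <- function(params, m = 20, stress_max = 200) {
  grid <- seq(stress_max / m, stress_max, length.out = m)
  mk <- function(dir) {
    lam <- vapply(grid, function(P)
      veinfit:::stretch_at_stress(params, dir, P), 0)
    data.frame(stretch = lam, nominal_stress_kPa = grid)
  }
  list(circ = mk("circumferential"), long = mk("longitudinal"))
}

# Brute-force oracle for the transverse stretch: dense scan of the
# zero-transverse-stress residual (pure-R residual, independent of the
# compiled Newton path).
scan_transverse <- function(params, direction, lam, step = 1e-6,
                            range = c(0.3, 1.5)) {
  geo <- veinfit:::fiber_geometry(params)
  if (direction == "circumferential") {
    wl <- geo$cos2; wt <- geo$sin2
  } else {
    wl <- geo$sin2; wt <- geo$cos2
  }
  zs <- seq(range[1], range[2], by = step)
  g <- veinfit:::transverse_residual(zs, rep(lam, length(zs)), params$mu,
                                     geo$k1, geo$k2, wl, wt)
  zs[which.min(abs(g))]
}
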
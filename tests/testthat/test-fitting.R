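test_that("objective worked examples hold exactly", {
  grid <- seq(10, 200, by = 10)
  # a near-zero-stress model against the 10..200 kPa grid in both
  # directions: Q = 2 * sum((10 k)^2) = 574000 kPa^2
  null_model <- four_fiber_params(1e-9, 0, 1, 0, 1, 0, 1, 45)
  curves <- list(circ = data.frame(stretch = seq(1.01, 1.4, length.out = 20),
                                   nominal_stress_kPa = grid),
                 long = data.frame(stretch = seq(1.01, 1.4, length.out = 20),
                                   nominal_stress_kPa = grid))
  expect_equal(objective(null_model, curves), 574000, tolerance = 1e-9)

  # self-consistency: curves generated from the parameters themselves
  p <- four_fiber_params(20, 50, 10, 30, 5, 10, 2, 40)
  own <- truth_curve_pair(p)
  expect_lt(objective(p, own), 1e-8)

  # offsetting the experimental stresses by delta adds exactly 2 m delta^2
  delta <- 3
  shifted <- lapply(own, function(cv) {
    cv$nominal_stress_kPa <- cv$nominal_stress_kPa + delta
    cv
  })
  expect_equal(objective(p, shifted), 2 * 20 * delta^2, tolerance = 1e-6)

  # per-direction weights multiply each bracketed sum
  expect_equal(objective(null_model, curves, weights = c(2, 0.5)),
               2.5 * 287000, tolerance = 1e-9)
})

test_that("objective scales quadratically when stresses and stress-like parameters scale", {
  p <- four_fiber_params(20, 50, 10, 30, 5, 10, 2, 40)
  curves <- truth_curve_pair(p, m = 10)
  curves$circ$nominal_stress_kPa <- curves$circ$nominal_stress_kPa * 1.07
  curves$long$nominal_stress_kPa <- curves$long$nominal_stress_kPa * 0.94
  q1 <- objective(p, curves)
  cfac <- 3
  p_scaled <- four_fiber_params(20 * cfac, 50 * cfac, 10, 30 * cfac, 5,
                                10 * cfac, 2, 40)
  curves_scaled <- lapply(curves, function(cv) {
    cv$nominal_stress_kPa <- cv$nominal_stress_kPa * cfac
    cv
  })
  expect_equal(objective(p_scaled, curves_scaled), cfac^2 * q1,
               tolerance = 1e-9)
})

test_that("R^2 bookkeeping: definition, worked example, degenerate input", {
  r2 <- veinfit:::.r2_values
  expect_equal(r2(c(100, 200), c(110, 190)), 1 - 200 / 5000)  # 0.96
  expect_equal(r2(c(100, 200), c(100, 200)), 1)
  expect_equal(r2(c(100, 200), c(150, 150)), 0)   # model = mean

  p <- four_fiber_params(20, 50, 10, 30, 5, 10, 2, 40)
  own <- truth_curve_pair(p, m = 10)
  expect_equal(r_squared(p, own$circ, "circumferential"), 1,
               tolerance = 1e-10)
  flat <- data.frame(stretch = c(1.1, 1.2), nominal_stress_kPa = c(5, 5))
  expect_warning(out <- r_squared(p, flat, "longitudinal"), "zero variance")
  expect_true(is.na(out))

  # Q and R^2 are consistent: Q = sum of per-direction SS_res
  noisy <- lapply(own, function(cv) {
    cv$nominal_stress_kPa <- cv$nominal_stress_kPa * 1.03
    cv
  })
  ssr <- function(cv, dir) {
    Pexp <- cv$nominal_stress_kPa
    (1 - r_squared(p, cv, dir)) * sum((Pexp - mean(Pexp))^2)
  }
  expect_equal(objective(p, noisy),
               ssr(noisy$circ, "circumferential") +
                 ssr(noisy$long, "longitudinal"), tolerance = 1e-8)
})

test_that("fit recovers noiseless synthetic curves and is deterministic", {
  set.seed(12)
  truth <- draw_donor_params("GSV")
  curves <- truth_curve_pair(truth)
  cfg <- fit_config(n_multistarts = 6, seed = 424242)
  fit <- fit_four_fiber(curves, cfg)
  expect_gte(fit$R2_circ, 0.999)
  expect_gte(fit$R2_long, 0.999)
  expect_equal(fit$Q, objective(fit$params, curves), tolerance = 1e-10)

  # optimum is no worse than the deterministic heuristic start
  h0 <- veinfit:::.from_x(veinfit:::.heuristic_start(curves, cfg))
  expect_lte(fit$Q, objective(veinfit:::.params_from_vec(h0), curves))

  refit <- fit_four_fiber(curves, cfg)
  expect_identical(fit, refit)     # bit-identical under the same seed
})

test_that("fit collapses to the isotropic special case on neo-Hookean data", {
  mu <- 100
  curves <- truth_curve_pair(neo_hookean_params(mu))
  fit <- fit_four_fiber(curves, fit_config(n_multistarts = 6, seed = 7))
  expect_gte(fit$R2_circ, 0.999)
  expect_gte(fit$R2_long, 0.999)
  # fitted fiber terms are negligible: k1 at the floor, or their
  # contribution below 0.1% of the peak stress
  p <- fit$params
  p_no_fib <- four_fiber_params(p$mu, 0, 1, 0, 1, 0, 1, 45)
  for (dir in c("circumferential", "longitudinal")) {
    cv <- if (dir == "circumferential") curves$circ else curves$long
    P_full <- stress_at_stretch(p, dir, cv$stretch)
    P_iso <- stress_at_stretch(p_no_fib, dir, cv$stretch)
    small_k1 <- max(p$k1_circ, p$k1_axial, p$k1_diag) <= 1e-2
    expect_true(small_k1 || max(abs(P_full - P_iso)) < 0.001 * 200)
  }
})

test_that("fit surfaces infeasibility diagnostics instead of silent failure", {
  # stretches below 1 violate the loading-branch contract pointwise
  bad <- list(circ = data.frame(stretch = c(0.98, 1.1),
                                nominal_stress_kPa = c(10, 20)),
              long = data.frame(stretch = c(1.05, 1.1),
                                nominal_stress_kPa = c(10, 20)))
  p <- four_fiber_params(20, 50, 10, 30, 5, 10, 2, 40)
  expect_error(objective(p, bad), class = "veinfit_infeasible")
})
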
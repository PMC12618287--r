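test_that("invariants reproduce hand-computed values and family ordering", {
  p45 <- four_fiber_params(10, 1, 1, 1, 1, 1, 1, 45)

  iv <- invariants(principal_stretches(1, 1, 1), p45)
  expect_equal(iv$I1, 3)
  expect_equal(iv$I4, rep(1, 4))

  # circumferential family sees lam_T^2 only
  p0 <- four_fiber_params(10, 1, 1, 1, 1, 1, 1, 0)
  iv <- invariants(incompressible_stretches(1.2, 1), p0)
  expect_equal(iv$I4[1], 1.44)
  expect_equal(iv$I4[2], 1)          # axial family sees lam_Z^2

  # diagonal families at 45 deg average the two in-plane squares
  iv <- invariants(incompressible_stretches(1.1, 1.3), p45)
  expect_equal(iv$I4[3], (1.21 + 1.69) / 2)
  expect_equal(iv$I4[4], iv$I4[3])

  expect_error(principal_stretches(-1, 1, 1), "positive|> 0")
})

test_that("strain energy matches scalar evaluation and vanishes at identity", {
  expect_equal(strain_energy(principal_stretches(1, 1, 1),
                             neo_hookean_params()), 0)

  # isotropic part only: W = (mu/2)(I1 - 3)
  st <- incompressible_stretches(1.2, 1)
  expect_equal(strain_energy(st, neo_hookean_params(100)),
               50 * (1.44 + 1 + 1 / 1.44 - 3), tolerance = 1e-12)

  # single fiber family, vanishing matrix: W -> (k1/(4 k2)) (e^(k2 x^2)-1)
  p_fib <- four_fiber_params(1e-12, 10, 1, 0, 1, 0, 1, 45)
  expect_equal(strain_energy(incompressible_stretches(1.1, 1), p_fib),
               2.5 * expm1(0.0441), tolerance = 1e-9)

  # exponential overflow is a reported divergence, not a silent Inf
  p_stiff <- four_fiber_params(10, 100, 5e3, 0, 1, 0, 1, 0)
  expect_error(strain_energy(incompressible_stretches(1.8, 1), p_stiff),
               "diverged")
})

test_that("PK1 stress matches the stress-free reference and neo-Hookean closed form", {
  p <- neo_hookean_params(100)
  P0 <- pk1_stress(principal_stretches(1, 1, 1), p, p = 100)
  expect_equal(unname(P0), c(0, 0, 0))

  lam <- 1.2
  st <- principal_stretches(lam^-0.5, lam, lam^-0.5)
  P <- pk1_stress(st, p, p = 100 / lam)
  expect_equal(P[["P_TT"]], nh_stress(100, lam), tolerance = 1e-12)
  expect_equal(P[["P_ZZ"]], 0, tolerance = 1e-12)
  expect_equal(P[["P_RR"]], 0, tolerance = 1e-12)
})

test_that("analytic PK1 agrees with central differences of the energy", {
  set.seed(421)
  for (rep in 1:100) {
    p <- random_params()
    st <- random_state(p)
    lam <- unclass(st)
    pm <- runif(1, 0, 50)
    P <- pk1_stress(st, p, p = pm)
    for (i in 1:3) {
      h <- 1e-6 * lam[i]
      up <- dn <- lam
      up[i] <- lam[i] + h; dn[i] <- lam[i] - h
      dW <- (strain_energy(principal_stretches(up[1], up[2], up[3]), p) -
             strain_energy(principal_stretches(dn[1], dn[2], dn[3]), p)) /
        (2 * h)
      P_fd <- dW - pm / lam[i]
      expect_lt(abs(P[[i]] - P_fd) / max(1, abs(P[[i]])), 1e-6)
    }
  }
})

test_that("mirror symmetry: swapping axes, families and beta leaves W unchanged", {
  set.seed(99)
  for (rep in 1:20) {
    p <- random_params()
    p_sw <- four_fiber_params(p$mu, p$k1_axial, p$k2_axial,
                              p$k1_circ, p$k2_circ,
                              p$k1_diag, p$k2_diag, 90 - p$beta_deg)
    lt <- runif(1, 0.9, 1.4); lz <- runif(1, 0.9, 1.4)
    expect_equal(strain_energy(incompressible_stretches(lt, lz), p),
                 strain_energy(incompressible_stretches(lz, lt), p_sw),
                 tolerance = 1e-12)
  }
})

test_that("energy is monotone in k1 under fiber extension and reduces to neo-Hookean", {
  st <- incompressible_stretches(1.25, 1.1)  # all I4 > 1
  base <- four_fiber_params(50, 10, 2, 10, 2, 10, 2, 30)
  for (f in c("k1_circ", "k1_axial", "k1_diag")) {
    up <- base; up[[f]] <- up[[f]] * 2
    class(up) <- "four_fiber_params"
    expect_gt(strain_energy(st, up), strain_energy(st, base))
  }

  # k1 = 0 collapses W and P to the isotropic closed forms exactly
  nh <- neo_hookean_params(80)
  st2 <- incompressible_stretches(1.3, 0.95)
  expect_equal(strain_energy(st2, nh), 40 * (sum(unclass(st2)^2) - 3))
  P <- pk1_stress(st2, nh, p = 7)
  expect_equal(unname(P), 80 * unclass(st2) - 7 / unclass(st2),
               ignore_attr = TRUE)
})

test_that("k2 -> 0 fiber energy uses the series limit continuously", {
  x2 <- 0.3^2
  mk <- function(k2) four_fiber_params(1e-12, 10, k2, 0, 1, 0, 1, 0)
  st <- incompressible_stretches(sqrt(1.3), 1)   # I4_circ = 1.3
  w_series <- strain_energy(st, mk(1e-9))        # series branch
  w_exact <- strain_energy(st, mk(1e-7))         # exponential branch
  expect_equal(w_series, 10 / 4 * x2, tolerance = 1e-7)
  expect_equal(w_series, w_exact, tolerance = 1e-6)
})

test_that("parameter validation and JSON round-trip", {
  expect_error(four_fiber_params(-1, 0, 1, 0, 1, 0, 1, 45), "mu")
  expect_error(four_fiber_params(1, -1, 1, 0, 1, 0, 1, 45), "k1_circ")
  expect_error(four_fiber_params(1, 0, 0, 0, 1, 0, 1, 45), "k2_circ")
  expect_error(four_fiber_params(1, 0, 1, 0, 1, 0, 1, 95), "beta_deg")

  p <- four_fiber_params(12.5, 100, 3.5, 50, 1.25, 8, 0.75, 41.2)
  f <- tempfile(fileext = ".json")
  write_params_json(p, f)
  expect_equal(read_params_json(f), p)

  bad <- tempfile(fileext = ".json")
  writeLines('{"mu_kPa": 1, "bogus": 2}', bad)
  expect_error(read_params_json(bad), "unknown keys")
})
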
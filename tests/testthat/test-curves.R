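mk_record <- function(samples, id = "s1", donor = "d1", dir = "circ",
                      ...) {
  specimen_record(id, donor, "BV", dir, samples, ...)
}

test_that("force-elongation records convert to nominal stress, others pass through", {
  r <- mk_record(data.frame(elongation_mm = c(0, 1, 2),
                            force_N = c(0, 0.5, 1.2)),
                 width_mm = 4, thickness_mm = 0.5, gauge_length_mm = 10)
  out <- to_nominal_stress(r)
  # 0.5 N over 2 mm^2 undeformed section = 0.25 MPa = 250 kPa
  expect_equal(out$samples$nominal_stress_kPa, c(0, 250, 600))
  expect_equal(out$samples$stretch, c(1, 1.1, 1.2))

  already <- mk_record(data.frame(stretch = c(1, 1.1),
                                  nominal_stress_kPa = c(0, 40)))
  expect_identical(to_nominal_stress(already), already)

  missing_geom <- mk_record(data.frame(elongation_mm = 0:1,
                                       force_N = c(0, 1)))
  expect_error(to_nominal_stress(missing_geom), "width_mm")
})

test_that("cleaning re-references, prunes reversals and rejects sparse curves", {
  lam <- seq(1, 1.3, length.out = 31)
  P <- 500 * (lam - 1)^2
  clean <- clean_loading_branch(mk_record(data.frame(
    stretch = lam, nominal_stress_kPa = P)))
  expect_equal(clean$samples$stretch, lam)
  expect_equal(clean$samples$nominal_stress_kPa, P)

  # one stress reversal point is dropped, the rest kept
  P_rev <- P; P_rev[10] <- P[9] - 1
  clean2 <- clean_loading_branch(mk_record(data.frame(
    stretch = lam, nominal_stress_kPa = P_rev)))
  expect_equal(nrow(clean2$samples), 30)
  expect_false(lam[10] %in% clean2$samples$stretch)

  # noisy curve comes out strictly increasing in both columns
  set.seed(5)
  noisy <- mk_record(data.frame(
    stretch = lam, nominal_stress_kPa = P * exp(rnorm(31, 0, 0.1))))
  cs <- clean_loading_branch(noisy)$samples
  expect_true(all(diff(cs$nominal_stress_kPa) > 0))
  expect_true(all(diff(cs$stretch) > 0))

  # pre-load toe: curve re-referenced to its first sample
  toe <- mk_record(data.frame(stretch = 1.02 * lam,
                              nominal_stress_kPa = P + 3))
  ct <- clean_loading_branch(toe)$samples
  expect_equal(ct$stretch[1], 1)
  expect_equal(ct$nominal_stress_kPa[1], 0)

  expect_error(clean_loading_branch(mk_record(data.frame(
    stretch = c(1, 1.1, 1.2), nominal_stress_kPa = c(0, 10, 20)))),
    class = "veinfit_specimen_rejected")
})

test_that("representative curve averages stretch at fixed stress levels", {
  lam <- seq(1, 1.5, length.out = 200)
  P <- 2000 * (lam - 1)^2          # reaches 500 kPa
  base <- data.frame(stretch = lam, nominal_stress_kPa = P)
  r1 <- mk_record(base, id = "a")
  r2 <- mk_record(base, id = "b")

  rep_c <- build_representative(list(r1, r2), m = 20, stress_max = 200)
  expect_equal(rep_c$nominal_stress_kPa, seq(10, 200, by = 10))
  expect_equal(rep_c$stretch,
               approx(P, lam, xout = seq(10, 200, by = 10))$y,
               tolerance = 1e-12)

  # shifting one specimen's stretch by +0.02 moves the mean by +0.01
  r3 <- mk_record(data.frame(stretch = lam + 0.02, nominal_stress_kPa = P),
                  id = "c")
  rep_s <- build_representative(list(r1, r3), m = 20, stress_max = 200)
  expect_equal(rep_s$stretch, rep_c$stretch + 0.01, tolerance = 1e-12)

  # specimen order does not matter
  rep_r <- build_representative(list(r3, r1), m = 20, stress_max = 200)
  expect_equal(rep_r$stretch, rep_s$stretch)

  # representative stretch stays inside the specimens' envelope
  expect_true(all(rep_s$stretch >= rep_c$stretch &
                  rep_s$stretch <= rep_c$stretch + 0.02))
})

test_that("short specimens truncate the stress range by default or reject on request", {
  lam <- seq(1, 1.5, length.out = 200)
  full <- mk_record(data.frame(stretch = lam,
                               nominal_stress_kPa = 2000 * (lam - 1)^2),
                    id = "full")
  short <- mk_record(data.frame(stretch = lam,
                                nominal_stress_kPa = 400 * (lam - 1)^2),
                     id = "short")   # tops out at 100 kPa
  expect_message(
    rc <- build_representative(list(full, short), m = 10, stress_max = 200),
    "truncated")
  expect_equal(max(rc$nominal_stress_kPa), 100)
  expect_equal(nrow(rc), 10)
  expect_error(build_representative(list(full, short), m = 10,
                                    stress_max = 200, on_short = "reject"),
               "reach")
})

test_that("representative options: anchor point and stretch parameterization", {
  lam <- seq(1, 1.5, length.out = 200)
  base <- data.frame(stretch = lam, nominal_stress_kPa = 2000 * (lam - 1)^2)
  recs <- list(mk_record(base, id = "a"), mk_record(base, id = "b"))
  with_anchor <- build_representative(recs, m = 10, stress_max = 200,
                                      anchor = TRUE)
  expect_equal(nrow(with_anchor), 11)
  expect_equal(with_anchor$stretch[1], 1)
  expect_equal(with_anchor$nominal_stress_kPa[1], 0)

  by_stretch <- build_representative(recs, m = 10, stress_max = 200,
                                     parameterization = "stretch")
  expect_equal(nrow(by_stretch), 10)
  expect_equal(by_stretch$nominal_stress_kPa,
               approx(lam, base$nominal_stress_kPa,
                      xout = by_stretch$stretch)$y, tolerance = 1e-12)
})
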
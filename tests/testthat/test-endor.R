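test_that("first-order ENDOR frequencies form the Larmor-centred doublet", {
  expect_equal(unname(endor_frequencies(0, 51.09)), c(51.09, 51.09))
  nu <- endor_frequencies(-3.8, 51.09)
  expect_equal(unname(nu), c(52.99, 49.19), tolerance = 1e-6)
  ## weak-coupling identity: splitting equals |A| whenever |A| < 2 nu_n
  set.seed(41)
  for (k in 1:20) {
    A <- stats::runif(1, -20, 20)
    f <- endor_frequencies(A, 51.09)
    expect_equal(unname(abs(diff(f))), abs(A), tolerance = 1e-10)
  }
  ## branch symmetry: A -> -A permutes the pair
  f1 <- endor_frequencies(5, 51.09)
  f2 <- endor_frequencies(-5, 51.09)
  expect_equal(sort(unname(f1)), sort(unname(f2)))
})

test_that("orientation selection picks the right molecular orientations", {
  sys <- cu_tacn_spin_system()
  mw <- 33.8e9
  ## field positions across the Q-band ESE envelope
  rf_z <- resonance_fields(sys, c(0, 0, 1), mw)
  B_low <- min(rf_z$field_mT) - 0.5      # extreme low-field gz edge
  sel <- orientation_selection(sys, B_low, mw, bandwidth = 60,
                               n_orient = 600)
  expect_equal(sum(sel$weights), 1, tolerance = 1e-9)
  expect_true(all(sel$weights >= 0))
  ## single-crystal-like: weights concentrated near theta ~ 0
  zbar <- sum(sel$weights * abs(sel$orientations[, 3]))
  expect_gt(zbar, 0.9)
  ## at the absorption maximum (perpendicular region) selection is broad
  B_perp <- resonance_field_isotropic(2.058, mw) * 1000
  sel2 <- orientation_selection(sys, B_perp, mw, bandwidth = 60,
                                n_orient = 600)
  zbar2 <- sum(sel2$weights * abs(sel2$orientations[, 3]))
  expect_lt(zbar2, 0.5)
  ## outside the envelope: all-zero weights, flagged
  expect_warning(orientation_selection(sys, 5000, mw, n_orient = 100),
                 "outside the EPR envelope")
})

test_that("powder ENDOR spectra: degenerate cases and linearity", {
  sys <- cu_tren_spin_system()
  mw <- 33.8e9
  B0 <- resonance_field_isotropic(2.1, mw) * 1000
  ## empty proton list gives an identically zero spectrum
  sp0 <- endor_powder_spectrum(sys, list(), B0, mw, n_orient = 100)
  expect_true(all(sp0$y == 0))
  ## doubling the multiplicity exactly doubles the raw intensity
  pr1 <- cu_tren_protons()[[1]]; pr1$multiplicity <- 1
  pr2 <- cu_tren_protons()[[1]]; pr2$multiplicity <- 2
  s1 <- endor_powder_spectrum(sys, list(pr1), B0, mw, n_orient = 200,
                              normalize = FALSE)
  s2 <- endor_powder_spectrum(sys, list(pr2), B0, mw, n_orient = 200,
                              normalize = FALSE)
  expect_equal(s2$y, 2 * s1$y, tolerance = 1e-12)
})

test_that("ENDOR doublets sit around nu_n with splitting below a_iso + aniso", {
  sys <- cu_tren_spin_system()
  mw <- 33.8e9
  B0 <- 1150
  sp <- endor_powder_spectrum(sys, cu_tren_protons(), B0, mw,
                              n_orient = 400)
  nu_n <- larmor_frequency("1H", B0 / 1000)
  ## spectrum is symmetric-ish about nu_n: intensity-weighted centre
  cen <- sum(sp$x * sp$y) / sum(sp$y)
  expect_lt(abs(cen - nu_n), 1)
  ## all intensity within nu_n +/- (|a_iso| + max dipolar)/2 + lineshape
  span <- max(abs(c(-5.2, -11.8, 5.7))) / 2 + 1
  on_range <- sp$y[abs(sp$x - nu_n) > span]
  expect_lt(max(on_range), 0.05)
})

test_that("ENDOR spectrum converges with orientation-grid refinement", {
  sys <- cu_tren_spin_system()
  mw <- 33.8e9
  B0 <- resonance_field_isotropic(2.1, mw) * 1000
  rf <- seq(larmor_frequency("1H", B0 / 1000) - 10,
            larmor_frequency("1H", B0 / 1000) + 10, length.out = 400)
  y1 <- endor_powder_spectrum(sys, cu_tren_protons(), B0, mw, rf,
                              n_orient = 10000)$y
  y2 <- endor_powder_spectrum(sys, cu_tren_protons(), B0, mw, rf,
                              n_orient = 20000)$y
  expect_lt(sqrt(sum((y1 - y2)^2) / sum(y2^2)), 0.01)
})

test_that("point-dipole inversion: round trip, scaling, and benchmark", {
  ## forward-inverse identity for purely axial tensors
  for (r in c(1.8, 2.59, 3.7)) {
    expect_equal(point_dipole_distance(dipole_proton_tensor(r)), r,
                 tolerance = 1e-9)
    expect_equal(point_dipole_distance(dipole_proton_tensor(r, a_iso = -3)),
                 r, tolerance = 1e-9)
  }
  ## scaling the dipolar part by 8 halves the distance
  t1 <- dipole_proton_tensor(2.6)
  t8 <- principal_tensor(8 * t1$x, 8 * t1$y, 8 * t1$z)
  expect_equal(point_dipole_distance(t8),
               point_dipole_distance(t1) / 2, tolerance = 1e-9)
  ## simulated water-proton tensor: within 15% of the 2.59 A benchmark
  r_est <- point_dipole_distance(principal_tensor(-2.80, 8.75, -8.5))
  expect_lt(abs(r_est / 2.59 - 1), 0.15)
  ## no positive dipolar component -> invalid geometry
  expect_error(point_dipole_distance(principal_tensor(1, 1, 1)),
               "invalid geometry")
})
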
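tacn_is <- function() inner_sphere_params(
  q = 2, r_MH = 2.56, A_H = 8.3e6, dH_M = 9.0e3, dS_M = -20.9,
  tau_S = 0.98e-9, tau_R_298 = 10.6e-12, E_R = 20.2e3)

test_that("dipolar rate matches a brute-force closed-form oracle", {
  B20 <- field_from_MHz(20)
  p <- tacn_is()
  ## benchmark point: ~6.0e3 1/s at 20 MHz, 298.15 K
  expect_equal(dipolar_rate(p, B20), 6.0e3, tolerance = 0.02)
  ## 20 random parameter points, relative error < 1e-10 against the oracle
  set.seed(11)
  for (k in 1:20) {
    r <- stats::runif(1, 2, 3.5)
    tR <- 10^stats::runif(1, -12, -10.5)
    tM <- 10^stats::runif(1, -11, -7)
    tS <- 10^stats::runif(1, -10, -8.5)
    B <- 10^stats::runif(1, -3, 0.5)
    q <- inner_sphere_params(q = 1, r_MH = r, tau_M_298 = tM, tau_S = tS,
                             tau_R_298 = tR)
    expect_lt(abs(dipolar_rate(q, B) /
                    oracle_dipolar(r, tR, tM, tS, B) - 1), 1e-10)
  }
})

test_that("dipolar rate limits: vanishes at long distance, disperses in field", {
  p <- tacn_is()
  far <- tacn_is(); far$r_MH <- 100
  expect_lt(dipolar_rate(far, 0.5) / dipolar_rate(p, 0.5), 1e-9)
  ## monotone non-increasing above the omega_S dispersion
  B <- seq(0.5, 3, length.out = 12)
  rr <- dipolar_rate(p, B)
  expect_true(all(diff(rr) <= 0))
  expect_error(dipolar_rate(p, -0.1), "> 0")
})

test_that("scalar rate scales quadratically in A_H and matches magnitude", {
  p <- tacn_is()
  B20 <- field_from_MHz(20)
  expect_equal(scalar_rate(p, B20), 70, tolerance = 0.02)
  p0 <- tacn_is(); p0$A_H <- 0
  expect_identical(scalar_rate(p0, B20), 0)
  p2 <- tacn_is(); p2$A_H <- 2 * p$A_H
  expect_equal(scalar_rate(p2, B20) / scalar_rate(p, B20), 4,
               tolerance = 1e-10)
})

test_that("inner-sphere relaxivity follows the mole-fraction form and limits", {
  p <- tacn_is()
  B20 <- field_from_MHz(20)
  expect_equal(inner_sphere_relaxivity(p, B20), 0.218, tolerance = 0.02)
  p0 <- tacn_is(); p0$q <- 0
  expect_identical(inner_sphere_relaxivity(p0, B20), 0)
  ## slow-exchange quenching: tau_M >> T1M kills the contribution
  slow <- inner_sphere_params(q = 2, r_MH = 2.56, tau_M_298 = 1,
                              tau_S = 0.98e-9, tau_R_298 = 10.6e-12)
  expect_lt(inner_sphere_relaxivity(slow, B20), 1e-4)
})

test_that("Freed spectral density has the correct zero-frequency limit", {
  expect_equal(freed_spectral_density(0, 1e-10, Inf), 1)
  expect_equal(freed_spectral_density(0, 1e-12, 1e-3), 1, tolerance = 1e-3)
  ## decreases with frequency
  J <- freed_spectral_density(10^seq(6, 12, 0.5), 1e-10, 1e-9)
  expect_true(all(diff(J) < 0))
})

test_that("outer-sphere relaxivity magnitude and monotonicity in a", {
  B20 <- field_from_MHz(20)
  os <- outer_sphere_params(a = 3.6, D_298 = 2.3e-9, E_D = 20e3)
  r1os <- outer_sphere_relaxivity(os, 0.98e-9, B20)
  expect_gt(r1os, 0.07); expect_lt(r1os, 0.13)
  aa <- seq(3, 5, 0.5)
  vals <- vapply(aa, function(a)
    outer_sphere_relaxivity(outer_sphere_params(a = a), 0.98e-9, B20),
    numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("NMRD profile is the exact pointwise sum of IS and OS terms", {
  p <- tacn_is()
  os <- outer_sphere_params()
  fields <- c(0.01, 0.1, 1, 10, 20, 60, 120)
  temps <- c(283, 298.15, 310)
  prof <- nmrd_profile(p, os, fields, temps)
  expect_equal(nrow(prof), length(fields) * length(temps))
  for (i in seq_len(nrow(prof))) {
    B <- field_from_MHz(prof$freq_MHz[i])
    expect_equal(prof$r1[i],
                 inner_sphere_relaxivity(p, B, prof$temp_K[i]) +
                   outer_sphere_relaxivity(os, p$tau_S, B, prof$temp_K[i]),
                 tolerance = 1e-12)
  }
  expect_true(all(prof$r1 >= 0))
})

test_that("full model reproduces the benchmark relaxivities at 20 MHz", {
  r_tacn <- nmrd_profile(cu_tacn_params(), fields = 20, temps = 298.15)$r1
  expect_equal(r_tacn, 0.31, tolerance = 0.1)
  r_tren <- nmrd_profile(cu_tren_params(), fields = 20, temps = 298.15)$r1
  expect_equal(r_tren, 0.23, tolerance = 0.1)
  ## on-curve 310 K values, looser model check
  expect_equal(nmrd_profile(cu_tacn_params(), fields = 20, temps = 310)$r1,
               0.25, tolerance = 0.1)
})

test_that("high-field relaxivity decreases with temperature (fast exchange)", {
  prof <- nmrd_profile(cu_tacn_params(), fields = c(40, 80),
                       temps = c(283, 298.15, 310))
  for (f in c(40, 80)) {
    r <- prof$r1[prof$freq_MHz == f]
    expect_true(all(diff(r) < 0))
  }
})

test_that("a zero-rate configuration yields an identically zero profile", {
  p <- relax_params(c(q = 0, A_H = 0, tau_S = 1e-9), model = "water")
  ## suppress outer sphere by an enormous closest-approach distance
  p$values["a"] <- 1e6
  prof <- nmrd_profile(p, fields = c(1, 10), temps = 298.15)
  expect_true(all(prof$r1 < 1e-12))
})
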
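tacn_o17 <- function() {
  ex <- inner_sphere_params(q = 2, r_MH = 2.56, dH_M = 9.0e3, dS_M = -20.9,
                            tau_S = 0.98e-9, tau_R_298 = 10.6e-12)
  o17_params(A_O = 2.82e8, q = 2, exchange = ex)
}

test_that("bound-water shift follows the Curie-law form", {
  expect_identical(delta_omega_M(0, 11.7, 298.15), 0)
  ## 1/T scaling at fixed A_O, B0
  d1 <- delta_omega_M(2.82e8, 11.7, 280)
  d2 <- delta_omega_M(2.82e8, 11.7, 560)
  expect_equal(d1 / d2, 2, tolerance = 1e-12)
  ## closed-form value
  cst <- cuprelax_constants
  expect_equal(delta_omega_M(2.82e8, 11.7, 298.15),
               cst$ge * cst$muB * 0.75 * 11.7 /
                 (3 * cst$kB * 298.15) * 2.82e8)
})

test_that("bound-water 17O scalar rate: quadratic in A_O, tau_e1-dominated", {
  expect_identical(t2m_scalar(0, 1e-9, 1e-9, 11.7), 0)
  r1 <- t2m_scalar(2.0e8, 253e-9, 0.54e-9, 11.7)
  r4 <- t2m_scalar(4.0e8, 253e-9, 0.54e-9, 11.7)
  expect_equal(r4 / r1, 4, tolerance = 1e-12)
  ## at 11.7 T the dispersive tau_e2 term is negligible: rate ~ S(S+1)/3 A^2 tau_e1
  te <- 1 / (1 / 253e-9 + 1 / 0.54e-9)
  expect_equal(r1, 0.25 * (2.0e8)^2 * te, tolerance = 1e-2)
  expect_error(t2m_scalar(2e8, -1e-9, 1e-9, 11.7), "> 0")
})

test_that("Swift-Connick limits hold to 1e-10 relative", {
  p <- tacn_o17()
  ## fast exchange: tau_M -> 0 gives R2r -> 1/T2M and dw_r -> dwM.
  ## The leading correction scales as dwM^2 tau_M T2M (dwM ~ B0), so the
  ## limit is taken at low field and very fast exchange.
  pf <- p
  pf$dS_M <- eyring_dS_from_tau(1e-14, pf$dH_M)
  pf$B0 <- 1e-3
  sc <- swift_connick_reduced(pf, 298.15)
  tauM <- tau_eyring(298.15, dH = pf$dH_M, dS = pf$dS_M)
  iT2M <- t2m_scalar(pf$A_O, tauM, pf$tau_S, pf$B0)
  dwM <- delta_omega_M(pf$A_O, pf$B0, 298.15)
  expect_lt(abs(sc$R2r / iT2M - 1), 1e-10)
  expect_lt(abs(sc$dw_r / dwM - 1), 1e-10)
  ## slow exchange: tau_M >> T2M with dwM tau_M >> 1 gives R2r -> 1/tau_M
  ps <- p; ps$dS_M <- eyring_dS_from_tau(1e4, ps$dH_M)
  tauM_s <- tau_eyring(298.15, dH = ps$dH_M, dS = ps$dS_M)
  scs <- swift_connick_reduced(ps, 298.15)
  expect_lt(abs(scs$R2r * tauM_s - 1), 1e-10)
})

test_that("Swift-Connick fraction matches an independent oracle", {
  p <- tacn_o17()
  set.seed(21)
  for (k in 1:20) {
    temp <- stats::runif(1, 270, 360)
    pp <- p
    pp$A_O <- 10^stats::runif(1, 7, 9)
    pp$tau_S <- 10^stats::runif(1, -10, -8.5)
    pp$dS_M <- eyring_dS_from_tau(10^stats::runif(1, -10, -6), pp$dH_M)
    tauM <- tau_eyring(temp, dH = pp$dH_M, dS = pp$dS_M)
    sc <- swift_connick_reduced(pp, temp)
    orc <- oracle_swift_connick(t2m_scalar(pp$A_O, tauM, pp$tau_S, pp$B0),
                                tauM, delta_omega_M(pp$A_O, pp$B0, temp))
    expect_lt(abs(sc$R2r / orc$R2r - 1), 1e-10)
    expect_lt(abs(sc$dw_r / orc$dw_r - 1), 1e-10)
  }
})

test_that("17O profiles: shapes, determinism, and the q = 0 degenerate case", {
  temps <- seq(272, 360, length.out = 25)
  p <- tacn_o17()
  d1 <- o17_profile(p, temps)
  d2 <- o17_profile(p, temps)
  expect_identical(d1, d2)
  expect_true(all(d1$R2r >= 0))
  ## q = 0: no inner-sphere water in exchange -> all-zero reduced data
  p0 <- p; p0$q <- 0
  d0 <- o17_profile(p0, temps)
  expect_true(all(d0$R2r == 0) && all(d0$dw_r == 0))
  ## A_O -> 0 sends the shift to zero
  pa <- p; pa$A_O <- 0
  expect_true(all(o17_profile(pa, temps)$dw_r == 0))
  expect_error(o17_profile(p, c(300, 300)), "strictly increasing")
})

test_that("slow-to-fast exchange crossover flattens R2r(T) and peaks", {
  ## slow-exchanging monoaqua system: R2r rises steeply with T in the
  ## slow-exchange branch (activated 1/tau_M growth) and the crossover to
  ## fast exchange happens across the measured 270-350 K window: the
  ## log-slope collapses by more than 90% between the window's ends, and
  ## the curve turns over (single maximum) just above it
  ex <- inner_sphere_params(q = 1, r_MH = 2.48, dH_M = 40.0e3, dS_M = 15.8,
                            tau_S = 0.54e-9, tau_R_298 = 10e-12)
  p <- o17_params(A_O = 2.0e8, q = 1, exchange = ex)
  temps <- seq(270, 400, length.out = 131)
  R <- o17_profile(p, temps)$R2r
  inside <- temps <= 350
  dlog <- diff(log(R[inside]))
  expect_gt(dlog[1], 0)
  expect_lt(dlog[length(dlog)] / dlog[1], 0.1)
  d <- diff(R)
  expect_lt(d[length(d)], 0)                 # falling past the maximum
  expect_equal(sum(diff(sign(d)) != 0), 1)   # a single turning point
  expect_lt(temps[which.max(R)], 380)
})
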
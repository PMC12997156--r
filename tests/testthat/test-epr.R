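test_that("perturbative resonance fields agree with exact diagonalization", {
  ## X band: < 0.15 mT; Q band: < 0.05 mT, over random orientations
  sys_list <- list(cu_tacn_spin_system(), cu_tren_spin_system())
  set.seed(31)
  for (sys in sys_list) {
    for (k in 1:6) {
      v <- runit()
      x <- resonance_fields(sys, v, 9.42e9, engine = "perturbation")
      xe <- resonance_fields(sys, v, 9.42e9, engine = "exact")
      expect_lt(max(abs(x$field_mT - xe$field_mT)), 0.15)
      q <- resonance_fields(sys, v, 33.8e9, engine = "perturbation")
      qe <- resonance_fields(sys, v, 33.8e9, engine = "exact")
      expect_lt(max(abs(q$field_mT - qe$field_mT)), 0.05)
    }
  }
  expect_error(resonance_fields(cu_tacn_spin_system(), c(1, 1, 0), 9.42e9),
               "unit vector")
})

test_that("degenerate and first-order limits of the resonance fields", {
  ## isotropic g, zero hyperfine: all lines coincide at h nu/(g muB)
  sys0 <- spin_system_cu(principal_tensor(2.0023, 2.0023, 2.0023),
                         principal_tensor(0, 0, 0))
  rf <- resonance_fields(sys0, c(0, 0, 1), 9.42e9)
  expect_equal(rf$field_mT, rep(336.13, 8), tolerance = 1e-4)
  ## 65Cu/63Cu line-spacing quotient equals the gyromagnetic-ratio quotient
  sys <- cu_tacn_spin_system()
  rf <- resonance_fields(sys, c(0, 0, 1), 9.42e9)
  sp63 <- diff(rf$field_mT[rf$isotope == "63Cu"])
  sp65 <- diff(rf$field_mT[rf$isotope == "65Cu"])
  ratio <- cuprelax_constants$gamma_65Cu / cuprelax_constants$gamma_63Cu
  expect_equal(mean(sp65 / sp63), ratio, tolerance = 1e-3)
  ## outer-line span along z ~ 3|Az| in field units (first order)
  span <- abs(diff(range(rf$field_mT[rf$isotope == "63Cu"])))
  gz <- sys$g$z
  expect_equal(span, 3 * 482 / (gz * cuprelax_constants$muB /
                                  cuprelax_constants$h * 1e-9),
               tolerance = 0.05)
})

test_that("powder spectra: normalization-stable under grid refinement", {
  sys <- cu_tacn_spin_system()
  grid <- seq(250, 380, length.out = 512)
  a1 <- powder_spectrum(sys, 9.42e9, grid, mode = "absorption",
                        n_orient = 600, normalize = FALSE)
  a2 <- powder_spectrum(sys, 9.42e9, grid, mode = "absorption",
                        n_orient = 1200, normalize = FALSE)
  dx <- grid[2] - grid[1]
  int1 <- sum(a1$y) * dx
  int2 <- sum(a2$y) * dx
  expect_lt(abs(int1 / int2 - 1), 0.005)
})

test_that("powder spectra are invariant under tensor permutation + relabeling", {
  sys1 <- spin_system_cu(principal_tensor(2.058, 2.058, 2.288),
                         principal_tensor(30, 30, -482, unit = "MHz"),
                         lwG = 1.5, lwL = 1.0)
  ## relabel axes (x,y,z) -> (z,x,y) in both tensors simultaneously
  sys2 <- spin_system_cu(principal_tensor(2.288, 2.058, 2.058),
                         principal_tensor(-482, 30, 30, unit = "MHz"),
                         lwG = 1.5, lwL = 1.0)
  grid <- seq(250, 380, length.out = 512)
  y1 <- powder_spectrum(sys1, 9.42e9, grid, mode = "absorption",
                        n_orient = 3000)$y
  y2 <- powder_spectrum(sys2, 9.42e9, grid, mode = "absorption",
                        n_orient = 3000)$y
  expect_lt(sqrt(sum((y1 - y2)^2) / sum(y1^2)), 0.03)
})

test_that("powder intensity is additive in the isotope abundance weights", {
  sys <- cu_tacn_spin_system()
  grid <- seq(250, 380, length.out = 400)
  full <- powder_spectrum(sys, 9.42e9, grid, mode = "absorption",
                          n_orient = 400, normalize = FALSE)$y
  only <- function(i) {
    s <- sys
    s$isotopes[[1]]$natural_abundance <- if (i == 1) 1 else 0
    s$isotopes[[2]]$natural_abundance <- if (i == 2) 1 else 0
    powder_spectrum(s, 9.42e9, grid, mode = "absorption",
                    n_orient = 400, normalize = FALSE)$y
  }
  recon <- 0.6917 * only(1) + 0.3083 * only(2)
  expect_equal(full, recon, tolerance = 1e-8)
})

test_that("isotropic powder derivative crosses zero at the resonance field", {
  sys0 <- spin_system_cu(principal_tensor(2.0023, 2.0023, 2.0023),
                         principal_tensor(0, 0, 0), lwG = 0.8, lwL = 0.4)
  grid <- seq(330, 342, length.out = 800)
  sp <- powder_spectrum(sys0, 9.42e9, grid, n_orient = 50)
  ## zero crossing of the derivative lineshape
  i <- which(diff(sign(sp$y)) != 0)
  crossing <- grid[i[which.min(abs(grid[i] - 336))]]
  expect_equal(crossing, 336.13, tolerance = 1e-3)
})

test_that("fast-motion spectrum: line positions, widths and limits", {
  sys <- cu_tacn_spin_system()
  sp <- fast_motion_spectrum(sys, 7.6e-12, 9.42e9)
  ln63 <- sp$lines[sp$lines$isotope == "63Cu", ]
  ln65 <- sp$lines[sp$lines$isotope == "65Cu", ]
  ## line-centre spacing ~ a_iso in field units; 65Cu scaled by the
  ## gyromagnetic quotient
  fB <- cuprelax_constants$muB / cuprelax_constants$h * 1e-9
  g_iso <- mean(c(sys$g$x, sys$g$y, sys$g$z))
  a_iso <- abs(isotropic_average(sys$A_Cu))
  expect_equal(abs(mean(diff(ln63$centre))), a_iso / (g_iso * fB),
               tolerance = 0.02)
  ratio <- cuprelax_constants$gamma_65Cu / cuprelax_constants$gamma_63Cu
  expect_equal(mean(diff(ln65$centre)) / mean(diff(ln63$centre)), ratio,
               tolerance = 1e-3)
  ## motional-narrowing limit: tau_R -> 0 collapses widths to the residual
  sp0 <- fast_motion_spectrum(sys, 1e-16, 9.42e9, lw_residual = 0.5)
  expect_equal(sp0$lines$hwhm, rep(0.25, 8), tolerance = 1e-3)
  expect_equal(sp0$lines$centre, sp$lines$centre)
  ## widths are mI-asymmetric at finite tau_R (the anisotropy signature)
  expect_gt(max(sp$lines$hwhm) / min(sp$lines$hwhm), 2)
  expect_error(fast_motion_spectrum(sys, -1e-12, 9.42e9), "tau_R")
})

test_that("tau_R is recovered from fast-motion spectra", {
  sys <- cu_tacn_spin_system()
  ## noiseless self-consistency: < 0.1%
  sp <- generate_cw_spectrum(sys, regime = "fast_motion", tau_R = 7.6e-12,
                             noise_frac = 0, seed = 1)
  f0 <- fit_tau_R(sp, sys)
  expect_equal(f0$tau_R, 7.6e-12, tolerance = 1e-3)
  ## 1% noise: within 10% with a usable uncertainty
  spn <- generate_cw_spectrum(sys, regime = "fast_motion", tau_R = 7.6e-12,
                              noise_frac = 0.01, seed = 7)
  fn <- fit_tau_R(spn, sys)
  expect_equal(fn$tau_R, 7.6e-12, tolerance = 0.1)
  expect_true(is.finite(fn$sigma) && fn$sigma > 0)
  ## an isotropic system carries no tau_R information
  sys0 <- spin_system_cu(principal_tensor(2.0023, 2.0023, 2.0023),
                         principal_tensor(0, 0, 0))
  sp0 <- suppressWarnings(
    generate_cw_spectrum(sys0, regime = "fast_motion", tau_R = 1e-11,
                         noise_frac = 0, seed = 1))
  expect_error(fit_tau_R(sp0, sys0), "unidentifiable")
})

test_that("rigid and fast-motion golden spectra are reproduced", {
  ## frozen reference traces generated by this package (self-referential
  ## regression guarding against unintended numerical drift)
  sys_tacn <- cu_tacn_spin_system()
  gold <- read_spectrum(test_path("_golden", "cw_tacn_rigid_xband.txt"))
  cur <- powder_spectrum(sys_tacn, 9.42e9, gold$x, n_orient = 800)
  expect_lt(sqrt(mean((cur$y - gold$y)^2)), 1e-6)
  gold2 <- read_spectrum(test_path("_golden", "cw_tacn_fast_xband.txt"))
  cur2 <- fast_motion_spectrum(sys_tacn, 7.6e-12, 9.42e9, gold2$x)
  expect_lt(sqrt(mean((cur2$y - gold2$y)^2)), 1e-6)
  ## reversed-axial pattern for the trigonal-bipyramidal system: the
  ## perpendicular (gx, gy ~ 2.2) intensity dominates, pulling the
  ## centre of mass of the absorption envelope well below the gz ~ 2.005
  ## resonance field
  sys_tren <- cu_tren_spin_system()
  grid <- seq(270, 370, length.out = 600)
  ab <- powder_spectrum(sys_tren, 9.42e9, grid, mode = "absorption",
                        n_orient = 800)
  com <- sum(ab$x * ab$y) / sum(ab$y)
  expect_lt(com, resonance_field_isotropic(2.05, 9.42e9) * 1000)
  expect_gt(com, resonance_field_isotropic(2.3, 9.42e9) * 1000)
})
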
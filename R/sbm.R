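#' Inner-sphere dipolar relaxation rate (Solomon-Bloembergen-Morgan)
#'
#' Longitudinal relaxation rate 1/T1M of a bound-water proton through the
#' electron-nuclear dipole-dipole mechanism, for an S = 1/2 centre:
#'
#'   1/T1M_DD = (2/15)(mu0/4pi)^2 gammaH^2 ge^2 muB^2 S(S+1) r^-6
#'              \[3 tau_c1/(1+omegaH^2 tau_c1^2) +
#'                7 tau_c2/(1+omegaS^2 tau_c2^2)\]
#'
#' with 1/tau_ci = 1/tau_R(T) + 1/tau_M(T) + 1/tau_S (a single,
#' field-independent tau_S serves as both electronic times, so
#' tau_c1 = tau_c2). The Curie contribution, negligible for S = 1/2, is
#' omitted.
#'
#' @param p an [inner_sphere_params()].
#' @param B0 magnetic field, T (> 0; vectorised).
#' @param temp temperature, K (vectorised with `B0`).
#' @return Rate 1/T1M^DD, s^-1.
#' @export
dipolar_rate <- function(p, B0, temp = .const$T_ref) {
  if (p$r_MH <= 0) stop("r_MH must be > 0", call. = FALSE)
  if (any(B0 <= 0)) stop("B0 must be > 0", call. = FALSE)
  S <- 0.5
  tau_R <- tau_arrhenius(p$tau_R_298, p$E_R, temp)
  tau_M <- tau_eyring(temp, dH = p$dH_M, dS = p$dS_M)
  tc <- 1 / (1 / tau_R + 1 / tau_M + 1 / p$tau_S)
  wH <- .const$gamma_1H * B0
  wS <- .const$ge * .const$muB * B0 / .const$hbar
  r <- p$r_MH * 1e-10
  pref <- (2 / 15) * (.const$mu0 / (4 * pi))^2 * .const$gamma_1H^2 *
    .const$ge^2 * .const$muB^2 * S * (S + 1) / r^6
  pref * (3 * tc / (1 + wH^2 * tc^2) + 7 * tc / (1 + wS^2 * tc^2))
}

#' Inner-sphere scalar (contact) relaxation rate
#'
#' 1/T1M_SC = (2/3) S(S+1) (A_H/hbar)^2 tau_e2/(1+omegaS^2 tau_e2^2), with
#' 1/tau_e2 = 1/tau_M(T) + 1/tau_S. Dominant only when the scalar coupling
#' is large and tau_e2 long (e.g. the hydroxo species at basic pH).
#'
#' @inheritParams dipolar_rate
#' @return Rate 1/T1M^SC, s^-1.
#' @export
scalar_rate <- function(p, B0, temp = .const$T_ref) {
  if (any(B0 <= 0)) stop("B0 must be > 0", call. = FALSE)
  S <- 0.5
  tau_M <- tau_eyring(temp, dH = p$dH_M, dS = p$dS_M)
  te2 <- 1 / (1 / tau_M + 1 / p$tau_S)
  wS <- .const$ge * .const$muB * B0 / .const$hbar
  (2 / 3) * S * (S + 1) * p$A_H^2 * te2 / (1 + wS^2 * te2^2)
}

#' Inner-sphere relaxivity
#'
#' Per-mM inner-sphere relaxivity: r1_IS = (q / 55560) / (T1M + tau_M(T)),
#' where 1/T1M is the sum of the dipolar and scalar rates and the 55 560
#' divisor is the mole-fraction normalization (q c / 55.56 with c in M,
#' evaluated per mM). Exchange slower than T1M quenches the contribution.
#'
#' @inheritParams dipolar_rate
#' @return Relaxivity, mM^-1 s^-1.
#' @export
inner_sphere_relaxivity <- function(p, B0, temp = .const$T_ref) {
  if (p$q == 0) return(0 * B0)
  tau_M <- tau_eyring(temp, dH = p$dH_M, dS = p$dS_M)
  T1M <- 1 / (dipolar_rate(p, B0, temp) + scalar_rate(p, B0, temp))
  (p$q / (.const$water_M * 1000)) / (T1M + tau_M)
}

#' Freed spectral density for translational diffusion
#'
#' J(omega) = Re\[(1 + z/4) / (1 + z + 4 z^2/9 + z^3/9)\],
#' z = sqrt(i omega tau_D + tau_D/tau_S). J(0) -> 1 as tau_D/tau_S -> 0.
#'
#' @param omega angular frequency, rad s^-1.
#' @param tau_D translational diffusion correlation time, s.
#' @param tau_S electronic relaxation time, s (`Inf` for none).
#' @return Dimensionless spectral density.
#' @export
freed_spectral_density <- function(omega, tau_D, tau_S = Inf) {
  z <- sqrt(complex(real = tau_D / tau_S, imaginary = omega * tau_D))
  Re((1 + z / 4) / (1 + z + 4 * z^2 / 9 + z^3 / 9))
}

#' Outer-sphere relaxivity (Freed translational-diffusion model)
#'
#' Relaxivity from water diffusing past the complex, in the force-free
#' pair-correlation (Ayant/Hwang-Freed) model:
#'
#'   r1_OS = (32 pi/405)(mu0/4pi)^2 gammaH^2 ge^2 muB^2 S(S+1)
#'           NA \[C\] / (a D(T)) \[3 J(omegaH) + 7 J(omegaS)\]
#'
#' per mM (\[C\] = 1 mol m^-3), with the spectral density of
#' [freed_spectral_density()] and the diffusive correlation time
#' tau_D = 2 a^2 / D(T). The electron relaxation time entering J is the
#' same single tau_S as in the inner-sphere model.
#'
#' @param os an [outer_sphere_params()].
#' @param tau_S electronic relaxation time, s.
#' @param B0 magnetic field, T (vectorised).
#' @param temp temperature, K.
#' @return Relaxivity, mM^-1 s^-1.
#' @export
outer_sphere_relaxivity <- function(os, tau_S, B0, temp = .const$T_ref) {
  if (os$a <= 0 || os$D_298 <= 0) stop("a and D must be > 0", call. = FALSE)
  S <- 0.5
  a <- os$a * 1e-10
  D <- diffusion_arrhenius(os$D_298, os$E_D, temp)
  tau_D <- 2 * a^2 / D
  wH <- .const$gamma_1H * B0
  wS <- .const$ge * .const$muB * B0 / .const$hbar
  pref <- (32 * pi / 405) * (.const$mu0 / (4 * pi))^2 * .const$gamma_1H^2 *
    .const$ge^2 * .const$muB^2 * S * (S + 1) * .const$N_A / (a * D)
  JH <- freed_spectral_density(wH, tau_D, tau_S)
  JS <- freed_spectral_density(wS, tau_D, tau_S)
  pref * (3 * JH + 7 * JS)
}

#' Full NMRD profile (inner + outer sphere)
#'
#' Evaluates r1(nu, T) = r1_IS + r1_OS on a grid of proton Larmor
#' frequencies and temperatures, at B0 = 2 pi nu / gammaH.
#'
#' @param p an [inner_sphere_params()] or a [relax_params()] (in which case
#'   `os` is taken from it and the exchange-model variant is honoured).
#' @param os an [outer_sphere_params()]; ignored when `p` is a
#'   [relax_params()].
#' @param fields proton Larmor frequencies, MHz (non-empty).
#' @param temps temperatures, K (non-empty).
#' @return A `data.frame` of class `nmrd_profile` with columns
#'   `freq_MHz`, `temp_K`, `r1`, `sigma` (NA), sorted by (temperature,
#'   frequency).
#' @examples
#' prof <- nmrd_profile(cu_tacn_params(), fields = c(0.01, 1, 20, 60),
#'                      temps = c(283, 298.15, 310))
#' @export
nmrd_profile <- function(p, os = NULL, fields, temps) {
  if (length(fields) == 0 || length(temps) == 0)
    stop("field and temperature grids must be non-empty", call. = FALSE)
  if (any(fields <= 0)) stop("frequencies must be > 0", call. = FALSE)
  if (inherits(p, "relax_params")) {
    inner <- .as_inner_model(p)
    os <- .as_outer(p)
  } else {
    inner <- list(eval = function(B0, temp) {
      inner_sphere_relaxivity(p, B0, temp)
    }, tau_S = p$tau_S)
  }
  grid <- expand.grid(freq_MHz = sort(fields), temp_K = sort(temps))
  grid <- grid[order(grid$temp_K, grid$freq_MHz), ]
  B0 <- MHz_to_rad_per_s(grid$freq_MHz) / .const$gamma_1H
  r1 <- numeric(nrow(grid))
  for (Tk in unique(grid$temp_K)) {
    i <- grid$temp_K == Tk
    r1[i] <- inner$eval(B0[i], Tk) +
      outer_sphere_relaxivity(os, inner$tau_S, B0[i], Tk)
  }
  out <- data.frame(freq_MHz = grid$freq_MHz, temp_K = grid$temp_K,
                    r1 = r1, sigma = NA_real_)
  rownames(out) <- NULL
  class(out) <- c("nmrd_profile", "data.frame")
  out
}

#' Inner-sphere evaluator honouring the exchange-model variant
#' @noRd
.as_inner_model <- function(p) {
  v <- p$values
  S <- 0.5
  eval_fun <- function(B0, temp) {
    if (v[["q"]] == 0) return(0 * B0)
    tau_M <- .tau_M_of_T(v, p$model, p$OH_conc, temp)
    tau_R <- tau_arrhenius(v[["tau_R_298"]], v[["E_R"]], temp)
    tc <- 1 / (1 / tau_R + 1 / tau_M + 1 / v[["tau_S"]])
    te2 <- 1 / (1 / tau_M + 1 / v[["tau_S"]])
    wH <- .const$gamma_1H * B0
    wS <- .const$ge * .const$muB * B0 / .const$hbar
    r <- v[["r_MH"]] * 1e-10
    dd <- (2 / 15) * (.const$mu0 / (4 * pi))^2 * .const$gamma_1H^2 *
      .const$ge^2 * .const$muB^2 * S * (S + 1) / r^6 *
      (3 * tc / (1 + wH^2 * tc^2) + 7 * tc / (1 + wS^2 * tc^2))
    sc <- (2 / 3) * S * (S + 1) * v[["A_H"]]^2 * te2 / (1 + wS^2 * te2^2)
    (v[["q"]] / (.const$water_M * 1000)) / (1 / (dd + sc) + tau_M)
  }
  list(eval = eval_fun, tau_S = v[["tau_S"]])
}
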
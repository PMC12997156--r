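#' Eyring temperature law for exchange lifetimes
#'
#' Residence lifetime tau_M(T) = 1/k_ex with the transition-state rate
#' k_ex = (kB T / h) exp(dS/R - dH/(R T)). Either the activation pair
#' `(dH, dS)` or a reference lifetime `tau_298` (plus `dH`) may be given;
#' in the latter case dS is chosen so that tau(298.15 K) = tau_298 exactly.
#'
#' @param temp temperature, K (vectorised; expected range 200-400 K).
#' @param dH activation enthalpy, J mol^-1.
#' @param dS activation entropy, J mol^-1 K^-1.
#' @param tau_298 lifetime at 298.15 K, s (alternative parametrization).
#' @return Lifetime tau(T), s.
#' @examples
#' tau_eyring(298.15, dH = 9.0e3, dS = -20.9)   # 0.075 ns
#' @export
tau_eyring <- function(temp, dH = NULL, dS = NULL, tau_298 = NULL) {
  if (any(temp < 200) || any(temp > 400))
    stop("temperature outside the supported 200-400 K range", call. = FALSE)
  R <- .const$R
  if (is.null(dS)) {
    if (is.null(tau_298) || is.null(dH))
      stop("supply either (dH, dS) or (tau_298, dH)", call. = FALSE)
    dS <- eyring_dS_from_tau(tau_298, dH)
  }
  kex <- (.const$kB * temp / .const$h) * exp(dS / R - dH / (R * temp))
  1 / kex
}

#' Activation entropy implied by a 298.15 K lifetime
#'
#' Inverts the Eyring equation at the reference temperature: the dS for
#' which tau(298.15 K) equals `tau_298` at the given dH.
#'
#' @inheritParams tau_eyring
#' @return dS, J mol^-1 K^-1.
#' @export
eyring_dS_from_tau <- function(tau_298, dH) {
  Tr <- .const$T_ref
  .const$R * (log(.const$h / (.const$kB * Tr * tau_298))) + dH / Tr
}

#' Arrhenius temperature scaling of a correlation time
#'
#' tau(T) = tau_298 exp\[(E/R)(1/T - 1/298.15)\]; used for the rotational
#' correlation time (activation energy E_R) and, inverted in sign through
#' its exponent, for the diffusion coefficient.
#'
#' @param tau_298 value at 298.15 K (s, or any unit; returned in kind).
#' @param E activation energy, J mol^-1.
#' @param temp temperature, K (> 0; vectorised).
#' @return tau(T), same unit as `tau_298`.
#' @examples
#' tau_arrhenius(10.6e-12, 20.2e3, 310)  # 7.76 ps
#' @export
tau_arrhenius <- function(tau_298, E, temp) {
  if (any(temp <= 0)) stop("temperature must be positive", call. = FALSE)
  tau_298 * exp((E / .const$R) * (1 / temp - 1 / .const$T_ref))
}

#' Diffusion coefficient with Arrhenius temperature dependence
#'
#' D(T) = D_298 exp\[-(E_D/R)(1/T - 1/298.15)\] (D increases with T).
#' @param D_298 relative diffusion coefficient at 298.15 K, m^2 s^-1.
#' @param E_D activation energy, J mol^-1.
#' @param temp temperature, K.
#' @return D(T), m^2 s^-1.
#' @export
diffusion_arrhenius <- function(D_298, E_D, temp) {
  tau_arrhenius(D_298, -E_D, temp)
}

#' Effective exchange lifetime including prototropic exchange
#'
#' Combines whole-water exchange and base-catalysed prototropic exchange:
#' 1/tau_M = 1/tau_M(H2O) + \[OH-\]/tau_M(H). Either contribution may be
#' absent; if both are, the situation is flagged as an explicit
#' no-exchange error rather than silently returning an infinite lifetime.
#'
#' @param tau_M_H2O whole-water residence lifetime, s, or `NULL`.
#' @param tau_M_H prototropic proton residence lifetime, s, or `NULL`.
#' @param OH_conc hydroxide concentration, mol L^-1 (>= 0).
#' @return Effective tau_M, s.
#' @examples
#' prototropic_tau_M(tau_M_H = 1.5e-9, OH_conc = 1e-2)  # 150 ns
#' @export
prototropic_tau_M <- function(tau_M_H2O = NULL, tau_M_H = NULL, OH_conc = 0) {
  if (any(OH_conc < 0)) stop("OH_conc must be >= 0", call. = FALSE)
  rate <- 0
  if (!is.null(tau_M_H2O)) rate <- rate + 1 / tau_M_H2O
  if (!is.null(tau_M_H)) rate <- rate + OH_conc / tau_M_H
  if (all(rate == 0))
    stop("no exchange pathway: both tau_M(H2O) and tau_M(H)*[OH-] absent ",
         "(tau_M would be infinite)", call. = FALSE)
  1 / rate
}

#' Hydroxide concentration from pH
#'
#' \[OH-\] = 10^(pH - 14) at 25 C; the temperature dependence of Kw is
#' ignored (documented design choice).
#' @param pH solution pH.
#' @return \[OH-\], mol L^-1.
#' @export
oh_conc_from_pH <- function(pH) 10^(pH - 14)
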
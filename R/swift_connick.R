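#' Bound-water 17O chemical shift
#'
#' Hyperfine (contact) shift of the bound-water 17O resonance:
#' Delta omega_M = ge muB S(S+1) B0 / (3 kB T) * (A_O/hbar), following the
#' Curie-law 1/T scaling.
#'
#' @param A_O 17O scalar coupling A_O/hbar, rad s^-1.
#' @param B0 magnetic field, T.
#' @param temp temperature, K (> 0).
#' @return Delta omega_M, rad s^-1.
#' @export
delta_omega_M <- function(A_O, B0, temp) {
  if (any(temp <= 0)) stop("temperature must be > 0", call. = FALSE)
  S <- 0.5
  .const$ge * .const$muB * S * (S + 1) * B0 / (3 * .const$kB * temp) * A_O
}

#' Bound-water 17O transverse scalar relaxation rate
#'
#' 1/T2M = (S(S+1)/3) (A_O/hbar)^2 \[tau_e1 + tau_e2/(1+omegaS^2 tau_e2^2)\]
#' with 1/tau_ei = 1/tau_M + 1/tau_S (a single electronic time serves as
#' both T1e and T2e). The scalar mechanism dominates bound-water 17O
#' transverse relaxation.
#'
#' @param A_O 17O scalar coupling, rad s^-1.
#' @param tau_M exchange lifetime, s (> 0).
#' @param tau_S electronic relaxation time, s (> 0).
#' @param B0 field, T.
#' @param temp temperature, K (unused by the rate itself; kept for
#'   interface symmetry).
#' @return Rate 1/T2M, s^-1.
#' @export
t2m_scalar <- function(A_O, tau_M, tau_S, B0, temp = .const$T_ref) {
  if (any(tau_M <= 0) || any(tau_S <= 0))
    stop("times must be > 0", call. = FALSE)
  S <- 0.5
  te <- 1 / (1 / tau_M + 1 / tau_S)
  wS <- .const$ge * .const$muB * B0 / .const$hbar
  (S * (S + 1) / 3) * A_O^2 * (te + te / (1 + wS^2 * te^2))
}

#' Swift-Connick reduced 17O observables
#'
#' Reduced (per bound-water mole fraction) transverse relaxation rate and
#' chemical shift of bulk water in exchange with the paramagnetic site:
#'
#'   R2r  = (1/tau_M) \[T2M^-2 + (T2M tau_M)^-1 + DwM^2\] /
#'          \[(T2M^-1 + tau_M^-1)^2 + DwM^2\]
#'   dw_r = DwM / \[(1 + tau_M/T2M)^2 + tau_M^2 DwM^2\]
#'
#' In the fast-exchange limit R2r -> 1/T2M and dw_r -> DwM; in the
#' slow-exchange limit R2r -> 1/tau_M.
#'
#' @param p an [o17_params()].
#' @param temp temperature, K (vectorised). tau_M(T) follows the Eyring
#'   law of the shared exchange parameters.
#' @return A list with components `R2r` (s^-1) and `dw_r` (rad s^-1).
#' @export
swift_connick_reduced <- function(p, temp) {
  stopifnot(inherits(p, "o17_params"))
  tau_M <- tau_eyring(temp, dH = p$dH_M, dS = p$dS_M)
  if (any(tau_M <= 0)) stop("tau_M must be > 0", call. = FALSE)
  iT2M <- t2m_scalar(p$A_O, tau_M, p$tau_S, p$B0, temp)
  dwM <- delta_omega_M(p$A_O, p$B0, temp)
  R2r <- (1 / tau_M) * (iT2M^2 + iT2M / tau_M + dwM^2) /
    ((iT2M + 1 / tau_M)^2 + dwM^2)
  dw_r <- dwM / ((1 + tau_M * iT2M)^2 + tau_M^2 * dwM^2)
  list(R2r = R2r, dw_r = dw_r)
}

#' Variable-temperature 17O dataset from the forward model
#'
#' Applies [swift_connick_reduced()] over a temperature grid. A q = 0
#' configuration (no inner-sphere water in exchange) yields an all-zero
#' reduced dataset, as observed for the hydroxo species at basic pH.
#'
#' @param p an [o17_params()].
#' @param temps temperatures, K (non-empty, strictly increasing after
#'   sorting).
#' @return A `data.frame` of class `o17_dataset` with columns `temp_K`,
#'   `R2r`, `dw_r`, `sigma_R2r`, `sigma_dwr`.
#' @export
o17_profile <- function(p, temps) {
  if (length(temps) == 0) stop("temperature grid is empty", call. = FALSE)
  temps <- sort(temps)
  if (any(diff(temps) <= 0))
    stop("temperatures must be strictly increasing", call. = FALSE)
  if (p$q == 0) {
    out <- data.frame(temp_K = temps, R2r = 0, dw_r = 0,
                      sigma_R2r = NA_real_, sigma_dwr = NA_real_)
  } else {
    sc <- swift_connick_reduced(p, temps)
    out <- data.frame(temp_K = temps, R2r = sc$R2r, dw_r = sc$dw_r,
                      sigma_R2r = NA_real_, sigma_dwr = NA_real_)
  }
  class(out) <- c("o17_dataset", "data.frame")
  out
}
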
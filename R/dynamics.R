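#' Rotational autocorrelation trace
#'
#' @param lag_ps lag times, ps (increasing, >= 10 points for fitting).
#' @param C correlation values (C(0) normalized to 1 within noise).
#' @param segment_length_ps,n_segments optional segment metadata.
#' @return Object of class `autocorr_trace`.
#' @export
autocorr_trace <- function(lag_ps, C, segment_length_ps = NA,
                           n_segments = NA) {
  if (length(lag_ps) != length(C)) stop("length mismatch", call. = FALSE)
  if (any(diff(lag_ps) <= 0)) stop("lags must be increasing", call. = FALSE)
  structure(list(lag_ps = lag_ps, C = C,
                 segment_length_ps = segment_length_ps,
                 n_segments = n_segments),
            class = "autocorr_trace")
}

#' Rotational correlation time from a single-exponential fit
#'
#' Least-squares fit of C(t) = exp(-t/tau_R) to a (segment-averaged)
#' autocorrelation trace. The amplitude prefactor is fixed at 1; a trace
#' whose initial value deviates from 1 by more than 5% triggers a
#' normalization warning. The fit window extends to 5 times the expected
#' tau_R or to the first zero crossing, whichever comes first (long-lag
#' noise otherwise dominates the fit).
#'
#' @param trace an [autocorr_trace()].
#' @return List of class `taur_fit` with `tau_R` and `sigma` in seconds
#'   (and `tau_R_ps`, `sigma_ps` for convenience).
#' @export
fit_autocorrelation_tau <- function(trace) {
  stopifnot(inherits(trace, "autocorr_trace"))
  t <- trace$lag_ps; C <- trace$C
  if (length(t) < 10) stop("need at least 10 lag points", call. = FALSE)
  C0 <- C[which.min(abs(t))]
  if (C0 <= 0) stop("initial correlation value must be positive",
                    call. = FALSE)
  if (abs(C0 - 1) > 0.05)
    warning(sprintf("trace is not normalized: C(0) = %.3f (amplitude is ",
                    C0), "fixed at 1)", call. = FALSE)
  ## rough tau from the 1/e crossing
  below <- which(C < exp(-1))
  tau0 <- if (length(below)) t[below[1]] else max(t) / 2
  if (tau0 <= 0) tau0 <- max(t) / 5
  zero <- which(C <= 0)
  t_max <- min(5 * tau0, if (length(zero)) t[zero[1]] else Inf)
  sel <- t <= t_max
  if (sum(sel) < 5) sel <- seq_len(min(10, length(t)))
  td <- t[sel]; Cd <- C[sel]
  if (all(diff(Cd) >= 0) || stats::cor(td, Cd) > 0)
    stop("trace does not decay: tau_R unidentifiable", call. = FALSE)
  ## scaleOffset makes the convergence test well defined for noiseless data
  fit <- stats::nls(Cd ~ exp(-td / tau), start = list(tau = tau0),
                    control = stats::nls.control(maxiter = 200,
                                                 scaleOffset = 1,
                                                 warnOnly = TRUE))
  s <- summary(fit)
  tau_ps <- s$coefficients["tau", "Estimate"]
  sig_ps <- s$coefficients["tau", "Std. Error"]
  structure(list(tau_R = tau_ps * 1e-12, sigma = sig_ps * 1e-12,
                 tau_R_ps = tau_ps, sigma_ps = sig_ps,
                 n_points = sum(sel), window_ps = t_max),
            class = "taur_fit")
}

#' Effective magnetic moment from the Evans/BMS shift
#'
#' Molar susceptibility from the bulk-magnetic-susceptibility shift of a
#' reference resonance, chi_M = 3 Delta_f / (4 pi f c 1000) (SI, m^3/mol;
#' cylindrical sample parallel to B0, c in mol/L), then
#' mu_eff = sqrt(3 kB / (mu0 NA)) / muB * sqrt(chi_M T) Bohr magnetons
#' (numerically 797.7 sqrt(chi_M T)). Diamagnetic corrections are not
#' applied.
#'
#' @param delta_f shift of the reference resonance, Hz.
#' @param spectrometer_f spectrometer frequency, Hz (> 0).
#' @param conc complex concentration, mol/L (> 0).
#' @param temp temperature, K.
#' @return List with `mu_eff` (Bohr magnetons), `chi_M_SI` (m^3/mol) and
#'   a `convention` note.
#' @examples
#' evans_mu_eff(evans_shift(1.78, 500e6, 0.025, 300), 500e6, 0.025, 300)
#' @export
evans_mu_eff <- function(delta_f, spectrometer_f, conc, temp) {
  if (conc <= 0) stop("concentration must be > 0", call. = FALSE)
  if (spectrometer_f <= 0) stop("spectrometer frequency must be > 0",
                                call. = FALSE)
  cst <- cuprelax_constants
  chi <- 3 * delta_f / (4 * pi * spectrometer_f * conc * 1000)
  k <- sqrt(3 * cst$kB / (cst$mu0 * cst$N_A)) / cst$muB
  mu <- k * sqrt(pmax(chi * temp, 0))
  list(mu_eff = mu, chi_M_SI = chi,
       convention = paste("SI molar susceptibility, cylindrical sample",
                          "parallel to B0; no diamagnetic correction"))
}

#' Forward Evans/BMS shift from a magnetic moment
#'
#' Inverse of [evans_mu_eff()]: the reference-resonance shift (Hz)
#' produced by a paramagnet of moment `mu_eff` at the given conditions.
#'
#' @inheritParams evans_mu_eff
#' @param mu_eff effective moment, Bohr magnetons.
#' @return Shift, Hz.
#' @export
evans_shift <- function(mu_eff, spectrometer_f, conc, temp) {
  cst <- cuprelax_constants
  k <- sqrt(3 * cst$kB / (cst$mu0 * cst$N_A)) / cst$muB
  chi <- (mu_eff / k)^2 / temp
  chi * 4 * pi * spectrometer_f * conc * 1000 / 3
}
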
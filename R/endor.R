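## First-order Davies ENDOR for weakly coupled protons (|A| < 2|nu_n|).

#' Proton hyperfine tensor
#'
#' @param A a [principal_tensor()] in MHz, with ZYZ Euler angles rotating
#'   its principal frame into the g frame.
#' @param label proton type: `"water"`, `"amino"` or `"CH"`.
#' @param multiplicity number of equivalent protons (>= 1).
#' @return Object of class `proton_hyperfine`.
#' @export
proton_hyperfine <- function(A, label = c("water", "amino", "CH"),
                             multiplicity = 1) {
  stopifnot(inherits(A, "principal_tensor"))
  label <- match.arg(label)
  if (multiplicity < 1) stop("multiplicity must be >= 1", call. = FALSE)
  structure(list(A = A, label = label, multiplicity = multiplicity),
            class = "proton_hyperfine")
}

#' First-order ENDOR doublet frequencies
#'
#' nu_pm = |nu_n +/- A_eff/2|: the proton doublet centred at the nuclear
#' Larmor frequency and split by the effective hyperfine coupling, valid
#' in the weak-coupling regime |A_eff| < 2 nu_n (where the splitting
#' equals |A_eff| exactly).
#'
#' @param A_eff effective hyperfine coupling, MHz (signed).
#' @param nu_n nuclear Larmor frequency, MHz.
#' @return Named numeric `c(nu_minus, nu_plus)`, MHz.
#' @examples
#' endor_frequencies(-3.8, 51.09)
#' @export
endor_frequencies <- function(A_eff, nu_n) {
  c(nu_minus = abs(nu_n - A_eff / 2), nu_plus = abs(nu_n + A_eff / 2))
}

#' Orientation-selection weights at a field position
#'
#' For every orientation on the grid, the weight is the abundance-weighted
#' sum over the copper mI lines of a Gaussian kernel in the (frequency)
#' offset between the working field and the orientation's resonance
#' fields, with width set by the excitation bandwidth. Weights are
#' normalized to sum to 1; an all-zero weight vector (field outside the
#' EPR envelope) is flagged with a warning.
#'
#' @param sys a [spin_system_cu()].
#' @param B0 working field, mT.
#' @param mw_freq microwave frequency, Hz.
#' @param bandwidth excitation bandwidth (FWHM of the kernel), MHz;
#'   default 60 MHz (16 ns inversion pulse).
#' @param orientations n x 3 matrix of unit vectors; default
#'   [sphere_grid()] with `n_orient` knots.
#' @param n_orient grid size when `orientations` is NULL.
#' @return List with `orientations` and normalized `weights`.
#' @export
orientation_selection <- function(sys, B0, mw_freq, bandwidth = 60,
                                  orientations = NULL, n_orient = 400) {
  if (is.null(orientations)) orientations <- sphere_grid(n_orient)
  gvals <- c(sys$g$x, sys$g$y, sys$g$z)
  A63 <- tensor_matrix(sys$A_Cu)
  sigma <- bandwidth / (2 * sqrt(2 * log(2)))
  fB <- .fB()
  geff <- sqrt(rowSums(sweep(orientations, 2, gvals, "*")^2))
  w <- numeric(nrow(orientations))
  for (k in seq_along(sys$isotopes)) {
    Bres <- .resfields_pt_batch(gvals, A63 * sys$A_scale[k], orientations,
                                mw_freq / 1e6)
    dnu <- (B0 - Bres) * geff * fB              # offset in MHz
    w <- w + sys$isotopes[[k]]$natural_abundance *
      rowSums(exp(-dnu^2 / (2 * sigma^2)))
  }
  tot <- sum(w)
  if (tot <= 0 || max(w) < 1e-12) {
    warning("working field lies outside the EPR envelope: all selection ",
            "weights are zero", call. = FALSE)
    return(list(orientations = orientations, weights = w))
  }
  list(orientations = orientations, weights = w / tot)
}

#' Davies selectivity factor for small couplings
#'
#' Single multiplicative suppression eta(A) = A^2/(A^2 + w_hole^2)
#' approximating the reduced Davies inversion efficiency for couplings
#' smaller than the preparation-pulse hole width; reproduces the
#' suppression of the weakly coupled (matrix, ~ +/-2 MHz) region.
#' @noRd
.davies_eta <- function(A_eff, hole_width = 2) {
  A_eff^2 / (A_eff^2 + hole_width^2)
}

#' Powder Davies ENDOR spectrum with orientation selection
#'
#' For each selected orientation and each proton, both first-order ENDOR
#' branches are accumulated at the orientation's nuclear Larmor frequency
#' and effective coupling (the proton tensor rotated by its Euler angles
#' into the g frame), weighted by the orientation-selection weight, the
#' proton multiplicity and the Davies selectivity factor, then convolved
#' with a Gaussian RF lineshape.
#'
#' @param sys a [spin_system_cu()].
#' @param protons list of [proton_hyperfine()] objects.
#' @param B0 working field, mT.
#' @param mw_freq microwave frequency, Hz.
#' @param rf_grid RF axis, MHz (uniform); auto-chosen around nu_n(1H)
#'   when `NULL`.
#' @param bandwidth excitation bandwidth, MHz.
#' @param rf_fwhm Gaussian RF lineshape FWHM, MHz.
#' @param hole_width Davies hole width for the selectivity factor, MHz.
#' @param n_orient orientation knots.
#' @param normalize scale to unit maximum intensity (default).
#' @return An `epr_spectrum` with `kind = "rf"`.
#' @export
endor_powder_spectrum <- function(sys, protons, B0, mw_freq, rf_grid = NULL,
                                  bandwidth = 60, rf_fwhm = 0.3,
                                  hole_width = 2, n_orient = 10000,
                                  normalize = TRUE) {
  nu_n0 <- larmor_frequency("1H", B0 / 1000)
  if (is.null(rf_grid))
    rf_grid <- seq(nu_n0 - 12, nu_n0 + 12, length.out = 600)
  sel <- orientation_selection(sys, B0, mw_freq, bandwidth,
                               orientations = sphere_grid(n_orient))
  y <- numeric(length(rf_grid))
  if (length(protons) == 0 || max(sel$weights) == 0)
    return(new_spectrum(rf_grid, y, kind = "rf",
                        metadata = list(B0_mT = B0, mw_freq_Hz = mw_freq)))
  gvals <- c(sys$g$x, sys$g$y, sys$g$z)
  keep <- which(sel$weights > 1e-8 * max(sel$weights))
  ors <- sel$orientations[keep, , drop = FALSE]
  GL <- sweep(ors, 2, gvals, "*")
  U <- GL / sqrt(rowSums(GL^2))           # electron quantization axes
  for (pr in protons) {
    Ap <- tensor_matrix(pr$A)
    AU <- U %*% Ap                        # rows: t(A) %*% u, MHz
    lo <- nu_n0 * ors - AU / 2
    hi <- nu_n0 * ors + AU / 2
    nus <- cbind(sqrt(rowSums(lo^2)), sqrt(rowSums(hi^2)))
    A_eff <- abs(nus[, 2] - nus[, 1])
    amp <- sel$weights[keep] * pr$multiplicity *
      .davies_eta(A_eff, hole_width)
    y <- y + .bin_sticks(as.numeric(nus), rep(amp, 2), rf_grid)
  }
  y <- .convolve_lineshape(rf_grid, y, fwhmG = rf_fwhm, fwhmL = 0)
  if (normalize) {
    ymax <- max(abs(y))
    if (ymax > 0) y <- y / ymax
  }
  new_spectrum(rf_grid, y, kind = "rf",
               metadata = list(B0_mT = B0, mw_freq_Hz = mw_freq,
                               bandwidth_MHz = bandwidth,
                               rf_fwhm_MHz = rf_fwhm))
}

#' Point-dipole metal-proton distance from a hyperfine tensor
#'
#' Removes the isotropic part, takes the largest principal value T_par of
#' the traceless remainder, and inverts the axial point-dipole form
#' (-T, -T, 2T) with T = K_dd/r^3:
#'   r = (2 K_dd / T_par)^(1/3),
#' where K_dd = (mu0/4pi) ge muB gH muN / h = 79.1 MHz A^3. The point
#' dipole approximation ignores spin-density delocalization, so distances
#' for directly coordinated water protons are accurate to ~10-15%.
#'
#' @param A a [principal_tensor()] in MHz.
#' @return Distance, Angstrom.
#' @examples
#' point_dipole_distance(dipole_proton_tensor(2.59))  # 2.59
#' @export
point_dipole_distance <- function(A) {
  vals <- if (inherits(A, "principal_tensor")) c(A$x, A$y, A$z)
  else as.numeric(A)
  tr <- vals - mean(vals)
  Tpar <- max(tr)
  if (Tpar <= 0)
    stop("traceless part has no positive principal value: ",
         "invalid geometry for the point-dipole inversion", call. = FALSE)
  (2 * .kdd() / Tpar)^(1 / 3)
}

#' Point-dipole coupling constant K_dd in MHz Angstrom^3
#' @noRd
.kdd <- function() {
  cst <- cuprelax_constants
  gH <- cst$gamma_1H * cst$hbar / cst$muN   # proton g factor
  (cst$mu0 / (4 * pi)) * cst$ge * cst$muB * gH * cst$muN / cst$h * 1e30 / 1e6
}

#' Axial point-dipole proton tensor at distance r
#'
#' Forward construction (-T, -T, 2T) + a_iso with T = K_dd/r^3; the
#' inverse of [point_dipole_distance()] for purely axial tensors.
#'
#' @param r distance, Angstrom (> 0).
#' @param a_iso isotropic part to add, MHz.
#' @return A [principal_tensor()] in MHz.
#' @export
dipole_proton_tensor <- function(r, a_iso = 0) {
  if (r <= 0) stop("r must be > 0", call. = FALSE)
  Tdd <- .kdd() / r^3
  principal_tensor(a_iso - Tdd, a_iso - Tdd, a_iso + 2 * Tdd, unit = "MHz")
}
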
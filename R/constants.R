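#' Physical constants (CODATA 2018)
#'
#' Single authoritative table of physical constants used throughout the
#' package. All internal computation is in SI units (fields in tesla,
#' frequencies in Hz, energies in J); mT and MHz appear only at I/O
#' boundaries.
#'
#' @format A named list:
#' \describe{
#'   \item{mu0}{vacuum permeability, N A^-2}
#'   \item{muB}{Bohr magneton, J T^-1}
#'   \item{muN}{nuclear magneton, J T^-1}
#'   \item{h, hbar}{Planck constant (and reduced), J s}
#'   \item{kB}{Boltzmann constant, J K^-1}
#'   \item{NA}{Avogadro constant, mol^-1}
#'   \item{R}{molar gas constant, J mol^-1 K^-1}
#'   \item{ge}{free-electron g factor (magnitude)}
#'   \item{gamma_1H, gamma_17O, gamma_63Cu, gamma_65Cu}{nuclear gyromagnetic
#'     ratios, rad s^-1 T^-1}
#'   \item{water_M}{molar concentration of pure water, mol L^-1 (55.56)}
#'   \item{T_ref}{reference temperature 298.15 K}
#' }
#' @export
cuprelax_constants <- list(
  mu0       = 1.25663706212e-6,
  muB       = 9.2740100783e-24,
  muN       = 5.0507837461e-27,
  h         = 6.62607015e-34,
  hbar      = 1.054571817e-34,
  kB        = 1.380649e-23,
  N_A       = 6.02214076e23,
  R         = 8.314462618,
  ge        = 2.00231930436,
  gamma_1H  = 2.6752218744e8,
  gamma_17O = -3.62808e7,
  gamma_63Cu = 7.09983e7,   # gN(63Cu) = 1.4824  x muN/hbar
  gamma_65Cu = 7.60462e7,   # gN(65Cu) = 1.5878  x muN/hbar
  water_M   = 55.56,
  T_ref     = 298.15
)

## internal shorthand
.const <- cuprelax_constants

#' Principal tensor with orientation
#'
#' Container for an interaction tensor given by its three principal values
#' and (optionally) the ZYZ Euler angles rotating its principal frame into
#' the g-tensor frame. Used for g-tensors (dimensionless) and hyperfine
#' tensors (MHz).
#'
#' @param x,y,z principal values (finite reals).
#' @param euler_alpha,euler_beta,euler_gamma Euler angles in degrees,
#'   each in \[-180, 180\]; default 0 (colinear with the g frame).
#' @param unit optional unit label ("MHz" or "" for dimensionless).
#' @return An object of class `principal_tensor`.
#' @examples
#' A <- principal_tensor(33, 60, -529, unit = "MHz")
#' isotropic_average(A)  # -145.33 MHz
#' @export
principal_tensor <- function(x, y, z, euler_alpha = 0, euler_beta = 0,
                             euler_gamma = 0, unit = "") {
  vals <- c(x = x, y = y, z = z)
  if (!all(is.finite(vals)))
    stop("principal values must be finite reals", call. = FALSE)
  ang <- c(alpha = euler_alpha, beta = euler_beta, gamma = euler_gamma)
  if (!all(is.finite(ang)) || any(abs(ang) > 180))
    stop("Euler angles must be finite and within [-180, 180] degrees",
         call. = FALSE)
  structure(list(x = x, y = y, z = z,
                 euler_alpha = euler_alpha, euler_beta = euler_beta,
                 euler_gamma = euler_gamma, unit = unit),
            class = "principal_tensor")
}

#' @export
print.principal_tensor <- function(x, ...) {
  u <- if (nzchar(x$unit)) paste0(" ", x$unit) else ""
  cat(sprintf("principal tensor: (%g, %g, %g)%s, iso %g%s\n",
              x$x, x$y, x$z, u, isotropic_average(x), u))
  if (any(c(x$euler_alpha, x$euler_beta, x$euler_gamma) != 0))
    cat(sprintf("  Euler angles (ZYZ, deg): %g %g %g\n",
                x$euler_alpha, x$euler_beta, x$euler_gamma))
  invisible(x)
}

#' Isotropic (scalar) part of a principal tensor
#'
#' Arithmetic mean of the three principal values: the a_iso of a hyperfine
#' tensor or the <g> of a g-tensor.
#'
#' @param t a [principal_tensor()], or a numeric vector of length 3.
#' @return Scalar, same unit as the input.
#' @export
isotropic_average <- function(t) {
  v <- if (inherits(t, "principal_tensor")) c(t$x, t$y, t$z) else as.numeric(t)
  if (length(v) != 3 || !all(is.finite(v)))
    stop("need three finite principal values", call. = FALSE)
  mean(v)
}

#' ZYZ Euler rotation matrix (degrees, active)
#' @noRd
.euler_zyz <- function(alpha, beta, gamma) {
  d <- pi / 180
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  Rz(alpha * d) %*% Ry(beta * d) %*% Rz(gamma * d)
}

#' Tensor as a 3x3 matrix in the g frame
#'
#' Rotates the diagonal principal-value matrix by the tensor's Euler angles
#' (ZYZ convention) into the g-tensor frame.
#'
#' @param t a [principal_tensor()].
#' @return 3x3 symmetric matrix, same unit as the principal values.
#' @export
tensor_matrix <- function(t) {
  stopifnot(inherits(t, "principal_tensor"))
  R <- .euler_zyz(t$euler_alpha, t$euler_beta, t$euler_gamma)
  R %*% diag(c(t$x, t$y, t$z)) %*% t(R)
}

#' Nucleus specification
#'
#' @param name text label, e.g. "1H". Known labels ("1H", "17O", "63Cu",
#'   "65Cu") fill the remaining fields from the constants table.
#' @param spin nuclear spin (half-integer).
#' @param gyromagnetic_ratio rad s^-1 T^-1 (signed).
#' @param natural_abundance fraction in \[0, 1\].
#' @return Object of class `nucleus_spec`.
#' @examples
#' nucleus_spec("63Cu")
#' @export
nucleus_spec <- function(name, spin = NULL, gyromagnetic_ratio = NULL,
                         natural_abundance = NULL) {
  known <- list(
    "1H"   = list(spin = 0.5, gamma = .const$gamma_1H,   ab = 0.999885),
    "17O"  = list(spin = 2.5, gamma = .const$gamma_17O,  ab = 3.8e-4),
    "63Cu" = list(spin = 1.5, gamma = .const$gamma_63Cu, ab = 0.6917),
    "65Cu" = list(spin = 1.5, gamma = .const$gamma_65Cu, ab = 0.3083)
  )
  if (name %in% names(known)) {
    k <- known[[name]]
    if (is.null(spin)) spin <- k$spin
    if (is.null(gyromagnetic_ratio)) gyromagnetic_ratio <- k$gamma
    if (is.null(natural_abundance)) natural_abundance <- k$ab
  }
  if (is.null(spin) || is.null(gyromagnetic_ratio) || is.null(natural_abundance))
    stop("unknown nucleus '", name, "': supply spin, gyromagnetic_ratio and ",
         "natural_abundance explicitly", call. = FALSE)
  if (spin < 0 || abs(spin * 2 - round(spin * 2)) > 1e-12)
    stop("spin must be a non-negative half-integer", call. = FALSE)
  if (natural_abundance < 0 || natural_abundance > 1)
    stop("natural_abundance must lie in [0, 1]", call. = FALSE)
  structure(list(name = name, spin = spin,
                 gyromagnetic_ratio = gyromagnetic_ratio,
                 natural_abundance = natural_abundance),
            class = "nucleus_spec")
}

#' Angular frequency to linear frequency conversion
#'
#' `rad_per_s_to_MHz()` converts a coupling given as an angular frequency
#' (rad s^-1, the unit used for A/hbar in relaxometric fits) to MHz;
#' `MHz_to_rad_per_s()` is the inverse.
#'
#' @param a angular frequency, rad s^-1.
#' @return Frequency in MHz.
#' @examples
#' rad_per_s_to_MHz(2.82e8)  # 44.88 MHz
#' @export
rad_per_s_to_MHz <- function(a) a / (2 * pi * 1e6)

#' @rdname rad_per_s_to_MHz
#' @param f frequency, MHz.
#' @export
MHz_to_rad_per_s <- function(f) f * 2 * pi * 1e6

#' Nuclear Larmor frequency
#'
#' |gamma| B0 / 2 pi, in MHz.
#'
#' @param nucleus a [nucleus_spec()] (or known nucleus label).
#' @param field magnetic field, T (non-negative).
#' @return Larmor frequency, MHz.
#' @examples
#' larmor_frequency("1H", 1.2)  # ~51 MHz
#' @export
larmor_frequency <- function(nucleus, field) {
  if (is.character(nucleus)) nucleus <- nucleus_spec(nucleus)
  stopifnot(inherits(nucleus, "nucleus_spec"))
  if (any(field < 0)) stop("field must be >= 0", call. = FALSE)
  abs(nucleus$gyromagnetic_ratio) * field / (2 * pi) / 1e6
}

#' Isotropic electron resonance field
#'
#' h nu / (g muB), the centre field of an isotropic S = 1/2 resonance.
#'
#' @param g g factor (> 0).
#' @param mw_frequency microwave frequency, Hz (> 0).
#' @return Resonance field, T.
#' @examples
#' resonance_field_isotropic(2.0023, 9.42e9)  # 0.3361 T
#' @export
resonance_field_isotropic <- function(g, mw_frequency) {
  if (any(g <= 0) || any(mw_frequency <= 0))
    stop("g and mw_frequency must be positive", call. = FALSE)
  .const$h * mw_frequency / (g * .const$muB)
}
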
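#' Inner-sphere relaxation parameters
#'
#' Parameters of the inner-sphere (bound-water) proton relaxation model:
#' hydration state, geometry, scalar coupling, exchange kinetics, and the
#' electronic and rotational correlation times.
#'
#' The exchange lifetime may be given either as `tau_M_298` or as the
#' Eyring activation pair `(dH_M, dS_M)`. When both are supplied they must
#' agree within 5% at 298.15 K (validated on construction); the Eyring pair
#' takes precedence in all temperature-dependent evaluation.
#'
#' @param q bound-water count (water-molecule equivalents; a single
#'   exchangeable proton counts as q = 0.5, see [cu_tren_ph12_params()]).
#' @param r_MH metal-proton distance, Angstrom (> 0).
#' @param A_H proton scalar coupling A_H/hbar, rad s^-1 (signed).
#' @param tau_M_298 water residence lifetime at 298.15 K, s.
#' @param dH_M,dS_M Eyring activation enthalpy (J mol^-1) and entropy
#'   (J mol^-1 K^-1) of the exchange.
#' @param tau_S electronic relaxation time, s (field- and, by default,
#'   temperature-independent).
#' @param tau_R_298 rotational correlation time at 298.15 K, s.
#' @param E_R Arrhenius activation energy of tau_R, J mol^-1.
#' @return Object of class `inner_sphere_params`.
#' @export
inner_sphere_params <- function(q, r_MH, A_H = 0, tau_M_298 = NULL,
                                dH_M = NULL, dS_M = NULL,
                                tau_S, tau_R_298, E_R = 0) {
  if (q < 0) stop("q must be >= 0", call. = FALSE)
  if (r_MH <= 0) stop("r_MH must be > 0", call. = FALSE)
  if (tau_S <= 0 || tau_R_298 <= 0)
    stop("correlation times must be > 0", call. = FALSE)
  have_eyring <- !is.null(dH_M) && !is.null(dS_M)
  if (is.null(tau_M_298) && !have_eyring)
    stop("supply tau_M_298 or the Eyring pair (dH_M, dS_M)", call. = FALSE)
  if (!is.null(tau_M_298) && tau_M_298 <= 0)
    stop("tau_M_298 must be > 0", call. = FALSE)
  if (!is.null(tau_M_298) && have_eyring) {
    tau_check <- tau_eyring(.const$T_ref, dH = dH_M, dS = dS_M)
    if (abs(tau_check / tau_M_298 - 1) > 0.05)
      stop(sprintf(paste0("tau_M_298 (%.3g s) and the Eyring pair ",
                          "(implying %.3g s) disagree by more than 5%%"),
                   tau_M_298, tau_check), call. = FALSE)
  }
  if (is.null(tau_M_298))
    tau_M_298 <- tau_eyring(.const$T_ref, dH = dH_M, dS = dS_M)
  if (!have_eyring) {
    dH_M <- if (is.null(dH_M)) 0 else dH_M
    dS_M <- eyring_dS_from_tau(tau_M_298, dH_M)
  }
  structure(list(q = q, r_MH = r_MH, A_H = A_H, tau_M_298 = tau_M_298,
                 dH_M = dH_M, dS_M = dS_M, tau_S = tau_S,
                 tau_R_298 = tau_R_298, E_R = E_R),
            class = "inner_sphere_params")
}

#' Outer-sphere relaxation parameters
#'
#' @param a distance of closest approach, Angstrom (> 0).
#' @param D_298 relative solute-water diffusion coefficient at 298.15 K,
#'   m^2 s^-1 (> 0).
#' @param E_D activation energy of D, J mol^-1.
#' @return Object of class `outer_sphere_params`.
#' @export
outer_sphere_params <- function(a = 3.6, D_298 = 2.3e-9, E_D = 20.0e3) {
  if (a <= 0 || D_298 <= 0) stop("a and D_298 must be > 0", call. = FALSE)
  structure(list(a = a, D_298 = D_298, E_D = E_D),
            class = "outer_sphere_params")
}

#' Bound-water 17O parameters
#'
#' @param A_O 17O scalar coupling A_O/hbar, rad s^-1.
#' @param q bound-water count.
#' @param exchange an [inner_sphere_params()] (or any list carrying
#'   `dH_M`, `dS_M`, `tau_S`) providing the shared exchange kinetics and
#'   electronic relaxation time.
#' @param tau_S electronic relaxation time, s (defaults to
#'   `exchange$tau_S`).
#' @param B0 magnetic field, T (default 11.7 T).
#' @return Object of class `o17_params`.
#' @export
o17_params <- function(A_O, q, exchange, tau_S = exchange$tau_S, B0 = 11.7) {
  if (!is.finite(A_O)) stop("A_O must be a finite real", call. = FALSE)
  if (q < 0) stop("q must be >= 0", call. = FALSE)
  if (B0 <= 0) stop("B0 must be > 0", call. = FALSE)
  structure(list(A_O = A_O, q = q, dH_M = exchange$dH_M, dS_M = exchange$dS_M,
                 tau_S = tau_S, B0 = B0),
            class = "o17_params")
}

## ---------------------------------------------------------------------------
## Full parameter set for the joint fit
## ---------------------------------------------------------------------------

#' Parameter names understood by [relax_params()]
#' @noRd
.relax_par_names <- c(
  "q",          # bound-water count (water-molecule equivalents)
  "r_MH",       # metal-proton distance, Angstrom
  "A_H",        # proton scalar coupling, rad/s
  "A_O",        # 17O scalar coupling, rad/s
  "dH_M",       # water-exchange activation enthalpy, J/mol
  "dS_M",       # water-exchange activation entropy, J/mol/K
  "dH_MH",      # prototropic activation enthalpy, J/mol
  "dS_MH",      # prototropic activation entropy, J/mol/K
  "tau_S",      # electronic relaxation time, s
  "tau_R_298",  # rotational correlation time at 298.15 K, s
  "E_R",        # activation energy of tau_R, J/mol
  "a",          # closest approach, Angstrom
  "D_298",      # diffusion coefficient at 298.15 K, m^2/s
  "E_D",        # activation energy of D, J/mol
  "B0_O17"     # 17O field, T
)

#' Full relaxometric parameter set with fixed/free control
#'
#' Houses every parameter of the joint SBM + Freed + Swift-Connick model
#' together with per-parameter free flags, bounds and the exchange-model
#' variant. This is the object [relax_fit()] optimises.
#'
#' Exchange-model variants: `"water"` (whole-water exchange via the Eyring
#' pair `dH_M`/`dS_M`), `"prototropic"` (base-catalysed proton exchange via
#' `dH_MH`/`dS_MH` and `OH_conc`), or `"both"`.
#'
#' @param values named numeric vector; any subset of
#'   `q, r_MH, A_H, A_O, dH_M, dS_M, dH_MH, dS_MH, tau_S, tau_R_298, E_R,
#'   a, D_298, E_D, B0_O17` (defaults fill the rest: the fixed-by-default
#'   values used throughout are a = 3.6 A, D_298 = 2.3e-9 m^2/s,
#'   E_D = 20.0 kJ/mol, B0_O17 = 11.7 T).
#' @param free character vector of parameter names to be optimised.
#' @param lower,upper named numeric vectors of bounds for free parameters;
#'   defaults are wide physically-motivated boxes.
#' @param model exchange-model variant (see Details).
#' @param OH_conc hydroxide concentration, mol L^-1 (prototropic models).
#' @return Object of class `relax_params`: list with elements `values`
#'   (full named vector), `free`, `lower`, `upper`, `model`, `OH_conc`.
#' @seealso [cu_tacn_params()], [cu_tren_params()], [cu_tren_ph12_params()]
#' @export
relax_params <- function(values, free = character(),
                         lower = NULL, upper = NULL,
                         model = c("water", "prototropic", "both"),
                         OH_conc = 0) {
  model <- match.arg(model)
  defaults <- c(q = 1, r_MH = 2.5, A_H = 0, A_O = 0,
                dH_M = 20e3, dS_M = 0, dH_MH = 50e3, dS_MH = 0,
                tau_S = 1e-9, tau_R_298 = 10e-12, E_R = 20e3,
                a = 3.6, D_298 = 2.3e-9, E_D = 20.0e3, B0_O17 = 11.7)
  unknown <- setdiff(names(values), .relax_par_names)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  v <- defaults
  v[names(values)] <- values
  unknown <- setdiff(free, .relax_par_names)
  if (length(unknown))
    stop("unknown free parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  def_lower <- c(q = 0, r_MH = 1.5, A_H = -1e9, A_O = -1e10,
                 dH_M = 1e3, dS_M = -200, dH_MH = 1e3, dS_MH = -200,
                 tau_S = 1e-12, tau_R_298 = 1e-13, E_R = 1e3,
                 a = 2, D_298 = 1e-10, E_D = 1e3, B0_O17 = 0.1)
  def_upper <- c(q = 6, r_MH = 4, A_H = 1e9, A_O = 1e10,
                 dH_M = 2e5, dS_M = 200, dH_MH = 2e5, dS_MH = 200,
                 tau_S = 1e-7, tau_R_298 = 1e-8, E_R = 1e5,
                 a = 6, D_298 = 1e-8, E_D = 1e5, B0_O17 = 30)
  lo <- def_lower; up <- def_upper
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) up[names(upper)] <- upper
  for (p in free) {
    if (!is.finite(lo[p]) || !is.finite(up[p]) ||
        v[p] < lo[p] || v[p] > up[p])
      stop("free parameter '", p, "' needs finite bounds containing its ",
           "initial value", call. = FALSE)
  }
  structure(list(values = v, free = free, lower = lo[.relax_par_names],
                 upper = up[.relax_par_names], model = model,
                 OH_conc = OH_conc),
            class = "relax_params")
}

#' @export
print.relax_params <- function(x, ...) {
  cat("Relaxometric parameter set (model: ", x$model, ")\n", sep = "")
  v <- x$values
  tag <- ifelse(names(v) %in% x$free, "free", "fixed")
  df <- data.frame(value = signif(v, 4), status = tag)
  print(df)
  if (x$OH_conc > 0) cat("  [OH-] =", x$OH_conc, "mol/L\n")
  invisible(x)
}

#' Effective exchange lifetime of a parameter set at temperature T
#' @noRd
.tau_M_of_T <- function(v, model, OH_conc, temp) {
  tw <- if (model %in% c("water", "both"))
    tau_eyring(temp, dH = v[["dH_M"]], dS = v[["dS_M"]]) else NULL
  th <- if (model %in% c("prototropic", "both"))
    tau_eyring(temp, dH = v[["dH_MH"]], dS = v[["dS_MH"]]) else NULL
  prototropic_tau_M(tau_M_H2O = tw, tau_M_H = th, OH_conc = OH_conc)
}

#' Views of a relax_params as the component parameter objects
#' @noRd
.as_inner <- function(p) {
  v <- p$values
  ## tau_M_298 consistent with the active exchange model
  tau298 <- .tau_M_of_T(v, p$model, p$OH_conc, .const$T_ref)
  list(q = v[["q"]], r_MH = v[["r_MH"]], A_H = v[["A_H"]],
       tau_M_298 = tau298, dH_M = v[["dH_M"]], dS_M = v[["dS_M"]],
       tau_S = v[["tau_S"]], tau_R_298 = v[["tau_R_298"]], E_R = v[["E_R"]])
}

#' @noRd
.as_outer <- function(p) {
  v <- p$values
  outer_sphere_params(a = v[["a"]], D_298 = v[["D_298"]], E_D = v[["E_D"]])
}

#' @noRd
.as_o17 <- function(p) {
  v <- p$values
  structure(list(A_O = v[["A_O"]], q = v[["q"]], dH_M = v[["dH_M"]],
                 dS_M = v[["dS_M"]], tau_S = v[["tau_S"]],
                 B0 = v[["B0_O17"]]),
            class = "o17_params")
}
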
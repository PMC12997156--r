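#' Weighted residual vector for the joint NMRD + 17O fit
#'
#' Concatenates (model - data)/sigma over all NMRD points and, when the
#' 17O dataset is present, both 17O channels (reduced rate and reduced
#' shift). When experimental sigmas are absent, sigma defaults to 1% of
#' the observable's maximum magnitude within each dataset/channel, so the
#' NMRD and 17O blocks are equally weighted after normalization.
#'
#' @param params a [relax_params()].
#' @param nmrd an `nmrd_profile` data frame (columns `freq_MHz`, `temp_K`,
#'   `r1` and optionally `sigma`), or `NULL`.
#' @param o17 an `o17_dataset` data frame (columns `temp_K`, `R2r`,
#'   `dw_r`, optional sigmas), or `NULL`. Dropping it reproduces the
#'   NMRD-only protocol used for the hydroxo species.
#' @param sigma_frac default relative sigma when none is supplied (0.01).
#' @return Numeric residual vector of length `nrow(nmrd) + 2*nrow(o17)`.
#' @export
build_residuals <- function(params, nmrd = NULL, o17 = NULL,
                            sigma_frac = 0.01) {
  if (is.null(nmrd) && is.null(o17))
    stop("at least one dataset must be supplied", call. = FALSE)
  if (!is.null(nmrd) && nrow(nmrd) == 0) stop("empty NMRD dataset",
                                              call. = FALSE)
  if (!is.null(o17) && nrow(o17) == 0) stop("empty 17O dataset",
                                            call. = FALSE)
  res <- numeric(0)
  if (!is.null(nmrd)) {
    mod <- nmrd_profile(params, fields = unique(nmrd$freq_MHz),
                        temps = unique(nmrd$temp_K))
    key <- function(d) paste(signif(d$freq_MHz, 10), signif(d$temp_K, 10))
    mod_r1 <- mod$r1[match(key(nmrd), key(mod))]
    sig <- nmrd$sigma
    if (is.null(sig) || all(is.na(sig)))
      sig <- rep(sigma_frac * max(abs(nmrd$r1)), nrow(nmrd))
    res <- c(res, (mod_r1 - nmrd$r1) / sig)
  }
  if (!is.null(o17)) {
    mod <- o17_profile(.as_o17(params), temps = o17$temp_K)
    sR <- o17$sigma_R2r
    if (is.null(sR) || all(is.na(sR)))
      sR <- rep(sigma_frac * max(abs(o17$R2r), 1), nrow(o17))
    sW <- o17$sigma_dwr
    if (is.null(sW) || all(is.na(sW)))
      sW <- rep(sigma_frac * max(abs(o17$dw_r), 1), nrow(o17))
    res <- c(res, (mod$R2r - o17$R2r) / sR, (mod$dw_r - o17$dw_r) / sW)
  }
  res
}

#' Joint least-squares fit of NMRD and 17O data
#'
#' Simultaneous weighted least-squares fit of multi-temperature NMRD
#' profiles and variable-temperature 17O data by trust-region
#' Levenberg-Marquardt (with box bounds), starting from the declared
#' initial values of the free parameters. Time-like positive parameters
#' are optimised on a log10 scale internally. The fit is deterministic
#' given identical inputs; `seed` is consumed only by the optional
#' multi-start perturbation.
#'
#' One-sigma uncertainties come from the covariance of the converged
#' least squares, scaled by the reduced chi-square.
#'
#' @inheritParams build_residuals
#' @param seed integer seed, used only when `n_starts > 1`.
#' @param n_starts number of optimisation starts (1 = deterministic start
#'   from the declared initial values; extra starts perturb the start
#'   point within bounds and keep the best converged result).
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @return Object of class `relax_fit`.
#' @examples
#' \donttest{
#' truth <- cu_tacn_params()
#' nm <- generate_nmrd(truth, noise_frac = 0.02, seed = 1)
#' ox <- generate_o17(truth, noise_frac = 0.02, seed = 1)
#' fit <- relax_fit(truth, nmrd = nm, o17 = ox)
#' summary(fit)
#' }
#' @export
relax_fit <- function(params, nmrd = NULL, o17 = NULL, sigma_frac = 0.01,
                      seed = 1, n_starts = 1,
                      control = minpack.lm::nls.lm.control(maxiter = 200)) {
  stopifnot(inherits(params, "relax_params"))
  free <- params$free
  n_obs <- (if (is.null(nmrd)) 0 else nrow(nmrd)) +
    (if (is.null(o17)) 0 else 2 * nrow(o17))
  if (length(free) == 0) {
    r <- build_residuals(params, nmrd, o17, sigma_frac)
    fit <- structure(list(params = params, coefficients = numeric(0),
                          sigma = numeric(0), vcov = matrix(0, 0, 0),
                          chisq = sum(r^2),
                          df = n_obs, redchi = sum(r^2) / n_obs,
                          residuals = r, nmrd = nmrd, o17 = o17,
                          converged = TRUE, iterations = 0L, seed = seed,
                          message = "no free parameters; forward model only"),
                     class = "relax_fit")
    return(fit)
  }
  if (n_obs < length(free))
    stop("fewer observations than free parameters", call. = FALSE)

  ## internal parametrization: log10 for strictly positive parameters,
  ## initial-value scaling otherwise, so the Jacobian is well conditioned
  is_log <- params$lower[free] > 0
  sc <- pmax(abs(params$values[free]), 1e-12)
  sc[is_log] <- 1
  fwd <- function(x) {
    out <- x / sc
    out[is_log] <- log10(x[is_log])
    out
  }
  bwd <- function(x) {
    out <- x * sc
    out[is_log] <- 10^x[is_log]
    out
  }
  x0 <- fwd(params$values[free])
  lo <- fwd(params$lower[free]); up <- fwd(params$upper[free])

  resid_fun <- function(x) {
    p <- params
    p$values[free] <- bwd(x)
    build_residuals(p, nmrd, o17, sigma_frac)
  }

  run_one <- function(x_start) {
    minpack.lm::nls.lm(par = x_start, lower = lo, upper = up,
                       fn = resid_fun, control = control)
  }
  best <- run_one(x0)
  if (n_starts > 1) {
    set.seed(seed)
    for (k in seq_len(n_starts - 1)) {
      xs <- pmin(pmax(x0 + stats::rnorm(length(x0), sd = 0.15 *
                                          pmax(abs(x0), 0.1)), lo), up)
      cand <- try(run_one(xs), silent = TRUE)
      if (!inherits(cand, "try-error") && cand$deviance < best$deviance)
        best <- cand
    }
  }
  converged <- best$info %in% 1:4
  if (!converged)
    warning("optimizer did not converge (info = ", best$info, "): ",
            best$message, "; returning best-so-far parameters",
            call. = FALSE)

  est <- bwd(best$par)
  names(est) <- free
  pfit <- params
  pfit$values[free] <- est
  r <- best$fvec
  dof <- max(n_obs - length(free), 1)
  redchi <- best$deviance / dof
  ## covariance in the transformed space, mapped back by the Jacobian of
  ## bwd; directions with (near-)zero curvature are unidentifiable and get
  ## infinite variance rather than a spuriously small pseudo-inverse one
  ev <- eigen(best$hessian, symmetric = TRUE)
  lam <- ev$values
  keep <- lam > 1e-10 * max(lam, 0)
  ct <- matrix(0, length(free), length(free))
  if (any(keep))
    ct <- ev$vectors[, keep, drop = FALSE] %*%
      diag(1 / lam[keep], sum(keep)) %*%
      t(ev$vectors[, keep, drop = FALSE]) * redchi
  null_load <- rowSums(ev$vectors[, !keep, drop = FALSE]^2)
  scale <- ifelse(is_log, log(10) * est, sc)
  vc <- ct * outer(scale, scale)
  dimnames(vc) <- list(free, free)
  sig <- sqrt(pmax(diag(vc), 0))
  sig[null_load > 1e-8] <- Inf

  structure(list(params = pfit, start = params, coefficients = est,
                 sigma = sig, vcov = vc, chisq = best$deviance, df = dof,
                 redchi = redchi, residuals = r, nmrd = nmrd, o17 = o17,
                 converged = converged, iterations = best$niter,
                 seed = seed, message = best$message),
            class = "relax_fit")
}

#' @export
print.relax_fit <- function(x, ...) {
  cat("Joint SBM / Swift-Connick relaxometric fit\n")
  cat(sprintf("  %d observations, %d free parameter(s), red. chi-square %.3g\n",
              length(x$residuals), length(x$coefficients), x$redchi))
  if (!x$converged) cat("  WARNING: not converged (", x$message, ")\n")
  if (length(x$coefficients)) {
    cat("  Estimates:\n")
    print(signif(x$coefficients, 4))
  }
  invisible(x)
}

#' @export
summary.relax_fit <- function(object, ...) {
  est <- object$coefficients
  tab <- data.frame(estimate = est, std.error = object$sigma,
                    row.names = names(est))
  out <- list(table = tab, redchi = object$redchi, df = object$df,
              converged = object$converged, iterations = object$iterations,
              fixed = object$params$values[
                setdiff(names(object$params$values), names(est))])
  class(out) <- "summary.relax_fit"
  out
}

#' @export
print.summary.relax_fit <- function(x, ...) {
  cat("Joint relaxometric fit: parameter estimates (1-sigma)\n")
  print(signif(as.matrix(x$table), 4))
  cat(sprintf("Reduced chi-square: %.3g on %d degrees of freedom (%s, %d iter)\n",
              x$redchi, x$df,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
coef.relax_fit <- function(object, ...) object$coefficients

#' @export
vcov.relax_fit <- function(object, ...) object$vcov

#' @export
residuals.relax_fit <- function(object, ...) object$residuals

#' @export
fitted.relax_fit <- function(object, ...) {
  out <- list()
  if (!is.null(object$nmrd))
    out$nmrd <- nmrd_profile(object$params,
                             fields = unique(object$nmrd$freq_MHz),
                             temps = unique(object$nmrd$temp_K))
  if (!is.null(object$o17))
    out$o17 <- o17_profile(.as_o17(object$params),
                           temps = object$o17$temp_K)
  out
}

#' Predict relaxivity or 17O observables from a fitted model
#'
#' @param object a `relax_fit`.
#' @param fields proton Larmor frequencies, MHz (NMRD channel).
#' @param temps temperatures, K.
#' @param channel `"nmrd"` or `"o17"`.
#' @param ... unused.
#' @return An `nmrd_profile` or `o17_dataset` data frame.
#' @export
predict.relax_fit <- function(object, fields = NULL, temps = NULL,
                              channel = c("nmrd", "o17"), ...) {
  channel <- match.arg(channel)
  if (channel == "nmrd") {
    if (is.null(fields)) fields <- default_nmrd_fields()
    if (is.null(temps)) temps <- c(283, 298.15, 310)
    nmrd_profile(object$params, fields = fields, temps = temps)
  } else {
    if (is.null(temps)) temps <- seq(278, 350, length.out = 25)
    o17_profile(.as_o17(object$params), temps = temps)
  }
}

#' Simulate datasets from a fitted model
#'
#' Draws synthetic NMRD and 17O datasets at the fitted parameter values on
#' the grids of the fitted data (parametric bootstrap style).
#'
#' @param object a `relax_fit`.
#' @param nsim number of replicate dataset pairs.
#' @param seed integer seed.
#' @param noise_frac relative noise level (default 0.01).
#' @param ... unused.
#' @return A list of length `nsim`; each element has components `nmrd`
#'   and/or `o17`.
#' @export
simulate.relax_fit <- function(object, nsim = 1, seed = 1,
                               noise_frac = 0.01, ...) {
  lapply(seq_len(nsim), function(k) {
    out <- list()
    if (!is.null(object$nmrd))
      out$nmrd <- generate_nmrd(object$params,
                                fields = unique(object$nmrd$freq_MHz),
                                temps = unique(object$nmrd$temp_K),
                                noise_frac = noise_frac, seed = seed + k - 1)
    if (!is.null(object$o17))
      out$o17 <- generate_o17(object$params,
                              temps = object$o17$temp_K,
                              noise_frac = noise_frac, seed = seed + k - 1)
    out
  })
}

#' Plot a fitted joint model over its data
#'
#' NMRD panel (relaxivity vs proton Larmor frequency on a log axis, one
#' curve per temperature) and, when present, the 17O reduced-rate panel.
#'
#' @param x a `relax_fit`.
#' @param ... passed to [plot()].
#' @export
plot.relax_fit <- function(x, ...) {
  has_o17 <- !is.null(x$o17)
  if (has_o17) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (!is.null(x$nmrd)) {
    d <- x$nmrd
    fgrid <- 10^seq(log10(min(d$freq_MHz)), log10(max(d$freq_MHz)),
                    length.out = 80)
    graphics::plot(d$freq_MHz, d$r1, log = "x",
                   xlab = "proton Larmor frequency (MHz)",
                   ylab = expression(r[1] ~ (mM^-1 ~ s^-1)),
                   pch = 1, col = as.integer(factor(d$temp_K)), ...)
    for (Tk in unique(d$temp_K)) {
      m <- nmrd_profile(x$params, fields = fgrid, temps = Tk)
      graphics::lines(m$freq_MHz, m$r1,
                      col = as.integer(factor(Tk, unique(d$temp_K))))
    }
  }
  if (has_o17) {
    d <- x$o17
    graphics::plot(d$temp_K, d$R2r, xlab = "T (K)",
                   ylab = expression(R[2 * r] ~ (s^-1)), pch = 1)
    m <- o17_profile(.as_o17(x$params),
                     temps = seq(min(d$temp_K), max(d$temp_K),
                                 length.out = 80))
    graphics::lines(m$temp_K, m$R2r)
  }
  invisible(x)
}
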
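## Seeded generators for every dataset type the pipeline consumes: the
## stand-in for the study's unreleased raw data. Every generator is a pure
## function of (truth, grid, seed); noiseless outputs invert to zero
## residuals in the corresponding fitter.

#' Default NMRD measurement grid
#'
#' 20 log-spaced proton Larmor frequencies spanning 0.01-120 MHz (the
#' fast-field-cycling range 0.01-10 MHz plus the high-field 20-120 MHz
#' range) and temperatures 283/298.15/310 K.
#' @return Numeric vector, MHz.
#' @export
default_nmrd_fields <- function() {
  10^seq(log10(0.01), log10(120), length.out = 20)
}

#' @rdname default_nmrd_fields
#' @export
default_nmrd_temps <- function() c(283, 298.15, 310)

#' Default variable-temperature 17O grid (K)
#' @export
default_o17_temps <- function() seq(278, 350, length.out = 10)

#' Generate a synthetic NMRD profile
#'
#' Forward model plus multiplicative Gaussian noise:
#' r1_obs = r1_model (1 + noise_frac * N(0,1)); deterministic per seed.
#' The recorded `sigma` column is noise_frac * r1_model (the 1%
#' instrumental uncertainty model).
#'
#' @param truth a [relax_params()] ground truth.
#' @param fields proton Larmor frequencies, MHz.
#' @param temps temperatures, K.
#' @param noise_frac relative noise level (>= 0; default 0.01).
#' @param seed integer seed (mandatory).
#' @return An `nmrd_profile` data frame.
#' @export
generate_nmrd <- function(truth, fields = default_nmrd_fields(),
                          temps = default_nmrd_temps(),
                          noise_frac = 0.01, seed) {
  if (noise_frac < 0) stop("noise_frac must be >= 0", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  prof <- nmrd_profile(truth, fields = fields, temps = temps)
  set.seed(seed)
  eps <- stats::rnorm(nrow(prof))
  prof$sigma <- noise_frac * prof$r1
  prof$r1 <- prof$r1 * (1 + noise_frac * eps)
  if (noise_frac == 0) prof$sigma <- NA_real_
  prof
}

#' Generate a synthetic variable-temperature 17O dataset
#'
#' Both reduced channels (R2r and shift) receive independent additive
#' Gaussian noise scaled to noise_frac times the channel's maximum
#' magnitude (so a q = 0 truth yields a pure-noise dataset around zero).
#'
#' @inheritParams generate_nmrd
#' @param temps temperature grid, K.
#' @return An `o17_dataset` data frame.
#' @export
generate_o17 <- function(truth, temps = default_o17_temps(),
                         noise_frac = 0.01, seed) {
  if (noise_frac < 0) stop("noise_frac must be >= 0", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  d <- o17_profile(.as_o17(truth), temps = temps)
  set.seed(seed)
  sR <- noise_frac * max(abs(d$R2r), 1)
  sW <- noise_frac * max(abs(d$dw_r), 1)
  d$sigma_R2r <- rep(sR, nrow(d))
  d$sigma_dwr <- rep(sW, nrow(d))
  d$R2r <- d$R2r + sR * stats::rnorm(nrow(d))
  d$dw_r <- d$dw_r + sW * stats::rnorm(nrow(d))
  if (noise_frac == 0) {
    d$sigma_R2r <- NA_real_
    d$sigma_dwr <- NA_real_
  }
  d
}

#' Generate a synthetic CW-EPR spectrum
#'
#' Wraps [powder_spectrum()] (rigid regime) or [fast_motion_spectrum()]
#' (fast-motion regime, tau_R required) and adds Gaussian noise scaled to
#' the maximum intensity.
#'
#' @param sys a [spin_system_cu()] ground truth.
#' @param regime `"rigid"` or `"fast_motion"`.
#' @param mw_freq microwave frequency, Hz.
#' @param tau_R rotational correlation time, s (fast-motion regime).
#' @param noise_frac noise level relative to max intensity.
#' @param seed integer seed (mandatory).
#' @param ... passed to the underlying simulator (field_grid, n_orient,
#'   lw_residual, mode, ...).
#' @return An `epr_spectrum`.
#' @export
generate_cw_spectrum <- function(sys, regime = c("rigid", "fast_motion"),
                                 mw_freq = 9.42e9, tau_R = NULL,
                                 noise_frac = 0.01, seed, ...) {
  regime <- match.arg(regime)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  sp <- if (regime == "rigid") {
    powder_spectrum(sys, mw_freq, ...)
  } else {
    if (is.null(tau_R)) stop("fast_motion regime needs tau_R", call. = FALSE)
    fast_motion_spectrum(sys, tau_R, mw_freq, ...)
  }
  set.seed(seed)
  if (noise_frac > 0)
    sp$y <- sp$y + noise_frac * max(abs(sp$y)) *
      stats::rnorm(length(sp$y))
  sp$metadata$noise_frac <- noise_frac
  sp$metadata$seed <- seed
  sp
}

#' Generate a synthetic segment-averaged autocorrelation trace
#'
#' Per segment exp(-t/tau_R) plus Gaussian noise, averaged over
#' `n_segments` segments (the average's noise shrinks as
#' 1/sqrt(n_segments)).
#'
#' @param tau_R rotational correlation time, ps.
#' @param dt lag step, ps (> 0).
#' @param n_lags number of lag points.
#' @param n_segments number of trajectory segments averaged.
#' @param noise_frac per-segment noise standard deviation.
#' @param seed integer seed (mandatory).
#' @return An [autocorr_trace()].
#' @export
generate_autocorr <- function(tau_R, dt = 0.2, n_lags = 250,
                              n_segments = 20, noise_frac = 0.02, seed) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  t <- (seq_len(n_lags) - 1) * dt
  set.seed(seed)
  acc <- matrix(exp(-t / tau_R), nrow = n_lags, ncol = n_segments) +
    noise_frac * matrix(stats::rnorm(n_lags * n_segments), n_lags)
  autocorr_trace(t, rowMeans(acc),
                 segment_length_ps = (n_lags - 1) * dt,
                 n_segments = n_segments)
}
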
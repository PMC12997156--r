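## Independent oracle implementations used to cross-check the package's
## forward models. These are deliberately written as straight, standalone
## transliterations of the closed forms (own constants, no package
## internals) so that agreement is a genuine dual-route check.

.or <- list(
  mu0_4pi = 1.25663706212e-6 / (4 * pi),   # CODATA 2018 mu0 over 4 pi
  muB = 9.2740100783e-24,
  hbar = 1.054571817e-34,
  h = 6.62607015e-34,
  kB = 1.380649e-23,
  ge = 2.00231930436,
  gH = 2.6752218744e8
)

## SBM inner-sphere dipolar rate, brute-force closed form
oracle_dipolar <- function(r_A, tau_R, tau_M, tau_S, B0) {
  w_I <- .or$gH * B0
  w_S <- .or$ge * .or$muB * B0 / .or$hbar
  tc <- 1 / (1 / tau_R + 1 / tau_M + 1 / tau_S)
  r <- r_A * 1e-10
  k <- (2 / 15) * .or$mu0_4pi^2 * .or$gH^2 * .or$ge^2 * .or$muB^2 *
    0.5 * 1.5 / r^6
  k * (3 * tc / (1 + (w_I * tc)^2) + 7 * tc / (1 + (w_S * tc)^2))
}

## Swift-Connick reduced rate and shift, independent fraction
oracle_swift_connick <- function(iT2M, tau_M, dwM) {
  num <- iT2M^2 + iT2M / tau_M + dwM^2
  den <- (iT2M + 1 / tau_M)^2 + dwM^2
  list(R2r = num / den / tau_M,
       dw_r = dwM / ((1 + tau_M * iT2M)^2 + (tau_M * dwM)^2))
}

## electron angular frequency at a field
oracle_omega_S <- function(B0) .or$ge * .or$muB * B0 / .or$hbar

## field (T) from a proton Larmor frequency in MHz
field_from_MHz <- function(f) 2 * pi * f * 1e6 / .or$gH

## random unit vector
runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}
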
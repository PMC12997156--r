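---
title: "Models and methods behind cuprelax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cuprelax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuprelax)
```

This vignette is the package's account of the science it implements:
the relaxation models and their assumptions, the parameters that
matter, what the synthetic-data generators do and do not emulate, and
the numerical choices made where the design was genuinely open.

## 1. The joint relaxometric model

### Inner sphere

Water protons bound to the Cu(II) centre relax with rate 1/T~1M~ and
exchange with bulk with lifetime τ~M~(T). The observable per-mM
relaxivity is the mole-fraction exchange form

$$r_1^{IS} = \frac{q}{55.56\,\mathrm{M}} \cdot
             \frac{1}{T_{1M} + \tau_M},$$

where q counts bound water molecules. A single exchangeable hydroxide
proton (the basic-pH case) is entered as q = 0.5 water-equivalents,
because the normalization counts two protons per water; the preset
`cu_tren_ph12_params()` documents this. 1/T~1M~ is the sum of the
Solomon–Bloembergen–Morgan dipolar rate (with S = 1/2 and correlation
rate 1/τ~c~ = 1/τ~R~(T) + 1/τ~M~(T) + 1/τ~S~) and the scalar rate
(correlation rate 1/τ~e2~ = 1/τ~M~(T) + 1/τ~S~). The Curie term is
omitted: for S = 1/2 it is orders of magnitude below the dipolar term
at every field considered here.

A single, field-independent τ~S~ plays the role of both electronic
relaxation times and also enters the outer-sphere spectral density.
This is the minimal parametrization consistent with one fitted τ~S~
per complex; whether τ~S~ carries a temperature dependence over
283–310 K is not resolvable from these data, so none is assumed (an
Arrhenius scaling hook exists in the code but is off by default).

### Outer sphere

Freely diffusing water is described by the force-free pair-correlation
(Ayant/Hwang–Freed) model,

$$r_1^{OS} = \frac{32\pi}{405}
  \left(\frac{\mu_0}{4\pi}\right)^2 \gamma_H^2 g_e^2 \mu_B^2 S(S+1)
  \frac{N_A [C]}{a\,D(T)} \left[3J(\omega_H) + 7J(\omega_S)\right],$$

with the spectral density
$J(\omega) = \mathrm{Re}\,[(1+z/4)/(1+z+4z^2/9+z^3/9)]$,
$z = \sqrt{i\omega\tau_D + \tau_D/\tau_S}$. Two conventions for the
diffusive correlation time circulate in the literature, τ~D~ = a²/D
and τ~D~ = 2a²/D. This package uses **τ~D~ = 2a²/D**: with the
benchmark parameter sets (a = 3.6 Å, D = 2.3 × 10⁻⁹ m²/s) it
reproduces the benchmark 20 MHz relaxivities within ~2%, whereas the
a²/D convention overshoots both by ~11%. The choice is a convention
pairing, not a free parameter, and it is fixed package-wide.

### Temperature laws and prototropic exchange

τ~M~(T) follows the Eyring law; τ~R~(T) and D(T) follow Arrhenius
laws anchored at 298.15 K. Exchange-model variants: `"water"`
(whole-water exchange), `"prototropic"`
(1/τ~M~ = [OH⁻]/τ~M~(H), base-catalysed proton transfer from a bound
hydroxide), or `"both"`. [OH⁻] is derived from pH as 10^(pH−14); the
temperature dependence of K~w~ is deliberately ignored, which is
adequate because all prototropic data enter at a single pH.

One subtlety is worth recording. An Eyring pair fitted to the
*effective* pseudo-first-order exchange at fixed [OH⁻] differs from
the per-proton pair by the mixing entropy R·ln(1/[OH⁻]) ≈ 38 J/mol/K
at pH 12. The pH-12 preset stores the per-proton entropy so that the
same parameter set reproduces both the effective lifetime (~150 ns)
and the per-proton lifetime (~1.5 ns).

### ¹⁷O Swift–Connick channel

Bound-water ¹⁷O transverse relaxation is scalar-dominated:
1/T~2M~ = (S(S+1)/3)(A~O~/ħ)²[τ~e1~ + τ~e2~/(1+ω~S~²τ~e2~²)], and the
bound-site contact shift Δω~M~ follows the Curie-law 1/T form. The
reduced (per bound-water mole fraction) observables follow the
Swift–Connick fractions; in the fast-exchange limit R~2r~ → 1/T~2M~
and Δω~r~ → Δω~M~, in the slow-exchange limit R~2r~ → 1/τ~M~. Outer
sphere ¹⁷O contributions are neglected: the q = 0 configuration
returns identically zero reduced data, matching the flat ¹⁷O response
of the hydroxo species. With the slow-exchanging mono-aqua benchmark
parameters the model's R~2r~(T) completes most of its slow-to-fast
crossover inside 270–350 K and peaks near 365 K; the tests assert the
crossover (log-slope collapse) inside the window and a single maximum
slightly above it.

### Fitting, weighting, uncertainties

`relax_fit()` concatenates (model − data)/σ over the NMRD block and,
when present, both ¹⁷O channels. When experimental σ are absent, σ
defaults to 1% of each observable's maximum per dataset/channel —
matching the instrument-level 1% uncertainty of fast-field-cycling
relaxometers — which also equalizes the weight of the blocks after
normalization; the relative weighting the original analysis used is
not stated anywhere, so this documented default is exposed rather than
hidden. Optimization is bounded trust-region Levenberg–Marquardt
(`minpack.lm::nls.lm`), with strictly positive parameters handled on a
log₁₀ scale and the rest scaled by their initial values so the
Jacobian is well conditioned. Uncertainties are 1σ values from the
covariance at the optimum scaled by the reduced chi-square; directions
of (near-)zero curvature are reported as infinite rather than being
silently pseudo-inverted, so an unidentifiable parameter announces
itself. A seeded multi-start option guards against local minima but is
off by default; the default fit is fully deterministic.

The basic-pH protocol fits the ¹H NMRD block alone (the ¹⁷O data are
flat). On a three-temperature NMRD grid the prototropic activation
pair (ΔH, ΔS) is nearly degenerate, so the default protocol fixes the
activation enthalpy and floats the entropy — equivalently, the 298 K
proton lifetime — alongside τ~S~, τ~R~, E~R~ and A~H~.

## 2. CW-EPR simulation

The working spin Hamiltonian is H = μ~B~ B·g·S + S·A·I with S = 1/2
and I = 3/2 for both copper isotopes (abundances 0.6917/0.3083; the
⁶⁵Cu hyperfine tensor is the ⁶³Cu tensor scaled by the
gyromagnetic-ratio quotient ≈ 1.071). Ligand ¹⁴N superhyperfine
couplings are unresolved in CW spectra and are not modelled.

**Position engine.** Resonance fields come from second-order
perturbation theory with the electron quantized along the effective g
axis u and the nucleus along the hyperfine field axis v = Aᵀu/|Aᵀu|.
That choice makes the first-order Hamiltonian exactly diagonal, and
the second-order sums collapse to two rotational invariants of the
hyperfine matrix (Z = |Av|² − K², P₂ = (‖A‖²~F~ − |Av|²)/2), giving a
closed form that vectorizes over orientations. Second order is
necessary — |A~z~| up to 482 MHz at X band shifts lines by ~1 mT —
and sufficient: the built-in exact 8×8 diagonalization oracle agrees
to better than 0.15 mT at X band and 0.05 mT at Q band for the
benchmark tensors (tested over random orientations). The oracle can
optionally include the copper nuclear Zeeman term; it is off by
default because the working Hamiltonian omits it and its effect on the
allowed transitions is only O(ν~n~²/A).

**Powder averaging** uses a deterministic golden-angle equal-area
spiral on the upper hemisphere (default 4000 knots) — no random
sampling, for bit-reproducibility — with an optional refinement check
that warns if doubling the knot count changes the spectrum by more
than 1%. Sticks are accumulated by linear interpolation onto a uniform
field grid and convolved with the system's Gaussian and Lorentzian
intrinsic widths; derivative mode models field modulation, absorption
mode models echo detection. Intensities use equal orientation weights;
g-dependent transition-moment corrections (~1% over this g range) are
neglected.

**Fast-motion regime.** Rapid tumbling averages the anisotropies,
leaving four Lorentzian lines per isotope centred at ⟨g⟩ and a~iso~
(including the static second-order hyperfine shift) with widths
1/T₂(m~I~) = a₀ + b₁m~I~ + c₂m~I~². The coefficients were derived
from Redfield theory for isotropic rotational diffusion (secular +
pseudosecular + nonsecular terms, Lorentzian spectral densities
u(ω) = τ/(1+ω²τ²)) in terms of the rotational invariants
Σδg~i~², Σδg~i~δA~i~, ΣδA~i~²; the g-only axial limit reproduces the
textbook (4/45)(Δgμ~B~B₀/ħ)²τ[1 + (3/4)/(1+ω~e~²τ²)] result, which
serves as an internal cross-check. Dynamic (Kivelson) second-order
frequency shifts are omitted: at τ~R~ ≈ 10 ps they amount to
~0.005 mT, three orders of magnitude below the linewidth. A warning
is emitted when anisotropy × τ~R~ > 1 (outside motional narrowing).

`fit_tau_R()` is a one-dimensional least-squares over log₁₀τ~R~ in
[0.1 ps, 10 ns] with amplitude and baseline profiled out linearly; its
uncertainty comes from the local curvature of the profiled sum of
squares, and a flat objective (isotropic system) raises an explicit
unidentifiability error. Because the rigid-limit tensors are held
fixed, τ~R~ is the single adjustable parameter.

## 3. Davies ENDOR

First-order frequencies only: ν± = |ν~n~ ± A~eff~/2|, justified
because every proton coupling here satisfies |A| < 2ν~n~ (couplings
≤ 12 MHz against ν~n~ ≈ 51 MHz at Q band). Orientation selection
weights each orientation by a Gaussian kernel in the frequency offset
between the working field and that orientation's copper resonance
fields; the kernel width is the excitation bandwidth, default 60 MHz
(a 16 ns inversion pulse). The reduced Davies sensitivity to very
small couplings is modelled by a single multiplicative selectivity
factor η(A) = A²/(A² + w²) with hole width w = 2 MHz by default,
which suppresses the ±2 MHz matrix region that the reference analysis
deliberately neglects. The RF lineshape is Gaussian, FWHM 0.3 MHz.
Proton tensors keep their (DFT-derived) Euler angles fixed. The
default orientation grid is 10 000 knots; past that density the
spectrum changes by well under 1% in L2 norm on refinement (tested).

The point-dipole inversion removes a~iso~, takes the largest principal
value T~∥~ of the traceless remainder and returns
r = (2K~dd~/T~∥~)^(1/3) with K~dd~ = (μ₀/4π)g~e~μ~B~g~H~μ~N~/h
≈ 79.1 MHz·Å³. It ignores spin-density delocalization, so distances
for directly coordinated water protons carry a ~10–15% systematic
uncertainty — the tests assert exactly that band, not better.

## 4. Auxiliary estimators

The MD-style rotational correlation time is a single-exponential fit
C(t) = exp(−t/τ~R~) to a segment-averaged autocorrelation trace. The
amplitude is fixed at 1 (a trace with C(0) off by >5% triggers a
normalization warning), and the fit window runs to 5× the expected
τ~R~ or the first zero crossing, whichever comes first, because
long-lag noise otherwise dominates. The Evans/BMS moment uses the SI
molar susceptibility χ~M~ = 3Δf/(4πf c·1000) (cylindrical sample
parallel to B₀) and μ~eff~ = √(3k~B~/(μ₀N~A~))/μ~B~ · √(χ~M~T)
≈ 797.7√(χ~M~T); the convention is labelled in the output because the
geometry factor the original measurement used is not stated.
Diamagnetic corrections are off by default.

## 5. Synthetic data: what it emulates, and what it does not

Every generator is a pure function of (truth, grid, seed). Defaults
mirror the benchmark measurement conditions: 20 log-spaced proton
Larmor frequencies over 0.01–120 MHz at 283/298.15/310 K for NMRD; 10
temperatures over 278–350 K at 11.7 T for ¹⁷O (the plotted range; the
exact experimental grid is not published); X-band 9.42 GHz and Q-band
33.8 GHz for EPR; 200 ps segments for autocorrelation traces. Noise is
1% multiplicative for relaxivities (the instrument specification) and
1% of the maximum for spectra and the additive ¹⁷O channels.

The generators emulate measurement noise only. They do not emulate
baseline drift, phase errors, temperature miscalibration, field
inhomogeneity, concentration errors, or — most importantly — model
misspecification: synthetic data are drawn from the same forward model
that is fitted back. Passing recovery tests therefore demonstrates
identifiability and correctness of the estimation machinery under the
stated conditions, not that the SBM/Swift–Connick model is the right
description of any particular real complex.

## 6. Numerical choices and problem sizes

* Constants are CODATA 2018, from a single authoritative table
  (`cuprelax_constants`); no physical literals elsewhere. Fields are
  tesla and frequencies Hz internally; mT and MHz appear only at I/O
  boundaries.
* Hyperfine signs follow the convention that the computed (DFT) signs
  fix the experimental ones; magnitudes are used where an observable
  is sign-blind.
* Parameter recovery suites run 50 seeded replicates per benchmark
  preset (each joint fit converges in a few iterations, so the full
  suite costs seconds); per-parameter 2σ coverage is the reported
  statistic. Requiring all seven free parameters to be covered jointly
  per replicate would have a nominal rate of only ~0.95⁷ ≈ 0.70 and is
  not a meaningful criterion.
* Golden-file spectra under `tests/testthat/_golden/` were generated
  by this package at a fixed version; they guard against unintended
  numerical drift and are self-referential by construction (the
  intrinsic linewidths used are this package's own choices — 1.5 mT
  Gaussian / 1.0 mT Lorentzian rigid-limit, 0.5 mT residual fast
  motion — since no reference values are published).

## 7. Known limitations

* Slow-motion EPR lineshapes (stochastic Liouville) are out of scope;
  the fast-motion model warns, but extrapolation beyond
  anisotropy·τ~R~ ≈ 1 is unreliable.
* ENDOR intensities use first-order frequencies with a heuristic
  selectivity factor; hyperfine enhancement and nuclear quadrupole
  effects are not modelled.
* The point-dipole distance is systematically biased for delocalized
  spin density.
* τ~S~ is a phenomenological single time; no field or temperature
  dependence is fitted.
* The experimental isotropic Cu hyperfine read from a room-temperature
  four-line splitting is a distinct observable from the mean of the
  rigid-limit tensor components; the package exposes both and never
  conflates them.
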
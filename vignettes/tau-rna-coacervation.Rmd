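---
title: "Modelling tau-RNA complex coacervation: lattice and field-theoretic thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tau-RNA complex coacervation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coacervate)
```

## The problem

Tau, a positively charged intrinsically disordered protein, forms liquid
droplets with polyU RNA by **complex coacervation**: electrostatic
correlations between the polycation and the polyanion drive demixing into
a polymer-rich coacervate and a dilute supernatant. The transition has a
*lower* critical solution temperature — heating promotes droplets — which
immediately implicates entropy as a driving force, since demixing on
heating must gain entropy somewhere (here, plausibly, from releasing
hydration water).

The experimental observable is a cloud point: the temperature `T_cp` at
which a heated tau-RNA mixture at fixed `[tau]` and `[NaCl]` turns turbid.
This package turns collections of cloud points into thermodynamics along
two independent modelling routes, and provides the generators needed to
exercise every stage synthetically.

## Charge model

Both routes share one charge convention (`assign_charges()`): at pH 7,
aspartate and glutamate carry −1, lysine and arginine +1, everything else
(including histidine and cysteine) 0; polyU is −1 per nucleotide
(`make_polyU()`). Phosphoserine is modelled as −2 (`phosphorylate()`), the
fully phosphorylated limiting case.

Two charge conventions for tau deliberately coexist and are never mixed:

* the **integer D/E/K/R count** used by the field-theoretic track (the
  shipped tau187 construct counts +9 bare, +10 with its tag);
* a **calculator-style fractional estimate** (`net_charge_hh()`,
  Henderson-Hasselbalch with termini), which reproduces the +11 per
  molecule commonly quoted for this construct. The lattice defaults
  (`fhvo_params()`: N = 207, q = +11) use that conventional value, because
  the lattice composition rules are defined with it.

The N-terminal His-tag sequence of the expression construct is not public;
the FASTA shipped in `inst/extdata/` marks its generic 20-residue tag as
synthetic. Both the bare 187-mer and the tagged 207-mer give the same
charge-matched chain fraction to printed precision (0.954), so nothing
downstream depends on the choice.

## Cloud points from turbidity

A heating-branch turbidity trace is min-max normalized and fitted by
unweighted least squares to

$$\mathrm{turbidity}(T) = \frac{1}{1 + e^{-k (T - T_{cp})}},$$

so `T_cp` is exactly the half-maximum crossing and `k` (1/K) the
transition steepness. Initial guesses are the first 0.5-crossing by linear
interpolation and `k = 4/(T_{90} - T_{10})`, which is robust for monotone
sigmoids; convergence is Levenberg-Marquardt with relative tolerance
1e-10 (the residual weighting and tolerance are our choices — nothing in
the source analysis pins them). Step-like transitions are fitted but
flagged `"steep"`; negative-`k` optima are flagged `"inverted"`. Only
heating branches feed reported transition temperatures: the
heating/cooling hysteresis is kinetic (nucleation), so cooling fits are
available but labelled. Per-curve normalization removes per-cycle
amplitude decay (slow RNA degradation) by construction, which is why
repeated heating cycles give stable cloud points.

## The lattice route (FH-VO)

Five species — tau (N = 207, σ = 11/207), RNA (N = 2941 from 900 kDa at
306 Da per nucleotide, σ = 1), Na⁺, Cl⁻, water (N = 1) — with free energy
per site

$$f = \sum_i \frac{\phi_i}{N_i}\ln\phi_i \;-\; \alpha(T)\Big[\sum_i \sigma_i\phi_i\Big]^{3/2} \;+\; \chi\,\phi_{\mathrm{poly}}\,\phi_w,$$

$$\alpha(T) = \tfrac{2}{3}\sqrt{\pi}\,(l_B/l_w)^{3/2},\qquad
l_w = \big(10^{-3}/(c_w N_A)\big)^{1/3},\; c_w = 55.56\,\mathrm{mol/L}.$$

Compositions map from experimental conditions at the 1:1 charge-matching
ratio: `phi_tau = [tau]·207/c_w`, `phi_RNA = [tau]·11/c_w`,
`phi_salt = ([NaCl] + 20 mM)/c_w` (the 20 mM is buffer; the printed
composition rules count total salt once, and we follow them literally
rather than double-counting the two ions), water the remainder.

**Design choices that were genuinely open.** A single scalar χ is applied
to the two polymer-water pairs and nowhere else: that is the most
conservative reading of "one adjustable parameter", and the dilute-branch
compositions that the fits use are insensitive to spreading χ over other
pairs. The Debye-Hückel prefactor is the standard Voorn-Overbeek
`(2/3)√π`, the only dimensionally consistent reading. The dielectric
constant is held at 80 independent of temperature, so `l_B ∝ 1/T`.

**Binodal construction.** At fixed T and salt (salt partitions equally
between phases, making the system effectively binary), coexisting
compositions solve equal tangent slope and equal intercept on
`f(φ_polymer)`:
a damped Newton iteration in `(log φ₁, log φ₂)` with analytic Jacobian,
seeded at the spinodal roots ∓10%. The log parameterization is what makes
the very steep dilute branch (φ₁ down to 1e-12) tractable. An independent
construction — the slope `m` at which the two per-side minima of
`f − mφ` coincide (a Legendre double-touch, `binodal_hull()`) — serves as
cross-check and fallback; the two agree to 1e-6 in φ on randomized
instances, and both reproduce the closed-form Flory-Huggins critical point
`φ_c = 1/(1+√N)`, `χ_c = (1+1/√N)²/2` when the electrostatic term is
switched off.

**χ fitting.** `fit_chi_point()` brackets and bisects the scalar χ until
the dilute branch passes through the measured composition at the measured
`T_cp` (tolerance 1e-8; the dilute fraction is monotone decreasing in χ,
so bisection is safe even where no coexistence exists at the lower
bracket). `fit_chi_law()` then regresses χ on 1/T. The package's own
forward model at the empirical law gives χ ≈ 0.46-0.49 near 293 K at the
reference conditions and a dense phase with φ_water ≈ 0.75 — the right
physical neighbourhood for a weakly complexed biological coacervate.

## Temperature maps and the decomposition

`bjerrum_length()` gives `l_B = e²/(4πε₀ε_r k_B T)` (0.70 nm at 300 K for
water), `excluded_volume()` the LCST form `v(T) = -v0(1 - θ/T)` with
defaults `v0 = 0.25 b³`, `θ = 309 K` (v = 0 at θ; positive, good solvent,
below it), and `chi_from_v()` the second-order relation `v = b³(1-2χ)`.
`decompose_thermo()` converts a `χ(T) = ε_s + ε_H/T` law into per-mole-of-
monomer quantities with water fraction `φ_w = 0.722` (treated as a
representative constant of the dense phase; the source analysis gives no
composition dependence for it): mixing values
`ΔH_mix = R φ_w ε_H`, `TΔS_mix = -R T φ_w ε_s`, reported with the
phase-separation sign convention (negated mixing values) at the reporting
layer only. The identity `ΔH_ex - TΔS_noncomb = -R T φ_w χ(T)` holds by
construction and is tested for random inputs.

```{r decomposition}
decompose_thermo(1.8, -390, T = 300, phi_w = 0.722)       # lattice route
law <- chi_law_from_map(temperature_map(v0 = 0.25, theta = 309))
decompose_thermo(law$A, law$B, T = 300, phi_w = 0.722)    # field-theory route
```

Both routes agree on the sign structure — a small unfavourable
non-electrostatic enthalpy beaten by a larger non-combinatoric entropy
gain — which is the quantitative face of the LCST observation.

## The field-theoretic route

The particle model (bead-spring chains, Gaussian excluded volume `v`,
Coulomb `l_B`, point ions, all segments smeared with a unit Gaussian of
variance `b²/6`) is transformed exactly into a field theory of two
fluctuating fields: `w` conjugate to total density and `φ_el` to charge
density. In units of `R0 = b/√6` (the prefactor of `R_g = R0 N^{1/2}`;
the alternative reading `b/6` is inconsistent with that relation and was
discarded) the state is fully specified by `B = v/R0³`, `E = 4π l_B/R0`,
`C = ρR0³` and the chain fractions, set by global charge neutrality
(`φ_tau = N/(N+q)` for matched equal-length chains). The smearing kernel
is `exp(-k²b²/12)` spectrally — the one consistent normalization of a
unit Gaussian of width ~b — and is isolated behind a single constant.

Chain statistics use pseudo-spectral Chapman-Kolmogorov propagators
(bond kernel `exp(-k²)` in R0 units); zero fields give Q = 1 exactly and
a uniform potential gives `Q = exp(-Nc)`, both asserted to machine
precision in the tests, and the field-free propagator reproduces ideal
random-walk spreading.

**Complex-Langevin sampling.** Both fields obey relaxational dynamics with
real Gaussian noise; the linear (Gaussian) part of each equation is
integrated exactly per step (exponential time differencing), including the
exact Ornstein-Uhlenbeck noise variance, which removes the O(Δt)
bias of the field variances — without it the osmotic-pressure operator is
visibly biased at small B. Defaults: Δt = 0.01, mobilities
λ_w = λ_φ = 1; for strongly coupled electrostatics (large E) the
φ-mobility should be raised to order E — its linear relaxation rate is
`λ_φ k²/E`, so λ_φ is a pure sampling-rate choice that leaves the
stationary measure untouched. The `φ_el` zero mode is a gauge direction
and is pinned to zero. The mean-field saddle (`w = -iB·ρ_tot`, `φ_el = 0`)
is the exact fixed point of the noise-free dynamics, which doubles as a
force-implementation test. Non-finite propagators abort the trajectory
with the step index (complex-Langevin divergence detection).

**Operators.** `μ_l = ln(Cφ_l/N_l) - ln Q_l` (the printed operator is
typographically corrupt; this reading is the one that reduces to the
ideal-gas chemical potential, and that limit is tested). The osmotic
pressure operator is assembled from dilation covariance of the regularized
theory: ideal translational terms, `-(1/2BV)∫w²`, `-(1/6EV)∫(∇φ)²`,
bond-stretch and smearing-scale terms, plus the Gaussian zero-point
constants `M³/2V` and `(M³-1)/6V` that render the thermal average finite
(a noise-free saddle evaluation omits them, `include_zero_point = FALSE`).
Certified limits: ideal gas `Π = C/N`, homogeneous mean field
`Π = C/N + BC²/2` (exact deterministically, and within CL errors
stochastically).

**Coexistence.** `fts_sweep()` tabulates `(C, μ, Π)`; `find_coexistence()`
segments the branches by the turning points of μ(C), interpolates Π(μ) on
the two stable branches and solves for the crossing — equal chemical
potential and pressure — reading the coexisting densities back from each
branch. The construction is validated against an analytic double-well free
energy whose coexistence pair is known in closed form.

## Synthetic data: what it emulates and what it does not

`gen_turbidity()` produces heating sigmoids with homoscedastic Gaussian
noise and optional per-cycle decay; `gen_cloudpoint_grid()` produces
cloud-point tables from an LCST `χ(T)` through the lattice forward solver
(grid points that never phase separate in the searched range are reported
missing, never fabricated); `gen_sequences()` produces charge sequences
with exact net charge and tunable blockiness. Noise on `T_cp` is Gaussian
and homoscedastic — the simplest defensible stand-in for the pH-drift and
RNA-degradation variability of real measurements, for which no model is
given. Passing recovery tests therefore shows the *pipeline* is unbiased
and self-consistent; it does not validate the lattice model against real
instrument noise, droplet light-scattering optics, or coarsening kinetics,
none of which are simulated.

## Problem sizes and numerical choices

The test-suite simulations are deliberately scaled down and state their
sizes explicitly: 16³ collocation meshes, 20-residue truncated tau/polyU
chains, a few thousand CL steps with Δt = 0.005-0.01, boxes of 10-16 R0 —
sizes at which the qualitative Fig.-4-style contrast between a coacervate
droplet (strong `l_B`, small `v`) and a homogeneous solution (weak `l_B`,
larger `v`) reproduces in about a minute per condition. Full binodal
surfaces of the sequence-resolved model need long trajectories at 32³ with
full-length chains and are outside what this package attempts at test
time; the machinery (`fts_sweep()` + `find_coexistence()`) is the same,
only the budget differs. Equilibration is cut by a marginal-standard-error
rule (minimum 20% discarded) and errors are block averages over 10 blocks.

Known limitations, by choice of scope: no counterion condensation and no
Gibbs-ensemble salt partitioning (salt is equipartitioned); no RPA or
other analytic field approximations; no temperature-dependent RNA charge;
no pKa titration model (the integer charge set is fixed); cooling-branch
thermodynamics (nucleation hysteresis) are not modelled. The
excluded-volume direction of the coexistence-gap monotonicity is not
asserted in tests: the affordable density-contrast proxy is confounded by
the B-dependence of the w-field's thermal amplitude, and the clean
statement lives on binodal densities whose measurement exceeds the test
budget.
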
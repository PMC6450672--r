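# Temperature maps connecting the experimental scale to both models:
# Bjerrum length l_B(T), temperature-dependent excluded volume v(T), the
# v <-> chi conversion, and the non-ionic enthalpy/entropy decomposition of
# the coacervation free energy.

#' Bjerrum length
#'
#' Distance at which the Coulomb energy between two unit charges equals the
#' thermal energy: `l_B = e^2 / (4 pi eps0 eps_r kB T)`. The dielectric
#' constant is treated as temperature-independent so that `l_B ~ 1/T`.
#'
#' @param T Temperature in kelvin.
#' @param eps_r Relative dielectric constant (default 80, water).
#' @return Bjerrum length in metres.
#' @export
#' @examples
#' bjerrum_length(300) * 1e9  # ~0.70 nm
bjerrum_length <- function(T, eps_r = 80) {
  stopifnot(all(T > 0), eps_r > 0)
  .const$e^2 / (4 * pi * .const$eps0 * eps_r * .const$kB * T)
}

#' Temperature map for the coarse-grained model
#'
#' Bundles the segment length, dielectric constant and the two parameters of
#' the LCST excluded-volume law `v(T) = -v0 (1 - theta/T)`: `v0` sets the
#' magnitude (in units of `b^3`) and `theta` is the theta temperature where
#' the chain is ideal and `v = 0`. Below `theta` the net monomer-monomer
#' interaction is repulsive (good solvent); above it the excluded volume
#' turns attractive.
#'
#' @param b Segment length in metres (default 4 Angstrom, about one
#'   C-alpha to C-alpha distance).
#' @param eps_r Relative dielectric constant (default 80).
#' @param v0 Excluded-volume magnitude in units of `b^3` (default 0.25).
#' @param theta Theta temperature in kelvin (default 309).
#' @return A `temperature_map` object.
#' @export
temperature_map <- function(b = 4e-10, eps_r = 80, v0 = 0.25, theta = 309) {
  stopifnot(b > 0, eps_r > 0, v0 > 0, theta > 0)
  structure(list(b = b, eps_r = eps_r, v0 = v0, theta = theta),
            class = "temperature_map")
}

#' @export
print.temperature_map <- function(x, ...) {
  cat(sprintf(
    "temperature_map: b = %.3g m, eps_r = %g, v0 = %g b^3, theta = %g K\n",
    x$b, x$eps_r, x$v0, x$theta))
  invisible(x)
}

#' Temperature-dependent excluded volume
#'
#' `v(T) = -v0 (1 - theta/T)` in units of `b^3`; zero exactly at the theta
#' temperature, positive (repulsive) below it.
#'
#' @param T Temperature in kelvin.
#' @param map A [temperature_map()].
#' @return Excluded volume in units of `b^3`.
#' @export
#' @examples
#' excluded_volume(300)  # +0.0075 b^3
excluded_volume <- function(T, map = temperature_map()) {
  stopifnot(all(T > 0))
  -map$v0 * (1 - map$theta / T)
}

#' Convert between excluded volume and the lattice chi parameter
#'
#' To second order in polymer volume fraction the continuum excluded volume
#' and the lattice interaction parameter are related by `v = b^3 (1 - 2 chi)`,
#' so `chi = 1/2` at the theta condition (`v = 0`). `v_b3` is the excluded
#' volume in units of `b^3`; the round trip is exact.
#'
#' @param v_b3 Excluded volume in units of `b^3`.
#' @return `chi_from_v`: the corresponding chi.
#' @export
#' @examples
#' chi_from_v(0)           # 0.5
#' v_from_chi(chi_from_v(0.02))  # 0.02
chi_from_v <- function(v_b3) (1 - v_b3) / 2

#' @rdname chi_from_v
#' @param chi Flory-Huggins interaction parameter.
#' @return `v_from_chi`: the excluded volume in units of `b^3`.
#' @export
v_from_chi <- function(chi) 1 - 2 * chi

#' chi(T) law implied by an excluded-volume map
#'
#' Substituting `v(T) = -v0 (1 - theta/T)` into `chi = (1 - v/b^3)/2` gives
#' the linear-in-1/T law `chi(T) = (1 + v0)/2 - (v0 theta / 2) / T`, i.e.
#' entropic coefficient `eps_s = (1 + v0)/2` and enthalpic coefficient
#' `eps_H = -v0 theta / 2` (kelvin).
#'
#' @param map A [temperature_map()].
#' @return A [chi_law()] with the implied `(A, B)`.
#' @export
#' @examples
#' chi_law_from_map()  # chi(T) = 0.625 - 38.625/T for the defaults
chi_law_from_map <- function(map = temperature_map()) {
  chi_law(A = (1 + map$v0) / 2, B = -map$v0 * map$theta / 2)
}

#' Non-ionic enthalpy/entropy decomposition of coacervation
#'
#' From a `chi(T) = eps_s + eps_H/T` decomposition, the non-combinatoric
#' contribution to the mixing free energy per mole of monomer is
#' `R T phi_w chi(T)`, giving a mixing enthalpy `dH_mix = R phi_w eps_H` and
#' a non-ideal mixing entropy `dS_mix = -R phi_w eps_s`. Reported
#' phase-separation quantities are the negated mixing quantities
#' (coacervation is demixing): `dH_ex = -R phi_w eps_H` and
#' `T dS_noncomb = R T phi_w eps_s`. The identity
#' `dH_ex - T dS_noncomb = -R T phi_w chi(T)` holds for all inputs.
#'
#' @param eps_s Entropic chi coefficient (dimensionless).
#' @param eps_H Enthalpic chi coefficient (kelvin).
#' @param T Temperature in kelvin (default 300).
#' @param phi_w Water volume fraction of the dense phase (default 0.722).
#' @return A `thermo_decomposition`: list with the inputs plus `dH_ex` and
#'   `TdS_noncomb` (kJ per mol monomer, phase-separation convention) and the
#'   mixing-convention values `dH_mix`, `TdS_mix`.
#' @export
#' @examples
#' decompose_thermo(1.8, -390)          # FH-VO empirical chi law
#' decompose_thermo(0.625, -38.625)     # law implied by v0 = 0.25, theta = 309
decompose_thermo <- function(eps_s, eps_H, T = 300, phi_w = 0.722) {
  stopifnot(T > 0, phi_w > 0, phi_w <= 1)
  R <- .const$R
  dH_mix <- R * phi_w * eps_H / 1000          # kJ / mol monomer
  TdS_mix <- -R * T * phi_w * eps_s / 1000    # kJ / mol monomer
  structure(list(eps_s = eps_s, eps_H = eps_H, T = T, phi_w = phi_w,
                 dH_mix = dH_mix, TdS_mix = TdS_mix,
                 dH_ex = -dH_mix, TdS_noncomb = -TdS_mix),
            class = "thermo_decomposition")
}

#' @export
print.thermo_decomposition <- function(x, ...) {
  cat(sprintf("thermo_decomposition at T = %g K, phi_w = %g\n", x$T, x$phi_w))
  cat(sprintf("  chi(T) = %g %+g/T  ->  chi(%g K) = %.4f\n",
              x$eps_s, x$eps_H, x$T, x$eps_s + x$eps_H / x$T))
  cat(sprintf("  phase separation: dH_ex = %.3g kJ/mol monomer, T dS_noncomb = %.3g kJ/mol monomer\n",
              x$dH_ex, x$TdS_noncomb))
  invisible(x)
}
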
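# Flory-Huggins lattice free energy with a Voorn-Overbeek Debye-Huckel
# electrostatic term, for the five-species mixture tau / RNA / Na+ / Cl- /
# water. Binodals are constructed by the common-tangent (bitangent)
# condition on f(phi_polymer) at fixed salt fraction and temperature;
# a per-condition scalar chi is fitted so the dilute branch passes through
# each experimental cloud point, then chi(T) = A + B/T is regressed.

#' Lattice-model parameter set
#'
#' Chain lengths and charges entering the lattice composition rules. The
#' defaults are the tau187-polyU system: tau with degree of polymerization
#' 207 (His-tagged construct) and net charge +11 per molecule, polyU RNA of
#' 2941 nucleotides (900 kDa at 306 Da per residue) with one negative charge
#' per monomer, monovalent ions and water with N = 1, water molarity
#' 55.56 mol/L and a 20 mM buffer contribution to the salt.
#'
#' Compositions are built at the 1:1 charge-matching ratio, so the RNA
#' monomer molarity is `tau_q` times the tau molarity and the polymer volume
#' fraction is `[tau] (tau_N + tau_q) / cw`.
#'
#' @param tau_N Tau degree of polymerization (default 207).
#' @param tau_q Tau net charge per molecule (default +11).
#' @param rna_N RNA degree of polymerization (default 2941).
#' @param cw Water molarity in mol/L (default 55.56).
#' @param buffer_mM Buffer salt contribution in mM (default 20).
#' @return An `fhvo_params` object.
#' @export
fhvo_params <- function(tau_N = 207, tau_q = 11, rna_N = 2941,
                        cw = 55.56, buffer_mM = 20) {
  stopifnot(tau_N >= 1, tau_q > 0, rna_N >= 1, cw > 0, buffer_mM >= 0)
  Np <- tau_N + tau_q # polymer lattice sites per tau molecule (tau + matched RNA)
  structure(list(tau_N = tau_N, tau_q = tau_q, rna_N = rna_N,
                 cw = cw, buffer_mM = buffer_mM,
                 r_tau = tau_N / Np, r_rna = tau_q / Np,
                 sigma_tau = tau_q / tau_N, sigma_rna = 1,
                 sigma_poly = 2 * tau_q / Np),
            class = "fhvo_params")
}

#' Lattice length
#'
#' Edge length of one lattice site, set by the water number density:
#' `lw = (1e-3 m^3 / (cw NA))^(1/3)`.
#'
#' @param cw Water molarity in mol/L.
#' @return Lattice length in metres (about 3.1 Angstrom for water).
#' @export
lattice_length <- function(cw = 55.56) {
  (1e-3 / (cw * .const$NAv))^(1 / 3)
}

#' Voorn-Overbeek electrostatic strength
#'
#' Dimensionless prefactor of the Debye-Huckel correlation term,
#' `alpha = (2/3) sqrt(pi) (l_B / lw)^(3/2)` with the Bjerrum length
#' evaluated at fixed dielectric constant.
#'
#' @param T Temperature in kelvin.
#' @param lw Lattice length in metres (default from [lattice_length()]).
#' @param eps_r Relative dielectric constant (default 80).
#' @return Dimensionless electrostatic strength (about 4 near room
#'   temperature).
#' @export
#' @examples
#' electrostatic_strength(300)  # ~3.97
electrostatic_strength <- function(T, lw = lattice_length(), eps_r = 80) {
  stopifnot(all(T > 0), lw > 0)
  (2 / 3) * sqrt(pi) * (bjerrum_length(T, eps_r) / lw)^(3 / 2)
}

#' Lattice system state
#'
#' Full five-species state: volume fractions, temperature, interaction
#' parameter and electrostatic strength. Volume fractions must be
#' non-negative and close (sum to 1 within 1e-12).
#'
#' @param phi Named numeric vector with entries `tau`, `rna`, `na`, `cl`,
#'   `water`.
#' @param T Temperature in kelvin.
#' @param chi Scalar interaction parameter applied to the tau-water and
#'   RNA-water pairs (all other pairs zero).
#' @param params An [fhvo_params()].
#' @return A `lattice_system` object (with `alpha` evaluated at `T`).
#' @export
lattice_system <- function(phi, T, chi = 0, params = fhvo_params()) {
  need <- c("tau", "rna", "na", "cl", "water")
  stopifnot(all(need %in% names(phi)))
  phi <- phi[need]
  if (any(phi < 0)) stop("all volume fractions must be >= 0")
  if (abs(sum(phi) - 1) > 1e-12) stop("volume fractions must sum to 1")
  structure(list(phi = phi, T = T, chi = chi,
                 alpha = electrostatic_strength(T),
                 N = c(tau = params$tau_N, rna = params$rna_N,
                       na = 1, cl = 1, water = 1),
                 sigma = c(tau = params$sigma_tau, rna = 1,
                           na = 1, cl = 1, water = 0),
                 params = params),
            class = "lattice_system")
}

#' Lattice composition from experimental conditions
#'
#' Maps `([tau] in uM, [NaCl] in mM)` to lattice volume fractions at the 1:1
#' charge-matching ratio: `phi_tau = c_tau tau_N / cw`,
#' `phi_rna = c_tau tau_q / cw`, total salt
#' `phi_salt = (c_NaCl + buffer) / cw` split equally between the two ions,
#' and water as the remainder.
#'
#' @param tau_uM Tau concentration in micromolar (>= 0).
#' @param nacl_mM NaCl concentration in millimolar (>= 0).
#' @param T Temperature in kelvin.
#' @param chi Interaction parameter to store in the state.
#' @param params An [fhvo_params()].
#' @return A `lattice_system`.
#' @export
#' @examples
#' s <- composition_from_conditions(50, 120)
#' s$phi["tau"]  # ~1.86e-4
composition_from_conditions <- function(tau_uM, nacl_mM, T = 293.15,
                                        chi = 0, params = fhvo_params()) {
  stopifnot(tau_uM >= 0, nacl_mM >= 0)
  c_tau <- tau_uM * 1e-6                       # mol/L
  phi_tau <- c_tau * params$tau_N / params$cw
  phi_rna <- c_tau * params$tau_q / params$cw
  phi_salt <- (nacl_mM + params$buffer_mM) * 1e-3 / params$cw
  phi_w <- 1 - phi_tau - phi_rna - phi_salt
  if (phi_w <= 0) stop("unphysical concentration: no room left for water")
  lattice_system(c(tau = phi_tau, rna = phi_rna,
                   na = phi_salt / 2, cl = phi_salt / 2, water = phi_w),
                 T = T, chi = chi, params = params)
}

#' Polymer volume fraction for given experimental conditions
#'
#' @param tau_uM Tau concentration in micromolar.
#' @param params An [fhvo_params()].
#' @return `phi_polymer = [tau] (tau_N + tau_q) / cw`.
#' @export
phi_polymer_from_tau <- function(tau_uM, params = fhvo_params()) {
  tau_uM * 1e-6 * (params$tau_N + params$tau_q) / params$cw
}

#' @rdname phi_polymer_from_tau
#' @param phi_polymer Polymer volume fraction.
#' @return `tau_from_phi_polymer`: tau concentration in micromolar.
#' @export
tau_from_phi_polymer <- function(phi_polymer, params = fhvo_params()) {
  phi_polymer * params$cw / (params$tau_N + params$tau_q) * 1e6
}

#' Mixing free energy per lattice site
#'
#' Evaluates `f = sum(phi_i/N_i log phi_i) - alpha (sum sigma_i phi_i)^(3/2)
#' + sum chi_ij phi_i phi_j` for a full five-species state; species with
#' zero volume fraction contribute nothing to the entropy. `chi` couples the
#' two polymer-water pairs only.
#'
#' @param sys A [lattice_system()].
#' @return Dimensionless free energy density (units of kT per site).
#' @export
free_energy_per_site <- function(sys) {
  stopifnot(inherits(sys, "lattice_system"))
  phi <- sys$phi
  xlogx <- ifelse(phi > 0, phi * log(phi), 0)
  ent <- sum(xlogx / sys$N)
  dh <- -sys$alpha * sum(sys$sigma * phi)^(3 / 2)
  en <- sys$chi * (phi[["tau"]] + phi[["rna"]]) * phi[["water"]]
  unname(ent + dh + en)
}

# Reduced free energy along the polymer axis at fixed salt and temperature.
# Returns closures f, df, d2f of phi = phi_polymer, plus the domain. The
# polymer splits internally as r (site fractions) over chains of length N
# and charge density sigma; salt enters the Debye-Huckel argument with
# weight 1 and the (constant) salt entropy is included so the reduced f
# agrees with free_energy_per_site.
fhvo_reduced <- function(phi_salt, T, chi, params = fhvo_params(),
                         alpha = NULL, r = NULL, N = NULL, sigma = NULL) {
  if (is.null(alpha)) alpha <- electrostatic_strength(T)
  if (is.null(r)) r <- c(params$r_tau, params$r_rna)
  if (is.null(N)) N <- c(params$tau_N, params$rna_N)
  if (is.null(sigma)) sigma <- c(params$sigma_tau, params$sigma_rna)
  stopifnot(abs(sum(r) - 1) < 1e-12, phi_salt >= 0, phi_salt < 1)
  sc <- sum(r * sigma)       # polymer charge per occupied site
  a1 <- sum(r / N)           # coefficient of the polymer entropy derivative
  clogr <- sum((r / N) * log(r))
  s_ent <- if (phi_salt > 0) phi_salt * log(phi_salt / 2) else 0
  hi <- 1 - phi_salt
  dh_on <- alpha != 0 && (sc > 0 || phi_salt > 0) # else 0/sqrt(0) at phi -> 0
  f <- function(phi) {
    pw <- hi - phi
    (a1 * phi * log(phi) + clogr * phi) + s_ent +
      ifelse(pw > 0, pw * log(pw), 0) -
      (if (dh_on) alpha * (sc * phi + phi_salt)^(3 / 2) else 0) +
      chi * phi * pw
  }
  df <- function(phi) {
    pw <- hi - phi
    a1 * (log(phi) + 1) + clogr - (log(pw) + 1) -
      (if (dh_on) 1.5 * alpha * sc * sqrt(sc * phi + phi_salt) else 0) +
      chi * (pw - phi)
  }
  d2f <- function(phi) {
    pw <- hi - phi
    a1 / phi + 1 / pw -
      (if (dh_on) 0.75 * alpha * sc^2 / sqrt(sc * phi + phi_salt) else 0) -
      2 * chi
  }
  list(f = f, df = df, d2f = d2f, lo = 0, hi = hi,
       sc = sc, alpha = alpha, phi_salt = phi_salt, chi = chi)
}

# Spinodal roots of d2f on (0, hi); returns numeric(0) if locally stable
# everywhere. A grid scan catches well-separated roots; near-critical
# (narrow) unstable windows are recovered from the minimum of d2f.
fhvo_spinodal <- function(fe, n_grid = 160) {
  hi <- fe$hi * (1 - 1e-9)
  grid <- sort(unique(c(
    10^seq(-14, log10(hi / 2), length.out = n_grid %/% 2),
    seq(hi / 2, hi, length.out = n_grid %/% 2))))
  v <- fe$d2f(grid)
  s <- which(diff(sign(v)) != 0)
  roots <- vapply(s, function(i)
    stats::uniroot(fe$d2f, c(grid[i], grid[i + 1]), tol = 1e-15)$root,
    numeric(1))
  if (length(roots) == 0) {
    o <- stats::optimize(function(u) fe$d2f(exp(u)),
                         interval = log(c(1e-14, hi)), tol = 1e-13)
    if (o$objective < 0) {
      pm <- exp(o$minimum)
      roots <- c(stats::uniroot(fe$d2f, c(1e-14, pm), tol = 1e-15)$root,
                 stats::uniroot(fe$d2f, c(pm, hi), tol = 1e-15)$root)
    }
  }
  roots
}

#' Critical point of the reduced free energy
#'
#' Locates the composition at which the curvature of the reduced free energy
#' is minimal (which does not depend on chi, since chi enters the curvature
#' as a constant) and returns the chi at which that minimal curvature
#' vanishes: the critical point `(chi_c, phi_c)` of the demixing transition.
#'
#' @inheritParams fhvo_bitangent
#' @return List with `phi_c` and `chi_c`.
#' @export
#' @examples
#' # plain Flory-Huggins: phi_c = 1/(1 + sqrt(N)), chi_c = (1 + 1/sqrt(N))^2/2
#' fe <- coacervate:::fhvo_reduced(0, 300, chi = 0, alpha = 0,
#'                                 r = 1, N = 100, sigma = 0)
#' fhvo_critical(fe = fe)
fhvo_critical <- function(phi_salt = NULL, T = NULL, params = fhvo_params(),
                          fe = NULL) {
  if (is.null(fe)) fe <- fhvo_reduced(phi_salt, T, chi = 0, params)
  d2f_chi0 <- function(phi) fe$d2f(phi) + 2 * fe$chi # remove the -2 chi shift
  o <- stats::optimize(function(u) d2f_chi0(exp(u)),
                       interval = log(c(1e-14, fe$hi * (1 - 1e-9))),
                       tol = 1e-14)
  phi_c <- exp(o$minimum)
  list(phi_c = phi_c, chi_c = o$objective / 2)
}

#' Common-tangent (bitangent) construction on the reduced free energy
#'
#' Finds the pair of polymer volume fractions `(phi1, phi2)` with equal
#' first derivative and equal `f - phi f'` (equal chemical potentials of
#' polymer and solvent) at fixed salt fraction and temperature. The primary
#' path is a damped Newton iteration in `(log phi1, log phi2)` with analytic
#' Jacobian, seeded near the spinodal; on failure the independent
#' convex-envelope construction ([binodal_hull()]) is used and the path that
#' succeeded is reported. Returns `NULL` when the free energy is convex (no
#' phase separation).
#'
#' @param phi_salt Total salt volume fraction (held equal in both phases).
#' @param T Temperature in kelvin.
#' @param chi Interaction parameter.
#' @param params An [fhvo_params()].
#' @param fe Optional precomputed reduced free energy (overrides the
#'   previous three arguments).
#' @param tol Residual tolerance of the Newton iteration.
#' @return A `binodal_pair`: list with `phi1 < phi2`, `phi_salt`, `T`,
#'   `chi`, `slope` (common tangent slope), `method` (`"newton"` or
#'   `"hull"`), `degenerate` (critical-point collapse); or `NULL`.
#' @export
#' @examples
#' # neutral polymer-solvent Flory-Huggins, N = 100
#' fe <- coacervate:::fhvo_reduced(0, 300, chi = 0.7, alpha = 0,
#'                                 r = 1, N = 100, sigma = 0)
#' fhvo_bitangent(fe = fe)
fhvo_bitangent <- function(phi_salt = NULL, T = NULL, chi = NULL,
                           params = fhvo_params(), fe = NULL, tol = 1e-11) {
  if (is.null(fe)) fe <- fhvo_reduced(phi_salt, T, chi, params)
  sp <- fhvo_spinodal(fe)
  if (length(sp) < 2) return(NULL)
  sp <- range(sp)
  res <- .bitangent_newton(fe, sp, tol = tol)
  method <- "newton"
  if (is.null(res)) {
    hull <- .bitangent_envelope(fe, sp)
    if (is.null(hull)) return(NULL)
    # retry Newton from the envelope solution; keep envelope if it diverges
    res <- .bitangent_newton(fe, sp, seed = c(hull$phi1, hull$phi2),
                             tol = tol)
    if (is.null(res)) { res <- hull; method <- "hull" }
  }
  degen <- (res$phi2 - res$phi1) < 1e-7 * res$phi2
  structure(list(phi1 = res$phi1, phi2 = res$phi2,
                 phi_salt = fe$phi_salt, T = T, chi = fe$chi,
                 slope = fe$df(res$phi2), method = method,
                 degenerate = degen),
            class = "binodal_pair")
}

#' @export
print.binodal_pair <- function(x, ...) {
  cat(sprintf("binodal_pair: phi1 = %.6g, phi2 = %.6g (phi_salt = %.4g, chi = %.5g, %s%s)\n",
              x$phi1, x$phi2, x$phi_salt, x$chi, x$method,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

# Damped Newton on g(u) = (f'(phi1) - f'(phi2),
#                          [f - phi f'](phi1) - [f - phi f'](phi2))
# in u = (log phi1, log phi2).
.bitangent_newton <- function(fe, sp, seed = NULL, tol = 1e-11,
                              max_iter = 200) {
  if (is.null(seed)) seed <- c(0.9 * sp[1], min(1.1 * sp[2], fe$hi * (1 - 1e-6)))
  u <- log(seed)
  gfun <- function(u) {
    p <- exp(u)
    d <- fe$df(p)
    c(d[1] - d[2],
      (fe$f(p[1]) - p[1] * d[1]) - (fe$f(p[2]) - p[2] * d[2]))
  }
  g <- gfun(u)
  if (any(!is.finite(g))) return(NULL)
  for (it in seq_len(max_iter)) {
    p <- exp(u)
    c1 <- fe$d2f(p[1]); c2 <- fe$d2f(p[2])
    J <- matrix(c(p[1] * c1,        -p[2] * c2,
                  -p[1]^2 * c1,      p[2]^2 * c2),
                nrow = 2, byrow = TRUE)
    step <- tryCatch(solve(J, -g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    step <- pmax(pmin(step, 2), -2)   # trust region in log space
    lam <- 1
    ok <- FALSE
    for (k in 1:30) {
      u_new <- u + lam * step
      p_new <- exp(u_new)
      if (p_new[2] < fe$hi && p_new[1] < p_new[2]) {
        g_new <- gfun(u_new)
        if (all(is.finite(g_new)) && sum(g_new^2) <= sum(g^2) * (1 - 1e-4 * lam) + 1e-300) {
          u <- u_new; g <- g_new; ok <- TRUE; break
        }
      }
      lam <- lam / 2
    }
    if (!ok) return(NULL)
    if (max(abs(g)) < tol) break
    if (it == max_iter) return(NULL)
  }
  p <- exp(u)
  # the pair must bracket the unstable window (allow critical collapse)
  if (!(p[1] <= sp[1] * (1 + 1e-6) && p[2] >= sp[2] * (1 - 1e-6)))
    return(NULL)
  list(phi1 = p[1], phi2 = p[2])
}

# Independent common-tangent construction through the convex conjugate: for
# trial slope m the tangent touches where f - m phi is minimal on each side
# of the spinodal; the common tangent is the m at which the two minima are
# equal. Monotone in m, solved by uniroot; the per-side minimisations run in
# log phi to resolve the steep dilute branch.
.bitangent_envelope <- function(fe, sp, lo = NULL) {
  if (is.null(lo)) lo <- max(1e-14, sp[1] * 1e-10)
  hi <- fe$hi * (1 - 1e-9)
  side_min <- function(m, a, b) {
    o <- stats::optimize(function(u) fe$f(exp(u)) - m * exp(u),
                         interval = log(c(a, b)), tol = 1e-13)
    c(phi = exp(o$minimum), val = o$objective)
  }
  dfun <- function(m) {
    side_min(m, lo, sp[1])["val"] - side_min(m, sp[2], hi)["val"]
  }
  m_lo <- fe$df(sp[2]); m_hi <- fe$df(sp[1])
  if (!is.finite(m_lo) || !is.finite(m_hi) || m_lo >= m_hi) return(NULL)
  d_lo <- dfun(m_lo); d_hi <- dfun(m_hi)
  if (!is.finite(d_lo) || !is.finite(d_hi) || d_lo * d_hi > 0) return(NULL)
  m <- stats::uniroot(dfun, c(m_lo, m_hi), tol = 1e-14)$root
  list(phi1 = unname(side_min(m, lo, sp[1])["phi"]),
       phi2 = unname(side_min(m, sp[2], hi)["phi"]))
}

#' Convex-envelope binodal oracle
#'
#' Common-tangent pair computed without the Newton system: the tangent
#' slope is found as the value at which the two per-side minima of
#' `f - m phi` coincide (a Legendre-transform double-touch construction).
#' Used as the independent cross-check and fallback for
#' [fhvo_bitangent()].
#'
#' @inheritParams fhvo_bitangent
#' @return A list with `phi1`, `phi2`, or `NULL` if the free energy is
#'   convex.
#' @export
binodal_hull <- function(phi_salt = NULL, T = NULL, chi = NULL,
                         params = fhvo_params(), fe = NULL) {
  if (is.null(fe)) fe <- fhvo_reduced(phi_salt, T, chi, params)
  sp <- fhvo_spinodal(fe)
  if (length(sp) < 2) return(NULL)
  .bitangent_envelope(fe, range(sp))
}

#' chi(T) law
#'
#' Linear-in-1/T interaction parameter `chi(T) = A + B/T`: `A` is the
#' entropic coefficient (dimensionless) and `B` the enthalpic coefficient
#' (kelvin). `B < 0` gives LCST behaviour (chi grows on heating).
#'
#' @param A Entropic coefficient.
#' @param B Enthalpic coefficient (K).
#' @param r_squared Coefficient of determination of the generating
#'   regression, if any.
#' @return A `chi_law` object.
#' @export
chi_law <- function(A, B, r_squared = NA_real_) {
  structure(list(A = A, B = B, r_squared = r_squared), class = "chi_law")
}

#' @export
print.chi_law <- function(x, ...) {
  cat(sprintf("chi(T) = %.4g %+.4g/T", x$A, x$B))
  if (is.finite(x$r_squared)) cat(sprintf("  (R^2 = %.3f)", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Evaluate a chi(T) law
#'
#' @param law A [chi_law()].
#' @param T Temperature(s) in kelvin.
#' @return `chi` values.
#' @export
chi_at <- function(law, T) law$A + law$B / T

#' Fit chi at a single experimental condition
#'
#' Finds the scalar interaction parameter at which the dilute binodal branch
#' at the observed cloud point passes through the experimental composition:
#' a bracketed bisection on chi (the dilute-branch fraction is monotone
#' decreasing in chi), refined to `tol`.
#'
#' @param tau_uM Tau concentration in micromolar.
#' @param nacl_mM NaCl concentration in millimolar.
#' @param T_cp Cloud-point temperature in kelvin.
#' @param params An [fhvo_params()].
#' @param bracket Search bracket for chi.
#' @param tol Absolute tolerance on chi (default 1e-8).
#' @return The fitted chi (scalar), with the matched `binodal_pair` as
#'   attribute `"pair"`.
#' @export
fit_chi_point <- function(tau_uM, nacl_mM, T_cp, params = fhvo_params(),
                          bracket = c(0.05, 3), tol = 1e-8) {
  phi_target <- phi_polymer_from_tau(tau_uM, params)
  stopifnot(phi_target > 0)
  phi_salt <- (nacl_mM + params$buffer_mM) * 1e-3 / params$cw
  gap <- function(chi) {
    pair <- fhvo_bitangent(phi_salt, T_cp, chi, params)
    if (is.null(pair)) Inf else log(pair$phi1 / phi_target)
  }
  lo <- bracket[1]; hi <- bracket[2]
  g_lo <- gap(lo); g_hi <- gap(hi)
  if (!is.finite(g_hi) || g_hi > 0)
    stop(sprintf(
      "no chi in [%.3g, %.3g] brings the dilute branch down to phi = %.3g (gap at ends: %.3g, %.3g)",
      lo, hi, phi_target, g_lo, g_hi))
  if (g_lo < 0)
    stop(sprintf(
      "dilute branch already below phi = %.3g at chi = %.3g; widen the bracket downward",
      phi_target, lo))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (gap(mid) > 0) lo <- mid else hi <- mid
  }
  chi <- (lo + hi) / 2
  structure(chi, pair = fhvo_bitangent(phi_salt, T_cp, chi, params))
}

#' Regress a chi(T) law from per-condition chi values
#'
#' Least-squares regression of chi on 1/T, the final step of the lattice
#' fit: each cloud point contributes one `(T_cp, chi)` pair and the law
#' `chi(T) = A + B/T` summarises them.
#'
#' @param T_cp Cloud-point temperatures in kelvin (length >= 3).
#' @param chi Fitted chi values (same length).
#' @return A [chi_law()] with `r_squared` from the regression.
#' @export
fit_chi_law <- function(T_cp, chi) {
  stopifnot(length(T_cp) == length(chi))
  if (length(T_cp) < 3) stop("need at least 3 points to fit chi(T)")
  fit <- stats::lm(chi ~ I(1 / T_cp))
  cf <- stats::coef(fit)
  ssr <- sum(stats::resid(fit)^2)
  sst <- sum((chi - mean(chi))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  chi_law(A = unname(cf[1]), B = unname(cf[2]), r_squared = r2)
}

#' Cloud-point temperature predicted by the lattice model
#'
#' Solves for the temperature at which the dilute binodal branch passes
#' through the composition of the given condition, i.e. the model cloud
#' point: a bisection in T (monotone for an LCST-type law).
#'
#' @param tau_uM Tau concentration in micromolar.
#' @param nacl_mM NaCl concentration in millimolar.
#' @param law A [chi_law()] (LCST-type laws have `B < 0`).
#' @param params An [fhvo_params()].
#' @param T_range Search range in kelvin.
#' @param tol Absolute tolerance on T (K).
#' @return Cloud-point temperature in kelvin, or `NA` if the condition does
#'   not phase separate anywhere in `T_range`.
#' @export
fhvo_tcp <- function(tau_uM, nacl_mM, law, params = fhvo_params(),
                     T_range = c(274, 372), tol = 1e-4) {
  phi_target <- phi_polymer_from_tau(tau_uM, params)
  stopifnot(phi_target > 0)
  phi_salt <- (nacl_mM + params$buffer_mM) * 1e-3 / params$cw
  gap <- function(T) {
    pair <- fhvo_bitangent(phi_salt, T, chi_at(law, T), params)
    if (is.null(pair)) Inf else log(pair$phi1 / phi_target)
  }
  lo <- T_range[1]; hi <- T_range[2]
  if (gap(hi) > 0) return(NA_real_)  # single phase over the whole range
  if (gap(lo) < 0) return(lo)        # already phase separated at range floor
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (gap(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Binodal curve in experimental units
#'
#' Maps the common-tangent construction back to measurable axes. For
#' `axis = "tau"` (resp. `"nacl"`) the cloud-point temperature is computed
#' for each grid value at the fixed other concentration; for `axis = "T"`
#' both branch compositions are reported over a temperature grid at fixed
#' salt. Salt is held equal in both phases throughout.
#'
#' @param law A [chi_law()].
#' @param axis One of `"tau"`, `"nacl"`, `"T"`.
#' @param values Grid of axis values (uM, mM or K respectively).
#' @param at Fixed value of the complementary condition (`nacl_mM` for
#'   `axis = "tau"`, `tau_uM` for `axis = "nacl"`, `c(tau_uM, nacl_mM)`
#'   for `axis = "T"`).
#' @param params An [fhvo_params()].
#' @param T_range Temperature search range (K).
#' @return Data frame with the axis values, `T_cp` (K) and, where computed,
#'   the dilute/dense branch polymer fractions (`phi_dilute`, `phi_dense`)
#'   and their tau-concentration equivalents in uM.
#' @export
binodal_curve <- function(law, axis = c("tau", "nacl", "T"), values, at,
                          params = fhvo_params(), T_range = c(274, 372)) {
  axis <- match.arg(axis)
  if (axis %in% c("tau", "nacl")) {
    rows <- lapply(values, function(v) {
      tau <- if (axis == "tau") v else at
      nacl <- if (axis == "nacl") v else at
      tcp <- fhvo_tcp(tau, nacl, law, params, T_range)
      phi1 <- phi2 <- NA_real_
      if (is.finite(tcp)) {
        phi_salt <- (nacl + params$buffer_mM) * 1e-3 / params$cw
        pair <- fhvo_bitangent(phi_salt, tcp, chi_at(law, tcp), params)
        if (!is.null(pair)) { phi1 <- pair$phi1; phi2 <- pair$phi2 }
      }
      data.frame(tau_uM = tau, nacl_mM = nacl, T_cp = tcp,
                 phi_dilute = phi1, phi_dense = phi2,
                 tau_dense_uM = tau_from_phi_polymer(phi2, params))
    })
  } else {
    tau <- at[1]; nacl <- at[2]
    phi_salt <- (nacl + params$buffer_mM) * 1e-3 / params$cw
    rows <- lapply(values, function(T) {
      pair <- fhvo_bitangent(phi_salt, T, chi_at(law, T), params)
      data.frame(tau_uM = tau, nacl_mM = nacl, T_cp = T,
                 phi_dilute = if (is.null(pair)) NA_real_ else pair$phi1,
                 phi_dense = if (is.null(pair)) NA_real_ else pair$phi2,
                 tau_dense_uM = if (is.null(pair)) NA_real_ else
                   tau_from_phi_polymer(pair$phi2, params))
    })
  }
  do.call(rbind, rows)
}
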
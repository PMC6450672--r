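# Sequence-charged coarse-grained polyelectrolyte model in its
# field-theoretic representation. All quantities are dimensionless: lengths
# in units of R0 = b/sqrt(6) (the prefactor of the ideal-chain radius of
# gyration, Rg = R0 N^(1/2)), so the Gaussian bond kernel is exp(-k^2) and
# the segment-smearing kernel exp(-k^2/2) in k-space. The thermodynamic
# state is set by B = v/R0^3 (excluded volume), E = 4 pi l_B/R0
# (electrostatic strength) and C = rho R0^3 (monomer number density).

#' Map temperature to the dimensionless electrostatic strength
#'
#' `E = 4 pi l_B / R0` with `R0 = b/sqrt(6)`.
#'
#' @param T Temperature in kelvin.
#' @param b Segment length in metres (default 4 Angstrom).
#' @param eps_r Relative dielectric constant (default 80).
#' @return Dimensionless `E`.
#' @export
#' @examples
#' fts_E_from_T(300)  # ~53.6 (l_B = 1.74 b)
fts_E_from_T <- function(T, b = 4e-10, eps_r = 80) {
  4 * pi * bjerrum_length(T, eps_r) * sqrt(6) / b
}

#' @rdname fts_E_from_T
#' @param lB_b Bjerrum length in units of `b`.
#' @return `fts_E_from_lB`: dimensionless `E`.
#' @export
fts_E_from_lB <- function(lB_b) 4 * pi * lB_b * sqrt(6)

#' Map excluded volume to the dimensionless B parameter
#'
#' `B = v / R0^3 = (v/b^3) 6^(3/2)`.
#'
#' @param v_b3 Excluded volume in units of `b^3`.
#' @return Dimensionless `B`.
#' @export
fts_B_from_v <- function(v_b3) v_b3 * 6^(3 / 2)

#' Map a monomer density in b^-3 units to the dimensionless C
#'
#' `C = rho R0^3 = (rho b^3) / 6^(3/2)`.
#'
#' @param rho_b3 Monomer number density in units of `1/b^3`.
#' @return Dimensionless `C`.
#' @export
fts_C_from_rho <- function(rho_b3) rho_b3 / 6^(3 / 2)

#' Convert a salt molarity to a dimensionless ion density
#'
#' @param mM Concentration in millimolar.
#' @param b Segment length in metres.
#' @return Number density per `R0^3`.
#' @export
#' @examples
#' fts_salt_density(120)  # ~3.1e-4 per ion species
fts_salt_density <- function(mM, b = 4e-10) {
  R0 <- b / sqrt(6)
  mM * 1e-3 * .const$NAv * 1e3 * R0^3
}

#' Build a field-theoretic simulation model
#'
#' Assembles the dimensionless state for a mixture of charged bead-spring
#' chains plus optional monovalent point ions on a periodic cubic mesh.
#' With two oppositely charged chain types the chain fractions are set by
#' global charge neutrality (the 1:1 charge-ratio rule): for a polycation of
#' net charge `+q` and an equal-length fully charged polyanion this gives
#' `phi_cation = N/(N+q)`. Any residual chain charge is neutralised by
#' adjusting the counter-ion density on top of the added salt; ions carry
#' the same Gaussian smearing and excluded volume as monomers.
#'
#' @param chains List of `charged_sequence` objects (see [assign_charges()]).
#' @param B Dimensionless excluded volume `v/R0^3` (> 0).
#' @param E Dimensionless electrostatic strength `4 pi l_B/R0` (>= 0).
#' @param C Dimensionless total monomer density `rho R0^3`.
#' @param salt_mM Added salt in mM (converted per [fts_salt_density()]).
#' @param L Box edge in units of R0 (default 34).
#' @param M Mesh points per edge (default 32).
#' @param dt Complex-Langevin time step (default 0.01).
#' @param lambda_w,lambda_phi Relaxation coefficients of the two fields.
#' @param b Segment length in metres (only used for unit conversions).
#' @param phi_chains Optional explicit chain monomer fractions (must sum to
#'   1); default: charge-neutrality rule.
#' @return An `fts_model` object.
#' @export
#' @examples
#' tau <- assign_charges(paste(rep("GK", 10), collapse = ""))  # +10 20-mer
#' rna <- make_polyU(20)
#' m <- fts_model(list(tau, rna), B = 0.1, E = 10, C = 0.1, M = 8, L = 10)
#' m$phi_chains  # 2/3, 1/3 by charge matching
fts_model <- function(chains, B, E, C, salt_mM = 0, L = 34, M = 32,
                      dt = 0.01, lambda_w = 1, lambda_phi = 1,
                      b = 4e-10, phi_chains = NULL) {
  stopifnot(B > 0, E >= 0, C > 0, L > 0, M >= 4, dt > 0, salt_mM >= 0)
  if (inherits(chains, "charged_sequence")) chains <- list(chains)
  stopifnot(length(chains) >= 1,
            all(vapply(chains, inherits, logical(1), "charged_sequence")))
  q <- vapply(chains, `[[`, numeric(1), "q_net")
  N <- vapply(chains, `[[`, numeric(1), "N")
  if (is.null(phi_chains)) {
    if (length(chains) == 1) {
      phi_chains <- 1
    } else if (length(chains) == 2 && q[1] * q[2] < 0) {
      # n1 q1 + n2 q2 = 0 -> monomer fractions by charge matching
      n_rel <- c(1, -q[1] / q[2])
      phi_chains <- n_rel * N / sum(n_rel * N)
    } else {
      stop("chain fractions cannot be set by charge neutrality; ",
           "pass phi_chains explicitly")
    }
  }
  stopifnot(length(phi_chains) == length(chains),
            abs(sum(phi_chains) - 1) < 1e-12, all(phi_chains >= 0))
  V <- L^3
  n_chains <- C * phi_chains * V / N        # chains of each type in the box
  chain_charge <- sum(n_chains * q) / V     # residual charge density
  salt <- fts_salt_density(salt_mM, b)
  rho_plus <- salt + max(-chain_charge, 0)
  rho_minus <- salt + max(chain_charge, 0)
  net <- sum(n_chains * q) / V + rho_plus - rho_minus
  if (abs(net) > 1e-10 * max(C, 1))
    stop("irreconcilable charge imbalance in the model")
  # mesh geometry and spectral kernels
  kv <- 2 * pi / L * c(0:(M / 2), -(M / 2 - 1):-1)[1:M]
  k2 <- outer(outer(kv^2, kv^2, `+`), kv^2, `+`)
  structure(list(
    chains = chains, N = N, q = q, phi_chains = phi_chains,
    B = B, E = E, C = C, L = L, M = M, V = V, dV = V / M^3,
    dt = dt, lambda_w = lambda_w, lambda_phi = lambda_phi,
    n_chains = n_chains, rho_plus = rho_plus, rho_minus = rho_minus,
    salt_mM = salt_mM, b = b,
    k2 = k2, Gamma_k = exp(-k2 / 2), Phi_k = exp(-k2),
    has_phi = E > 0 && (any(vapply(chains, function(ch) any(ch$z != 0),
                                   logical(1))) ||
                          rho_plus > 0 || rho_minus > 0)),
    class = "fts_model")
}

#' @export
print.fts_model <- function(x, ...) {
  cat(sprintf("fts_model: B = %g, E = %g, C = %g, box %g R0, mesh %d^3, dt = %g\n",
              x$B, x$E, x$C, x$L, x$M, x$dt))
  for (i in seq_along(x$chains))
    cat(sprintf("  chain %d: N = %d, q = %+d, phi = %.4f, n = %.3f\n",
                i, x$N[i], x$q[i], x$phi_chains[i], x$n_chains[i]))
  if (x$rho_plus > 0 || x$rho_minus > 0)
    cat(sprintf("  ions: rho+ = %.4g, rho- = %.4g (per R0^3)\n",
                x$rho_plus, x$rho_minus))
  invisible(x)
}

# --- spectral helpers -------------------------------------------------------

.fft3 <- function(a) stats::fft(a)
.ifft3 <- function(a) stats::fft(a, inverse = TRUE) / length(a)

# A_{-k} from A_k for R's FFT frequency layout
.revk <- function(a) {
  M <- dim(a)[1]
  idx <- c(1L, M:2L)
  a[idx, idx, idx]
}

# mean over the box of the (analytic) product of two fields given their FFTs
.kmean_prod <- function(Fa, Fb_rev, weight = 1) {
  sum(weight * Fa * Fb_rev) / length(Fa)^2
}

#' Gaussian segment smearing
#'
#' Convolves a mesh field with the unit-normalised Gaussian segment profile
#' (spectral form `exp(-k^2 b^2 / 12)`, i.e. `exp(-k^2/2)` in R0 units),
#' conserving the spatial mean. Applying it twice equals one smear with a
#' `sqrt(2)`-wider kernel.
#'
#' @param field Complex or numeric array of dimension `c(M, M, M)`.
#' @param model An [fts_model()].
#' @return The smeared field (complex array).
#' @export
fts_smear <- function(field, model) {
  .ifft3(model$Gamma_k * .fft3(field))
}

#' One Gaussian-bond transfer step
#'
#' Applies the bond transition kernel `(3/(2 pi b^2))^(3/2)
#' exp(-3|r-r'|^2/(2 b^2))` (spectral form `exp(-k^2)` in R0 units) to a
#' chain propagator slice.
#'
#' @inheritParams fts_smear
#' @return The propagated field.
#' @export
fts_bond_step <- function(field, model) {
  .ifft3(model$Phi_k * .fft3(field))
}

#' Gaussian-chain propagators in per-monomer potential fields
#'
#' Iterates the Chapman-Kolmogorov transfer step
#' `q(r, j+1) = exp(-psi_{j+1}(r)) [Phi * q(., j)](r)` with
#' `q(r, 0) = exp(-psi_0(r))`, plus the complementary propagator from the
#' far end, and returns the single-chain partition function
#' `Q = (1/V) int q(r, N-1) dr`. Zero fields give `Q = 1` exactly; a
#' spatially uniform potential `c` gives `Q = exp(-N c)`.
#'
#' @param psi List of `N` complex mesh arrays: the per-monomer potentials
#'   `psi_j = i Gamma*w + i z_j Gamma*phi` (assembled by the caller or by
#'   [fts_chain_psi()]).
#' @param model An [fts_model()].
#' @param forward_only Skip the complementary propagator (saves half the
#'   work when only `Q` is needed).
#' @return List with `q` (forward slices), `qdag` (complementary slices,
#'   unless `forward_only`), `Fq`, `Fqdag` (their FFTs, for operator
#'   evaluation) and `Q` (complex scalar).
#' @export
propagate_chain <- function(psi, model, forward_only = FALSE) {
  N <- length(psi)
  stopifnot(N >= 1)
  eneg <- lapply(psi, function(p) exp(-p))
  q <- vector("list", N); Fq <- vector("list", N)
  q[[1]] <- eneg[[1]]
  for (j in seq_len(N - 1)) {
    Fq[[j]] <- .fft3(q[[j]])
    q[[j + 1]] <- eneg[[j + 1]] * .ifft3(model$Phi_k * Fq[[j]])
  }
  Q <- mean(q[[N]])
  if (!all(is.finite(Re(Q)) & is.finite(Im(Q))) ||
      !all(vapply(q, function(a) all(is.finite(Mod(a))), logical(1))))
    stop("non-finite chain propagator (complex-Langevin divergence)")
  if (forward_only)
    return(list(q = q, Fq = Fq, Q = Q))
  qdag <- vector("list", N); Fqdag <- vector("list", N)
  qdag[[N]] <- eneg[[N]]
  if (N > 1) for (j in (N - 1):1) {
    Fqdag[[j + 1]] <- .fft3(qdag[[j + 1]])
    qdag[[j]] <- eneg[[j]] * .ifft3(model$Phi_k * Fqdag[[j + 1]])
  }
  list(q = q, qdag = qdag, Fq = Fq, Fqdag = Fqdag, Q = Q)
}

#' Assemble per-monomer potentials for a charged chain
#'
#' `psi_j = i (Gamma*w) + i z_j (Gamma*phi)`: every monomer sees the smeared
#' excluded-volume field, and charged monomers additionally couple to the
#' smeared electrostatic field with their integer charge.
#'
#' @param w_s Smeared excluded-volume field (`Gamma*w`).
#' @param phi_s Smeared electrostatic field (`Gamma*phi`), or `NULL`.
#' @param z Integer charge vector along the chain.
#' @return List of per-monomer complex potential fields.
#' @export
fts_chain_psi <- function(w_s, phi_s, z) {
  lapply(z, function(zj) {
    if (is.null(phi_s) || zj == 0) 1i * w_s else 1i * (w_s + zj * phi_s)
  })
}

#' Initialise the auxiliary fields
#'
#' `init = "saddle"` starts from the homogeneous mean-field saddle point
#' (`w = -i B (C + ions)`, `phi = 0`), the stationary point of the
#' noise-free dynamics; `init = "zero"` starts from zero fields.
#'
#' @param model An [fts_model()].
#' @param init `"saddle"` or `"zero"`.
#' @return A `field_state`: list with complex arrays `w` and (if the model
#'   has charges) `phi`.
#' @export
field_state <- function(model, init = c("saddle", "zero")) {
  init <- match.arg(init)
  M <- model$M
  zero <- array(0i, dim = c(M, M, M))
  w <- zero
  if (init == "saddle") {
    rho_tot <- model$C + model$rho_plus + model$rho_minus
    w <- zero - 1i * model$B * rho_tot
  }
  structure(list(w = w, phi = if (model$has_phi) zero else NULL),
            class = "field_state")
}

# --- single-configuration evaluation ---------------------------------------

# Propagation plus density accumulation for one chain type, with the
# per-monomer Boltzmann factors cached per distinct charge value and the
# monomer densities assembled from stored propagator intermediates
# (q_j qdag_j e^{psi_j} = [Phi*q_{j-1}] qdag_j), avoiding per-monomer
# exponentials.
.chain_eval <- function(w_s, phi_s, z, model, want_bond = FALSE) {
  N <- length(z)
  zu <- sort(unique(z))
  eneg_u <- lapply(zu, function(zv) {
    p <- if (is.null(phi_s) || zv == 0) 1i * w_s else 1i * (w_s + zv * phi_s)
    exp(-p)
  })
  ui <- match(z, zu)
  q <- vector("list", N); qdag <- vector("list", N)
  tq <- vector("list", N)
  Fq <- if (want_bond) vector("list", N) else NULL
  Fqdag <- if (want_bond) vector("list", N) else NULL
  q[[1]] <- eneg_u[[ui[1]]]
  if (N > 1) for (j in 2:N) {
    f <- .fft3(q[[j - 1]])
    if (want_bond) Fq[[j - 1]] <- f
    tq[[j]] <- .ifft3(model$Phi_k * f)
    q[[j]] <- eneg_u[[ui[j]]] * tq[[j]]
  }
  qdag[[N]] <- eneg_u[[ui[N]]]
  if (N > 1) for (j in (N - 1):1) {
    f <- .fft3(qdag[[j + 1]])
    if (want_bond) Fqdag[[j + 1]] <- f
    qdag[[j]] <- eneg_u[[ui[j]]] * .ifft3(model$Phi_k * f)
  }
  Q <- mean(q[[N]])
  if (!is.finite(Re(Q)) || !is.finite(Im(Q)))
    stop("non-finite chain propagator (complex-Langevin divergence)")
  # per-monomer densities without exponentials
  rho <- if (N == 1) qdag[[1]] else qdag[[1]] + q[[N]]
  rho_c <- NULL
  if (!is.null(phi_s)) {
    rho_c <- z[1] * qdag[[1]]
    if (N > 1) rho_c <- rho_c + z[N] * q[[N]]
  }
  if (N > 2) for (j in 2:(N - 1)) {
    dj <- tq[[j]] * qdag[[j]]
    rho <- rho + dj
    if (!is.null(rho_c) && z[j] != 0) rho_c <- rho_c + z[j] * dj
  }
  bond <- 0 + 0i
  if (want_bond && N > 1) {
    Kb <- model$k2 * model$Phi_k
    for (j in seq_len(N - 1))
      bond <- bond + .kmean_prod(Fq[[j]], .revk(Fqdag[[j + 1]]), Kb)
  }
  list(Q = Q, rho = rho, rho_c = rho_c, bond = bond)
}

# Evaluates everything needed for one CL step and for the operators:
# propagators per chain type, densities, CL forces, H, Q_l, and (optionally)
# the osmotic pressure decomposition.
.fts_eval <- function(state, model, want_pressure = FALSE) {
  M <- model$M; V <- model$V
  w_s <- fts_smear(state$w, model)
  phi_s <- if (model$has_phi) fts_smear(state$phi, model) else NULL
  rho <- array(0i, dim = dim(state$w))   # total monomer+ion density
  rho_c <- if (model$has_phi) rho else NULL
  lnQ_sum <- 0 + 0i
  Q <- complex(length(model$chains))
  bond_sum <- 0 + 0i
  for (l in seq_along(model$chains)) {
    z <- model$chains[[l]]$z
    ce <- .chain_eval(w_s, phi_s, z, model, want_bond = want_pressure)
    Q[l] <- ce$Q
    lnQ_sum <- lnQ_sum + model$n_chains[l] * log(ce$Q)
    pref <- model$n_chains[l] / (V * ce$Q)
    rho <- rho + pref * ce$rho
    if (!is.null(rho_c)) rho_c <- rho_c + pref * ce$rho_c
    if (want_pressure)
      bond_sum <- bond_sum + (2 / 3) * model$n_chains[l] * ce$bond / ce$Q / V
  }
  Qion <- c(NA_complex_, NA_complex_)
  for (s in 1:2) {
    rho_s <- c(model$rho_plus, model$rho_minus)[s]
    if (rho_s <= 0) next
    zs <- c(1, -1)[s]
    psi_s <- if (is.null(phi_s)) 1i * w_s else 1i * (w_s + zs * phi_s)
    bolt <- exp(-psi_s)
    Qs <- mean(bolt)
    Qion[s] <- Qs
    lnQ_sum <- lnQ_sum + rho_s * V * log(Qs)
    d <- (rho_s / Qs) * bolt
    rho <- rho + d
    if (!is.null(rho_c)) rho_c <- rho_c + zs * d
  }
  # quadratic field terms
  Fw <- .fft3(state$w)
  w2_mean <- .kmean_prod(Fw, .revk(Fw))
  H <- V * w2_mean / (2 * model$B) - lnQ_sum
  gradphi2_mean <- 0 + 0i
  Fphi <- NULL
  if (model$has_phi) {
    Fphi <- .fft3(state$phi)
    gradphi2_mean <- .kmean_prod(Fphi, .revk(Fphi), model$k2)
    H <- H + V * gradphi2_mean / (2 * model$E)
  }
  out <- list(
    w_s = w_s, phi_s = phi_s, rho = rho, rho_c = rho_c,
    Q = Q, Qion = Qion, H = H, Fw = Fw, Fphi = Fphi,
    rho_mean = mean(rho),
    force_w = -model$lambda_w * 1i * fts_smear(rho, model),
    force_phi = if (model$has_phi)
      -model$lambda_phi * 1i * fts_smear(rho_c, model) else NULL)
  if (want_pressure) {
    ideal <- (sum(model$n_chains) / V + model$rho_plus + model$rho_minus)
    Pi_w <- -w2_mean / (2 * model$B)
    zp_w <- M^3 / (2 * V)
    Pi_phi <- 0 + 0i; zp_phi <- 0
    Pi_smear <- 0 + 0i
    KG <- model$k2 * model$Gamma_k
    sw <- .ifft3(KG * Fw)
    Pi_smear <- Pi_smear - mean(rho * (1i / 3) * sw)
    if (model$has_phi) {
      Pi_phi <- -gradphi2_mean / (6 * model$E)
      zp_phi <- (M^3 - 1) / (6 * V)
      sp <- .ifft3(KG * Fphi)
      Pi_smear <- Pi_smear - mean(rho_c * (1i / 3) * sp)
    }
    out$Pi_parts <- list(ideal = ideal, w = Pi_w, phi = Pi_phi,
                         bond = bond_sum, smear = Pi_smear,
                         zero_point = zp_w + zp_phi)
    out$Pi <- ideal + Pi_w + Pi_phi + bond_sum + Pi_smear + zp_w + zp_phi
  }
  out
}

#' Field-theoretic Hamiltonian
#'
#' `H = (1/2B) int w^2 + (1/2E) int (grad phi)^2 - sum_l n_l ln Q_l` (ions
#' enter as single-bead chains), evaluated for a field configuration. Zero
#' fields give `H = 0`; the electrostatic term is invariant under adding a
#' constant to `phi`.
#'
#' @param state A [field_state()].
#' @param model An [fts_model()].
#' @return Complex scalar `H`.
#' @export
fts_hamiltonian <- function(state, model) {
  .fts_eval(state, model)$H
}

#' Chemical potential operator
#'
#' `mu_l = ln(C phi_l / N_l) - ln Q_l`: the ideal translational part (the
#' log of the chain number density) plus the single-chain partition-function
#' correction. For non-interacting single beads (`Q = 1`) this reduces to
#' the ideal-gas chemical potential exactly.
#'
#' @param Q Sampled single-chain partition function (complex).
#' @param C Total monomer density.
#' @param phi_l Chain monomer fraction.
#' @param N_l Chain length.
#' @return Complex chemical potential.
#' @export
chemical_potential_op <- function(Q, C, phi_l, N_l) {
  log(C * phi_l / N_l) - log(Q)
}

#' Osmotic pressure operator
#'
#' Dimensionless osmotic pressure assembled from the dilation covariance of
#' the regularized field theory: the ideal (chain + ion translational) part,
#' the excluded-volume field term `-(1/2BV) int w^2`, the electrostatic
#' field term `-(1/6EV) int (grad phi)^2`, the bond-stretch term and the
#' smearing-scale term, plus the Gaussian zero-point constants of the two
#' field sectors (`M^3/2V` and `(M^3-1)/6V`) which make the thermal
#' ensemble average regular. In the non-interacting limit the average is the
#' ideal-gas law `Pi = C/N`; at the homogeneous mean-field saddle (without
#' the zero-point constants, which the missing fluctuations would cancel)
#' it is `C/N + B C^2/2`.
#'
#' @param state A [field_state()].
#' @param model An [fts_model()].
#' @param include_zero_point Include the Gaussian zero-point constants
#'   (default TRUE; set FALSE when evaluating deterministic saddle-point
#'   configurations).
#' @return Complex pressure, with the decomposition in attribute `"parts"`.
#' @export
pressure_op <- function(state, model, include_zero_point = TRUE) {
  ev <- .fts_eval(state, model, want_pressure = TRUE)
  p <- ev$Pi
  if (!include_zero_point) p <- p - ev$Pi_parts$zero_point
  attr(p, "parts") <- ev$Pi_parts
  p
}
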
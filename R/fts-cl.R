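# Complex-Langevin sampling of the field theory: exponential
# time-differencing (ETD) updates of both auxiliary fields with real
# Gaussian noise, trajectory bookkeeping with automatic equilibration
# cutoff and block-averaged errors, and phase-coexistence determination
# from the intersection of the dilute and concentrated branches in the
# pressure-chemical potential plane.

# One ETD advance given a precomputed configuration evaluation. The linear
# (Gaussian) part of each field equation is integrated exactly, including
# the noise: the per-step noise variance is the exact Ornstein-Uhlenbeck
# value (2 lambda dt / dV) (1 - e^(-2 c dt)) / (2 c dt), which removes the
# time-step bias of the Gaussian field variance.
.cl_advance <- function(state, model, ev, noise = TRUE) {
  dt <- model$dt
  # w sector: linear coefficient lambda_w/B is mode-independent
  cw <- model$lambda_w / model$B
  decay <- exp(-cw * dt)
  w <- decay * state$w + ((1 - decay) / cw) * ev$force_w
  if (noise) {
    sd <- sqrt(2 * model$lambda_w * dt / model$dV) *
      sqrt((1 - decay^2) / (2 * cw * dt))
    w <- w + array(stats::rnorm(length(w), sd = sd), dim = dim(w))
  }
  phi <- state$phi
  if (model$has_phi) {
    ck <- model$lambda_phi * model$k2 / model$E
    decay_k <- exp(-ck * dt)
    fac <- ifelse(ck > 0, (1 - decay_k) / ck, dt)
    Fphi <- ev$Fphi
    Fforce <- .fft3(ev$force_phi)
    Fnew <- decay_k * Fphi + fac * Fforce
    if (noise) {
      eta <- array(stats::rnorm(length(phi),
                                sd = sqrt(2 * model$lambda_phi * dt / model$dV)),
                   dim = dim(phi))
      # per-mode exact OU amplitude (c_k depends on |k| only, so the
      # scaled noise stays a real field)
      scale_k <- sqrt(ifelse(ck > 0, (1 - decay_k^2) / (2 * ck * dt), 1))
      Fnew <- Fnew + scale_k * .fft3(eta)
    }
    Fnew[1, 1, 1] <- 0 # gauge: pin the mean of phi
    phi <- .ifft3(Fnew)
  }
  structure(list(w = w, phi = phi), class = "field_state")
}

#' One complex-Langevin step
#'
#' Advances both auxiliary fields by one exponential-time-difference update
#' with (optional) real Gaussian noise of variance `2 lambda dt / dV` per
#' mesh site. With noise off, the homogeneous saddle point is a fixed point
#' of the dynamics.
#'
#' @param state A [field_state()].
#' @param model An [fts_model()].
#' @param noise Add the stochastic term (default TRUE).
#' @return The advanced `field_state`.
#' @export
cl_step <- function(state, model, noise = TRUE) {
  ev <- .fts_eval(state, model)
  .cl_advance(state, model, ev, noise = noise)
}

# marginal-standard-error equilibration cutoff: discard the prefix that
# minimises the standard error of the remaining mean, at least min_frac.
.equilibration_cutoff <- function(x, min_frac = 0.2) {
  n <- length(x)
  if (n < 10) return(0L)
  cand <- unique(floor(seq(0, 0.8 * n, length.out = 33)))
  sem2 <- vapply(cand, function(d) stats::var(x[(d + 1):n]) / (n - d),
                 numeric(1))
  d <- cand[which.min(sem2)]
  max(d, floor(min_frac * n))
}

.block_stats <- function(x, nblocks = 10) {
  n <- length(x)
  if (n < nblocks) return(c(mean = mean(x), se = NA_real_))
  idx <- cut(seq_len(n), nblocks, labels = FALSE)
  bm <- tapply(x, idx, mean)
  c(mean = mean(x), se = stats::sd(bm) / sqrt(nblocks))
}

#' Run a complex-Langevin trajectory
#'
#' Iterates [cl_step()] for `steps` steps from the homogeneous saddle
#' point, recording the Hamiltonian, single-chain partition functions,
#' chemical potentials, mean density and (every `pressure_every` samples)
#' the osmotic pressure. Equilibration is cut automatically by a marginal
#' standard-error rule (at least 20% of the trajectory is discarded) and
#' means carry block-averaged standard errors (10 blocks). Fixing `seed`
#' makes the trajectory bitwise reproducible.
#'
#' @param model An [fts_model()].
#' @param steps Number of CL steps.
#' @param seed Integer seed for the noise stream.
#' @param init Initial condition, see [field_state()].
#' @param noise Stochastic term on/off (off gives the mean-field
#'   relaxation).
#' @param sample_every Record observables every this many steps.
#' @param pressure_every Evaluate the pressure operator every this many
#'   recorded samples (it is the most expensive operator).
#' @param state Optional explicit initial `field_state`.
#' @return A `cl_trajectory`: list with `samples` (data frame of complex
#'   observables), `summary` (post-equilibration block means/errors),
#'   `equilibration` (discarded samples), `diverged_at` (step index, or NA)
#'   and the final `state`.
#' @export
run_cl <- function(model, steps, seed = NULL, init = "saddle", noise = TRUE,
                   sample_every = 1, pressure_every = 1, state = NULL) {
  stopifnot(steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) state <- field_state(model, init = init)
  nu <- model$n_chains / model$n_chains[1]
  rec <- list(); diverged_at <- NA_integer_
  for (i in seq_len(steps)) {
    want_p <- (i %% (sample_every * pressure_every)) == 0
    ev <- tryCatch(.fts_eval(state, model, want_pressure = want_p),
                   error = function(e) e)
    if (inherits(ev, "error")) { diverged_at <- i; break }
    if (i %% sample_every == 0) {
      mu <- chemical_potential_op(ev$Q, model$C, model$phi_chains, model$N)
      dens <- Re(fts_smear(ev$rho, model))
      qs <- stats::quantile(dens, c(0.1, 0.9))
      rec[[length(rec) + 1]] <- data.frame(
        step = i, H = ev$H, rho_mean = ev$rho_mean,
        mu_total = sum(nu * mu),
        t(stats::setNames(mu, paste0("mu_", seq_along(mu)))),
        t(stats::setNames(ev$Q, paste0("Q_", seq_along(ev$Q)))),
        Pi = if (want_p) ev$Pi else NA_complex_,
        contrast_cv = stats::sd(dens) / mean(dens),
        decile_ratio = unname(qs[2] / max(qs[1], 1e-12)))
    }
    state <- .cl_advance(state, model, ev, noise = noise)
    if (!all(is.finite(Mod(state$w)))) { diverged_at <- i; break }
  }
  samples <- do.call(rbind, rec)
  cut <- 0L; summ <- NULL
  if (!is.null(samples) && nrow(samples) >= 10) {
    cut <- .equilibration_cutoff(Re(samples$H))
    post <- samples[(cut + 1):nrow(samples), ]
    stat_of <- function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(c(mean = NA_real_, se = NA_real_,
                               im = NA_real_, im_se = NA_real_))
      re <- .block_stats(Re(x)); im <- .block_stats(Im(x))
      c(mean = unname(re["mean"]), se = unname(re["se"]),
        im = unname(im["mean"]), im_se = unname(im["se"]))
    }
    keys <- c("H", "rho_mean", "mu_total", "Pi",
              grep("^mu_[0-9]+$", names(samples), value = TRUE))
    summ <- do.call(rbind, lapply(keys, function(k) stat_of(post[[k]])))
    rownames(summ) <- keys
  }
  structure(list(samples = samples, summary = summ, equilibration = cut,
                 diverged_at = diverged_at, state = state, model = model),
            class = "cl_trajectory")
}

#' @export
print.cl_trajectory <- function(x, ...) {
  n <- if (is.null(x$samples)) 0 else nrow(x$samples)
  cat(sprintf("cl_trajectory: %d samples (%d discarded as equilibration)%s\n",
              n, x$equilibration,
              if (is.finite(x$diverged_at))
                sprintf(", DIVERGED at step %d", x$diverged_at) else ""))
  if (!is.null(x$summary)) {
    cat("  post-equilibration means +/- block SE (real part; imaginary):\n")
    s <- x$summary
    for (k in rownames(s))
      cat(sprintf("  %-9s %12.6g +/- %-10.3g (im %10.3g)\n",
                  k, s[k, "mean"], s[k, "se"], s[k, "im"]))
  }
  invisible(x)
}

#' Sweep the monomer density and collect branch data
#'
#' Runs one CL trajectory per density value (same thermodynamic parameters
#' otherwise) and tabulates the charge-neutral chemical potential
#' combination and the osmotic pressure with their block errors: the raw
#' material for [find_coexistence()].
#'
#' @param C_values Densities `rho R0^3` to simulate.
#' @param build Function `C -> fts_model` building the model at density C.
#' @param steps CL steps per density.
#' @param seed Base seed (density index is added to decorrelate runs).
#' @param ... Passed to [run_cl()].
#' @return Data frame with columns `C`, `mu`, `se_mu`, `Pi`, `se_Pi`,
#'   `im_mu`, `im_Pi`, `diverged`.
#' @export
fts_sweep <- function(C_values, build, steps, seed = 1, ...) {
  rows <- lapply(seq_along(C_values), function(i) {
    m <- build(C_values[i])
    tr <- run_cl(m, steps, seed = seed + i - 1, ...)
    s <- tr$summary
    data.frame(C = C_values[i],
               mu = if (is.null(s)) NA_real_ else s["mu_total", "mean"],
               se_mu = if (is.null(s)) NA_real_ else s["mu_total", "se"],
               Pi = if (is.null(s)) NA_real_ else s["Pi", "mean"],
               se_Pi = if (is.null(s)) NA_real_ else s["Pi", "se"],
               im_mu = if (is.null(s)) NA_real_ else s["mu_total", "im"],
               im_Pi = if (is.null(s)) NA_real_ else s["Pi", "im"],
               diverged = is.finite(tr$diverged_at))
  })
  do.call(rbind, rows)
}

#' Locate phase coexistence from branch data
#'
#' Classifies `(C, mu, Pi)` samples into dilute / unstable / concentrated
#' branches by the turning points of `mu(C)` and finds the crossing of the
#' two stable branches in the pressure-chemical potential plane: equal
#' chemical potential and equal osmotic pressure. Branch curves are
#' interpolated monotonically in `mu`; the crossing densities are read back
#' from each branch.
#'
#' @param samples Data frame with columns `C`, `mu`, `Pi` (numeric, real
#'   parts) and optionally `se_mu`, `se_Pi`.
#' @return A `coexistence_point`: list with the coexisting densities
#'   `rho_I < rho_II`, the common chemical potential `mu_star` and pressure
#'   `Pi_star`, and propagated uncertainties where errors were supplied;
#'   or `NULL` (with a message describing the gap) when the branches do
#'   not cross in the sampled window.
#' @export
find_coexistence <- function(samples) {
  s <- samples[order(samples$C), ]
  s <- s[is.finite(s$mu) & is.finite(s$Pi), ]
  n <- nrow(s)
  if (n < 6) stop("need at least 3 points per branch")
  dmu <- diff(s$mu)
  rising <- dmu > 0
  # contiguous rising runs = candidate stable branches
  r <- rle(rising)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  runs <- which(r$values)
  if (length(runs) < 2) {
    message("no coexistence: mu(C) is monotone (single branch)")
    return(NULL)
  }
  take <- function(k) seq(starts[k], ends[k] + 1) # diffs -> points
  dil <- s[take(runs[1]), ]
  con <- s[take(runs[length(runs)]), ]
  if (nrow(dil) < 3 || nrow(con) < 3)
    stop("need at least 3 points on each stable branch")
  lo <- max(min(dil$mu), min(con$mu))
  hi <- min(max(dil$mu), max(con$mu))
  if (lo >= hi) {
    message(sprintf(
      "no coexistence: branches do not overlap in mu (dilute up to %.4g, concentrated from %.4g)",
      max(dil$mu), min(con$mu)))
    return(NULL)
  }
  Pd <- stats::approxfun(dil$mu, dil$Pi); Pc <- stats::approxfun(con$mu, con$Pi)
  g <- function(mu) Pd(mu) - Pc(mu)
  if (g(lo) * g(hi) > 0) {
    message(sprintf(
      "no coexistence: pressure branches do not cross on the shared mu window [%.4g, %.4g]",
      lo, hi))
    return(NULL)
  }
  mu_star <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  Pi_star <- Pd(mu_star)
  rho_I <- stats::approx(dil$mu, dil$C, xout = mu_star)$y
  rho_II <- stats::approx(con$mu, con$C, xout = mu_star)$y
  se <- NA_real_
  if (all(c("se_mu", "se_Pi") %in% names(s))) {
    slope_d <- diff(range(dil$Pi)) / max(diff(range(dil$mu)), 1e-12)
    slope_c <- diff(range(con$Pi)) / max(diff(range(con$mu)), 1e-12)
    se <- sqrt(mean(s$se_Pi^2, na.rm = TRUE)) /
      max(abs(slope_c - slope_d), 1e-12)
  }
  structure(list(rho_I = rho_I, rho_II = rho_II,
                 mu_star = mu_star, Pi_star = Pi_star, se_mu_star = se,
                 dilute = dil, concentrated = con),
            class = "coexistence_point")
}

#' @export
print.coexistence_point <- function(x, ...) {
  cat(sprintf("coexistence_point: rho_I = %.5g, rho_II = %.5g (mu* = %.5g, Pi* = %.5g)\n",
              x$rho_I, x$rho_II, x$mu_star, x$Pi_star))
  invisible(x)
}

#' Spatial contrast of the polymer density field
#'
#' Summary statistic used to distinguish a homogeneous solution from a
#' phase-separated (droplet) configuration: the real smeared monomer
#' density is reduced to its spatial coefficient of variation and the
#' 90/10 inter-decile ratio, averaged over the recorded configurations.
#'
#' @param state A [field_state()].
#' @param model An [fts_model()].
#' @return Named vector with `cv` (sd/mean of the density field) and
#'   `decile_ratio`.
#' @export
density_contrast <- function(state, model) {
  ev <- .fts_eval(state, model)
  d <- Re(fts_smear(ev$rho, model))
  qs <- stats::quantile(d, c(0.1, 0.9))
  c(cv = stats::sd(d) / mean(d),
    decile_ratio = unname(qs[2] / max(qs[1], 1e-12)))
}
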
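# Synthetic-data generators emulating the measured inputs: noisy turbidity
# sigmoids (with optional per-cycle amplitude decay mimicking slow RNA
# degradation), cloud-point grids produced from a known chi(T) ground truth
# through the lattice-model forward solver, and random charged sequences
# for field-theory property tests. Everything is reproducible from a single
# integer seed.

#' Specification for the synthetic-data generators
#'
#' @param truth Ground truth: a [chi_law()] (for cloud-point grids) or a
#'   data frame with columns `T_cp` (K) and `k` (1/K) (for turbidity
#'   curves).
#' @param tau_uM Tau concentrations of the grid (default spans the
#'   experimental 2-240 uM range).
#' @param nacl_mM NaCl concentrations of the grid (default spans
#'   30-120 mM).
#' @param noise_sd Gaussian noise, on normalized turbidity (dimensionless)
#'   or on the cloud point (K), depending on the generator.
#' @param decay Per-cycle amplitude factor in (0, 1]; 1 means no decay.
#' @param seed Integer seed; regenerating with the same seed is bitwise
#'   identical.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(truth = chi_law(1.8, -390),
                           tau_uM = c(5, 20, 60, 150),
                           nacl_mM = c(30, 75, 120),
                           noise_sd = 0.5, decay = 1, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (decay <= 0 || decay > 1) stop("decay must be in (0, 1]")
  structure(list(truth = truth, tau_uM = tau_uM, nacl_mM = nacl_mM,
                 noise_sd = noise_sd, decay = decay, seed = seed),
            class = "synthetic_spec")
}

#' Generate noisy turbidity heating curves
#'
#' Heating-branch sigmoids `1/(1 + exp(-k (T - T_cp)))` with additive
#' Gaussian noise and an optional per-cycle amplitude decay (the raw maxima
#' shrink by `decay` each cycle while the transition temperature stays
#' put, as when the RNA slowly degrades). Per-curve normalization removes
#' the decay again, so the extracted cloud points are cycle-independent.
#'
#' @param spec A [synthetic_spec()] whose `truth` is a data frame with
#'   columns `T_cp` and `k`.
#' @param cycles Number of heating cycles per condition.
#' @param T Temperature grid in kelvin.
#' @return Named list of `turbidity_curve` objects
#'   (`<row>_cycle<cycle>`).
#' @export
gen_turbidity <- function(spec, cycles = 1,
                          T = seq(285, 301, by = 0.25)) {
  stopifnot(inherits(spec, "synthetic_spec"), is.data.frame(spec$truth),
            all(c("T_cp", "k") %in% names(spec$truth)))
  set.seed(spec$seed)
  out <- list()
  for (i in seq_len(nrow(spec$truth))) {
    tcp <- spec$truth$T_cp[i]; k <- spec$truth$k[i]
    for (cy in seq_len(cycles)) {
      amp <- spec$decay^(cy - 1)
      y <- amp / (1 + exp(-k * (T - tcp))) +
        stats::rnorm(length(T), sd = spec$noise_sd)
      out[[sprintf("curve%d_cycle%d", i, cy)]] <-
        turbidity_curve(T, y, branch = "heating")
    }
  }
  out
}

#' Generate a cloud-point grid from a chi(T) ground truth
#'
#' For every `([tau], [NaCl])` grid point the forward lattice model is
#' solved for the temperature at which the dilute binodal branch passes
#' through that composition, and Gaussian noise is added. Grid points that
#' do not phase separate anywhere in the searched temperature range are
#' reported with `T_cp = NA` (missing, never fabricated).
#'
#' @param spec A [synthetic_spec()] whose `truth` is an LCST-type
#'   [chi_law()] (`B < 0`).
#' @param params An [fhvo_params()].
#' @param T_range Temperature search range (K).
#' @return Data frame with columns `tau_uM`, `nacl_mM`, `T_cp` (K).
#' @export
#' @examples
#' \donttest{
#' g <- gen_cloudpoint_grid(synthetic_spec(noise_sd = 0, seed = 1))
#' }
gen_cloudpoint_grid <- function(spec, params = fhvo_params(),
                                T_range = c(274, 372)) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(spec$truth, "chi_law"))
  if (spec$truth$B >= 0)
    stop("truth must be an LCST-type chi law (B < 0)")
  set.seed(spec$seed)
  grid <- expand.grid(tau_uM = spec$tau_uM, nacl_mM = spec$nacl_mM,
                      KEEP.OUT.ATTRS = FALSE)
  t0 <- mapply(function(a, b) fhvo_tcp(a, b, spec$truth, params, T_range),
               grid$tau_uM, grid$nacl_mM)
  noise <- stats::rnorm(nrow(grid), sd = spec$noise_sd)
  grid$T_cp <- t0 + ifelse(is.na(t0), NA_real_, noise)
  grid
}

#' Read or write a cloud-point table
#'
#' CSV interchange format (`tau_uM`, `nacl_mM`, `T_cp`) shared by the
#' generator and the lattice-fit pipeline.
#'
#' @param table Data frame as produced by [gen_cloudpoint_grid()].
#' @param file Path.
#' @return The table (invisibly for the writer).
#' @export
write_cloudpoint_table <- function(table, file) {
  utils::write.csv(table, file, row.names = FALSE, quote = FALSE)
  invisible(table)
}

#' @rdname write_cloudpoint_table
#' @export
read_cloudpoint_table <- function(file) {
  d <- utils::read.csv(file)
  need <- c("tau_uM", "nacl_mM", "T_cp")
  if (!all(need %in% names(d)))
    stop("cloud-point table must have columns: ", paste(need, collapse = ", "))
  d
}

#' Fit the lattice model to a cloud-point table
#'
#' The full chi pipeline: per-condition chi from [fit_chi_point()] (rows
#' with missing cloud points are skipped), then the `chi(T) = A + B/T`
#' regression from [fit_chi_law()].
#'
#' @param table Data frame with `tau_uM`, `nacl_mM`, `T_cp`.
#' @param params An [fhvo_params()].
#' @return List with `points` (the table plus fitted `chi`) and `law`
#'   (the fitted [chi_law()]).
#' @export
fit_phase_diagram <- function(table, params = fhvo_params()) {
  ok <- is.finite(table$T_cp)
  pts <- table[ok, , drop = FALSE]
  pts$chi <- mapply(function(a, b, t)
    as.numeric(fit_chi_point(a, b, t, params)),
    pts$tau_uM, pts$nacl_mM, pts$T_cp)
  list(points = pts, law = fit_chi_law(pts$T_cp, pts$chi))
}

#' Generate random charged sequences
#'
#' Random sequences with an exact net charge and tunable charge
#' clustering. Lysines carry the positive charges, glutamates the negative
#' ones, glycines are neutral; the charged-residue count is a fixed
#' function of length and net charge, so composition depends only on those
#' two while `blockiness` redistributes the arrangement from fully random
#' (0) to fully clustered blocks (1).
#'
#' @param n_chains Number of sequences.
#' @param length Chain length.
#' @param net_charge Required net charge (`|net_charge| <= length`).
#' @param blockiness Charge clustering in `[0, 1]`.
#' @param seed Integer seed.
#' @return List of `charged_sequence` objects.
#' @export
#' @examples
#' gen_sequences(1, 20, -20, seed = 1)[[1]]$sigma  # fully charged chain
gen_sequences <- function(n_chains, length, net_charge, blockiness = 0,
                          seed = 1) {
  stopifnot(n_chains >= 1, length >= 1)
  if (abs(net_charge) > length)
    stop("infeasible: |net_charge| exceeds the chain length")
  if (blockiness < 0 || blockiness > 1) stop("blockiness must be in [0, 1]")
  set.seed(seed)
  # fixed composition rule: charged fraction ~40% beyond the net charge
  extra <- 2 * floor(0.2 * (length - abs(net_charge)))
  n_charged <- abs(net_charge) + extra
  n_plus <- (n_charged + net_charge) / 2
  n_minus <- n_charged - n_plus
  base <- c(rep("K", n_plus), rep("G", length - n_charged), rep("E", n_minus))
  lapply(seq_len(n_chains), function(i) {
    res <- base
    n_swaps <- round((1 - blockiness) * 3 * length)
    if (n_swaps > 0) for (s in seq_len(n_swaps)) {
      ij <- sample.int(length, 2)
      res[ij] <- res[rev(ij)]
    }
    assign_charges(paste(res, collapse = ""))
  })
}

#' Lag-1 charge autocorrelation of a sequence
#'
#' Simple blockiness diagnostic: the correlation between neighbouring
#' per-residue charges.
#'
#' @param seq A `charged_sequence`.
#' @return Correlation coefficient (NA for constant charge vectors).
#' @export
charge_autocorr <- function(seq) {
  z <- seq$z
  if (stats::sd(z) == 0) return(NA_real_)
  stats::cor(z[-length(z)], z[-1])
}
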
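# Cloud-point extraction from turbidity-temperature curves. The transition
# temperature T_cp is the half-maximum of a normalized turbidity sigmoid
# 1/(1 + exp(-k (T - T_cp))) fitted by unweighted least squares.

#' Construct a turbidity curve
#'
#' Container for an absorbance-at-500-nm vs temperature trace from one
#' heating or cooling ramp.
#'
#' @param T Temperature series in kelvin, strictly monotone within a branch.
#' @param A500 Absorbance series (dimensionless).
#' @param branch `"heating"` or `"cooling"`.
#' @param normalized Whether `A500` has already been min-max scaled to
#'   `[0, 1]`.
#' @return A `turbidity_curve` object.
#' @export
turbidity_curve <- function(T, A500, branch = c("heating", "cooling"),
                            normalized = FALSE) {
  branch <- match.arg(branch)
  stopifnot(length(T) == length(A500), !anyNA(T), !anyNA(A500))
  d <- diff(T)
  if (!(all(d > 0) || all(d < 0)))
    stop("temperature must be strictly monotone within a branch")
  if (normalized && (min(A500) < -1e-9 || max(A500) > 1 + 1e-9))
    stop("normalized curve must lie in [0, 1]")
  structure(list(T = as.numeric(T), A500 = as.numeric(A500),
                 branch = branch, normalized = normalized),
            class = "turbidity_curve")
}

#' @export
print.turbidity_curve <- function(x, ...) {
  cat(sprintf("turbidity_curve (%s%s): %d points, T %.2f..%.2f K, A500 %.3g..%.3g\n",
              x$branch, if (x$normalized) ", normalized" else "",
              length(x$T), min(x$T), max(x$T), min(x$A500), max(x$A500)))
  invisible(x)
}

#' Min-max normalize a turbidity curve
#'
#' Affine map of the absorbance to `[0, 1]`; temperatures are untouched.
#' Per-curve normalization removes any per-cycle amplitude decay (e.g. from
#' slow RNA degradation) by construction, so repeated ramps remain
#' comparable.
#'
#' @param curve A `turbidity_curve`.
#' @return The normalized `turbidity_curve`.
#' @export
normalize_turbidity <- function(curve) {
  stopifnot(inherits(curve, "turbidity_curve"))
  if (length(curve$A500) < 4) stop("need at least 4 points")
  rng <- range(curve$A500)
  if (diff(rng) <= 0 || diff(rng) < 1e-12 * max(abs(rng), 1))
    stop("constant signal: no transition to normalize")
  curve$A500 <- (curve$A500 - rng[1]) / diff(rng)
  curve$normalized <- TRUE
  curve
}

# linear-interpolation temperature at which the normalized signal first
# crosses `level`, used for initial guesses
.crossing_temperature <- function(T, y, level) {
  if (T[1] > T[length(T)]) { T <- rev(T); y <- rev(y) }
  above <- y >= level
  if (!any(above)) return(NA_real_)
  if (above[1]) return(T[1])
  i <- which(diff(above) == 1L)[1] # first upward crossing
  T[i] + (level - y[i]) * (T[i + 1] - T[i]) / (y[i + 1] - y[i])
}

#' Fit a sigmoid cloud point to a normalized turbidity curve
#'
#' Least-squares fit of `1/(1 + exp(-k (T - T_cp)))` to a normalized
#' heating-branch curve. `T_cp` is the temperature at which the fitted curve
#' crosses 0.5 (exactly, by the parameterization); `k` is the transition
#' steepness in 1/K. Initial guesses are the first 0.5-crossing by linear
#' interpolation for `T_cp` and `4/(T90 - T10)` for `k`. Cooling-branch
#' curves can be fitted but are labelled as such; transition temperatures
#' reported by the package come from heating ramps.
#'
#' @param curve A normalized `turbidity_curve` (see [normalize_turbidity()]).
#' @param k_flag_threshold Steepness (1/K) beyond which the transition is
#'   flagged as step-like (the `k -> Inf` limit of the sigmoid).
#' @return A `cloud_point_fit`: list with `T_cp` (K), `k` (1/K), `residual`
#'   (sum of squared residuals), `cov` (2x2 covariance of `(k, T_cp)`), `se`
#'   (standard errors), `branch`, and `flag` (`"ok"`, `"steep"` or
#'   `"inverted"`).
#' @export
#' @examples
#' T <- seq(288, 298, by = 0.25)
#' y <- 1 / (1 + exp(-2 * (T - 293.15)))
#' fit_cloud_point(turbidity_curve(T, y, normalized = TRUE))
fit_cloud_point <- function(curve, k_flag_threshold = 50) {
  stopifnot(inherits(curve, "turbidity_curve"))
  if (!curve$normalized)
    stop("curve must be normalized first (see normalize_turbidity)")
  T <- curve$T; y <- curve$A500
  t50 <- .crossing_temperature(T, y, 0.5)
  t10 <- .crossing_temperature(T, y, 0.1)
  t90 <- .crossing_temperature(T, y, 0.9)
  if (is.na(t50)) t50 <- stats::median(T)
  k0 <- if (!is.na(t10) && !is.na(t90) && t90 > t10) 4 / (t90 - t10) else
    10 / diff(range(T))
  dat <- data.frame(T = T, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + exp(-k * (T - Tcp))), data = dat,
                      start = list(k = k0, Tcp = t50),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop(sprintf(
      "sigmoid fit did not converge (initial guesses k = %.3g 1/K, T_cp = %.2f K): %s",
      k0, t50, conditionMessage(fit)))
  cf <- stats::coef(fit)
  k <- unname(cf["k"]); tcp <- unname(cf["Tcp"])
  vc <- tryCatch(stats::vcov(fit), error = function(e)
    matrix(NA_real_, 2, 2, dimnames = list(c("k", "Tcp"), c("k", "Tcp"))))
  flag <- if (k <= 0) "inverted" else if (k > k_flag_threshold) "steep" else "ok"
  structure(list(T_cp = tcp, k = k,
                 residual = sum(stats::resid(fit)^2),
                 cov = vc, se = sqrt(pmax(diag(vc), 0)),
                 branch = curve$branch, flag = flag, fit = fit),
            class = "cloud_point_fit")
}

#' @export
print.cloud_point_fit <- function(x, ...) {
  cat(sprintf("cloud_point_fit (%s): T_cp = %.3f K, k = %.3g 1/K [%s]\n",
              x$branch, x$T_cp, x$k, x$flag))
  if (all(is.finite(x$se)))
    cat(sprintf("  se(T_cp) = %.3g K, se(k) = %.3g 1/K, SSR = %.3g\n",
                x$se["Tcp"], x$se["k"], x$residual))
  invisible(x)
}

#' Evaluate a fitted cloud-point sigmoid
#'
#' @param fit A `cloud_point_fit`.
#' @param T Temperatures (K).
#' @return Fitted normalized turbidity.
#' @export
predict_cloud_point <- function(fit, T) {
  stopifnot(inherits(fit, "cloud_point_fit"))
  1 / (1 + exp(-fit$k * (T - fit$T_cp)))
}

#' Read turbidity curves from a delimited text file
#'
#' Expects columns `curve_id`, `T`, `A500`, `branch` (comma-separated by
#' default). Returns one `turbidity_curve` per `curve_id`.
#'
#' @param file Path to the delimited file.
#' @param sep Field separator.
#' @return Named list of `turbidity_curve` objects.
#' @export
read_turbidity <- function(file, sep = ",") {
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("curve_id", "T", "A500", "branch")
  if (!all(need %in% names(d)))
    stop("file must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(d, d$curve_id), function(g)
    turbidity_curve(g$T, g$A500, branch = g$branch[1]))
  out
}

#' Write turbidity curves to a delimited text file
#'
#' @param curves Named list of `turbidity_curve` objects.
#' @param file Output path.
#' @param sep Field separator.
#' @return The combined data frame, invisibly.
#' @export
write_turbidity <- function(curves, file, sep = ",") {
  ids <- names(curves)
  if (is.null(ids)) ids <- as.character(seq_along(curves))
  d <- do.call(rbind, lapply(seq_along(curves), function(i)
    data.frame(curve_id = ids[i], T = curves[[i]]$T,
               A500 = curves[[i]]$A500, branch = curves[[i]]$branch)))
  utils::write.table(d, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(d)
}

#' Fit cloud points for a set of turbidity curves
#'
#' Normalizes each curve and fits the sigmoid, returning a results table
#' (one row per curve) with the fitted cloud point, steepness and 95%
#' confidence half-widths.
#'
#' @param curves Named list of `turbidity_curve` objects.
#' @param heating_only Fit heating-branch curves only (default TRUE, the
#'   convention used for reported transition temperatures).
#' @return Data frame with columns `curve_id`, `T_cp`, `k`, `ci_T_cp`,
#'   `ci_k`, `flag`.
#' @export
fit_cloud_points <- function(curves, heating_only = TRUE) {
  ids <- names(curves)
  if (is.null(ids)) ids <- as.character(seq_along(curves))
  keep <- if (heating_only)
    vapply(curves, function(c) c$branch == "heating", logical(1))
  else rep(TRUE, length(curves))
  rows <- lapply(which(keep), function(i) {
    f <- fit_cloud_point(normalize_turbidity(curves[[i]]))
    data.frame(curve_id = ids[i], T_cp = f$T_cp, k = f$k,
               ci_T_cp = 1.96 * f$se["Tcp"], ci_k = 1.96 * f$se["k"],
               flag = f$flag, row.names = NULL)
  })
  do.call(rbind, rows)
}
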
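test_that("lattice compositions follow the charge-matched mixing rules", {
  p <- fhvo_params()
  s <- composition_from_conditions(50, 120)
  cw <- 55.56
  expect_equal(unname(s$phi["tau"]), 50e-6 * 207 / cw)   # 1.863e-4
  expect_equal(unname(s$phi["rna"]), 50e-6 * 11 / cw)    # 9.90e-6
  expect_equal(unname(s$phi["na"] + s$phi["cl"]), 0.140 / cw) # 2.520e-3
  expect_equal(sum(s$phi), 1)
  # buffer-only limit
  s0 <- composition_from_conditions(0, 0)
  expect_equal(unname(s0$phi["tau"] + s0$phi["rna"]), 0)
  expect_equal(unname(s0$phi["na"] + s0$phi["cl"]), 0.020 / cw)
  # closure holds across random conditions
  set.seed(2)
  for (i in 1:10) {
    sr <- composition_from_conditions(runif(1, 0, 240), runif(1, 0, 120))
    expect_lt(abs(sum(sr$phi) - 1), 1e-12)
  }
  expect_error(composition_from_conditions(3e6, 0), "unphysical")
})

test_that("lattice length and electrostatic strength match direct arithmetic", {
  expect_equal(lattice_length(), 3.103e-10, tolerance = 1e-3)
  co <- physical_constants()
  lB300 <- co$e^2 / (4 * pi * co$eps0 * 80 * co$kB * 300)
  a300 <- (2 / 3) * sqrt(pi) * (lB300 / lattice_length())^1.5
  expect_equal(electrostatic_strength(300), a300)       # ~3.97
  expect_equal(round(electrostatic_strength(300), 2), 3.97)
  expect_lt(electrostatic_strength(1e9), 1e-8)          # alpha -> 0 as T -> Inf
})

test_that("the free energy per site has the right limits and symmetries", {
  p <- fhvo_params()
  pure_w <- lattice_system(c(tau = 0, rna = 0, na = 0, cl = 0, water = 1),
                           T = 300, chi = 0)
  expect_equal(free_energy_per_site(pure_w), 0)
  # ideal two-species mixture (alpha irrelevant: no charges)
  sys <- lattice_system(c(tau = 0.2, rna = 0, na = 0, cl = 0, water = 0.8),
                        T = 300, chi = 0)
  hand <- 0.2 / 207 * log(0.2) + 0.8 * log(0.8) -
    sys$alpha * (0.2 * 11 / 207)^1.5
  expect_equal(free_energy_per_site(sys), hand)
  # swapping the two identical ion species leaves f unchanged
  a <- lattice_system(c(tau = 1e-4, rna = 1e-5, na = 2e-3, cl = 1e-3,
                        water = 1 - 1e-4 - 1e-5 - 3e-3), T = 300, chi = 0.5)
  b <- lattice_system(c(tau = 1e-4, rna = 1e-5, na = 1e-3, cl = 2e-3,
                        water = 1 - 1e-4 - 1e-5 - 3e-3), T = 300, chi = 0.5)
  expect_equal(free_energy_per_site(a), free_energy_per_site(b))
})

test_that("the reduced closure agrees with the five-species free energy", {
  p <- fhvo_params()
  phi_salt <- 2e-3; T <- 295; chi <- 0.48
  fe <- coacervate:::fhvo_reduced(phi_salt, T, chi, p)
  for (phi in c(1e-6, 1e-4, 0.05, 0.3)) {
    sys <- lattice_system(
      c(tau = phi * p$r_tau, rna = phi * p$r_rna,
        na = phi_salt / 2, cl = phi_salt / 2,
        water = 1 - phi - phi_salt), T = T, chi = chi)
    expect_equal(fe$f(phi), free_energy_per_site(sys), tolerance = 1e-12)
  }
  # analytic derivatives match numerical differentiation
  h <- 1e-7
  for (phi in c(1e-4, 0.05, 0.3)) {
    expect_equal(fe$df(phi), (fe$f(phi + h) - fe$f(phi - h)) / (2 * h),
                 tolerance = 1e-5)
    expect_equal(fe$d2f(phi), (fe$df(phi + h) - fe$df(phi - h)) / (2 * h),
                 tolerance = 1e-5)
  }
})

fh_neutral <- function(chi, N) {
  coacervate:::fhvo_reduced(0, 300, chi = chi, alpha = 0,
                            r = 1, N = N, sigma = 0)
}

test_that("the solver reproduces the closed-form Flory-Huggins critical point", {
  for (N in c(10, 100, 1000)) {
    cr <- fhvo_critical(fe = fh_neutral(0, N))
    expect_equal(cr$phi_c, 1 / (1 + sqrt(N)), tolerance = 1e-6)
    expect_equal(cr$chi_c, (1 + 1 / sqrt(N))^2 / 2, tolerance = 1e-8)
  }
})

test_that("subcritical chi gives no bitangent, supercritical matches the envelope", {
  expect_null(fhvo_bitangent(fe = fh_neutral(0.58, 100)))  # chi_c = 0.605
  pair <- fhvo_bitangent(fe = fh_neutral(0.7, 100))
  hull <- binodal_hull(fe = fh_neutral(0.7, 100))
  expect_lt(abs(pair$phi1 - hull$phi1), 1e-6)
  expect_lt(abs(pair$phi2 - hull$phi2), 1e-6)
  expect_identical(pair$method, "newton")
  # just above the critical point the pair collapses onto phi_c
  near <- fhvo_bitangent(fe = fh_neutral(0.60501, 100))
  expect_false(is.null(near))
  expect_lt(abs((near$phi1 + near$phi2) / 2 - 1 / 11), 2e-3)
})

test_that("Newton and the envelope oracle agree on randomized charged systems", {
  set.seed(5)
  n_ok <- 0
  for (i in 1:25) {
    chi <- runif(1, 0.45, 0.75)
    phi_salt <- runif(1, 1e-4, 5e-3)
    T <- runif(1, 278, 368)
    fe <- coacervate:::fhvo_reduced(phi_salt, T, chi)
    pn <- fhvo_bitangent(fe = fe)
    pe <- binodal_hull(fe = fe)
    expect_identical(is.null(pn), is.null(pe))
    if (is.null(pn)) next
    n_ok <- n_ok + 1
    expect_lt(abs(pn$phi1 - pe$phi1), 1e-6)
    expect_lt(abs(pn$phi2 - pe$phi2), 1e-6)
    # binodal pair brackets the spinodal
    sp <- coacervate:::fhvo_spinodal(fe)
    expect_lt(pn$phi1, min(sp) * (1 + 1e-9))
    expect_gt(pn$phi2, max(sp) * (1 - 1e-9))
  }
  expect_gte(n_ok, 20)
})

test_that("increasing chi widens the coexistence gap monotonically", {
  gaps <- vapply(seq(0.48, 0.60, 0.02), function(chi) {
    pair <- fhvo_bitangent(2e-3, 293, chi)
    pair$phi2 - pair$phi1
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("chi fitted from a forward-generated point recovers the truth", {
  p <- fhvo_params()
  chi_true <- 0.55; T <- 300; nacl <- 50
  phi_salt <- (nacl + 20) * 1e-3 / p$cw
  pair <- fhvo_bitangent(phi_salt, T, chi_true, p)
  tau_uM <- tau_from_phi_polymer(pair$phi1, p)
  chi_hat <- fit_chi_point(tau_uM, nacl, T, p)
  expect_lt(abs(as.numeric(chi_hat) - chi_true), 1e-6)
})

test_that("the two reference experimental conditions run end to end", {
  for (cond in list(c(50, 120), c(40, 30))) {
    chi <- fit_chi_point(cond[1], cond[2], 293.15)
    expect_gt(as.numeric(chi), 0.3)
    expect_lt(as.numeric(chi), 0.7)
    pair <- attr(chi, "pair")
    expect_lt(pair$phi1, pair$phi2)
  }
})

test_that("chi(T) regression is exact on noiseless data and rejects n < 3", {
  T <- seq(280, 320, 5)
  law <- fit_chi_law(T, 1.8 - 390 / T)
  expect_equal(law$A, 1.8, tolerance = 1e-9)
  expect_equal(law$B, -390, tolerance = 1e-6)
  expect_equal(law$r_squared, 1)
  flat <- fit_chi_law(T, rep(0.5, length(T)))
  expect_equal(flat$B, 0, tolerance = 1e-9)
  expect_error(fit_chi_law(c(290, 300), c(0.4, 0.5)), "at least 3")
})

test_that("points generated on the binodal curve refit to the generating law", {
  law <- chi_law(1.8, -390)
  curve <- binodal_curve(law, axis = "tau", values = c(10, 80), at = 60)
  expect_true(all(is.finite(curve$T_cp)))
  for (i in seq_len(nrow(curve))) {
    chi_hat <- fit_chi_point(curve$tau_uM[i], curve$nacl_mM[i], curve$T_cp[i])
    expect_lt(abs(as.numeric(chi_hat) - chi_at(law, curve$T_cp[i])), 1e-4)
  }
})
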
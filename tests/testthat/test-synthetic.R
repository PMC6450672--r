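test_that("turbidity generation passes through the cloud point and round-trips", {
  truth <- data.frame(T_cp = c(292, 295.5), k = c(1.5, 3))
  spec0 <- synthetic_spec(truth = truth, noise_sd = 0, seed = 4)
  curves <- gen_turbidity(spec0)
  # zero noise: the curve crosses 0.5 at T_cp exactly
  c1 <- curves[[1]]
  expect_equal(approx(c1$A500, c1$T, xout = 0.5)$y, 292, tolerance = 1e-6)
  # noisy round trip through the sigmoid fit recovers the truth
  spec <- synthetic_spec(truth = truth, noise_sd = 0.02, seed = 4)
  for (i in 1:2) {
    f <- fit_cloud_point(normalize_turbidity(gen_turbidity(spec)[[i]]))
    expect_lt(abs(f$T_cp - truth$T_cp[i]), 3 * 1.96 * f$se[["Tcp"]] + 0.05)
    expect_lt(abs(f$k - truth$k[i]) / truth$k[i], 0.25)
  }
  expect_error(synthetic_spec(noise_sd = -1), "noise_sd")
})

test_that("per-cycle decay shrinks raw maxima but not the fitted cloud point", {
  truth <- data.frame(T_cp = 293, k = 2)
  spec <- synthetic_spec(truth = truth, noise_sd = 0, decay = 0.9, seed = 1)
  curves <- gen_turbidity(spec, cycles = 3)
  maxima <- vapply(curves, function(cv) max(cv$A500), numeric(1))
  expect_equal(unname(maxima[2] / maxima[1]), 0.9, tolerance = 1e-9)
  expect_equal(unname(maxima[3] / maxima[2]), 0.9, tolerance = 1e-9)
  tcps <- vapply(curves, function(cv)
    fit_cloud_point(normalize_turbidity(cv))$T_cp, numeric(1))
  expect_lt(max(abs(tcps - 293)), 1e-6)
})

test_that("generated datasets are bitwise reproducible under a fixed seed", {
  spec <- synthetic_spec(noise_sd = 0.3, seed = 42,
                         tau_uM = c(20, 60), nacl_mM = c(30, 120))
  expect_identical(gen_cloudpoint_grid(spec), gen_cloudpoint_grid(spec))
  truth <- data.frame(T_cp = 293, k = 2)
  sp2 <- synthetic_spec(truth = truth, noise_sd = 0.05, seed = 9)
  expect_identical(gen_turbidity(sp2)[[1]]$A500, gen_turbidity(sp2)[[1]]$A500)
  s1 <- gen_sequences(3, 30, -4, blockiness = 0.5, seed = 7)
  s2 <- gen_sequences(3, 30, -4, blockiness = 0.5, seed = 7)
  expect_identical(lapply(s1, `[[`, "residues"), lapply(s2, `[[`, "residues"))
})

test_that("a noiseless cloud-point grid refits to the generating chi law", {
  law <- chi_law(1.8, -390)
  spec <- synthetic_spec(truth = law, noise_sd = 0,
                         tau_uM = c(10, 60, 180), nacl_mM = c(30, 120),
                         seed = 1)
  grid <- gen_cloudpoint_grid(spec)
  expect_true(all(is.finite(grid$T_cp)))
  # generated T_cp decreases with [tau] at fixed [NaCl]
  for (na in unique(grid$nacl_mM)) {
    sub <- grid[grid$nacl_mM == na, ]
    expect_true(all(diff(sub$T_cp[order(sub$tau_uM)]) < 0))
  }
  fitres <- fit_phase_diagram(grid)
  expect_equal(fitres$law$A, 1.8, tolerance = 0.01)
  expect_equal(fitres$law$B, -390, tolerance = 3)
  expect_error(gen_cloudpoint_grid(synthetic_spec(truth = chi_law(0.3, 50))),
               "LCST")
})

test_that("cloud-point tables round-trip through the CSV interchange format", {
  spec <- synthetic_spec(noise_sd = 0.2, tau_uM = c(20, 60),
                         nacl_mM = 30, seed = 3)
  grid <- gen_cloudpoint_grid(spec)
  f <- tempfile(fileext = ".csv")
  write_cloudpoint_table(grid, f)
  back <- read_cloudpoint_table(f)
  expect_equal(back$T_cp, grid$T_cp, tolerance = 1e-10)
})

test_that("sequence generation hits exact net charge with tunable blockiness", {
  # fully charged limit
  full <- gen_sequences(1, 20, -20, seed = 1)[[1]]
  expect_equal(full$q_net, -20L)
  expect_equal(full$sigma, 1)
  # exact net charge, fixed composition, different clustering
  set.seed(NULL)
  random <- gen_sequences(5, 60, 0, blockiness = 0, seed = 2)
  blocky <- gen_sequences(5, 60, 0, blockiness = 1, seed = 2)
  comp <- function(s) sort(table(s$residues))
  for (i in 1:5) {
    expect_equal(random[[i]]$q_net, 0L)
    expect_identical(comp(random[[i]]), comp(blocky[[i]]))
  }
  ac_r <- mean(vapply(random, charge_autocorr, numeric(1)))
  ac_b <- mean(vapply(blocky, charge_autocorr, numeric(1)))
  expect_gt(ac_b, ac_r + 0.3)  # clustered charges correlate along the chain
  expect_error(gen_sequences(1, 5, 8), "infeasible")
})
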
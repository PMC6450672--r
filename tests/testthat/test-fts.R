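small_neutral_model <- function(B = 0.05, C = 0.2, N = 20, M = 16, L = 10,
                                dt = 0.01) {
  fts_model(list(neutral_chain(N)), B = B, E = 0, C = C, L = L, M = M,
            dt = dt)
}

test_that("dimensionless parameter maps match direct substitution", {
  # E = 4 pi l_B sqrt(6) / b
  expect_equal(fts_E_from_lB(1.75), 4 * pi * 1.75 * sqrt(6)) # ~53.9
  expect_equal(fts_E_from_T(300),
               fts_E_from_lB(bjerrum_length(300) / 4e-10))
  expect_equal(fts_B_from_v(0.0068), 0.0068 * 6^1.5)
  # 120 mM -> ~3.1e-4 ions per R0^3
  expect_equal(fts_salt_density(120), 3.147e-4, tolerance = 1e-3)
})

test_that("chain fractions follow the 1:1 charge-matching rule", {
  tau <- tau187his_seq()
  m <- fts_model(list(tau, make_polyU(tau$N)), B = 0.1, E = 10, C = 0.01,
                 L = 8, M = 8)
  expect_equal(m$phi_chains[1], tau$N / (tau$N + tau$q_net))  # 0.954
  expect_equal(m$phi_chains[2], 1 - m$phi_chains[1])
  # global neutrality: chains + ions
  qdens <- sum(m$n_chains * m$q) / m$V + m$rho_plus - m$rho_minus
  expect_lt(abs(qdens), 1e-14)
  # same-sign chains cannot be matched
  expect_error(fts_model(list(tau, tau), B = 0.1, E = 1, C = 0.01,
                         L = 8, M = 8), "charge neutrality")
})

test_that("residual chain charge is neutralised by counter-ions", {
  pair <- truncated_pair(20)
  ptau <- phosphorylate(pair$tau, which(pair$tau$residues == "S"))
  expect_lt(ptau$q_net, 0)
  m <- fts_model(list(ptau, pair$rna), B = 0.1, E = 10, C = 0.01,
                 L = 8, M = 8, salt_mM = 100,
                 phi_chains = c(0.5, 0.5))
  qdens <- sum(m$n_chains * m$q) / m$V + m$rho_plus - m$rho_minus
  expect_lt(abs(qdens), 1e-12)
  expect_gt(m$rho_plus, m$rho_minus)  # extra cations offset the anionic chains
})

test_that("smearing conserves the mean and composes as Gaussian kernels", {
  m <- small_neutral_model(M = 16)
  const <- array(2.5 + 0i, dim = c(16, 16, 16))
  expect_equal(fts_smear(const, m), const)
  set.seed(8)
  x <- array(rnorm(16^3), dim = c(16, 16, 16))
  s1 <- fts_smear(x, m)
  expect_equal(mean(Re(s1)), mean(x), tolerance = 1e-12)
  # double smear = single smear with a sqrt(2)-wider kernel
  s2 <- fts_smear(s1, m)
  wide <- coacervate:::.ifft3(exp(-m$k2) * coacervate:::.fft3(x))
  expect_lt(max(Mod(s2 - wide)), 1e-12)
  # a delta impulse spreads into a positive unit-mass bump
  delta <- array(0i, dim = c(16, 16, 16)); delta[8, 8, 8] <- 1
  sd1 <- Re(fts_smear(delta, m))
  expect_equal(sum(sd1), 1, tolerance = 1e-10)
  expect_gt(min(sd1), -1e-10)
})

test_that("propagators satisfy the zero-field and uniform-field closed forms", {
  m <- small_neutral_model(M = 8, L = 8)
  zero <- array(0i, dim = c(8, 8, 8))
  pr <- propagate_chain(rep(list(zero), 12), m)
  expect_identical(Mod(pr$Q - 1), 0)  # Q = 1 exactly at zero fields
  cc <- 0.17 - 0.06i
  pru <- propagate_chain(rep(list(zero + cc), 12), m)
  expect_complex_equal(pru$Q, exp(-12 * cc), tol = 1e-12)
})

test_that("the field-free chain spreads like an ideal random walk", {
  # second moment of the end distribution after n bonds = n b^2 = 6 n R0^2
  M <- 32; L <- 24
  m <- fts_model(list(neutral_chain(2)), B = 0.01, E = 0, C = 0.01,
                 L = L, M = M)
  q <- array(0i, dim = c(M, M, M)); q[1, 1, 1] <- 1
  nb <- 6
  for (i in seq_len(nb)) q <- fts_bond_step(q, m)
  ax <- (L / M) * c(0:(M / 2), -(M / 2 - 1):-1)[1:M]  # min-image coords
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  moment <- sum(r2 * Re(q)) / sum(Re(q))
  expect_equal(moment, 6 * nb, tolerance = 0.01)
})

test_that("the Hamiltonian vanishes at zero fields and its gradient term is gauge-invariant", {
  pair <- truncated_pair(10)
  m <- fts_model(list(pair$tau, pair$rna), B = 0.1, E = 5, C = 0.05,
                 L = 8, M = 8)
  st <- field_state(m, "zero")
  expect_complex_equal(fts_hamiltonian(st, m), 0 + 0i, tol = 1e-12)
  # quadratic spectral terms equal direct real-space sums (Parseval)
  set.seed(4)
  w <- array(rnorm(8^3), dim = c(8, 8, 8)) + 1i * array(rnorm(8^3), dim = c(8, 8, 8))
  Fw <- coacervate:::.fft3(w)
  expect_complex_equal(coacervate:::.kmean_prod(Fw, coacervate:::.revk(Fw)),
                       mean(w * w), tol = 1e-10)
  # adding a constant to phi leaves the gradient term unchanged
  st$phi <- st$phi + (0.3 + 0.1i)
  Fphi <- coacervate:::.fft3(st$phi)
  grad <- coacervate:::.kmean_prod(Fphi, coacervate:::.revk(Fphi), m$k2)
  expect_complex_equal(grad, 0 + 0i, tol = 1e-12)
})

test_that("the noise-free dynamics are stationary at the homogeneous saddle", {
  pair <- truncated_pair(15)
  m <- fts_model(list(pair$tau, pair$rna), B = 0.08, E = 20, C = 0.05,
                 L = 8, M = 8)
  st <- field_state(m, "saddle")
  st2 <- cl_step(st, m, noise = FALSE)
  expect_lt(max(Mod(st2$w - st$w)), 1e-13)
  expect_lt(max(Mod(st2$phi - st$phi)), 1e-13)
})

test_that("one-step noise variance scales linearly with dt", {
  m1 <- small_neutral_model(B = 5, C = 0.01, N = 2, M = 8, L = 8, dt = 0.01)
  m2 <- small_neutral_model(B = 5, C = 0.01, N = 2, M = 8, L = 8, dt = 0.02)
  st <- field_state(m1, "saddle")
  one_step_var <- function(m, seed) {
    set.seed(seed)
    det <- cl_step(st, m, noise = FALSE)
    noisy <- cl_step(st, m, noise = TRUE)
    stats::var(as.vector(Re(noisy$w - det$w)))
  }
  v1 <- one_step_var(m1, 21); v2 <- one_step_var(m2, 22)
  expect_equal(v2 / v1, 2, tolerance = 0.1)
})

test_that("a pure-Gaussian field relaxes to the analytic measure", {
  # no effective chain coupling: the w sector is an Ornstein-Uhlenbeck
  # process whose stationary per-site variance is B / dV
  m <- fts_model(list(neutral_chain(1)), B = 0.1, E = 0, C = 1e-10,
                 L = 8, M = 8, dt = 0.02)
  st <- field_state(m, "zero")
  set.seed(31)
  burn <- 200; keep <- 500; acc <- numeric(keep)
  for (i in seq_len(burn + keep)) {
    st <- cl_step(st, m)
    if (i > burn) acc[i - burn] <- mean(Re(st$w)^2)
  }
  expect_equal(mean(acc), m$B / m$dV, tolerance = 0.05)
})

test_that("trajectories are bitwise reproducible under a fixed seed", {
  m <- small_neutral_model(N = 5, M = 8, L = 8)
  t1 <- run_cl(m, 40, seed = 17, pressure_every = 10)
  t2 <- run_cl(m, 40, seed = 17, pressure_every = 10)
  expect_identical(t1$samples, t2$samples)
  t3 <- run_cl(m, 40, seed = 18, pressure_every = 10)
  expect_false(identical(t3$samples$H, t1$samples$H))
})

test_that("the mean density operator equals C for every configuration", {
  pair <- truncated_pair(8)
  m <- fts_model(list(pair$tau, pair$rna), B = 0.1, E = 5, C = 0.07,
                 L = 8, M = 8)
  tr <- run_cl(m, 30, seed = 5, pressure_every = 1e9)
  expect_lt(max(Mod(tr$samples$rho_mean - m$C)), 1e-10)
})

test_that("the chemical potential operator has the ideal-gas limit and grows with C", {
  # single beads, Q = 1: mu = ln(C phi) exactly
  expect_complex_equal(chemical_potential_op(1 + 0i, 0.05, 1, 1),
                       log(0.05) + 0i, tol = 1e-14)
  mus <- vapply(c(0.05, 0.15, 0.3), function(C) {
    m <- small_neutral_model(B = 0.1, C = C, N = 5, M = 8, L = 8)
    tr <- run_cl(m, 250, seed = 9, pressure_every = 1e9)
    tr$summary["mu_total", "mean"]
  }, numeric(1))
  expect_true(all(diff(mus) > 0))
})

test_that("identical chain types report identical chemical potentials", {
  ch <- neutral_chain(6)
  m <- fts_model(list(ch, ch), B = 0.05, E = 0, C = 0.1, L = 8, M = 8,
                 phi_chains = c(0.5, 0.5))
  tr <- run_cl(m, 40, seed = 2, pressure_every = 1e9)
  expect_equal(tr$samples$mu_1, tr$samples$mu_2)
})

test_that("coexistence is recovered from an analytic double-well free energy", {
  # symmetric regular-solution free energy: the coexistence pair solves
  # ln(rho/(1-rho)) = -chi (1 - 2 rho), symmetric about 1/2
  chi <- 2.4
  f <- function(r) r * log(r) + (1 - r) * log(1 - r) + chi * r * (1 - r)
  mu <- function(r) log(r) - log(1 - r) + chi * (1 - 2 * r)
  Pi <- function(r) r * mu(r) - f(r)
  rho1 <- uniroot(function(r) mu(r), c(1e-6, 0.49), tol = 1e-14)$root
  C <- seq(0.02, 0.98, length.out = 240)
  cx <- find_coexistence(data.frame(C = C, mu = mu(C), Pi = Pi(C)))
  expect_false(is.null(cx))
  expect_equal(cx$rho_I, rho1, tolerance = 1e-3)
  expect_equal(cx$rho_II, 1 - rho1, tolerance = 1e-3)
  expect_equal(cx$mu_star, 0, tolerance = 1e-6)
  # a monotone single branch yields no coexistence
  expect_message(
    mono <- find_coexistence(data.frame(C = C, mu = sort(mu(C)), Pi = Pi(C))),
    "single branch")
  expect_null(mono)
})

test_that("imaginary parts of physical observables average to zero within errors", {
  m <- small_neutral_model(B = 0.05, C = 0.2, N = 10, M = 8, L = 8)
  tr <- run_cl(m, 400, seed = 13, pressure_every = 2)
  s <- tr$summary
  for (k in c("rho_mean", "mu_total", "Pi"))
    expect_lt(abs(s[k, "im"]), 3 * max(s[k, "im_se"], 1e-12) + 1e-9)
})

charged_contrast <- function(chains, lB_b, v_b3, steps = 1200, seed = 11,
                             phi_chains = NULL, salt_mM = 0) {
  E <- fts_E_from_lB(lB_b)
  m <- fts_model(chains, B = fts_B_from_v(v_b3), E = E,
                 C = fts_C_from_rho(0.22), L = 16, M = 16, dt = 0.005,
                 lambda_phi = max(E, 1), phi_chains = phi_chains,
                 salt_mM = salt_mM)
  tr <- run_cl(m, steps, seed = seed, sample_every = 10,
               pressure_every = 1e9)
  expect_false(is.finite(tr$diverged_at))
  tail_idx <- tr$samples$step > steps * 2 / 3
  stats::median(tr$samples$contrast_cv[tail_idx])
}

test_that("stronger electrostatics sharpen demixing at fixed solvent quality", {
  pair <- truncated_pair(20)
  chains <- list(pair$tau, pair$rna)
  weak_lB <- charged_contrast(chains, lB_b = 0.8, v_b3 = 0.0068)
  strong_lB <- charged_contrast(chains, lB_b = 3.25, v_b3 = 0.0068)
  expect_gt(strong_lB, 1.5 * weak_lB)   # larger l_B favours the coacervate
})

test_that("phosphorylation weakens demixing at matched conditions", {
  pair <- truncated_pair(20)
  ser <- which(pair$tau$residues == "S")[1:2]
  ptau <- phosphorylate(pair$tau, ser)
  base <- fts_model(list(pair$tau, pair$rna), B = 1, E = 1, C = 0.01,
                    L = 8, M = 8)
  plain <- charged_contrast(list(pair$tau, pair$rna), 3.25, 0.0068,
                            seed = 19)
  # same chain composition; counter-ions restore neutrality for the
  # phosphorylated variant (as added excess salt would)
  phos <- charged_contrast(list(ptau, pair$rna), 3.25, 0.0068, seed = 19,
                           phi_chains = base$phi_chains)
  expect_lt(phos, plain)
})
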
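test_that("material containers enforce their invariants", {
  expect_error(prony_series(c(0.5, 0.6), c(0.01, 0.1)), "< 1")
  expect_error(prony_series(0.5, -1), "tau")
  expect_error(material_params(200, K0 = 200), "50")
  expect_error(material_set(-5), "mu0")
  ms <- material_set(220, f = 6, g_B = 0.8)
  expect_equal(ms$skin$mu0 / ms$breast$mu0, 6)
  expect_equal(ms$breast$rho, 1000)
  expect_equal(ms$breast$prony$g_inf, 0.2, tolerance = 1e-15)
})

test_that("neo-Hookean energy: zero at rotations, closed form, FD stress", {
  mat <- material_params(200)
  expect_identical(neo_hookean_energy(diag(3), mat), 0)
  set.seed(3)
  R <- random_rotation()
  expect_equal(neo_hookean_energy(R, mat), 0, tolerance = 1e-12)

  # isochoric uniaxial stretch: Psi = mu0/2 (lam^2 + 2/lam - 3)
  lam <- 1.2
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  expect_equal(neo_hookean_energy(F, mat),
               100 * (lam^2 + 2 / lam - 3), tolerance = 1e-12)
  expect_error(deformation_state(diag(c(-1, 1, 1))), "inverted")
})

test_that("neo-Hookean stress: identity, simple shear, incompressible limit", {
  mat <- material_params(200)
  expect_equal(neo_hookean_stress(diag(3), mat), matrix(0, 3, 3))

  # simple shear gamma = 0.3: J = 1 so sigma_12 = mu0 gamma = 60 Pa
  F <- diag(3); F[1, 2] <- 0.3
  sig <- neo_hookean_stress(F, mat)
  expect_equal(sig[1, 2], 60, tolerance = 1e-12)
  expect_equal(sig, t(sig))

  # incompressible uniaxial: nominal stress -> mu0 (lam - lam^-2)
  lam <- 1.2
  mat_i <- material_params(200, K0 = 1e4 * 200)
  # lateral stretch from sigma_22 = 0 (solve radially)
  f22 <- function(q) {
    F <- diag(c(lam, q, q))
    neo_hookean_stress(F, mat_i)[2, 2]
  }
  q <- uniroot(f22, c(0.5, 1.2), tol = 1e-14)$root
  F <- diag(c(lam, q, q))
  sig <- neo_hookean_stress(F, mat_i)
  P11 <- sig[1, 1] * det(F) / lam # nominal from Cauchy
  expect_equal(P11, 200 * (lam - lam^-2), tolerance = 0.01)
})

test_that("stress-energy FD consistency over 100 random states", {
  mat <- material_params(200)
  set.seed(42)
  worst <- 0
  for (k in 1:100) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.15), 3, 3)
    J <- det(F)
    if (J <= 0) next
    F <- F * (runif(1, 0.7, 1.4) / J)^(1 / 3) # J in [0.7, 1.4]
    sig <- neo_hookean_stress(F, mat)
    sig_fd <- fd_cauchy_stress(F, mat)
    worst <- max(worst, max(abs(sig - sig_fd)) / max(abs(sig), 1))
  }
  expect_lt(worst, 1e-5)
})

test_that("objectivity: Psi(RF) = Psi(F) for random rotations", {
  mat <- material_params(200)
  set.seed(5)
  for (k in 1:20) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.2), 3, 3)
    if (det(F) <= 0.1) next
    R <- random_rotation()
    expect_equal(neo_hookean_energy(R %*% F, mat),
                 neo_hookean_energy(F, mat), tolerance = 1e-11)
  }
})

test_that("relaxation modulus G(t): limits, value at t = tau, monotone", {
  mat <- material_params(200, prony = prony_series(0.8, 0.01))
  expect_equal(relaxation_modulus(0, mat), 200)
  expect_equal(relaxation_modulus(100, mat), 0.2 * 200, tolerance = 1e-8)
  expect_equal(relaxation_modulus(0.01, mat) / 200,
               1 - 0.8 * (1 - exp(-1)), tolerance = 1e-12)
  tt <- seq(0, 0.1, by = 1e-3)
  expect_true(all(diff(relaxation_modulus(tt, mat)) <= 0))
  expect_error(relaxation_modulus(-1, mat), ">= 0")
})

test_that("visco_update: degenerate g, step-load limit, quadrature oracle", {
  # g absent -> passthrough, histories stay zero
  pr0 <- prony_series()
  S <- matrix(rnorm(9), 3, 3); S <- (S + t(S)) / 2; diag(S) <- diag(S) - sum(diag(S)) / 3
  out <- visco_update(S, matrix(0, 3, 3), NULL, 1e-3, pr0)
  expect_equal(out$stress, S)
  expect_length(out$history, 0)

  # held step load relaxes to (1 - g) S
  pr <- prony_series(0.8, 0.01)
  state <- visco_update(S, matrix(0, 3, 3), NULL, 1e-4, pr)
  for (k in 1:2000) state <- visco_update(S, S, state$history, 1e-4, pr)
  expect_equal(state$stress, 0.2 * S, tolerance = 1e-6)

  # random piecewise-linear history vs direct convolution quadrature
  set.seed(8)
  nstep <- 200; dt <- 2e-3
  times <- seq(0, by = dt, length.out = nstep + 1)
  incr <- replicate(nstep, matrix(rnorm(9, sd = 0.3), 3, 3),
                    simplify = FALSE)
  S_list <- vector("list", nstep + 1)
  S_list[[1]] <- matrix(0, 3, 3)
  for (k in seq_len(nstep)) {
    Sk <- S_list[[k]] + incr[[k]]
    Sk <- (Sk + t(Sk)) / 2; diag(Sk) <- diag(Sk) - sum(diag(Sk)) / 3
    S_list[[k + 1]] <- Sk
  }
  state <- NULL; hist <- NULL
  for (k in seq_len(nstep)) {
    state <- visco_update(S_list[[k + 1]], S_list[[k]], hist, dt, pr)
    hist <- state$history
  }
  oracle <- convolution_oracle(times, S_list, pr)
  expect_lt(max(abs(state$stress - oracle)) / max(abs(oracle)), 0.005)
})

test_that("viscous dissipation is non-negative over closed strain cycles", {
  pr <- prony_series(0.8, 0.01)
  mu <- 200
  set.seed(13)
  for (rep in 1:5) {
    # random smooth closed deviatoric strain path, 3 full cycles
    A1 <- matrix(rnorm(9, sd = 0.02), 3, 3); A1 <- (A1 + t(A1)) / 2
    A2 <- matrix(rnorm(9, sd = 0.02), 3, 3); A2 <- (A2 + t(A2)) / 2
    diag(A1) <- diag(A1) - sum(diag(A1)) / 3
    diag(A2) <- diag(A2) - sum(diag(A2)) / 3
    tt <- seq(0, 3 * 0.05, length.out = 400)
    dt <- diff(tt)[1]
    eps <- lapply(tt, function(t)
      A1 * sin(2 * pi * t / 0.05) + A2 * (1 - cos(2 * pi * t / 0.05)))
    work <- 0
    hist <- NULL
    S_old <- matrix(0, 3, 3)
    for (k in 2:length(tt)) {
      S_new <- 2 * mu * eps[[k]]
      st <- visco_update(S_new, S_old, hist, dt, pr)
      hist <- st$history; S_old <- S_new
      work <- work + sum(st$stress * (eps[[k]] - eps[[k - 1]]))
    }
    expect_gt(work, -1e-12)
  }
})
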
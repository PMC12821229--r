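# independent oracles (deliberately separate code paths from R/ and src/)

# Cauchy stress by central finite differences of the strain energy:
# P_ij = dPsi/dF_ij, sigma = P F^T / J
fd_cauchy_stress <- function(F, mat, h = 1e-7) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Fp <- F; Fp[i, j] <- Fp[i, j] + h
    Fm <- F; Fm[i, j] <- Fm[i, j] - h
    P[i, j] <- (neo_hookean_energy(deformation_state(Fp), mat) -
                  neo_hookean_energy(deformation_state(Fm), mat)) / (2 * h)
  }
  P %*% t(F) / det(F)
}

# direct quadrature of the hereditary integral for a piecewise-linear
# deviatoric stress history: S_rel(t_N) = int_0^tN Grel(t-s)/G0 dS/ds ds
# with the per-interval integral of Grel done analytically
convolution_oracle <- function(times, S_list, prony) {
  tN <- times[length(times)]
  Gint <- function(u1, u2) { # int_{u1}^{u2} Grel(u)/G0 du
    g_inf <- prony$g_inf
    out <- g_inf * (u2 - u1)
    for (k in seq_along(prony$g))
      out <- out + prony$g[k] * prony$tau[k] *
        (exp(-u1 / prony$tau[k]) - exp(-u2 / prony$tau[k]))
    out
  }
  S_rel <- matrix(0, 3, 3)
  for (k in 2:length(times)) {
    dS <- S_list[[k]] - S_list[[k - 1]]
    dt <- times[k] - times[k - 1]
    S_rel <- S_rel + dS / dt * Gint(tN - times[k], tN - times[k - 1])
  }
  S_rel
}

# nodal internal forces of a single linear tet under constant Cauchy
# stress, from shape-function gradients computed by matrix inversion in
# the deformed configuration: f_a = V * sigma * gradN_a
constant_stress_tet_forces <- function(coords_def, sigma) {
  M <- cbind(1, coords_def)        # 4 x 4
  C <- solve(M)                    # rows: coefficients of N_a
  grads <- t(C[2:4, ])             # 4 x 3, gradN_a in rows
  V <- abs(det(M)) / 6
  t(apply(grads, 1, function(g) V * as.numeric(sigma %*% g)))
}

# independent neo-Hookean nodal forces for a whole mesh (plain constant-
# gradient elements, no F-bar), used as the gradient of the static oracle
nh_forces_plain <- function(mesh, u, mu, K) {
  n <- mesh$nodes; t4 <- mesh$tets
  f <- matrix(0, nrow(n), 3)
  energy <- 0
  for (e in seq_len(nrow(t4))) {
    id <- t4[e, ]
    X <- n[id, ]
    Dm <- t(X[2:4, ]) - X[1, ]
    DmInv <- solve(Dm)
    x <- X + u[id, ]
    Ds <- t(x[2:4, ]) - x[1, ]
    F <- Ds %*% DmInv
    J <- det(F)
    if (J <= 0) stop("inverted trial element")
    V0 <- det(Dm) / 6
    Fit <- t(solve(F))
    I1 <- sum(F * F)
    # P = mu J^{-2/3} (F - I1/3 F^{-T}) + K (J-1) J F^{-T}
    P <- mu * J^(-2 / 3) * (F - I1 / 3 * Fit) + K * (J - 1) * J * Fit
    energy <- energy + V0 * (mu / 2 * (J^(-2 / 3) * I1 - 3) +
                               K / 2 * (J - 1)^2)
    H <- V0 * P %*% t(DmInv)
    f[id[2], ] <- f[id[2], ] + H[, 1]
    f[id[3], ] <- f[id[3], ] + H[, 2]
    f[id[4], ] <- f[id[4], ] + H[, 3]
    f[id[1], ] <- f[id[1], ] - (H[, 1] + H[, 2] + H[, 3])
  }
  list(forces = f, energy = energy)
}

# static equilibrium by direct minimization of strain + gravity
# potential (L-BFGS-B with the analytic plain-element gradient);
# fixed_nodes are fully clamped
static_minimize_oracle <- function(mesh, mu, K, rho, gravity,
                                   fixed_nodes, maxit = 2000) {
  nn <- nrow(mesh$nodes)
  free <- setdiff(seq_len(nn), fixed_nodes)
  masses <- rep(0, nn)
  vol <- tet_volumes(mesh)
  for (a in 1:4) {
    s <- rowsum(rho * vol / 4, mesh$tets[, a])
    idx <- as.integer(rownames(s))
    masses[idx] <- masses[idx] + s[, 1]
  }
  fg <- matrix(gravity, nn, 3, byrow = TRUE) * masses
  unpack <- function(par) {
    u <- matrix(0, nn, 3)
    u[free, ] <- matrix(par, ncol = 3)
    u
  }
  fn <- function(par) {
    u <- unpack(par)
    e <- try(nh_forces_plain(mesh, u, mu, K)$energy, silent = TRUE)
    if (inherits(e, "try-error")) return(1e6) # inverted trial state
    e - sum(fg * u)
  }
  gr <- function(par) {
    u <- unpack(par)
    g <- try(nh_forces_plain(mesh, u, mu, K)$forces, silent = TRUE)
    if (inherits(g, "try-error")) return(numeric(3 * length(free)))
    as.numeric((g - fg)[free, ])
  }
  span <- 0.05 # box keeps L-BFGS line searches from inverting elements
  res <- stats::optim(rep(0, 3 * length(free)), fn, gr,
                      method = "L-BFGS-B",
                      lower = -span, upper = span,
                      control = list(maxit = maxit, factr = 10,
                                     pgtol = 1e-12))
  unpack(res$par)
}

# small-strain linear elasticity on the same tet mesh (CST elements),
# assembled independently and solved directly
linear_fe_oracle <- function(mesh, mu, K, rho, gravity, fixed_nodes) {
  lambda <- K - 2 * mu / 3
  nn <- nrow(mesh$nodes)
  t4 <- mesh$tets
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  D <- matrix(0, 6, 6) # Voigt xx yy zz xy yz zx (engineering shear)
  D[1:3, 1:3] <- lambda
  diag(D)[1:3] <- lambda + 2 * mu
  diag(D)[4:6] <- mu
  for (e in seq_len(nrow(t4))) {
    id <- t4[e, ]
    X <- mesh$nodes[id, ]
    M <- cbind(1, X)
    C <- solve(M)
    grads <- t(C[2:4, ])  # 4 x 3
    V <- abs(det(M)) / 6
    B <- matrix(0, 6, 12)
    for (a in 1:4) {
      g <- grads[a, ]
      cset <- (a - 1) * 3
      B[1, cset + 1] <- g[1]; B[2, cset + 2] <- g[2]; B[3, cset + 3] <- g[3]
      B[4, cset + 1] <- g[2]; B[4, cset + 2] <- g[1]
      B[5, cset + 2] <- g[3]; B[5, cset + 3] <- g[2]
      B[6, cset + 1] <- g[3]; B[6, cset + 3] <- g[1]
    }
    Ke <- V * t(B) %*% D %*% B
    dofs <- as.vector(t(cbind((id - 1) * 3 + 1, (id - 1) * 3 + 2,
                              (id - 1) * 3 + 3)))
    for (p in 1:12) {
      trip_i <- c(trip_i, rep(dofs[p], 12))
      trip_j <- c(trip_j, dofs)
      trip_x <- c(trip_x, Ke[p, ])
    }
  }
  Kmat <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                               dims = c(3 * nn, 3 * nn))
  masses <- rep(0, nn)
  vol <- tet_volumes(mesh)
  for (a in 1:4) {
    s <- rowsum(rho * vol / 4, t4[, a])
    idx <- as.integer(rownames(s))
    masses[idx] <- masses[idx] + s[, 1]
  }
  fvec <- as.numeric(t(matrix(gravity, nn, 3, byrow = TRUE) * masses))
  fixed_dofs <- as.vector(vapply(fixed_nodes,
                                 function(n) (n - 1) * 3 + 1:3,
                                 numeric(3)))
  free <- setdiff(seq_len(3 * nn), fixed_dofs)
  u <- numeric(3 * nn)
  u[free] <- as.numeric(Matrix::solve(Kmat[free, free], fvec[free]))
  matrix(u, nn, 3, byrow = TRUE)
}
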
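#' Prony relaxation series
#'
#' Dimensionless generalized-Maxwell relaxation: each term has a modulus
#' ratio g_k = G_k / G0 and a relaxation time tau_k = eta_k / G_k. The
#' long-term ratio is g_inf = 1 - sum(g_k).
#'
#' @param g numeric vector of modulus ratios (dimensionless)
#' @param tau numeric vector of relaxation times (s)
#' @return a `prony_series`
#' @export
prony_series <- function(g = numeric(0), tau = numeric(0)) {
  g <- as.numeric(g); tau <- as.numeric(tau)
  if (length(g) != length(tau)) stop("g and tau must have equal length")
  if (any(g < 0)) stop("Prony ratios g_k must be >= 0")
  if (sum(g) >= 1) stop("sum of Prony ratios must be < 1")
  if (any(tau <= 0)) stop("relaxation times tau_k must be > 0")
  structure(list(g = g, tau = tau, g_inf = 1 - sum(g)),
            class = "prony_series")
}

#' Visco-hyperelastic material parameters
#'
#' Neo-Hookean instantaneous response (initial shear modulus `mu0`, bulk
#' modulus `K0`) with optional Prony-series shear relaxation; `G0 = mu0`.
#' Quasi-incompressibility is enforced by requiring `K0 >= 50 mu0`.
#'
#' @param mu0 initial shear modulus (Pa)
#' @param K0 initial bulk modulus (Pa); default `100 * mu0`
#' @param rho density (kg/m^3)
#' @param prony a `prony_series` (default: purely hyperelastic)
#' @return a `material_params`
#' @export
material_params <- function(mu0, K0 = 100 * mu0, rho = 1000,
                            prony = prony_series()) {
  if (mu0 <= 0) stop("mu0 must be > 0")
  if (rho <= 0) stop("rho must be > 0")
  if (K0 < 50 * mu0)
    stop("K0 must be >= 50*mu0 for quasi-incompressible behaviour")
  if (!inherits(prony, "prony_series")) stop("prony must be a prony_series")
  structure(list(mu0 = mu0, K0 = K0, rho = rho, prony = prony, G0 = mu0),
            class = "material_params")
}

#' Two-tissue material set (breast + skin)
#'
#' The skin shear modulus is tied to the breast modulus by the factor f:
#' mu_S = f * mu_B. Both tissues share the same density and, absent
#' separate skin data, the same Prony relaxation.
#'
#' @param mu_B breast shear modulus (Pa)
#' @param f skin scaling factor (mu_S = f * mu_B)
#' @param g_B Prony ratio for the single-term series (0 disables
#'   viscoelasticity)
#' @param tau relaxation time (s), default 0.01
#' @param K_ratio bulk-to-shear ratio K0/mu0, default 100
#' @param rho density (kg/m^3), default 1000
#' @return a `material_set` with elements `breast`, `skin`, `f`
#' @export
material_set <- function(mu_B, f = 6, g_B = 0, tau = 0.01,
                         K_ratio = 100, rho = 1000) {
  pr <- if (g_B > 0) prony_series(g_B, tau) else prony_series()
  breast <- material_params(mu_B, K0 = K_ratio * mu_B, rho = rho, prony = pr)
  skin <- material_params(f * mu_B, K0 = K_ratio * f * mu_B, rho = rho,
                          prony = pr)
  structure(list(breast = breast, skin = skin, f = f), class = "material_set")
}

#' Kinematic state of a material point
#'
#' Derived quantities of a deformation gradient F: J = det F, the
#' isochoric left Cauchy-Green tensor Bbar = J^(-2/3) F F^T and its trace
#' I1bar.
#'
#' @param F 3x3 deformation gradient
#' @return a `deformation_state` with `F`, `J`, `Bbar`, `I1bar`
#' @export
deformation_state <- function(F) {
  F <- matrix(as.numeric(F), 3, 3)
  J <- det(F)
  if (J <= 0) stop("inverted element: det(F) <= 0")
  B <- F %*% t(F)
  Bbar <- J^(-2 / 3) * B
  structure(list(F = F, J = J, Bbar = Bbar, I1bar = sum(diag(Bbar))),
            class = "deformation_state")
}

#' Neo-Hookean strain-energy density
#'
#' Psi = mu0/2 (I1bar - 3) + K0/2 (J - 1)^2, the compressible neo-Hookean
#' potential with a quadratic volumetric term. Zero iff F is a rotation.
#'
#' @param state a `deformation_state` (or 3x3 matrix F)
#' @param mat a `material_params`
#' @return energy density (Pa = J/m^3)
#' @export
neo_hookean_energy <- function(state, mat) {
  if (!inherits(state, "deformation_state")) state <- deformation_state(state)
  mat$mu0 / 2 * (state$I1bar - 3) + mat$K0 / 2 * (state$J - 1)^2
}

#' Neo-Hookean Cauchy stress
#'
#' sigma = (mu0 / J^(5/3)) dev(B) + K0 (J - 1) I, the stress conjugate to
#' the energy above (verified against finite differences in the tests).
#'
#' @param state a `deformation_state` (or 3x3 matrix F)
#' @param mat a `material_params`
#' @return symmetric 3x3 Cauchy stress (Pa)
#' @export
neo_hookean_stress <- function(state, mat) {
  if (!inherits(state, "deformation_state")) state <- deformation_state(state)
  B <- state$F %*% t(state$F)
  devB <- B - sum(diag(B)) / 3 * diag(3)
  mat$mu0 * state$J^(-5 / 3) * devB + mat$K0 * (state$J - 1) * diag(3)
}

#' Shear relaxation modulus G(t)
#'
#' G(t) = G0 (1 - sum_k g_k (1 - exp(-t / tau_k))): monotone
#' non-increasing from G(0) = G0 to G0 (1 - sum g_k).
#'
#' @param t time (s), vectorized, must be >= 0
#' @param mat a `material_params`
#' @return G(t) in Pa
#' @export
relaxation_modulus <- function(t, mat) {
  if (any(t < 0)) stop("t must be >= 0")
  pr <- mat$prony
  out <- rep(1, length(t))
  for (k in seq_along(pr$g))
    out <- out - pr$g[k] * (1 - exp(-t / pr$tau[k]))
  mat$G0 * out
}

#' One step of the Prony internal-variable stress update
#'
#' Advances the hereditary (convolution) integral for a deviatoric stress
#' history that is piecewise linear in time. Each term carries an internal
#' tensor h_k = g_k * int_0^t exp(-(t-s)/tau_k) dS_dev/ds ds, updated
#' exactly by
#'   h_k^(n+1) = exp(-dt/tau_k) h_k^n
#'               + g_k (1 - exp(-dt/tau_k)) / (dt/tau_k) (S^(n+1) - S^n),
#' and the relaxed deviatoric stress is
#'   (1 - sum g_k) S^(n+1) + sum_k h_k^(n+1),
#' which reproduces the convolution with G(t)/G0 exactly for piecewise
#' linear input and recovers (1 - g) S under a held step load.
#'
#' @param S_new deviatoric stress at step n+1 (3x3)
#' @param S_old deviatoric stress at step n (3x3)
#' @param history list of 3x3 internal tensors h_k at step n (zeros at
#'   t = 0); `NULL` initializes them
#' @param dt time step (s), > 0
#' @param prony a `prony_series`
#' @return list with `stress` (relaxed deviatoric stress) and `history`
#'   (updated internal tensors)
#' @export
visco_update <- function(S_new, S_old, history, dt, prony) {
  if (dt <= 0) stop("dt must be > 0")
  K <- length(prony$g)
  if (is.null(history)) history <- replicate(K, matrix(0, 3, 3),
                                             simplify = FALSE)
  S_new <- matrix(as.numeric(S_new), 3, 3)
  S_old <- matrix(as.numeric(S_old), 3, 3)
  out <- prony$g_inf * S_new
  hist_new <- vector("list", K)
  for (k in seq_len(K)) {
    x <- dt / prony$tau[k]
    e <- exp(-x)
    hk <- e * history[[k]] + prony$g[k] * (1 - e) / x * (S_new - S_old)
    hist_new[[k]] <- hk
    out <- out + hk
  }
  list(stress = out, history = hist_new)
}
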
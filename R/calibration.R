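#' Piecewise Prony-ratio rule g_B(mu_B)
#'
#' The viscous modulus ratio is tied to the calibrated shear modulus:
#' g_B = 0.8 on [160, 230) Pa, 0.5 on [230, 300) Pa and 0.1 from 300 Pa
#' upward (left-closed brackets).
#'
#' @param mu_B breast shear modulus (Pa), must be >= 160
#' @return g_B (dimensionless)
#' @export
g_from_mu <- function(mu_B) {
  if (any(mu_B < 160))
    stop("mu_B below 160 Pa is outside the calibrated g_B rule")
  ifelse(mu_B < 230, 0.8, ifelse(mu_B < 300, 0.5, 0.1))
}

#' Calibration configuration
#'
#' @param mu_bounds search bounds for mu_B (Pa), default [160, 300]
#' @param stop_threshold nipple-distance stopping threshold (m). The
#'   clinical-scale default is 5 mm; phantom-scale runs typically use
#'   2 mm.
#' @param f_candidates skin factors for the exhaustive search
#' @param tau relaxation time (s), fixed at 0.01
#' @param friction chest-wall Coulomb coefficient phi, fixed at 0.5
#' @param sa_temp initial annealing temperature (objective units, mm)
#' @param sa_cooling geometric cooling ratio per evaluation
#' @param sa_sigma Gaussian proposal standard deviation (Pa)
#' @param sa_max_eval maximum objective evaluations for annealing
#' @param golden_steps maximum golden-section refinement steps
#' @param seed RNG seed
#' @return a `calibration_config`
#' @export
calibration_config <- function(mu_bounds = c(160, 300),
                               stop_threshold = 5e-3,
                               f_candidates = c(4, 6, 8, 10, 12),
                               tau = 0.01, friction = 0.5,
                               sa_temp = 20, sa_cooling = 0.95,
                               sa_sigma = 20, sa_max_eval = 40,
                               golden_steps = 10, seed = 1L) {
  if (length(mu_bounds) != 2 || mu_bounds[1] >= mu_bounds[2] ||
      mu_bounds[1] <= 0)
    stop("mu_bounds must be ordered and positive")
  if (stop_threshold <= 0) stop("stop_threshold must be > 0")
  if (!length(f_candidates)) stop("need at least one f candidate")
  structure(list(mu_bounds = mu_bounds, stop_threshold = stop_threshold,
                 f_candidates = f_candidates, tau = tau,
                 friction = friction, sa_temp = sa_temp,
                 sa_cooling = sa_cooling, sa_sigma = sa_sigma,
                 sa_max_eval = sa_max_eval, golden_steps = golden_steps,
                 seed = as.integer(seed)),
            class = "calibration_config")
}

#' Nipple-distance objective
#'
#' Builds the material set for a trial mu_B (g_B from the piecewise
#' rule, mu_S = f mu_B), runs the explicit simulation, applies the
#' closest-approach stopping criterion against the target nipple and
#' returns the achieved nipple distance. Deterministic per
#' (mu_B, f, config).
#'
#' @param mu_B trial breast shear modulus (Pa)
#' @param model a `body_model`
#' @param target_nipple observed supine nipple (3-vector, m)
#' @param f skin factor
#' @param sim_config a `simulation_config`
#' @param calib_config a `calibration_config` (tau, friction)
#' @param details return the stop state as well
#' @return nipple distance (m), or a list when `details = TRUE`
#' @export
nipple_objective <- function(mu_B, model, target_nipple, f = 6,
                             sim_config = simulation_config(),
                             calib_config = calibration_config(),
                             details = FALSE) {
  g_B <- g_from_mu(mu_B)
  model$materials <- material_set(mu_B, f = f, g_B = g_B,
                                  tau = calib_config$tau)
  if (!is.null(model$contact))
    model$contact$friction <- calib_config$friction
  traj <- tryCatch(run_simulation(model, sim_config),
                   error = function(e)
                     stop("simulation failed at mu_B = ", mu_B, " Pa: ",
                          conditionMessage(e)))
  stop_state <- select_stop_state(traj, target_nipple)
  if (details)
    c(stop_state, list(distance = stop_state$nipple_distance,
                       trajectory = traj, g_B = g_B))
  else stop_state$nipple_distance
}

#' Bounded hybrid simulated annealing over mu_B
#'
#' Simulated annealing with Gaussian proposals clipped to the bounds,
#' geometric cooling and Metropolis acceptance, followed by a
#' golden-section refinement bracketing the annealing incumbent (the
#' "hybrid" step). Exits early as soon as the objective falls below the
#' stop threshold. Seeded and reproducible.
#'
#' @param objective function(mu) -> distance (m)
#' @param config a `calibration_config`
#' @return list: `mu` (incumbent, Pa), `value` (m), `evaluations`,
#'   `converged` (threshold reached), `history` (data frame of
#'   evaluations)
#' @export
anneal_mu <- function(objective, config = calibration_config()) {
  set.seed(config$seed)
  lo <- config$mu_bounds[1]; hi <- config$mu_bounds[2]
  thr <- config$stop_threshold
  evals <- 0
  hist_mu <- numeric(0); hist_val <- numeric(0)
  ev <- function(mu) {
    evals <<- evals + 1
    val <- objective(mu)
    hist_mu[evals] <<- mu; hist_val[evals] <<- val
    val
  }
  cur <- (lo + hi) / 2
  cur_val <- ev(cur)
  best <- cur; best_val <- cur_val
  temp <- config$sa_temp
  if (best_val > thr) {
    while (evals < config$sa_max_eval) {
      prop <- min(hi, max(lo, cur + stats::rnorm(1, 0, config$sa_sigma)))
      val <- ev(prop)
      if (val < best_val) { best <- prop; best_val <- val }
      if (best_val <= thr) break
      # Metropolis on the objective in mm to keep temperatures O(10)
      if (val <= cur_val ||
          stats::runif(1) < exp(-(val - cur_val) * 1e3 / temp)) {
        cur <- prop; cur_val <- val
      }
      temp <- temp * config$sa_cooling
    }
  }
  if (best_val > thr && config$golden_steps > 0) {
    # golden-section refinement around the incumbent
    gr <- (sqrt(5) - 1) / 2
    span <- min(config$sa_sigma, (hi - lo) / 4)
    a <- max(lo, best - span); b <- min(hi, best + span)
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- ev(x1); f2 <- ev(x2)
    for (k in seq_len(max(0, config$golden_steps - 2))) {
      if (min(f1, f2) <= thr) break
      if (f1 < f2) {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - gr * (b - a); f1 <- ev(x1)
      } else {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (b - a); f2 <- ev(x2)
      }
    }
    i <- which.min(hist_val)
    best <- hist_mu[i]; best_val <- hist_val[i]
  }
  list(mu = best, value = best_val, evaluations = evals,
       converged = best_val <= thr,
       history = data.frame(mu = hist_mu, value = hist_val))
}

#' Patient-specific material calibration
#'
#' Two-stage identification: simulated annealing over mu_B at the
#' default skin factor, then an exhaustive search over the skin-factor
#' candidates at the incumbent mu_B (ties broken toward the smaller f).
#'
#' @param model a `body_model`
#' @param target_nipple observed supine nipple position (3-vector, m)
#' @param config a `calibration_config`
#' @param sim_config a `simulation_config`
#' @param f_init skin factor used during the mu_B annealing stage
#' @return a `calibration_result`: `mu_B`, `g_B`, `f`, `distance` (m),
#'   `t_star` (s), `evaluations`, `seed`, `converged`
#' @export
calibrate <- function(model, target_nipple,
                      config = calibration_config(),
                      sim_config = simulation_config(), f_init = 6) {
  obj_f <- function(f) function(mu)
    nipple_objective(mu, model, target_nipple, f = f,
                     sim_config = sim_config, calib_config = config)
  sa <- anneal_mu(obj_f(f_init), config)
  evals <- sa$evaluations
  mu_star <- sa$mu

  fs <- config$f_candidates
  f_vals <- numeric(length(fs))
  for (i in seq_along(fs)) {
    f_vals[i] <- if (fs[i] == f_init) sa$value else obj_f(fs[i])(mu_star)
    if (fs[i] != f_init) evals <- evals + 1
  }
  i_best <- which.min(f_vals) # ties -> first = smaller f (sorted input)
  f_star <- fs[i_best]
  detail <- nipple_objective(mu_star, model, target_nipple, f = f_star,
                             sim_config = sim_config,
                             calib_config = config, details = TRUE)
  structure(list(mu_B = mu_star, g_B = g_from_mu(mu_star), f = f_star,
                 distance = f_vals[i_best], t_star = detail$t_star,
                 stop_index = detail$index,
                 displacement = detail$displacement,
                 evaluations = evals, seed = config$seed,
                 converged = f_vals[i_best] <= config$stop_threshold),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(paste0("calibration_result: mu_B = %.1f Pa (g_B = %.1f), ",
                     "f = %g\n  nipple distance %.2f mm at t* = %.3f s ",
                     "(%d evaluations, seed %d)\n"),
              x$mu_B, x$g_B, x$f, 1e3 * x$distance, x$t_star,
              x$evaluations, x$seed))
  invisible(x)
}
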
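#' Chest-wall contact specification
#'
#' @param mode `"sliding"` (penalty contact with Coulomb friction against
#'   the rigid chest wall, small-sliding anchor facets) or `"fixed"`
#'   (chest-interface nodes fully constrained).
#' @param friction Coulomb friction coefficient phi (default 0.5)
#' @param penalty_beta penalty scale: k = beta * m_node / dt^2 (default
#'   0.5; the central-difference stability bound for a contact spring
#'   alone is beta = 4, so 0.5 leaves ample margin while holding
#'   penetration well below 0.1 mm on the phantom)
#' @return a `contact_spec`
#' @export
contact_spec <- function(mode = c("sliding", "fixed"), friction = 0.5,
                         penalty_beta = 0.5) {
  mode <- match.arg(mode)
  if (friction < 0 || friction > 1.5) stop("friction must be in [0, 1.5]")
  if (penalty_beta <= 0) stop("penalty_beta must be > 0")
  structure(list(mode = mode, friction = friction,
                 penalty_beta = penalty_beta), class = "contact_spec")
}

#' Explicit simulation configuration
#'
#' The supine position is simulated by inverting the prone gravity load:
#' the default gravity vector is (0, -9.8, 0) m/s^2 in the internal frame
#' (y = posterior to anterior), pressing the breast toward the chest wall.
#'
#' @param gravity gravity vector (m/s^2)
#' @param total_time simulated time span (s), default 0.3
#' @param safety CFL safety factor in (0, 1], default 0.9
#' @param record_interval trajectory sampling interval (s), default 0.005
#' @param ramp_time if > 0, gravity is ramped linearly over this time;
#'   default 0 (instantaneous load, matching the no-pre-stress transient
#'   protocol)
#' @param damping mass-proportional damping coefficient (1/s), default 0
#'   (off); used only for quasi-static experiments
#' @param fbar use nodal-volume-averaged dilatation (F-bar type) to
#'   mitigate volumetric locking (default TRUE)
#' @param seed integer recorded with the trajectory for provenance
#' @return a `simulation_config`
#' @export
simulation_config <- function(gravity = c(0, -9.8, 0), total_time = 0.3,
                              safety = 0.9, record_interval = 0.005,
                              ramp_time = 0, damping = 0, fbar = TRUE,
                              seed = 1L) {
  if (total_time <= 0) stop("total_time must be > 0")
  if (safety <= 0 || safety > 1) stop("safety must be in (0, 1]")
  if (record_interval <= 0) stop("record_interval must be > 0")
  structure(list(gravity = as.numeric(gravity), total_time = total_time,
                 safety = safety, record_interval = record_interval,
                 ramp_time = ramp_time, damping = damping,
                 fbar = isTRUE(fbar), seed = as.integer(seed)),
            class = "simulation_config")
}

#' Dilatational wave speed of a material
#' @param mat a `material_params`
#' @return c = sqrt((K0 + 4 mu0 / 3) / rho) in m/s
#' @export
wave_speed <- function(mat) sqrt((mat$K0 + 4 * mat$mu0 / 3) / mat$rho)

# per-element material vectors from a material_set and region labels;
# tumor elements carry breast properties (two-tissue model)
element_materials <- function(mesh, materials) {
  is_skin <- mesh$regions == "skin"
  pick <- function(field) {
    b <- materials$breast[[field]]; s <- materials$skin[[field]]
    ifelse(is_skin, s, b)
  }
  pr_b <- materials$breast$prony
  pr_s <- materials$skin$prony
  g_b <- if (length(pr_b$g)) pr_b$g[1] else 0
  g_s <- if (length(pr_s$g)) pr_s$g[1] else 0
  tau_b <- if (length(pr_b$tau)) pr_b$tau[1] else 1
  tau_s <- if (length(pr_s$tau)) pr_s$tau[1] else 1
  if (length(pr_b$g) > 1 || length(pr_s$g) > 1)
    stop("the explicit solver supports a single-term Prony series")
  list(mu = pick("mu0"), K = pick("K0"), rho = pick("rho"),
       g = ifelse(is_skin, g_s, g_b), tau = ifelse(is_skin, tau_s, tau_b))
}

# characteristic element length: smallest altitude 3V/A_max, scaled by
# 0.75 because the maximum eigenfrequency of a lumped-mass constant-
# strain tetrahedron exceeds 2c/altitude by up to ~1/0.85 (measured on
# structured meshes); the margin keeps safety = 0.9 genuinely stable
element_char_length <- function(mesh) {
  n <- mesh$nodes; t4 <- mesh$tets
  vol <- tet_volumes(mesh)
  tri_area <- function(a, b, c3) {
    e1 <- n[b, , drop = FALSE] - n[a, , drop = FALSE]
    e2 <- n[c3, , drop = FALSE] - n[a, , drop = FALSE]
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    0.5 * sqrt(rowSums(cr^2))
  }
  amax <- pmax(tri_area(t4[, 1], t4[, 2], t4[, 3]),
               tri_area(t4[, 1], t4[, 2], t4[, 4]),
               tri_area(t4[, 2], t4[, 3], t4[, 4]),
               tri_area(t4[, 1], t4[, 3], t4[, 4]))
  0.75 * 3 * vol / amax
}

#' Stable explicit time step (CFL bound)
#'
#' dt = safety * min_e(L_e / c_e) with L_e the smallest element altitude
#' and c_e the dilatational wave speed of the element's material.
#'
#' @param mesh a `tet_mesh`
#' @param materials a `material_set`
#' @param safety safety factor in (0, 1]
#' @return time step (s)
#' @export
stable_timestep <- function(mesh, materials, safety = 0.9) {
  if (safety <= 0 || safety > 1) stop("safety must be in (0, 1]")
  em <- element_materials(mesh, materials)
  cel <- sqrt((em$K + 4 * em$mu / 3) / em$rho)
  safety * min(element_char_length(mesh) / cel)
}

#' Lumped (row-sum) nodal masses
#' @param mesh a `tet_mesh`
#' @param materials a `material_set`
#' @return numeric vector of nodal masses (kg)
#' @export
lumped_masses <- function(mesh, materials) {
  em <- element_materials(mesh, materials)
  vol <- tet_volumes(mesh)
  w <- em$rho * vol / 4
  m <- numeric(nrow(mesh$nodes))
  for (a in 1:4) {
    s <- rowsum(w, mesh$tets[, a])
    idx <- as.integer(rownames(s))
    m[idx] <- m[idx] + s[, 1]
  }
  m
}

#' Internal nodal forces for a displacement state
#'
#' Total-Lagrangian constant-gradient tetrahedra with nodal-volume-
#' averaged dilatation; forces sum to zero for self-equilibrated states
#' and vanish for rigid-body motion. When `dt > 0` and the material is
#' viscoelastic, the Prony internal variables are advanced one step.
#'
#' @param mesh a `tet_mesh`
#' @param materials a `material_set`
#' @param displacements nodal displacement matrix (n x 3, m)
#' @param viscous_state optional list with `s_el` and `history` matrices
#'   from a previous call (zeros otherwise)
#' @param dt time step for the viscous update (s); `0` for a purely
#'   elastic evaluation
#' @param fbar use nodal-averaged dilatation (default TRUE)
#' @return list: `forces` (n x 3), `viscous_state`, `strain_energy`
#' @export
internal_forces <- function(mesh, materials, displacements,
                            viscous_state = NULL, dt = 0, fbar = TRUE) {
  pre <- cpp_precompute(mesh$nodes, mesh$tets)
  em <- element_materials(mesh, materials)
  ne <- nrow(mesh$tets)
  if (is.null(viscous_state))
    viscous_state <- list(s_el = matrix(0, ne, 6),
                          history = matrix(0, ne, 6))
  out <- cpp_internal_forces(mesh$nodes, mesh$tets, pre$DmInv, pre$V0,
                             em$mu, em$K, em$g, em$tau,
                             as.matrix(displacements),
                             viscous_state$s_el, viscous_state$history,
                             dt, fbar)
  list(forces = out$forces,
       viscous_state = list(s_el = out$s_el, history = out$history),
       strain_energy = out$strain_energy)
}

#' Penalty contact forces against a rigid wall
#'
#' One-shot evaluation of the sliding-contact law used inside the
#' solver: for each node, the closest wall facet acts as the anchor;
#' penetration (negative gap along the facet normal, oriented toward
#' `body_side`) produces a penalty normal force k = beta * m / dt^2
#' times the depth, and the tangential offset from the anchor point
#' produces a friction force capped by the Coulomb cone
#' phi * ||normal force||.
#'
#' @param points deformed chest-interface node positions (n x 3, m)
#' @param wall rigid wall `tri_surface`
#' @param spec a `contact_spec` (mode must be `"sliding"`)
#' @param masses nodal masses (kg), length n
#' @param dt time step (s)
#' @param body_side optional point on the body's side of the wall, used
#'   to orient facet normals; if `NULL` the facet winding is trusted
#' @param anchors optional n x 3 matrix of small-sliding anchor points
#'   (where each node first touched the wall); defaults to the current
#'   closest points, which zeroes the tangential springs
#' @return n x 3 matrix of contact forces (N)
#' @export
contact_forces <- function(points, wall, spec, masses, dt,
                           body_side = NULL, anchors = NULL) {
  if (spec$mode != "sliding")
    stop("contact_forces applies to sliding mode; fixed mode constrains ",
         "the nodes instead")
  points <- matrix(as.numeric(points), ncol = 3)
  fn <- surface_face_normals(wall)
  out <- matrix(0, nrow(points), 3)
  k <- spec$penalty_beta * masses / dt^2
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    # anchor = closest facet
    best <- Inf; bq <- NULL; bt <- 0L
    for (t in seq_len(nrow(wall$faces))) {
      q <- closest_point_triangle(p, wall$vertices[wall$faces[t, 1], ],
                                  wall$vertices[wall$faces[t, 2], ],
                                  wall$vertices[wall$faces[t, 3], ])
      d <- sum((p - q)^2)
      if (d < best) { best <- d; bq <- q; bt <- t }
    }
    n <- fn[bt, ]
    if (!is.null(body_side) && sum((body_side - bq) * n) < 0) n <- -n
    if (!is.null(anchors)) bq <- as.numeric(anchors[i, ])
    gap <- sum((p - bq) * n)
    if (gap >= 0) next
    f_n <- -k[i] * gap
    tvec <- (p - bq) - gap * n
    f_t <- -k[i] * tvec
    cap <- spec$friction * f_n
    tl <- sqrt(sum(f_t^2))
    if (tl > cap && tl > 0) f_t <- f_t * cap / tl
    out[i, ] <- f_n * n + f_t
  }
  out
}

#' Run the explicit prone-to-supine simulation
#'
#' Central-difference dynamics with lumped masses. Boundary conditions:
#' `junction` nodes have u_x = 0, `superior_inferior` nodes u_z = 0;
#' with fixed-tie contact the `chest_interface` nodes are fully fixed,
#' with sliding contact they interact with the rigid chest wall through
#' penalty forces. Deterministic for a given model and configuration.
#'
#' @param model a `body_model` (see [make_breast_phantom()]), or a list
#'   with `mesh`, `chest_wall`, `materials`, `contact`, `landmarks`
#' @param config a `simulation_config`
#' @param initial_displacement optional n x 3 matrix of nodal
#'   displacements at t = 0 (released from rest); used for free-vibration
#'   verification experiments
#' @return a `trajectory`: sample `times`, displacement `snapshots`,
#'   `nipple` positions per sample, `energy` ledger (kinetic, strain,
#'   external work, internal work, viscous dissipation, max penetration)
#' @export
run_simulation <- function(model, config = simulation_config(),
                           initial_displacement = NULL) {
  mesh <- model$mesh
  materials <- model$materials
  pre <- cpp_precompute(mesh$nodes, mesh$tets)
  em <- element_materials(mesh, materials)
  dt_stable <- stable_timestep(mesh, materials, config$safety)
  nsteps <- max(1L, as.integer(ceiling(config$total_time / dt_stable)))
  dt <- config$total_time / nsteps

  nsamp <- floor(config$total_time / config$record_interval) + 1
  record_steps <- unique(as.integer(round(
    (seq_len(nsamp) - 1) * config$record_interval / dt)))
  record_steps <- pmin(record_steps, nsteps)

  ns <- mesh$node_sets
  fixed <- integer(0)
  contact_nodes <- integer(0)
  wall <- model$chest_wall
  if (is.null(model$contact) || model$contact$mode == "sliding") {
    contact_nodes <- as.integer(ns$chest_interface)
    cs <- if (is.null(model$contact)) contact_spec() else model$contact
  } else {
    fixed <- as.integer(ns$chest_interface)
    cs <- model$contact
  }
  if (is.null(wall) || !length(contact_nodes)) {
    wall_v <- matrix(0, 3, 3); wall_f <- matrix(1:3, 1, 3)
    contact_nodes <- integer(0)
  } else {
    wall_v <- wall$vertices; wall_f <- wall$faces
  }
  nipple_node <- as.integer(ns$nipple[1])
  if (is.na(nipple_node)) stop("model mesh must define a nipple node set")

  masses <- lumped_masses(mesh, materials)
  raw <- cpp_run_sim(mesh$nodes, mesh$tets, pre$DmInv, pre$V0,
                     em$mu, em$K, em$g, em$tau, masses,
                     config$gravity, dt, nsteps, record_steps,
                     as.integer(ns$junction %||% integer(0)),
                     as.integer(ns$superior_inferior %||% integer(0)),
                     fixed, contact_nodes, wall_v, wall_f,
                     cs$penalty_beta, cs$friction,
                     config$damping, nipple_node,
                     config$fbar %||% TRUE, config$ramp_time,
                     if (is.null(initial_displacement)) matrix(0, 0, 3)
                     else as.matrix(initial_displacement))
  energy <- raw$energy
  colnames(energy) <- c("kinetic", "strain", "work_external",
                        "work_internal", "dissipation", "max_penetration")
  structure(list(times = as.numeric(raw$times), snapshots = raw$snapshots,
                 nipple = raw$nipple, energy = energy,
                 max_penetration = raw$max_penetration,
                 dt = dt, config = config),
            class = "trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d samples over %.3f s (dt = %.2e s)\n",
              length(x$times), max(x$times), x$dt))
  invisible(x)
}

#' Select the stopping state of a trajectory
#'
#' Picks the sample whose simulated nipple position is closest to the
#' target (supine) nipple position; ties break toward the earliest time.
#'
#' @param traj a `trajectory`
#' @param target_nipple 3-vector (m), the observed supine nipple
#' @return list: `t_star`, `index`, `displacement` (snapshot matrix),
#'   `nipple_distance` (m)
#' @export
select_stop_state <- function(traj, target_nipple) {
  if (!length(traj$times)) stop("empty trajectory")
  d <- sqrt(rowSums(sweep(traj$nipple, 2, as.numeric(target_nipple))^2))
  i <- which.min(d) # which.min returns the first (earliest) minimum
  list(t_star = traj$times[i], index = i,
       displacement = traj$snapshots[[i]], nipple_distance = d[i])
}
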
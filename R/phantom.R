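#' Synthetic breast phantom specification
#'
#' Describes a parametric prone phantom: a half-ellipsoid breast body
#' resting on a planar chest wall (y = 0), a 1.5 mm extruded skin shell,
#' a spherical tumor inclusion, an apex nipple landmark and labelled
#' boundary node sets. The prone geometry is treated as the stress-free
#' reference configuration (no pre-stress).
#'
#' @param radii semi-axes (x, y, z) in metres; default 60/60/55 mm
#' @param skin_thickness skin shell thickness (m), default 1.5 mm
#' @param tumor_center tumor sphere centre (m); default offset 12 mm
#'   laterally at mid depth
#' @param tumor_radius tumor sphere radius (m), default 7.5 mm
#' @param edge target tetrahedral edge length (m), default 6 mm
#' @param chest_margin how far the rigid chest-wall plane extends past
#'   the breast footprint (m)
#' @param bilateral also build a bilateral prone surface with a flat
#'   intermammary strip (for alignment experiments)
#' @param strip_half_width intermammary strip half-width (m), bilateral
#'   surfaces only
#' @param jitter node jitter amplitude (m); must be < 0.1 * edge
#' @param seed RNG seed controlling the jitter
#' @return a `phantom_spec`
#' @export
phantom_spec <- function(radii = c(0.060, 0.060, 0.055),
                         skin_thickness = 1.5e-3,
                         tumor_center = c(0.012, 0.030, 0),
                         tumor_radius = 7.5e-3,
                         edge = 6e-3,
                         chest_margin = 0.015,
                         bilateral = FALSE,
                         strip_half_width = 0.015,
                         jitter = 3e-4, seed = 1L) {
  radii <- as.numeric(radii)
  if (length(radii) != 3 || any(radii <= 0)) stop("radii must be 3 positive")
  if (edge >= min(radii) / 4)
    stop("edge length must be < smallest semi-axis / 4")
  if (jitter >= 0.1 * edge) stop("jitter must be < 0.1 * edge length")
  rho_t <- sqrt(sum((tumor_center / radii)^2))
  # tumor strictly inside the body: centre margin covers the radius
  lim <- 1 - tumor_radius / min(radii)
  if (tumor_center[2] - tumor_radius <= 0 || rho_t >= lim)
    stop("tumor must lie strictly inside the breast body")
  structure(list(radii = radii, skin_thickness = skin_thickness,
                 tumor_center = as.numeric(tumor_center),
                 tumor_radius = tumor_radius, edge = edge,
                 chest_margin = chest_margin, bilateral = bilateral,
                 strip_half_width = strip_half_width,
                 jitter = jitter, seed = as.integer(seed)),
            class = "phantom_spec")
}

# "spiderweb" unit-disc triangulation: rings j = 0..m, ring j carries
# 6j vertices at radius j/m; near-equilateral and deterministic
disc_mesh <- function(m) {
  verts <- matrix(c(0, 0), 1, 2)
  ring_ids <- list(1L)
  for (j in seq_len(m)) {
    ang <- 2 * pi * (seq_len(6 * j) - 1) / (6 * j)
    ring_ids[[j + 1]] <- nrow(verts) + seq_len(6 * j)
    verts <- rbind(verts, (j / m) * cbind(cos(ang), sin(ang)))
  }
  faces <- NULL
  for (j in seq_len(m))
    faces <- rbind(faces, zip_rings(verts, ring_ids[[j]],
                                    ring_ids[[j + 1]]))
  # consistent counter-clockwise winding
  sa <- (verts[faces[, 2], 1] - verts[faces[, 1], 1]) *
    (verts[faces[, 3], 2] - verts[faces[, 1], 2]) -
    (verts[faces[, 3], 1] - verts[faces[, 1], 1]) *
    (verts[faces[, 2], 2] - verts[faces[, 1], 2])
  faces[sa < 0, c(2, 3)] <- faces[sa < 0, c(3, 2)]
  list(verts = verts, faces = faces, ring_ids = ring_ids)
}

# triangulate the annulus between two concentric vertex rings by a
# two-pointer angular sweep (ni + no triangles)
zip_rings <- function(verts, inner, outer) {
  no <- length(outer)
  if (length(inner) == 1L)
    return(cbind(inner, outer, outer[c(2:no, 1)]))
  ni <- length(inner)
  ai <- atan2(verts[inner, 2], verts[inner, 1])
  ao <- atan2(verts[outer, 2], verts[outer, 1])
  ai <- ifelse(ai < -1e-12, ai + 2 * pi, ai)
  ao <- ifelse(ao < -1e-12, ao + 2 * pi, ao)
  ai_u <- c(ai, ai[1] + 2 * pi)
  ao_u <- c(ao, ao[1] + 2 * pi)
  i <- 1L; o <- 1L; f <- 0L
  faces <- matrix(0L, ni + no, 3)
  while (i <= ni || o <= no) {
    adv_outer <- if (o > no) FALSE else if (i > ni) TRUE else
      ao_u[o + 1] <= ai_u[i + 1]
    f <- f + 1L
    cur_i <- inner[(i - 1L) %% ni + 1L]
    cur_o <- outer[(o - 1L) %% no + 1L]
    if (adv_outer) {
      faces[f, ] <- c(cur_i, cur_o, outer[o %% no + 1L])
      o <- o + 1L
    } else {
      faces[f, ] <- c(cur_i, cur_o, inner[i %% ni + 1L])
      i <- i + 1L
    }
  }
  faces[seq_len(f), , drop = FALSE]
}

#' Generate a prone breast phantom
#'
#' Builds the body model natively and deterministically: a spiderweb
#' disc triangulation is lifted onto the hemisphere (Lambert equal-area
#' lift), stacked into radially graded shells down to a central apex
#' (prisms split by the lowest-global-index diagonal rule, cone
#' tetrahedra at the core), and scaled to the ellipsoid semi-axes; a
#' skin shell is extruded from the curved outer surface, tumor elements
#' are labelled by a centroid-in-sphere test, and seeded jitter is
#' applied to interior nodes.
#'
#' @param spec a `phantom_spec`
#' @param materials a `material_set` attached to the model (default
#'   mu_B = 200 Pa, f = 6, purely hyperelastic until calibrated)
#' @param contact a `contact_spec` (default sliding, phi = 0.5)
#' @return a `body_model`: `mesh` (`tet_mesh`), `chest_wall`
#'   (`tri_surface`), `outer_surface` (skin outer surface referencing
#'   mesh nodes), `landmarks` (prone nipple), `materials`, `contact`,
#'   `spec`, and `bilateral_surface` if requested
#' @export
make_breast_phantom <- function(spec = phantom_spec(),
                                materials = material_set(200, f = 6),
                                contact = contact_spec()) {
  a <- spec$radii[1]; b <- spec$radii[2]; c3 <- spec$radii[3]
  h <- spec$edge
  rmax <- max(a, b, c3)

  # hemisphere surface: spiderweb disc lifted by the Lambert equal-area
  # map (colatitude theta = 2 asin(rho / sqrt(2)); equator stays y = 0)
  m <- max(2L, as.integer(round(pi * (a + c3) / 2 / (3 * h))))
  dm <- disc_mesh(m)
  rho <- sqrt(rowSums(dm$verts^2))
  theta <- 2 * asin(pmin(1, rho / sqrt(2)))
  phi <- atan2(dm$verts[, 2], dm$verts[, 1])
  dirs <- cbind(sin(theta) * cos(phi), cos(theta), sin(theta) * sin(phi))
  nv <- nrow(dirs)
  equator <- dm$ring_ids[[m + 1]]

  # radial shells graded geometrically so radial spacing tracks the
  # shrinking lateral edge; a cone of tets fills the core
  hn <- h / rmax
  gamma <- 1 - min(0.5, hn)
  radii_sh <- 1
  while (radii_sh[length(radii_sh)] * gamma > 2 * hn)
    radii_sh <- c(radii_sh, radii_sh[length(radii_sh)] * gamma)
  K <- length(radii_sh)
  nodes <- do.call(rbind, lapply(radii_sh, function(r)
    sweep(r * dirs, 2, c(a, b, c3), "*")))
  center_id <- K * nv + 1L
  nodes <- rbind(nodes, c(0, 0, 0))

  # prisms between consecutive shells, lowest-global-index diagonals
  tets <- NULL
  for (k in seq_len(K - 1)) {
    topo <- (k - 1L) * nv; boto <- k * nv
    tri <- dm$faces
    o <- t(apply(tri, 1, order))
    v0 <- tri[cbind(seq_len(nrow(tri)), o[, 1])]
    v1 <- tri[cbind(seq_len(nrow(tri)), o[, 2])]
    v2 <- tri[cbind(seq_len(nrow(tri)), o[, 3])]
    tets <- rbind(tets,
                  cbind(topo + v0, topo + v1, topo + v2, boto + v0),
                  cbind(topo + v1, topo + v2, boto + v0, boto + v1),
                  cbind(topo + v2, boto + v0, boto + v1, boto + v2))
  }
  inno <- (K - 1L) * nv
  tets <- rbind(tets, cbind(inno + dm$faces, center_id))

  # node sets: chest plane (equator rings + centre), medial junction
  # patch and superior/inferior strips on the outer shell
  chest_interface <- c(as.vector(vapply(seq_len(K) - 1L,
                                        function(k) k * nv + equator,
                                        integer(length(equator)))),
                       center_id)
  junction <- which(dirs[, 1] <= -0.75)
  superior_inferior <- which(abs(dirs[, 3]) >= 0.75)
  on_surface <- c(rep(TRUE, nv), rep(FALSE, (K - 1) * nv), TRUE)
  on_surface[chest_interface] <- TRUE

  # seeded jitter on free interior nodes (deterministic)
  if (spec$jitter > 0) {
    set.seed(spec$seed)
    interior <- which(!on_surface)
    jit <- matrix(stats::runif(3 * length(interior), -spec$jitter,
                               spec$jitter), ncol = 3)
    nodes[interior, ] <- nodes[interior, ] + jit
  }

  # orient tets positive (Kuhn tets start either-handed; decided on the
  # final node positions)
  vol6 <- tet_signed_vol(nodes, tets)
  neg <- vol6 < 0
  tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]

  regions <- rep("breast", nrow(tets))
  cen <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] + nodes[tets[, 3], ] +
            nodes[tets[, 4], ]) / 4
  in_tumor <- rowSums(sweep(cen, 2, spec$tumor_center)^2) <=
    spec$tumor_radius^2
  regions[in_tumor] <- "tumor"

  # curved outer surface = boundary faces off the chest plane
  body <- tet_mesh(nodes, tets, regions,
                   node_sets = list(chest_interface = chest_interface,
                                    junction = junction,
                                    superior_inferior = superior_inferior,
                                    nipple = 1L)) # placeholder, fixed below
  bs <- boundary_surface(body)
  fy <- cbind(nodes[bs$faces[, 1], 2], nodes[bs$faces[, 2], 2],
              nodes[bs$faces[, 3], 2])
  curved <- rowSums(fy < 1e-12) < 3
  outer_faces <- bs$faces[curved, , drop = FALSE]

  # extrude the skin shell on the curved patch and merge into the body
  sv <- sort(unique(as.vector(outer_faces)))
  svmap <- integer(nrow(nodes)); svmap[sv] <- seq_along(sv)
  patch <- tri_surface(nodes[sv, , drop = FALSE],
                       matrix(svmap[outer_faces], ncol = 3))
  shell <- extrude_skin(patch, spec$skin_thickness)
  nb <- nrow(nodes)
  npatch <- length(sv)
  all_nodes <- rbind(nodes, shell$mesh$nodes[npatch + seq_len(npatch), ,
                                             drop = FALSE])
  shell_tets <- shell$mesh$tets
  shell_tets_mapped <- shell_tets
  inner_sel <- shell_tets <= npatch
  shell_tets_mapped[inner_sel] <- sv[shell_tets[inner_sel]]
  shell_tets_mapped[!inner_sel] <- nb + (shell_tets[!inner_sel] - npatch)
  all_tets <- rbind(tets, shell_tets_mapped)
  all_regions <- c(regions, rep("skin", nrow(shell_tets_mapped)))

  outer_ids <- nb + seq_len(npatch)
  outer_faces_global <- matrix(outer_ids[svmap[outer_faces]], ncol = 3)

  # nipple: outer-skin node at the anterior apex
  apex <- c(0, b + spec$skin_thickness, 0)
  nip <- outer_ids[which.min(colSums((t(all_nodes[outer_ids, ]) - apex)^2))]

  # boundary sets extended onto coincident skin rim nodes
  rim_sets <- function(ids) {
    on <- ids
    for (id in seq_along(sv)) {
      if (sv[id] %in% ids) on <- c(on, nb + id)
    }
    sort(unique(on))
  }
  mesh <- tet_mesh(all_nodes, all_tets, all_regions,
                   node_sets = list(chest_interface = chest_interface,
                                    junction = rim_sets(junction),
                                    superior_inferior =
                                      rim_sets(superior_inferior),
                                    nipple = nip))

  # rigid chest wall: plane y = 0 extending past the breast footprint
  m <- spec$chest_margin
  wx <- c(-a - m, a + m); wz <- c(-c3 - m, c3 + m)
  wv <- as.matrix(expand.grid(x = seq(wx[1], wx[2], length.out = 3),
                              y = 0, z = seq(wz[1], wz[2], length.out = 3)))
  wv <- wv[, c("x", "y", "z")]
  wf <- NULL
  for (i in 1:2) for (j in 1:2) {
    v00 <- i + 3 * (j - 1); v10 <- i + 1 + 3 * (j - 1)
    v01 <- i + 3 * j; v11 <- i + 1 + 3 * j
    wf <- rbind(wf, c(v00, v10, v11), c(v00, v11, v01))
  }
  chest_wall <- tri_surface(wv, wf)

  landmarks <- landmark_set(list(nipple_prone = all_nodes[nip, ]))
  model <- structure(
    list(mesh = mesh, chest_wall = chest_wall,
         outer_surface = tri_surface(all_nodes, outer_faces_global),
         landmarks = landmarks, materials = materials, contact = contact,
         spec = spec),
    class = "body_model")
  if (spec$bilateral)
    model$bilateral_surface <- make_bilateral_surface(spec)
  model
}

tet_signed_vol <- function(nodes, tets) {
  a <- nodes[tets[, 2], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 3], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  c3 <- nodes[tets[, 4], , drop = FALSE] - nodes[tets[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) +
   a[, 2] * (b[, 3] * c3[, 1] - b[, 1] * c3[, 3]) +
   a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' @export
print.body_model <- function(x, ...) {
  cat("body_model\n")
  print(x$mesh)
  cat(sprintf("  nipple at (%.1f, %.1f, %.1f) mm\n",
              1e3 * x$landmarks$points$nipple_prone[1],
              1e3 * x$landmarks$points$nipple_prone[2],
              1e3 * x$landmarks$points$nipple_prone[3]))
  invisible(x)
}

#' Bilateral prone chest surface with intermammary strip
#'
#' Height-field surface: two mirrored ellipsoidal breast mounds over a
#' flat chest plane, with a flat strip of half-width `strip_half_width`
#' between them. Labels: `strip` (flat intermammary vertices),
#' `nipple_left`, `nipple_right` (apex vertex ids).
#'
#' @param spec a `phantom_spec`
#' @return a `tri_surface` with labels; jitter (spec$jitter / 3 on the
#'   height) makes no vertex star perfectly flat
#' @export
make_bilateral_surface <- function(spec = phantom_spec(bilateral = TRUE)) {
  a <- spec$radii[1]; b <- spec$radii[2]; c3 <- spec$radii[3]
  w <- spec$strip_half_width
  x0 <- a + w # breast centres at +/- x0
  h <- spec$edge
  xs <- seq(-(x0 + a), x0 + a, length.out = 2 * ceiling((x0 + a) / h) + 1)
  zs <- seq(-c3, c3, length.out = 2 * ceiling(c3 / h) + 1)
  gx <- rep(xs, times = length(zs))
  gz <- rep(zs, each = length(xs))
  # tensor-product dome with parabolic (finite-slope) feet: positive
  # over the full |z| < c band beneath each breast, so the only flat
  # interior region is the strip, and foot faces stay well-conditioned
  bump <- function(xc) {
    fx2 <- pmax(0, 1 - ((gx - xc) / a)^2)
    fz2 <- pmax(0, 1 - (gz / c3)^2)
    b * fx2 * fz2
  }
  y <- pmax(bump(-x0), bump(x0), 0)
  set.seed(spec$seed + 1L)
  y <- y + stats::runif(length(y), -spec$jitter / 3, spec$jitter / 3)
  nxg <- length(xs)
  verts <- cbind(gx, y, gz)
  faces <- NULL
  idx <- function(i, k) i + nxg * (k - 1)
  i <- rep(seq_len(nxg - 1), times = length(zs) - 1)
  k <- rep(seq_len(length(zs) - 1), each = nxg - 1)
  # wind so normals point along +y
  faces <- rbind(cbind(idx(i, k), idx(i, k + 1), idx(i + 1, k)),
                 cbind(idx(i + 1, k), idx(i, k + 1), idx(i + 1, k + 1)))
  # strip: flat intermammary vertices, excluding the surface boundary
  # (half-star normals there are unreliable for flatness tests)
  on_boundary <- abs(gx) >= max(abs(xs)) - 1e-12 |
    abs(gz) >= max(abs(zs)) - 1e-12
  # one-edge margin from the feet keeps every strip vertex's star flat
  strip <- which(abs(gx) <= w - h + 1e-12 &
                   pmax(bump(-x0), bump(x0)) < 1e-12 & !on_boundary)
  nip_l <- which.min((gx + x0)^2 + gz^2)
  nip_r <- which.min((gx - x0)^2 + gz^2)
  s <- tri_surface(verts, faces,
                   labels = list(strip = strip, nipple_left = nip_l,
                                 nipple_right = nip_r))
  s
}

#' Forward-simulate a supine ground truth
#'
#' Runs the explicit solver on a phantom with known material parameters
#' and returns the "observed" supine state at `sample_time`: the deformed
#' outer skin surface, the supine nipple position, the supine tumor
#' centroid (prone centroid carried through the displacement field), and
#' the full trajectory.
#'
#' @param model a `body_model`
#' @param mu_B true breast shear modulus (Pa), within [80, 400]
#' @param f true skin factor
#' @param config a `simulation_config`
#' @param sample_time time at which the supine state is extracted (s);
#'   default 0.16, the scale of the reported average stopping time
#' @param g_B Prony ratio; by default from the piecewise rule
#'   [g_from_mu()] when mu_B >= 160, else 0.8
#' @param tau relaxation time (s)
#' @return list: `surface`, `nipple`, `tumor_centroid`, `trajectory`,
#'   `sample_time`, `sample_index`, `mu_B`, `f`, `g_B`
#' @export
make_supine_truth <- function(model, mu_B = 220, f = 6,
                              config = simulation_config(),
                              sample_time = 0.16,
                              g_B = NULL, tau = 0.01) {
  if (mu_B < 80 || mu_B > 400)
    stop("true mu_B must be within [80, 400] Pa")
  if (is.null(g_B)) g_B <- if (mu_B >= 160) g_from_mu(mu_B) else 0.8
  model$materials <- material_set(mu_B, f = f, g_B = g_B, tau = tau)
  traj <- run_simulation(model, config)
  i <- which.min(abs(traj$times - sample_time))
  u <- traj$snapshots[[i]]
  prone_tumor <- region_centroid(model$mesh, "tumor")
  supine_tumor <- as.numeric(deform_points(model$mesh, u,
                                           matrix(prone_tumor, 1, 3)))
  surf <- model$outer_surface
  surf$vertices <- model$mesh$nodes + u
  list(surface = surf, nipple = as.numeric(traj$nipple[i, ]),
       tumor_centroid = supine_tumor, trajectory = traj,
       sample_time = traj$times[i], sample_index = i,
       mu_B = mu_B, f = f, g_B = g_B)
}
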
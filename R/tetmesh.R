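#' Tetrahedral volume mesh
#'
#' Four-node linear tetrahedra with per-element region labels and named
#' node sets. Node sets used by the solver: `junction` (u_x = 0),
#' `superior_inferior` (u_z = 0), `chest_interface` (contact or tie) and
#' `nipple` (exactly one node, tracked for the stopping criterion).
#'
#' @param nodes numeric matrix, one row per node (m)
#' @param tets integer matrix, one row per element, 1-based node ids
#' @param regions character vector per element (`"breast"`, `"skin"`,
#'   `"tumor"`)
#' @param node_sets named list of integer node-id vectors
#' @return a `tet_mesh`
#' @export
tet_mesh <- function(nodes, tets, regions = rep("breast", nrow(tets)),
                     node_sets = list()) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  tets <- as.matrix(tets); storage.mode(tets) <- "integer"
  dimnames(tets) <- NULL
  if (ncol(nodes) != 3L) stop("nodes must have 3 columns")
  if (ncol(tets) != 4L) stop("tets must have 4 columns")
  if (min(tets) < 1L || max(tets) > nrow(nodes))
    stop("tet node indices out of range")
  if (length(regions) != nrow(tets)) stop("one region label per element")
  for (nm in names(node_sets)) {
    ids <- node_sets[[nm]]
    if (any(ids < 1L | ids > nrow(nodes)))
      stop("node set '", nm, "' references invalid nodes")
  }
  if (!is.null(node_sets$nipple) && length(node_sets$nipple) != 1L)
    stop("nipple node set must contain exactly one node")
  m <- structure(list(nodes = nodes, tets = tets,
                      regions = as.character(regions),
                      node_sets = node_sets), class = "tet_mesh")
  vol <- tet_volumes(m)
  if (any(vol <= 0))
    stop("non-positive tetrahedron volume at elements: ",
         paste(utils::head(which(vol <= 0), 5), collapse = ", "))
  m
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tets\n", nrow(x$nodes), nrow(x$tets)))
  tab <- table(x$regions)
  cat("  regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (length(x$node_sets))
    cat("  node sets:",
        paste(sprintf("%s(%d)", names(x$node_sets),
                      lengths(x$node_sets)), collapse = ", "), "\n")
  invisible(x)
}

#' Signed volumes of all tetrahedra
#' @param mesh a `tet_mesh`
#' @return numeric vector (m^3)
#' @export
tet_volumes <- function(mesh) {
  n <- mesh$nodes; t4 <- mesh$tets
  a <- n[t4[, 2], , drop = FALSE] - n[t4[, 1], , drop = FALSE]
  b <- n[t4[, 3], , drop = FALSE] - n[t4[, 1], , drop = FALSE]
  c3 <- n[t4[, 4], , drop = FALSE] - n[t4[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) +
   a[, 2] * (b[, 3] * c3[, 1] - b[, 1] * c3[, 3]) +
   a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Boundary surface of a tetrahedral mesh
#'
#' Faces appearing in exactly one element, wound so normals point out of
#' the volume. Vertex indices refer to the parent mesh nodes.
#'
#' @param mesh a `tet_mesh`
#' @param elements optional element subset to extract the boundary of
#' @return a `tri_surface` whose vertices alias `mesh$nodes`
#' @export
boundary_surface <- function(mesh, elements = NULL) {
  t4 <- if (is.null(elements)) mesh$tets else
    mesh$tets[elements, , drop = FALSE]
  # outward-wound faces of tet (1,2,3,4) with positive volume
  fc <- rbind(t4[, c(1, 3, 2)], t4[, c(1, 2, 4)],
              t4[, c(2, 3, 4)], t4[, c(1, 4, 3)])
  key <- apply(fc, 1, function(r) paste(sort(r), collapse = "_"))
  cnt <- table(key)
  keep <- cnt[key] == 1
  tri_surface(mesh$nodes, fc[keep, , drop = FALSE])
}

#' Extrude a skin shell from a surface patch
#'
#' Offsets each vertex along its (area-weighted) outward normal by
#' `thickness` and fills the gap with one prism per triangle, each split
#' into three tetrahedra using the lowest-global-index diagonal rule so
#' neighbouring prisms share compatible diagonals and the meshing is
#' deterministic.
#'
#' @param surface a `tri_surface` patch with outward winding
#' @param thickness shell thickness (m); the skin layer default is
#'   1.5e-3 m
#' @return list with `mesh` (a `tet_mesh`, region `"skin"`; node sets
#'   `inner` and `outer`) and `outer` (the offset `tri_surface`)
#' @export
extrude_skin <- function(surface, thickness) {
  if (!is.numeric(thickness) || thickness <= 0)
    stop("thickness must be > 0")
  validate_surface(surface)
  nv <- nrow(surface$vertices)
  nrm <- surface_vertex_normals(surface)
  outer_v <- surface$vertices + thickness * nrm
  # self-intersection guard: offset must not flip any triangle
  outer_s <- tri_surface(outer_v, surface$faces)
  n0 <- surface_face_normals(surface)
  n1 <- face_cross(outer_s)
  flip <- rowSums(n0 * n1) <= 0
  if (any(flip))
    stop("offset surface self-intersects (curvature too high for ",
         "thickness) near vertices: ",
         paste(utils::head(unique(as.vector(surface$faces[flip, ])), 6),
               collapse = ", "))
  nodes <- rbind(surface$vertices, outer_v)
  tets <- matrix(0L, 3 * nrow(surface$faces), 4)
  for (i in seq_len(nrow(surface$faces))) {
    tri <- surface$faces[i, ]
    o <- order(tri)                  # global-index ordering fixes diagonals
    v0 <- tri[o[1]]; v1 <- tri[o[2]]; v2 <- tri[o[3]]
    tets[3 * i - 2, ] <- c(v0, v1, v2, v0 + nv)
    tets[3 * i - 1, ] <- c(v1, v2, v0 + nv, v1 + nv)
    tets[3 * i, ] <- c(v2, v0 + nv, v1 + nv, v2 + nv)
  }
  # orient for positive volume (ordering rule does not control sign)
  vol6 <- function(t4) {
    a <- nodes[t4[2], ] - nodes[t4[1], ]
    b <- nodes[t4[3], ] - nodes[t4[1], ]
    c3 <- nodes[t4[4], ] - nodes[t4[1], ]
    sum(a * c(b[2] * c3[3] - b[3] * c3[2], b[3] * c3[1] - b[1] * c3[3],
              b[1] * c3[2] - b[2] * c3[1]))
  }
  for (i in seq_len(nrow(tets)))
    if (vol6(tets[i, ]) < 0) tets[i, c(3, 4)] <- tets[i, c(4, 3)]
  mesh <- tet_mesh(nodes, tets, regions = rep("skin", nrow(tets)),
                   node_sets = list(inner = seq_len(nv),
                                    outer = nv + seq_len(nv)))
  list(mesh = mesh, outer = tri_surface(outer_v, surface$faces))
}

#' Interpolate a nodal displacement field at arbitrary points
#'
#' Locates each point in a tetrahedron (barycentric coordinates allowed
#' down to `-tol`) and interpolates linearly; exact for globally affine
#' fields.
#'
#' @param mesh a `tet_mesh` (reference configuration)
#' @param displacements numeric matrix, one row per node (m)
#' @param points numeric matrix, one row per query point (m)
#' @param tol barycentric tolerance for the inside test
#' @return matrix of displaced points (`points + u`)
#' @export
deform_points <- function(mesh, displacements, points, tol = 1e-9) {
  points <- matrix(as.numeric(points), ncol = 3)
  displacements <- as.matrix(displacements)
  loc <- locate_points(mesh, points, tol = tol)
  u <- matrix(0, nrow(points), 3)
  for (i in seq_len(nrow(points))) {
    nd <- mesh$tets[loc$element[i], ]
    u[i, ] <- as.numeric(loc$bary[i, ] %*%
                           displacements[nd, , drop = FALSE])
  }
  points + u
}

# point location by signed-volume barycentric coordinates
locate_points <- function(mesh, points, tol = 1e-9) {
  n <- mesh$nodes; t4 <- mesh$tets
  vol <- tet_volumes(mesh)
  # element AABBs for pre-filtering
  xs <- matrix(n[t4, 1], ncol = 4); ys <- matrix(n[t4, 2], ncol = 4)
  zs <- matrix(n[t4, 3], ncol = 4)
  lo <- cbind(apply(xs, 1, min), apply(ys, 1, min), apply(zs, 1, min))
  hi <- cbind(apply(xs, 1, max), apply(ys, 1, max), apply(zs, 1, max))
  pad <- tol + 1e-12
  elem <- integer(nrow(points)); bary <- matrix(0, nrow(points), 4)
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    cand <- which(p[1] >= lo[, 1] - pad & p[1] <= hi[, 1] + pad &
                  p[2] >= lo[, 2] - pad & p[2] <= hi[, 2] + pad &
                  p[3] >= lo[, 3] - pad & p[3] <= hi[, 3] + pad)
    found <- FALSE
    best <- -Inf; best_e <- NA_integer_
    for (e in cand) {
      nd <- t4[e, ]
      b <- tet_barycentric(n[nd[1], ], n[nd[2], ], n[nd[3], ], n[nd[4], ],
                           p, vol[e])
      m <- min(b)
      if (m > best) { best <- m; best_e <- e; bary_best <- b }
      if (m >= -tol) {
        elem[i] <- e; bary[i, ] <- b; found <- TRUE; break
      }
    }
    if (!found) {
      if (is.na(best_e) || best < -1e-6)
        stop(sprintf(paste0("point %d (%.4g, %.4g, %.4g) lies outside the ",
                            "mesh (nearest element %s, min barycentric ",
                            "%.3g)"), i, p[1], p[2], p[3],
                     ifelse(is.na(best_e), "none", best_e),
                     ifelse(is.finite(best), best, NA)))
      elem[i] <- best_e; bary[i, ] <- bary_best
    }
  }
  list(element = elem, bary = bary)
}

tet_barycentric <- function(a, b, c3, d, p, vol) {
  sv <- function(p1, p2, p3, p4) {
    u <- p2 - p1; v <- p3 - p1; w <- p4 - p1
    (u[1] * (v[2] * w[3] - v[3] * w[2]) +
     u[2] * (v[3] * w[1] - v[1] * w[3]) +
     u[3] * (v[1] * w[2] - v[2] * w[1])) / 6
  }
  c(sv(p, b, c3, d), sv(a, p, c3, d), sv(a, b, p, d), sv(a, b, c3, p)) / vol
}

#' Centroid of a labelled element region
#' @param mesh a `tet_mesh`
#' @param region region label, e.g. `"tumor"`
#' @return volume-weighted centroid (3-vector, m)
#' @export
region_centroid <- function(mesh, region) {
  sel <- mesh$regions == region
  if (!any(sel)) stop("no elements in region '", region, "'")
  t4 <- mesh$tets[sel, , drop = FALSE]
  vol <- tet_volumes(mesh)[sel]
  cen <- (mesh$nodes[t4[, 1], , drop = FALSE] +
          mesh$nodes[t4[, 2], , drop = FALSE] +
          mesh$nodes[t4[, 3], , drop = FALSE] +
          mesh$nodes[t4[, 4], , drop = FALSE]) / 4
  colSums(cen * vol) / sum(vol)
}
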
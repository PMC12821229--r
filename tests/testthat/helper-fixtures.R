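# fixtures built in code (no binary files)

# ASCII STL of the unit cube (12 triangles), coordinates in mm
write_unit_cube_stl <- function(path) {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  quads <- list(
    c(1, 3, 4, 2), c(5, 6, 8, 7),  # z = 0 (down), z = 1 (up)
    c(1, 2, 6, 5), c(3, 7, 8, 4),  # y faces
    c(1, 5, 7, 3), c(2, 4, 8, 6))  # x faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid cube", con)
  for (q in quads) {
    for (tri in list(q[c(1, 2, 3)], q[c(1, 3, 4)])) {
      writeLines("  facet normal 0 0 0", con)
      writeLines("    outer loop", con)
      for (k in tri)
        writeLines(sprintf("      vertex %g %g %g",
                           v[k, 1], v[k, 2], v[k, 3]), con)
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
  }
  writeLines("endsolid cube", con)
  invisible(path)
}

# Slicer markups JSON with given labels/positions (mm) and frame
write_markups_fixture <- function(path, labels, positions,
                                  frame = "RAS") {
  cps <- lapply(seq_along(labels), function(i)
    list(id = as.character(i), label = labels[[i]],
         position = positions[[i]]))
  doc <- list(markups = list(list(type = "Fiducial",
                                  coordinateSystem = frame,
                                  controlPoints = cps)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# one regular tetrahedron with positive volume, edge `a` (m)
regular_tet_mesh <- function(a = 0.006) {
  n <- a * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                 c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  tet_mesh(n, matrix(1:4, 1, 4))
}

# structured block mesh (Kuhn 6-tet split), dimensions in m
block_mesh <- function(lx = 0.06, ly = 0.02, lz = 0.02, h = 0.01,
                       regions = "breast") {
  xs <- seq(0, lx, by = h); ys <- seq(0, ly, by = h); zs <- seq(0, lz, by = h)
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  nid <- function(i, j, k) i + nx * (j - 1) + nx * ny * (k - 1)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cubes <- as.matrix(expand.grid(i = seq_len(nx - 1), j = seq_len(ny - 1),
                                 k = seq_len(nz - 1)))
  tets <- NULL
  for (p in seq_len(6)) {
    off <- matrix(0, 4, 3)
    for (k in 1:3) off[k + 1, ] <- off[k, ] + diag(3)[perms[p, k], ]
    tets <- rbind(tets, cbind(
      nid(cubes[, 1] + off[1, 1], cubes[, 2] + off[1, 2],
          cubes[, 3] + off[1, 3]),
      nid(cubes[, 1] + off[2, 1], cubes[, 2] + off[2, 2],
          cubes[, 3] + off[2, 3]),
      nid(cubes[, 1] + off[3, 1], cubes[, 2] + off[3, 2],
          cubes[, 3] + off[3, 3]),
      nid(cubes[, 1] + off[4, 1], cubes[, 2] + off[4, 2],
          cubes[, 3] + off[4, 3])))
  }
  vol6 <- function(t4) {
    a1 <- nodes[t4[, 2], ] - nodes[t4[, 1], ]
    b1 <- nodes[t4[, 3], ] - nodes[t4[, 1], ]
    c1 <- nodes[t4[, 4], ] - nodes[t4[, 1], ]
    a1[, 1] * (b1[, 2] * c1[, 3] - b1[, 3] * c1[, 2]) +
      a1[, 2] * (b1[, 3] * c1[, 1] - b1[, 1] * c1[, 3]) +
      a1[, 3] * (b1[, 1] * c1[, 2] - b1[, 2] * c1[, 1])
  }
  neg <- vol6(tets) < 0
  tets[neg, c(3, 4)] <- tets[neg, c(4, 3)]
  tet_mesh(nodes, tets, regions = rep(regions, nrow(tets)),
           node_sets = list(
             xmin = which(nodes[, 1] < 1e-12),
             ymin = which(nodes[, 2] < 1e-12),
             nipple = which.max(nodes[, 1] + nodes[, 2] + nodes[, 3])))
}

# random rotation matrix from a seed-controlled RNG state
random_rotation <- function(angle_max = pi) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, angle_max)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# default bilateral surface + nipple landmarks for alignment tests
bilateral_fixture <- function(seed = 1L) {
  spec <- phantom_spec(bilateral = TRUE, seed = seed)
  s <- make_bilateral_surface(spec)
  nips <- landmark_set(list(
    nipple_left = s$vertices[s$labels$nipple_left, ],
    nipple_right = s$vertices[s$labels$nipple_right, ]))
  list(surface = s, nipples = nips, spec = spec)
}
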
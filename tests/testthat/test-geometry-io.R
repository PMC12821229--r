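test_that("STL read: unit cube welds to 8 vertices, closed, volume 1 mm^3", {
  path <- withr::local_tempfile(fileext = ".stl")
  write_unit_cube_stl(path)
  s <- read_stl(path) # mm -> m
  expect_equal(nrow(s$vertices), 8)
  expect_equal(nrow(s$faces), 12)
  expect_equal(surface_volume(s), 1e-9, tolerance = 1e-12)
})

test_that("STL round-trip (binary and ASCII) preserves geometry to 1e-6 mm", {
  s <- make_icosphere(0.001, 2) # 2 mm bounding box in m
  for (bin in c(TRUE, FALSE)) {
    path <- withr::local_tempfile(fileext = ".stl")
    write_stl(s, path, binary = bin)
    s2 <- read_stl(path)
    expect_equal(nrow(s2$vertices), nrow(s$vertices))
    # welding may permute vertices; match by nearest neighbour
    d <- sqrt(rowSums((s$vertices -
                         s2$vertices[apply(s$vertices, 1, function(p)
                           which.min(colSums((t(s2$vertices) - p)^2))), ])^2))
    expect_lt(max(d), 1e-6 * 1e-3) # 1e-6 mm, in metres
  }
})

test_that("STL unit_scale is applied and malformed/empty files error", {
  s <- make_icosphere(0.001, 1)
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(s, path) # written in mm
  s_m <- read_stl(path, unit_scale = 1e-3)
  expect_equal(diff(range(s_m$vertices[, 1])), 0.002, tolerance = 1e-8)
  s_mm <- read_stl(path, unit_scale = 1)
  expect_equal(diff(range(s_mm$vertices[, 1])), 2, tolerance = 1e-5)

  bad <- withr::local_tempfile(fileext = ".stl")
  writeLines("not an stl at all, definitely not", bad)
  expect_error(read_stl(bad), "malformed")
  expect_error(read_stl(file.path(tempdir(), "missing.stl")), "not found")
})

test_that("markups reader: labels, units, frames, duplicate errors", {
  path <- withr::local_tempfile(fileext = ".mrk.json")
  write_markups_fixture(path, list("nipple"), list(c(10, 20, 30)))
  lm <- read_markups(path)
  expect_equal(landmark(lm, "nipple"), c(0.010, 0.020, 0.030))

  lps <- withr::local_tempfile(fileext = ".mrk.json")
  write_markups_fixture(lps, list("nipple"), list(c(10, 20, 30)),
                        frame = "LPS")
  expect_equal(landmark(read_markups(lps), "nipple"),
               c(-0.010, -0.020, 0.030))

  dup <- withr::local_tempfile(fileext = ".mrk.json")
  write_markups_fixture(dup, list("a", "a"), list(c(1, 2, 3), c(4, 5, 6)))
  expect_error(read_markups(dup), "duplicate")
})

test_that("markups round-trip through write_markups", {
  lm <- landmark_set(list(nipple_prone = c(0.01, 0.02, 0.03),
                          nipple_supine = c(-0.01, 0.005, 0.02)))
  path <- withr::local_tempfile(fileext = ".mrk.json")
  write_markups(lm, path)
  lm2 <- read_markups(path)
  expect_equal(landmark(lm2, "nipple_prone"), c(0.01, 0.02, 0.03),
               tolerance = 1e-12)
  expect_equal(landmark(lm2, "nipple_supine"), c(-0.01, 0.005, 0.02),
               tolerance = 1e-12)
})

test_that("extrude_skin: prism volumes, analytic sphere shell, errors", {
  # flat 10 x 10 mm patch, thickness 1.5 mm -> 150 mm^3 exactly
  v <- rbind(c(0, 0, 0), c(0.01, 0, 0), c(0.01, 0, 0.01), c(0, 0, 0.01))
  f <- rbind(c(1, 3, 2), c(1, 4, 3)) # +y normals
  patch <- tri_surface(v, f)
  shell <- extrude_skin(patch, 1.5e-3)
  expect_lt(abs(sum(tet_volumes(shell$mesh)) - 150e-9), 1e-18) # 1e-9 mm^3
  expect_true(all(shell$mesh$regions == "skin"))

  # sphere r = 50 mm, thickness 1.5 mm, ~6 mm edges
  sp <- make_icosphere(0.05, 3)
  sh <- extrude_skin(sp, 1.5e-3)
  analytic <- 4 / 3 * pi * (0.0515^3 - 0.05^3)
  expect_equal(sum(tet_volumes(sh$mesh)), analytic, tolerance = 0.02)

  expect_error(extrude_skin(patch, 0), "thickness")
  # concave valley (curvature radius 1 mm) offset by 2 mm: the offset
  # crosses the focal line and flips faces -> self-intersection error
  R <- 1e-3
  xs <- seq(-3e-3, 3e-3, by = 5e-4); zs <- seq(0, 3e-3, by = 5e-4)
  g <- expand.grid(x = xs, z = zs)
  vv <- cbind(g$x, g$x^2 / (2 * R), g$z)
  nx <- length(xs)
  idx <- function(i, k) i + nx * (k - 1)
  i <- rep(seq_len(nx - 1), times = length(zs) - 1)
  k <- rep(seq_len(length(zs) - 1), each = nx - 1)
  ff <- rbind(cbind(idx(i, k), idx(i, k + 1), idx(i + 1, k)),
              cbind(idx(i + 1, k), idx(i, k + 1), idx(i + 1, k + 1)))
  valley <- tri_surface(vv, ff)
  expect_error(extrude_skin(valley, 2e-3), "self-intersect")
})

test_that("extrude_skin area x thickness conservation on gentle curvature", {
  sp <- make_icosphere(0.05, 3) # radius 33x thickness
  sh <- extrude_skin(sp, 1.5e-3)
  expect_equal(sum(tet_volumes(sh$mesh)), surface_area(sp) * 1.5e-3,
               tolerance = 0.02)
})

test_that("geodesic distances: sources, chains, sphere arc, components", {
  s <- make_icosphere(1, 3)
  ip <- which.max(s$vertices[, 3])
  d <- geodesic_distance(s, ip)
  expect_identical(d[ip], 0)
  expect_true(all(d >= 0))
  ia <- which.min(s$vertices[, 3])
  expect_equal(d[ia], pi, tolerance = 0.03)

  # straight edge chain of total length 1
  v <- rbind(cbind(seq(0, 1, by = 0.25), 0, 0), c(0.5, 0.3, 0))
  f <- rbind(c(1, 2, 6), c(2, 3, 6), c(3, 4, 6), c(4, 5, 6))
  s2 <- tri_surface(v, f)
  expect_equal(geodesic_distance(s2, 1)[5], 1, tolerance = 1e-12)

  # disconnected component -> Inf
  two <- tri_surface(rbind(v, v + 10), rbind(f, f + 6))
  expect_true(all(is.infinite(geodesic_distance(two, 1)[7:12])))
  expect_error(geodesic_distance(s2, integer(0)), "non-empty")
})

test_that("geodesic single-source symmetry on a small mesh", {
  s <- make_icosphere(1, 1) # 42 vertices
  set.seed(7)
  pairs <- matrix(sample(nrow(s$vertices), 10), ncol = 2)
  for (r in seq_len(nrow(pairs))) {
    dab <- geodesic_distance(s, pairs[r, 1])[pairs[r, 2]]
    dba <- geodesic_distance(s, pairs[r, 2])[pairs[r, 1]]
    expect_equal(dab, dba, tolerance = 1e-12)
  }
})

test_that("deform_points: nodal exactness, affine completeness, oracle", {
  mesh <- block_mesh(0.03, 0.02, 0.02, h = 0.01)
  set.seed(11)
  u <- matrix(rnorm(3 * nrow(mesh$nodes), sd = 1e-3), ncol = 3)

  # point coincident with a node -> that node's displacement
  p <- mesh$nodes[17, , drop = FALSE]
  expect_equal(as.numeric(deform_points(mesh, u, p)),
               as.numeric(p + u[17, ]), tolerance = 1e-14)

  # affine field reproduced exactly
  A <- matrix(c(0.1, 0.02, -0.03, 0, 0.05, 0.01, 0.04, -0.02, 0.08), 3, 3)
  b <- c(1e-3, -2e-3, 5e-4)
  ua <- t(A %*% t(mesh$nodes)) + matrix(b, nrow(mesh$nodes), 3, byrow = TRUE)
  pts <- matrix(runif(30, 0.002, 0.018), ncol = 3)
  pts[, 1] <- pts[, 1] + 0.005
  got <- deform_points(mesh, ua, pts)
  expect_equal(got, pts + t(A %*% t(pts)) +
                 matrix(b, nrow(pts), 3, byrow = TRUE), tolerance = 1e-12)

  # random smooth field vs per-element shape-function oracle
  us <- cbind(sin(40 * mesh$nodes[, 1]), cos(30 * mesh$nodes[, 2]),
              mesh$nodes[, 3]^2) * 1e-3
  loc <- breastdeform:::locate_points(mesh, pts)
  for (i in seq_len(5)) {
    nd <- mesh$tets[loc$element[i], ]
    M <- cbind(1, mesh$nodes[nd, ])
    w <- as.numeric(solve(t(M), c(1, pts[i, ])))
    expect_equal(as.numeric(deform_points(mesh, us, pts[i, , drop = FALSE])),
                 pts[i, ] + as.numeric(w %*% us[nd, ]), tolerance = 1e-10)
  }

  # point far outside -> error
  expect_error(deform_points(mesh, u, c(1, 1, 1)), "outside")
})
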
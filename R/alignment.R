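#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1)
#' @param translation 3-vector (m)
#' @return a `rigid_transform`
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(t(rotation) %*% rotation - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points or a surface
#'
#' @param transform a `rigid_transform`
#' @param geometry an `n x 3` point matrix, 3-vector, `tri_surface` or
#'   `landmark_set`
#' @return transformed geometry of the same type
#' @export
apply_transform <- function(transform, geometry) {
  tx <- function(p) sweep(p %*% t(transform$rotation), 2,
                          transform$translation, "+")
  if (inherits(geometry, "tri_surface")) {
    geometry$vertices <- tx(geometry$vertices)
    geometry
  } else if (inherits(geometry, "landmark_set")) {
    geometry$points <- lapply(geometry$points,
                              function(p) as.numeric(tx(matrix(p, 1, 3))))
    geometry
  } else if (is.matrix(geometry)) {
    tx(geometry)
  } else {
    as.numeric(tx(matrix(as.numeric(geometry), 1, 3)))
  }
}

#' Compose two rigid transforms (t2 after t1)
#' @param t2,t1 `rigid_transform`s
#' @return the composition as a `rigid_transform`
#' @export
compose_transform <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) +
                    t2$translation)
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`
#' @return the inverse `rigid_transform`
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$rotation),
                  -as.numeric(t(transform$rotation) %*%
                                transform$translation))
}

# vertices on the open boundary of a surface patch (incident to an edge
# used by exactly one face); their half-star normals are unreliable
boundary_vertices <- function(surface) {
  f <- surface$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  open_e <- e[cnt[key] == 1, , drop = FALSE]
  unique(as.vector(open_e))
}

# vertex adjacency list of a surface
vertex_neighbors <- function(surface) {
  e <- surface_edges(surface)
  nb <- vector("list", nrow(surface$vertices))
  for (i in seq_len(nrow(e))) {
    nb[[e[i, 1]]] <- c(nb[[e[i, 1]]], e[i, 2])
    nb[[e[i, 2]]] <- c(nb[[e[i, 2]]], e[i, 1])
  }
  nb
}

#' Detect the intermammary patch on a bilateral prone surface
#'
#' Region-grows from the mid-point between the nipples, accepting
#' vertices whose normal deviates from the running patch-mean normal by
#' less than `threshold_deg` (default 10 degrees over the vertex star);
#' growth is restricted to the band between the two nipples.
#'
#' @param prone a bilateral `tri_surface`
#' @param nipples a `landmark_set` with `nipple_left` and `nipple_right`
#' @param threshold_deg flatness threshold in degrees
#' @return integer vector of patch vertex ids
#' @export
detect_intermammary <- function(prone, nipples, threshold_deg = 10) {
  nl <- landmark(nipples, "nipple_left")
  nr <- landmark(nipples, "nipple_right")
  v <- prone$vertices
  nrm <- surface_vertex_normals(prone)
  seedp <- (nl + nr) / 2
  seedp[2] <- min(v[, 2]) # drop to the chest plane between the breasts
  seed <- which.min(colSums((t(v) - seedp)^2))
  band <- v[, 1] > min(nl[1], nr[1]) & v[, 1] < max(nl[1], nr[1])
  if (!band[seed]) stop("no inter-breast band found: is the surface ",
                        "bilateral with both nipples?")
  mean_n <- nrm[seed, ]
  costhr <- cos(threshold_deg * pi / 180)
  flat <- band & (nrm %*% mean_n)[, 1] >= costhr
  flat[boundary_vertices(prone)] <- FALSE
  if (!flat[seed])
    stop("no flat region found at threshold ", threshold_deg,
         " degrees; try a larger threshold")
  nb <- vertex_neighbors(prone)
  inpatch <- logical(nrow(v))
  inpatch[seed] <- TRUE
  frontier <- seed
  while (length(frontier)) {
    cand <- unique(unlist(nb[frontier]))
    cand <- cand[!inpatch[cand] & flat[cand]]
    inpatch[cand] <- TRUE
    frontier <- cand
  }
  patch <- which(inpatch)
  if (length(patch) < 3)
    stop("intermammary patch too small at threshold ", threshold_deg,
         " degrees; try a larger threshold")
  patch
}

#' Transfer the intermammary boundary to the supine surface
#'
#' Reproduces the geodesic-radius rule: the patch consists of vertices
#' whose geodesic distance from each nipple exceeds that side's radius
#' (the prone nipple-to-boundary geodesic distance), restricted to the
#' band between the breasts.
#'
#' @param supine a bilateral `tri_surface`
#' @param nipples a `landmark_set` with `nipple_left`, `nipple_right`
#'   (positions on/near the supine surface)
#' @param radius_left,radius_right geodesic radii (m)
#' @return integer vector of patch vertex ids
#' @export
transfer_boundary <- function(supine, nipples, radius_left, radius_right) {
  v <- supine$vertices
  nl <- landmark(nipples, "nipple_left")
  nr <- landmark(nipples, "nipple_right")
  il <- which.min(colSums((t(v) - nl)^2))
  ir <- which.min(colSums((t(v) - nr)^2))
  dl <- geodesic_distance(supine, il)
  dr <- geodesic_distance(supine, ir)
  if (radius_left > max(dl[is.finite(dl)]) ||
      radius_right > max(dr[is.finite(dr)]))
    stop("geodesic radius exceeds the surface extent")
  band <- v[, 1] > min(v[il, 1], v[ir, 1]) &
    v[, 1] < max(v[il, 1], v[ir, 1])
  patch <- which(band & dl >= radius_left & dr >= radius_right)
  if (!length(patch))
    stop("empty transfer patch: geodesic radius too large")
  patch
}

# least-squares rigid fit (Kabsch) mapping source -> target
kabsch <- function(source, target) {
  cs <- colMeans(source); ct <- colMeans(target)
  H <- t(sweep(source, 2, cs)) %*% sweep(target, 2, ct)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.numeric(R %*% cs))
}

#' Point-based rigid registration (ICP with Kabsch inner step)
#'
#' Iterative closest point between two point patches: nearest-neighbour
#' correspondences, least-squares rigid fit, repeated until the mean
#' closest-point distance changes by less than `tol` (1e-6 m).
#' Initialization aligns centroids and principal axes. Optionally levels
#' the nipples afterwards by a pure z-translation (cranial-caudal
#' direction only).
#'
#' @param source point matrix (n x 3): prone patch, moving
#' @param target point matrix (m x 3): supine patch, fixed
#' @param level_nipples apply the nipple-levelling z-shift
#' @param nipple_source,nipple_target nipple positions (m) used when
#'   `level_nipples = TRUE`
#' @param max_iter maximum ICP iterations
#' @param tol convergence tolerance on the mean distance change (m)
#' @return a `rigid_transform` with attributes `residual` (final mean
#'   closest-point distance, m) and `converged`
#' @export
rigid_register <- function(source, target, level_nipples = FALSE,
                           nipple_source = NULL, nipple_target = NULL,
                           max_iter = 100, tol = 1e-6) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) < 3 || nrow(target) < 3)
    stop("need at least 3 points per patch")
  if (degenerate_patch(source) || degenerate_patch(target))
    stop("degenerate (collinear) patch")

  # initialization: centroids + principal axes (sign-disambiguated)
  init <- principal_axes_init(source, target)
  cur <- apply_transform(init, source)
  trans <- init
  prev_res <- Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    nn <- nearest_rows(cur, target)
    fit <- kabsch(cur, target[nn, , drop = FALSE])
    trans <- compose_transform(fit, trans)
    cur <- apply_transform(fit, cur)
    res <- mean(sqrt(rowSums((cur - target[nn, , drop = FALSE])^2)))
    if (abs(prev_res - res) < tol) { converged <- TRUE; break }
    prev_res <- res
  }
  if (!converged)
    warning("ICP did not converge in ", max_iter,
            " iterations; returning best transform")
  if (level_nipples) {
    if (is.null(nipple_source) || is.null(nipple_target))
      stop("nipple positions required for levelling")
    zs <- apply_transform(trans, nipple_source)[3]
    dz <- nipple_target[3] - zs
    trans$translation[3] <- trans$translation[3] + dz
  }
  attr(trans, "residual") <- prev_res
  attr(trans, "converged") <- converged
  trans
}

degenerate_patch <- function(p) {
  s <- svd(sweep(p, 2, colMeans(p)))$d
  s[2] < 1e-12 * max(s[1], 1e-300)
}

principal_axes_init <- function(source, target) {
  cs <- colMeans(source); ct <- colMeans(target)
  es <- eigen(stats::cov(source), symmetric = TRUE)$vectors
  et <- eigen(stats::cov(target), symmetric = TRUE)$vectors
  best <- NULL; best_res <- Inf
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    E <- es %*% diag(c(s1, s2, s1 * s2))
    R <- et %*% t(E)
    if (det(R) < 0) next
    tr <- rigid_transform(R, ct - as.numeric(R %*% cs))
    moved <- apply_transform(tr, source)
    nn <- nearest_rows(moved, target)
    res <- mean(rowSums((moved - target[nn, , drop = FALSE])^2))
    if (res < best_res) { best_res <- res; best <- tr }
  }
  best
}

# index of the nearest row of `pool` for each row of `query`
nearest_rows <- function(query, pool) {
  qn <- rowSums(query^2)
  pn <- rowSums(pool^2)
  d2 <- outer(qn, pn, "+") - 2 * query %*% t(pool)
  max.col(-d2, ties.method = "first")
}

#' Full prone-to-supine rigid alignment
#'
#' Runs the alignment stage end to end: detect the intermammary patch on
#' the prone surface, measure each nipple's geodesic distance to the
#' patch boundary, transfer the boundary to the supine surface by the
#' same geodesic radii, and register the prone patch onto the supine
#' patch (ICP), with optional cranial-caudal nipple levelling.
#'
#' @param prone,supine bilateral `tri_surface`s
#' @param prone_nipples,supine_nipples `landmark_set`s with
#'   `nipple_left`/`nipple_right`
#' @param threshold_deg flatness threshold for patch detection
#' @param level_nipples apply the z-levelling shift
#' @return a `rigid_transform` (prone -> supine) with a `residual`
#'   attribute
#' @export
align_prone_supine <- function(prone, supine, prone_nipples,
                               supine_nipples, threshold_deg = 10,
                               level_nipples = TRUE) {
  patch <- detect_intermammary(prone, prone_nipples, threshold_deg)
  v <- prone$vertices
  nl <- landmark(prone_nipples, "nipple_left")
  nr <- landmark(prone_nipples, "nipple_right")
  il <- which.min(colSums((t(v) - nl)^2))
  ir <- which.min(colSums((t(v) - nr)^2))
  dl <- geodesic_distance(prone, il)
  dr <- geodesic_distance(prone, ir)
  radius_left <- min(dl[patch]); radius_right <- min(dr[patch])
  spatch <- transfer_boundary(supine, supine_nipples, radius_left,
                              radius_right)
  ns <- landmark(supine_nipples, "nipple_left")
  rigid_register(v[patch, , drop = FALSE],
                 supine$vertices[spatch, , drop = FALSE],
                 level_nipples = level_nipples,
                 nipple_source = nl, nipple_target = ns)
}
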
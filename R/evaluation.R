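#' Euclidean tumor centroid distance
#'
#' @param estimated,reference tumor centroids (3-vectors, m), same frame
#' @return distance in millimetres
#' @export
tumor_distance <- function(estimated, reference) {
  estimated <- as.numeric(estimated); reference <- as.numeric(reference)
  if (!all(is.finite(c(estimated, reference))))
    stop("centroids must be finite")
  1e3 * sqrt(sum((estimated - reference)^2))
}

# closest point on a single triangle (Ericson's region test)
closest_point_triangle <- function(p, a, b, c3) {
  ab <- b - a; ac <- c3 - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + ab * d1 / (d1 - d3))
  cp <- p - c3
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c3)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + ac * d2 / (d2 - d6))
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + (c3 - b) * (d4 - d3) / ((d4 - d3) + (d5 - d6)))
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}

#' Closest point on a triangulated surface
#'
#' @param surface a `tri_surface`
#' @param point 3-vector (m)
#' @return the closest surface point (3-vector, m)
#' @export
project_to_surface <- function(surface, point) {
  if (!nrow(surface$faces)) stop("empty surface")
  point <- as.numeric(point)
  v <- surface$vertices; f <- surface$faces
  # prune with vertex distances: closest facet must touch the ball
  dv <- sqrt(colSums((t(v) - point)^2))
  fdmin <- pmin(dv[f[, 1]], dv[f[, 2]], dv[f[, 3]])
  cand <- which(fdmin <= min(fdmin) + max(sqrt(surface_face_areas(surface))))
  best <- NULL; best_d <- Inf
  for (i in cand) {
    q <- closest_point_triangle(point, v[f[i, 1], ], v[f[i, 2], ],
                                v[f[i, 3], ])
    d <- sum((q - point)^2)
    if (d < best_d) { best_d <- d; best <- q }
  }
  best
}

#' Tumor-skin projection distance
#'
#' Projects the estimated and reference tumor centroids onto the
#' deformed skin surface (closest point over all facets) and returns the
#' Euclidean distance between the two projections, a proxy for the
#' incision-planning error.
#'
#' @param estimated,reference tumor centroids (3-vectors, m)
#' @param skin_surface deformed outer `tri_surface`
#' @return distance in millimetres
#' @export
tumor_skin_projection_distance <- function(estimated, reference,
                                           skin_surface) {
  pe <- project_to_surface(skin_surface, estimated)
  pr <- project_to_surface(skin_surface, reference)
  1e3 * sqrt(sum((pe - pr)^2))
}

#' Evaluate a simulated supine state against a reference
#'
#' @param model the `body_model` that was simulated
#' @param stop_state output of [select_stop_state()] (or a displacement
#'   snapshot matrix)
#' @param reference_tumor reference supine tumor centroid (3-vector, m)
#' @param target_nipple observed supine nipple (3-vector, m), for the
#'   reported nipple residual
#' @return an `evaluation_report`: `tumor_distance_mm`,
#'   `tumor_skin_projection_mm`, `nipple_residual_mm`, `t_star`,
#'   `estimated_tumor` (m)
#' @export
evaluate_supine <- function(model, stop_state, reference_tumor,
                            target_nipple = NULL) {
  u <- if (is.matrix(stop_state)) stop_state else stop_state$displacement
  prone_tumor <- region_centroid(model$mesh, "tumor")
  est <- as.numeric(deform_points(model$mesh, u,
                                  matrix(prone_tumor, 1, 3)))
  skin <- model$outer_surface
  skin$vertices <- model$mesh$nodes + u
  td <- tumor_distance(est, reference_tumor)
  tsp <- tumor_skin_projection_distance(est, reference_tumor, skin)
  nres <- NA_real_
  if (!is.null(target_nipple) && !is.matrix(stop_state))
    nres <- 1e3 * stop_state$nipple_distance
  structure(list(tumor_distance_mm = td, tumor_skin_projection_mm = tsp,
                 nipple_residual_mm = nres,
                 t_star = if (is.matrix(stop_state)) NA_real_
                          else stop_state$t_star,
                 estimated_tumor = est),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("evaluation_report: tumor distance %.2f mm, ",
                     "tumor-skin projection %.2f mm\n"),
              x$tumor_distance_mm, x$tumor_skin_projection_mm))
  if (is.finite(x$nipple_residual_mm))
    cat(sprintf("  nipple residual %.2f mm at t* = %.3f s\n",
                x$nipple_residual_mm, x$t_star))
  invisible(x)
}
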
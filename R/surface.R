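#' Triangulated surface
#'
#' A `tri_surface` stores a triangle mesh as an `n x 3` matrix of vertex
#' coordinates (metres, internally) and an `m x 3` integer matrix of
#' 1-based vertex indices, plus optional named vertex subsets (`labels`).
#'
#' @param vertices numeric matrix, one row per vertex (x, y, z) in metres.
#' @param faces integer matrix, one row per triangle, 1-based vertex ids.
#' @param labels optional named list of integer vectors (vertex subsets).
#' @return An object of class `tri_surface`.
#' @export
tri_surface <- function(vertices, faces, labels = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  structure(list(vertices = vertices, faces = faces, labels = labels),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("tri_surface: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  if (length(x$labels))
    cat("  labels:", paste(names(x$labels), collapse = ", "), "\n")
  invisible(x)
}

face_cross <- function(surface) {
  v <- surface$vertices; f <- surface$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Per-face areas of a surface
#' @param surface a `tri_surface`
#' @return numeric vector of triangle areas (m^2)
#' @export
surface_face_areas <- function(surface) {
  cr <- face_cross(surface)
  0.5 * sqrt(rowSums(cr^2))
}

#' Total surface area
#' @param surface a `tri_surface`
#' @return total area (m^2)
#' @export
surface_area <- function(surface) sum(surface_face_areas(surface))

#' Signed enclosed volume of a closed surface
#'
#' Computed by the divergence theorem; positive when the winding is
#' consistently outward.
#' @param surface a `tri_surface`
#' @return signed volume (m^3)
#' @export
surface_volume <- function(surface) {
  v <- surface$vertices; f <- surface$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) +
      a[, 2] * (b[, 3] * c3[, 1] - b[, 1] * c3[, 3]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

#' Per-face unit normals
#' @param surface a `tri_surface`
#' @return matrix of unit normals, one row per face
#' @export
surface_face_normals <- function(surface) {
  cr <- face_cross(surface)
  nrm <- sqrt(rowSums(cr^2))
  if (any(nrm <= 0)) stop("degenerate (zero-area) triangle present")
  cr / nrm
}

#' Area-weighted per-vertex unit normals
#' @param surface a `tri_surface`
#' @return matrix of unit normals, one row per vertex
#' @export
surface_vertex_normals <- function(surface) {
  cr <- face_cross(surface)  # area-weighted face normals (2A n)
  n <- matrix(0, nrow(surface$vertices), 3)
  for (k in 1:3) {
    idx <- surface$faces[, k]
    n[, 1] <- n[, 1] + tapply_add(cr[, 1], idx, nrow(n))
    n[, 2] <- n[, 2] + tapply_add(cr[, 2], idx, nrow(n))
    n[, 3] <- n[, 3] + tapply_add(cr[, 3], idx, nrow(n))
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# scatter-add helper: sums vals by integer index into a length-n vector
tapply_add <- function(vals, idx, n) {
  out <- numeric(n)
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Edge list of a surface
#' @param surface a `tri_surface`
#' @return two-column integer matrix of unique undirected edges
#' @export
surface_edges <- function(surface) {
  f <- surface$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

validate_surface <- function(surface, check_closed = FALSE) {
  areas <- surface_face_areas(surface)
  if (any(areas <= 1e-18))
    stop("degenerate (zero-area) triangles at faces: ",
         paste(utils::head(which(areas <= 1e-18), 5), collapse = ", "))
  if (check_closed && surface_volume(surface) < 0)
    stop("closed surface has inward winding (negative signed volume)")
  invisible(surface)
}

## ---------------------------------------------------------------- STL I/O
## STL has no reader in the R stack used here, and the format is a fixed
## 50-byte-record binary / trivial ASCII layout, so it is read natively.

#' Read an STL surface (binary or ASCII, auto-detected)
#'
#' Duplicate vertices are welded exactly; coordinates are scaled from file
#' units into metres by `unit_scale` (default interprets files as mm).
#'
#' @param path path to an `.stl` file
#' @param unit_scale multiplicative scale applied to coordinates
#'   (default `1e-3`, millimetres to metres).
#' @return a `tri_surface`
#' @export
read_stl <- function(path, unit_scale = 1e-3) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (sz < 15) stop("malformed STL (file too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  head84 <- readBin(con, "raw", n = min(sz, 84))
  is_binary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(head84[81:84], "integer", size = 4, endian = "little")
    if (!is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)) is_binary <- TRUE
  }
  if (!is_binary) {
    lead <- rawToChar(head84[1:min(5, length(head84))])
    if (!grepl("^solid", lead, ignore.case = TRUE))
      stop("malformed STL at byte 0: neither binary (size mismatch) ",
           "nor ASCII 'solid' header")
  }
  tri <- if (is_binary) read_stl_binary(con, head84) else read_stl_ascii(path)
  if (nrow(tri) == 0) stop("empty STL mesh: ", path)
  weld_triangle_soup(tri * unit_scale)
}

read_stl_binary <- function(con, head84) {
  ntri <- readBin(head84[81:84], "integer", size = 4, endian = "little")
  # each record: normal (3f), 3 vertices (9f), 2-byte attribute
  raw <- readBin(con, "raw", n = 50 * ntri)
  if (length(raw) != 50 * ntri)
    stop("malformed STL at byte ", 84 + length(raw), ": truncated records")
  m <- matrix(raw, nrow = 50)
  vert_raw <- as.raw(m[13:48, ])             # skip normal, keep 9 floats
  vals <- readBin(vert_raw, "double", size = 4, n = 9 * ntri,
                  endian = "little")
  matrix(vals, ncol = 3, byrow = TRUE)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) return(matrix(numeric(0), 0, 3))
  parts <- strsplit(trimws(vl), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 4L)
  if (length(bad))
    stop("malformed ASCII STL: bad vertex line ", bad[1])
  vals <- vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))
  if (anyNA(vals)) stop("malformed ASCII STL: non-numeric vertex")
  t(vals)
}

# (3k x 3) triangle-soup vertices -> welded tri_surface
weld_triangle_soup <- function(vmat) {
  key <- paste(vmat[, 1], vmat[, 2], vmat[, 3], sep = "_")
  uid <- match(key, key[!duplicated(key)])
  verts <- vmat[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  tri_surface(verts, faces[keep, , drop = FALSE])
}

#' Write a surface to STL
#'
#' @param surface a `tri_surface`
#' @param path output path
#' @param unit_scale scale applied before writing (default `1e3`:
#'   metres to millimetres).
#' @param binary write binary STL (default) or ASCII.
#' @return `path`, invisibly
#' @export
write_stl <- function(surface, path, unit_scale = 1e3, binary = TRUE) {
  v <- surface$vertices * unit_scale
  f <- surface$faces
  n <- surface_face_normals(surface)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    # interleave: normal, v1, v2, v3 per triangle as float32 + attr
    block <- cbind(n, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                   v[f[, 3], , drop = FALSE])
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(block[i, ]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid surface", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9e %.9e %.9e",
                         n[i, 1], n[i, 2], n[i, 3]), con)
      writeLines("    outer loop", con)
      for (k in 1:3) {
        p <- v[f[i, k], ]
        writeLines(sprintf("      vertex %.9e %.9e %.9e",
                           p[1], p[2], p[3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid surface", con)
  }
  invisible(path)
}

#' Icosphere surface
#'
#' Recursive icosahedron subdivision; used by tests and phantoms that need
#' a near-uniform sphere triangulation.
#'
#' @param radius sphere radius (m)
#' @param subdivisions number of 4-to-1 refinement passes
#' @param center sphere centre
#' @return a closed `tri_surface` with outward winding
#' @export
make_icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env()
    newv <- list()
    getmid <- function(a, b) {
      k <- edge_key(a, b)
      if (!is.null(mids[[k]])) return(mids[[k]])
      p <- (v[a, ] + v[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      id <- nrow(v) + length(newv)
      mids[[k]] <- id
      id
    }
    fnew <- matrix(0L, 4 * nf, 3)
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- getmid(a, b); bc <- getmid(b, c3); ca <- getmid(c3, a)
      fnew[4 * i - 3, ] <- c(a, ab, ca)
      fnew[4 * i - 2, ] <- c(b, bc, ab)
      fnew[4 * i - 1, ] <- c(c3, ca, bc)
      fnew[4 * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- fnew
  }
  verts <- v * radius
  verts <- sweep(verts, 2, center, "+")
  tri_surface(verts, f)
}
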
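#' Named landmark set
#'
#' Stores labelled 3-D points (metres, internal frame) with a
#' coordinate-frame tag. Landmark names must be unique.
#'
#' @param points named list (or named 3-row-less matrix rows) of 3-vectors
#'   in metres.
#' @param frame coordinate frame tag, `"internal"` after loading.
#' @return a `landmark_set`
#' @export
landmark_set <- function(points, frame = "internal") {
  if (is.matrix(points)) {
    nm <- rownames(points)
    points <- lapply(seq_len(nrow(points)), function(i) points[i, ])
    names(points) <- nm
  }
  nm <- names(points)
  if (is.null(nm) || any(nm == "")) stop("all landmarks must be named")
  if (anyDuplicated(nm)) stop("duplicate landmark labels: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  pts <- lapply(points, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3 || !all(is.finite(p)))
      stop("landmark coordinates must be finite 3-vectors")
    p
  })
  structure(list(points = pts, frame = frame), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set (%s frame):\n", x$frame))
  for (nm in names(x$points))
    cat(sprintf("  %s: (%.4f, %.4f, %.4f) m\n", nm,
                x$points[[nm]][1], x$points[[nm]][2], x$points[[nm]][3]))
  invisible(x)
}

#' Read Slicer markups (.mrk.json) landmarks
#'
#' Parses the 3D Slicer markups dialect: a top-level `markups` list whose
#' entries carry `controlPoints` with `label` and `position`. Positions are
#' interpreted in millimetres and converted to metres. Files declaring an
#' LPS coordinate system are converted to the internal RAS-like frame by
#' negating x and y; the frame can be forced with `frame`.
#'
#' @param path path to a `.mrk.json` file
#' @param frame `"auto"` (honour the file's `coordinateSystem`), `"RAS"`,
#'   or `"LPS"`.
#' @param unit_scale scale from file units to metres (default mm -> m).
#' @return a `landmark_set` in the internal frame
#' @export
read_markups <- function(path, frame = "auto", unit_scale = 1e-3) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$markups)) stop("not a markups file (no 'markups' list)")
  pts <- list()
  for (mk in doc$markups) {
    file_frame <- if (frame != "auto") frame
      else if (!is.null(mk$coordinateSystem)) mk$coordinateSystem else "RAS"
    for (cp in mk$controlPoints) {
      if (is.null(cp$label) || is.null(cp$position))
        stop("control point missing label or position",
             if (!is.null(cp$label)) paste0(" (label '", cp$label, "')")
             else if (!is.null(cp$id)) paste0(" (id '", cp$id, "')") else "")
      p <- as.numeric(unlist(cp$position)) * unit_scale
      if (toupper(file_frame) == "LPS") p[1:2] <- -p[1:2]
      if (!is.null(pts[[cp$label]]))
        stop("duplicate landmark label: ", cp$label)
      pts[[cp$label]] <- p
    }
  }
  if (!length(pts)) stop("markups file contains no control points")
  landmark_set(pts, frame = "internal")
}

#' Write landmarks as a Slicer markups (.mrk.json) file
#'
#' @param landmarks a `landmark_set` (internal frame, metres)
#' @param path output path
#' @param frame `"RAS"` (written as-is) or `"LPS"` (x, y negated on write)
#' @param unit_scale scale from metres to file units (default m -> mm)
#' @return `path`, invisibly
#' @export
write_markups <- function(landmarks, path, frame = "RAS", unit_scale = 1e3) {
  cps <- lapply(names(landmarks$points), function(nm) {
    p <- landmarks$points[[nm]] * unit_scale
    if (toupper(frame) == "LPS") p[1:2] <- -p[1:2]
    list(id = nm, label = nm, position = p)
  })
  doc <- list(
    `@schema` = paste0("https://raw.githubusercontent.com/slicer/slicer/",
                       "master/Modules/Loadable/Markups/Resources/Schema/",
                       "markups-schema-v1.0.3.json"),
    markups = list(list(type = "Fiducial", coordinateSystem = frame,
                        controlPoints = cps)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Fetch one landmark by name
#' @param landmarks a `landmark_set`
#' @param name landmark label
#' @return numeric 3-vector (m)
#' @export
landmark <- function(landmarks, name) {
  p <- landmarks$points[[name]]
  if (is.null(p)) stop("no landmark named '", name, "'")
  p
}
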
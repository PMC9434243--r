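#' Landmark sets, osteophyte polygons and hip annotations
#'
#' A `landmark_set` holds the 85-point left-hip outline produced by the
#' point-placement step, together with the pixel spacing (mm per pixel) and a
#' `region_map` naming index subsets of the outline. Coordinates are in image
#' space: x to the right, y downwards, origin at the top-left. All distances
#' and areas reported by the package are in mm after pixel-spacing scaling.
#'
#' The outline convention (which of the 85 indices trace the superior femoral
#' head and which the acetabular sourcil) is not fixed by the package: the
#' `region_map` is part of the input. The synthetic generator ships a
#' documented default convention; annotations from other tools must supply
#' their own mapping.
#'
#' @param points An 85 x 2 numeric matrix (or data frame with columns `x`,
#'   `y`) of outline coordinates in pixels.
#' @param pixel_spacing Positive scalar, mm per pixel.
#' @param region_map Named list of integer index vectors (1-based) into the
#'   outline. Must contain at least `femoral_head_superior`,
#'   `acetabulum_sourcil` and `full_outline`; each region needs >= 2 indices
#'   within 1..85.
#' @return An object of class `landmark_set`.
#' @seealso [compute_mjsw()], [extract_region()], [read_landmark_file()]
#' @export
landmark_set <- function(points, pixel_spacing, region_map) {
  points <- as_xy_matrix(points, what = "landmark points")
  if (nrow(points) != 85L) {
    abort(sprintf("a landmark set must have exactly 85 points, got %d", nrow(points)),
          class = "rhoadx_format_error")
  }
  check_pixel_spacing(pixel_spacing)
  if (!is.list(region_map) || is.null(names(region_map)) || any(names(region_map) == "")) {
    abort("`region_map` must be a named list of index vectors", class = "rhoadx_format_error")
  }
  region_map <- lapply(region_map, function(idx) {
    idx <- as.integer(idx)
    if (length(idx) < 2L || anyNA(idx) || any(idx < 1L | idx > 85L)) {
      abort("each region needs >= 2 integer indices within 1..85",
            class = "rhoadx_format_error")
    }
    idx
  })
  structure(
    list(points = points, pixel_spacing = as.numeric(pixel_spacing),
         region_map = region_map),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set: 85 points, pixel spacing %.4g mm, regions: %s>\n",
              x$pixel_spacing, paste(names(x$region_map), collapse = ", ")))
  invisible(x)
}

#' Construct an osteophyte polygon
#'
#' Osteophytes are marked up as closed polygons at one of three hip sites:
#' the lateral acetabulum, the superolateral femoral head or the inferomedial
#' femoral head. The closing edge from the last vertex back to the first is
#' implicit; annotation tools commonly omit it.
#'
#' @param vertices An n x 2 numeric matrix (n >= 3) of polygon vertices in
#'   pixels, ordered along the boundary.
#' @param site One of `"acetabular"`, `"superior_femoral"`,
#'   `"inferior_femoral"`.
#' @param pixel_spacing Positive scalar, mm per pixel.
#' @return An object of class `osteophyte_polygon`.
#' @export
osteophyte_polygon <- function(vertices, site, pixel_spacing) {
  site <- match.arg(site, osteophyte_sites())
  vertices <- as_xy_matrix(vertices, what = "polygon vertices")
  check_pixel_spacing(pixel_spacing)
  if (nrow(vertices) < 3L) {
    abort("an osteophyte polygon needs at least 3 vertices",
          class = "rhoadx_degenerate_polygon")
  }
  if (polygon_self_intersects(vertices)) {
    abort(sprintf("self-intersecting %s osteophyte polygon", site),
          class = "rhoadx_invalid_polygon")
  }
  if (shoelace_area(vertices) == 0) {
    abort("polygon has zero area after closure", class = "rhoadx_degenerate_polygon")
  }
  structure(
    list(site = site, vertices = vertices, pixel_spacing = as.numeric(pixel_spacing)),
    class = "osteophyte_polygon"
  )
}

#' Valid osteophyte sites
#' @return Character vector of the three marked-up sites.
#' @export
osteophyte_sites <- function() {
  c("acetabular", "superior_femoral", "inferior_femoral")
}

#' Bundle one participant's hip annotation
#'
#' @param participant_id Participant identifier (coerced to character).
#' @param landmarks A [landmark_set()].
#' @param osteophytes List of 0-3 [osteophyte_polygon()]s, at most one per
#'   site. Absence of a polygon at a site means no osteophyte was marked.
#' @param qc_flag Image QC status. Anything other than `"ok"` excludes the
#'   record from grading.
#' @return An object of class `hip_annotation`.
#' @export
hip_annotation <- function(participant_id, landmarks, osteophytes = list(),
                           qc_flag = c("ok", "hip_not_fully_visualized",
                                       "poor_quality", "duplicate")) {
  qc_flag <- match.arg(qc_flag)
  stopifnot(inherits(landmarks, "landmark_set"))
  if (!all(vapply(osteophytes, inherits, logical(1), "osteophyte_polygon"))) {
    abort("`osteophytes` must be a list of osteophyte_polygon objects",
          class = "rhoadx_format_error")
  }
  sites <- vapply(osteophytes, `[[`, character(1), "site")
  if (anyDuplicated(sites)) {
    abort("at most one osteophyte polygon per site", class = "rhoadx_format_error")
  }
  structure(
    list(participant_id = as.character(participant_id), landmarks = landmarks,
         osteophytes = osteophytes, qc_flag = qc_flag),
    class = "hip_annotation"
  )
}

#' Osteophyte polygon area in mm^2
#'
#' Shoelace (surveyor's) area of the auto-closed polygon, scaled by the
#' squared pixel spacing. Orientation-independent.
#'
#' @param poly An [osteophyte_polygon()].
#' @return Enclosed area in mm^2.
#' @examples
#' sq <- osteophyte_polygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
#'                          "acetabular", pixel_spacing = 1)
#' polygon_area(sq) # 1
#' @export
polygon_area <- function(poly) {
  stopifnot(inherits(poly, "osteophyte_polygon"))
  shoelace_area(poly$vertices) * poly$pixel_spacing^2
}

# |sum of cross products| / 2 over the closed vertex cycle
shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Proper-crossing test between non-adjacent edges of the closed polygon.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  a <- v
  b <- v[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    # edge n is adjacent to edge 1
    if (i == 1L) js <- js[js != n]
    for (j in js) {
      if (segments_properly_cross(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

segments_properly_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Extract a named outline region in mm
#'
#' @param landmarks A [landmark_set()].
#' @param name Region name present in the landmark set's `region_map`.
#' @return A k x 2 matrix of coordinates in mm, in outline order.
#' @export
extract_region <- function(landmarks, name) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (!name %in% names(landmarks$region_map)) {
    abort(sprintf("unknown region '%s'; available: %s", name,
                  paste(names(landmarks$region_map), collapse = ", ")),
          class = "rhoadx_key_error")
  }
  landmarks$points[landmarks$region_map[[name]], , drop = FALSE] *
    landmarks$pixel_spacing
}

#' Superior minimum joint space width (mJSW) in mm
#'
#' The minimum distance between the superior femoral head margin and the
#' acetabular sourcil, each treated as an open polyline: the minimum over
#' point-to-segment distances in both directions (vertices of one curve
#' against segments of the other, and vice versa). Point-to-segment distance
#' is used rather than point-to-point so that sparse landmark sampling does
#' not overestimate the width.
#'
#' @param landmarks A [landmark_set()] whose `region_map` defines
#'   `femoral_head_superior` and `acetabulum_sourcil`.
#' @return mJSW in mm. Invariant under rigid motion of the annotation and
#'   proportional to `pixel_spacing`.
#' @export
compute_mjsw <- function(landmarks) {
  a <- extract_region(landmarks, "femoral_head_superior")
  b <- extract_region(landmarks, "acetabulum_sourcil")
  polyline_min_distance(a, b)
}

#' Minimum distance between two polylines
#'
#' @param a,b k x 2 coordinate matrices (k >= 2), vertices of open polylines.
#' @return The minimum Euclidean distance between the two polylines.
#' @keywords internal
#' @export
polyline_min_distance <- function(a, b) {
  a <- as_xy_matrix(a, what = "polyline"); b <- as_xy_matrix(b, what = "polyline")
  if (nrow(a) < 2L || nrow(b) < 2L) {
    abort("each curve needs at least 2 points", class = "rhoadx_degenerate_curve")
  }
  min(points_to_segments_min(a, b), points_to_segments_min(b, a))
}

# Vectorised min over all (point of P, segment of S) pairs.
points_to_segments_min <- function(p, s) {
  s1 <- s[-nrow(s), , drop = FALSE]
  s2 <- s[-1, , drop = FALSE]
  dx <- s2[, 1] - s1[, 1]
  dy <- s2[, 2] - s1[, 2]
  len2 <- dx^2 + dy^2
  best <- Inf
  for (k in seq_len(nrow(s1))) {
    wx <- p[, 1] - s1[k, 1]
    wy <- p[, 2] - s1[k, 2]
    t <- if (len2[k] > 0) pmin(1, pmax(0, (wx * dx[k] + wy * dy[k]) / len2[k])) else 0
    d2 <- (wx - t * dx[k])^2 + (wy - t * dy[k])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

as_xy_matrix <- function(x, what = "coordinates") {
  if (is.data.frame(x)) {
    if (!all(c("x", "y") %in% names(x))) {
      abort(sprintf("%s data frame needs columns x and y", what),
            class = "rhoadx_format_error")
    }
    x <- cbind(x$x, x$y)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L || !is.numeric(x) || anyNA(x)) {
    abort(sprintf("%s must be a numeric n x 2 matrix without NAs", what),
          class = "rhoadx_format_error")
  }
  storage.mode(x) <- "double"
  unname(x)
}

check_pixel_spacing <- function(pixel_spacing) {
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      is.na(pixel_spacing) || pixel_spacing <= 0) {
    abort("`pixel_spacing` must be a positive scalar (mm per pixel)",
          class = "rhoadx_format_error")
  }
  invisible(pixel_spacing)
}
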
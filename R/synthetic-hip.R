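#' Specification for a synthetic hip annotation
#'
#' Parametric left-hip geometry used to exercise the measurement pipeline:
#' the superior femoral head is an arc of a circle, the acetabular sourcil a
#' concentric arc offset radially so the minimum polyline distance between
#' the two sampled curves equals the target mJSW (a chord-sagitta correction
#' is applied so the identity holds at the sampled resolution, not just in
#' the continuum limit). Remaining outline points fill the femoral neck and
#' shaft. Osteophyte polygons are star-shaped 12-gons scaled to the target
#' area exactly.
#'
#' @param mjsw_mm Target superior minimum joint space width (mm, >= 0).
#' @param head_radius_mm Femoral head radius (mm, > 0).
#' @param noise_sd_mm Gaussian landmark jitter (mm) applied to outline
#'   points; osteophyte polygons are re-scaled to the exact target area
#'   after jitter.
#' @param osteophyte_areas_mm2 Named vector of target areas (mm^2) for any
#'   subset of [osteophyte_sites()]; 0 or absent means no polygon.
#' @param pixel_spacing mm per pixel of the emulated image.
#' @param seed Integer seed; the annotation is deterministic given the spec.
#' @param participant_id Identifier carried into the annotation.
#' @return An object of class `synthetic_hip_spec`.
#' @export
synthetic_hip_spec <- function(mjsw_mm = 2.89, head_radius_mm = 25,
                               noise_sd_mm = 0, osteophyte_areas_mm2 = numeric(),
                               pixel_spacing = 0.25, seed = 1L,
                               participant_id = "synthetic-hip") {
  if (mjsw_mm < 0) abort("target mJSW must be >= 0", class = "rhoadx_domain_error")
  if (head_radius_mm <= 0) abort("head radius must be > 0", class = "rhoadx_domain_error")
  if (noise_sd_mm < 0) abort("noise sd must be >= 0", class = "rhoadx_domain_error")
  if (length(osteophyte_areas_mm2)) {
    bad <- setdiff(names(osteophyte_areas_mm2), osteophyte_sites())
    if (length(bad) || is.null(names(osteophyte_areas_mm2))) {
      abort("osteophyte_areas_mm2 must be named by site", class = "rhoadx_key_error")
    }
    if (any(osteophyte_areas_mm2 < 0)) {
      abort("osteophyte areas must be >= 0", class = "rhoadx_domain_error")
    }
  }
  check_pixel_spacing(pixel_spacing)
  structure(
    list(mjsw_mm = mjsw_mm, head_radius_mm = head_radius_mm,
         noise_sd_mm = noise_sd_mm, osteophyte_areas_mm2 = osteophyte_areas_mm2,
         pixel_spacing = pixel_spacing, seed = as.integer(seed),
         participant_id = participant_id),
    class = "synthetic_hip_spec"
  )
}

#' Default outline region convention of the synthetic generator
#'
#' Indices (1-based) into the 85-point outline: points 1-32 trace the
#' superior femoral head margin, 33-64 the acetabular sourcil, 65-85 the
#' femoral neck and proximal shaft. Real-data users must supply the mapping
#' that matches their annotation tool.
#'
#' @return Named list of integer index vectors.
#' @export
default_region_map <- function() {
  list(femoral_head_superior = 1:32,
       acetabulum_sourcil = 33:64,
       full_outline = 1:85)
}

#' Generate a synthetic hip annotation
#'
#' @param spec A [synthetic_hip_spec()].
#' @param qc_flag QC status to stamp on the annotation (default `"ok"`).
#' @return A [hip_annotation()]; with `noise_sd_mm = 0`, [compute_mjsw()] on
#'   it returns the target mJSW to about 1e-6 mm and [polygon_area()] the
#'   target areas to machine precision.
#' @export
generate_synthetic_hip <- function(spec, qc_flag = "ok") {
  stopifnot(inherits(spec, "synthetic_hip_spec"))
  with_seed(spec$seed, {
    centre <- c(35, 40) # head centre, mm from image origin
    k <- 32L
    theta <- seq(50, 130, length.out = k) * pi / 180
    step <- diff(theta[1:2])
    r <- spec$head_radius_mm
    # radial offset corrected for the sagitta of the outer arc's chords, so
    # the sampled polylines sit exactly mjsw apart
    R <- r + spec$mjsw_mm / cos(step / 2)
    head_arc <- cbind(centre[1] + r * cos(theta), centre[2] - r * sin(theta))
    sourcil <- cbind(centre[1] + R * cos(theta), centre[2] - R * sin(theta))
    # neck/shaft filler: two strokes running inferolaterally from the head
    t21 <- seq(0, 1, length.out = 21L)
    neck <- cbind(centre[1] + 5 + 25 * t21, centre[2] + r - 4 + 45 * t21)
    pts_mm <- rbind(head_arc, sourcil, neck)
    if (spec$noise_sd_mm > 0) {
      pts_mm <- pts_mm + matrix(rnorm(length(pts_mm), sd = spec$noise_sd_mm),
                                ncol = 2)
    }
    lm <- landmark_set(pts_mm / spec$pixel_spacing, spec$pixel_spacing,
                       default_region_map())
    anchors <- list(
      acetabular = centre + c((R + 4) * cos(theta[1]), -(R + 4) * sin(theta[1])),
      superior_femoral = centre + c(r * cos(110 * pi / 180) - 2,
                                    -r * sin(110 * pi / 180) - 3),
      inferior_femoral = centre + c(-r + 2, 12)
    )
    polys <- list()
    areas <- spec$osteophyte_areas_mm2
    for (site in names(areas)) {
      if (areas[[site]] <= 0) next
      polys[[length(polys) + 1L]] <- synth_blob(
        anchors[[site]], areas[[site]], spec$noise_sd_mm, site, spec$pixel_spacing)
    }
    hip_annotation(spec$participant_id, lm, polys, qc_flag = qc_flag)
  })
}

# Star-shaped 12-gon around `centre` scaled to enclose exactly `area` mm^2.
synth_blob <- function(centre, area, noise_sd, site, pixel_spacing) {
  ang <- seq(0, 2 * pi, length.out = 13L)[-13L]
  rad <- 1 + 0.25 * sin(3 * ang + runif(1, 0, 2 * pi))
  if (noise_sd > 0) rad <- pmax(0.3, rad + rnorm(12L, sd = 0.1))
  v <- cbind(cos(ang) * rad, sin(ang) * rad)
  v <- v * sqrt(area / shoelace_area(v))
  v <- sweep(v, 2, centre, "+")
  osteophyte_polygon(v / pixel_spacing, site, pixel_spacing)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
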
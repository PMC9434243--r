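#' Grading configuration
#'
#' All thresholds used to turn continuous measurements into semi-quantitative
#' grades, as a single versioned object. Area thresholds are inclusive lower
#' bounds (grade = largest threshold not exceeding the area); mJSW cut-offs
#' are inclusive upper bounds.
#'
#' Defaults: osteophyte grade 1 at >= 1 mm^2 everywhere; grade 2 at >= 10
#' (acetabular), >= 19 (superior femoral) and >= 15 (inferior femoral) mm^2;
#' grade 3 at >= 50 mm^2. JSN grade 3 at raw mJSW <= 1.5 mm; grades 1 and 2
#' from height-adjusted mJSW, with default cuts at the 20th (2.301 mm) and
#' 5th (1.739 mm) percentiles of a Normal(2.89, 0.7) reference adjusted-mJSW
#' distribution. The composite sum-to-grade map is
#' 0 -> 0, 1 -> 1, 2-3 -> 2, 4-6 -> 3, 7-12 -> 4.
#'
#' The per-site grade-2 thresholds, the height model and the JSN percentile
#' cuts are calibration assumptions (see the package vignette) and should be
#' replaced when a reference calibration is available.
#'
#' @param osteophyte_grade1_mm2,osteophyte_grade2_mm2 Named numeric vectors
#'   of per-site thresholds (names: the three [osteophyte_sites()]).
#' @param osteophyte_grade3_mm2 Scalar grade-3 area threshold.
#' @param jsn_grade3_mjsw_mm Raw-mJSW cut for JSN grade 3 (inclusive).
#' @param jsn_grade1_adjusted_cut,jsn_grade2_adjusted_cut Height-adjusted
#'   mJSW cuts (inclusive) for JSN grades 1 and 2; grade2 cut < grade1 cut.
#' @param composite_cuts Integer vector of length 13 mapping grade sums
#'   0..12 to composite rHOA grades 0..4.
#' @param height_model List with `slope_mm_per_cm` and `reference_height_cm`
#'   for the linear mJSW-on-height adjustment.
#' @param config_version Version string embedded in serialized output.
#' @return An object of class `grading_config`.
#' @export
grading_config <- function(
    osteophyte_grade1_mm2 = c(acetabular = 1, superior_femoral = 1, inferior_femoral = 1),
    osteophyte_grade2_mm2 = c(acetabular = 10, superior_femoral = 19, inferior_femoral = 15),
    osteophyte_grade3_mm2 = 50,
    jsn_grade3_mjsw_mm = 1.5,
    jsn_grade1_adjusted_cut = 2.301,
    jsn_grade2_adjusted_cut = 1.739,
    composite_cuts = c(0, 1, 2, 2, 3, 3, 3, 4, 4, 4, 4, 4, 4),
    height_model = list(slope_mm_per_cm = 0.012, reference_height_cm = 170.1),
    config_version = "rhoa_v1") {
  sites <- osteophyte_sites()
  g1 <- as_site_vector(osteophyte_grade1_mm2, sites, "osteophyte_grade1_mm2")
  g2 <- as_site_vector(osteophyte_grade2_mm2, sites, "osteophyte_grade2_mm2")
  g3 <- as.numeric(osteophyte_grade3_mm2)
  if (any(!(g1 < g2 & g2 < g3))) {
    abort("per-site thresholds must satisfy grade1 < grade2 < grade3",
          class = "rhoadx_config_error")
  }
  if (!(jsn_grade2_adjusted_cut < jsn_grade1_adjusted_cut)) {
    abort("jsn_grade2_adjusted_cut must be below jsn_grade1_adjusted_cut",
          class = "rhoadx_config_error")
  }
  composite_cuts <- as.integer(composite_cuts)
  if (length(composite_cuts) != 13L || anyNA(composite_cuts) ||
      any(composite_cuts < 0L | composite_cuts > 4L) ||
      is.unsorted(composite_cuts)) {
    abort("composite_cuts must be 13 non-decreasing grades in 0..4 for sums 0..12",
          class = "rhoadx_config_error")
  }
  if (!is.list(height_model) ||
      !all(c("slope_mm_per_cm", "reference_height_cm") %in% names(height_model))) {
    abort("height_model needs slope_mm_per_cm and reference_height_cm",
          class = "rhoadx_config_error")
  }
  structure(
    list(osteophyte_grade1_mm2 = g1, osteophyte_grade2_mm2 = g2,
         osteophyte_grade3_mm2 = g3, jsn_grade3_mjsw_mm = as.numeric(jsn_grade3_mjsw_mm),
         jsn_grade1_adjusted_cut = as.numeric(jsn_grade1_adjusted_cut),
         jsn_grade2_adjusted_cut = as.numeric(jsn_grade2_adjusted_cut),
         composite_cuts = composite_cuts,
         height_model = lapply(height_model, as.numeric),
         config_version = as.character(config_version)),
    class = "grading_config"
  )
}

as_site_vector <- function(x, sites, what) {
  if (length(x) == 1L && is.null(names(x))) x <- setNames(rep(as.numeric(x), 3L), sites)
  if (!all(sites %in% names(x))) {
    abort(sprintf("%s must name all sites: %s", what, paste(sites, collapse = ", ")),
          class = "rhoadx_config_error")
  }
  as.numeric(x[sites]) |> setNames(sites)
}

#' @export
print.grading_config <- function(x, ...) {
  cat(sprintf("<grading_config %s>\n", x$config_version))
  cat(sprintf("  osteophyte mm^2 thresholds (g1/g2/g3): %s / %s / %g\n",
              paste(x$osteophyte_grade1_mm2, collapse = ","),
              paste(x$osteophyte_grade2_mm2, collapse = ","),
              x$osteophyte_grade3_mm2))
  cat(sprintf("  JSN: grade3 raw <= %g mm; adjusted cuts g1 <= %g, g2 <= %g mm\n",
              x$jsn_grade3_mjsw_mm, x$jsn_grade1_adjusted_cut, x$jsn_grade2_adjusted_cut))
  cat(sprintf("  composite sum->grade: %s\n", paste(x$composite_cuts, collapse = "")))
  invisible(x)
}

#' Grade an osteophyte from its area
#'
#' Grade 0 below 1 mm^2 (default), then the largest grade whose per-site
#' threshold does not exceed the area; all thresholds inclusive.
#'
#' @param area_mm2 Non-negative area(s) in mm^2 (vectorised).
#' @param site One of [osteophyte_sites()].
#' @param cfg A [grading_config()].
#' @return Integer grade(s) 0-3.
#' @examples
#' grade_osteophyte(c(0.5, 1, 12, 50), "acetabular", grading_config())
#' @export
grade_osteophyte <- function(area_mm2, site, cfg = grading_config()) {
  site <- match.arg(site, osteophyte_sites())
  stopifnot(inherits(cfg, "grading_config"))
  if (any(is.na(area_mm2)) || any(area_mm2 < 0)) {
    abort("osteophyte area must be non-negative", class = "rhoadx_domain_error")
  }
  (area_mm2 >= cfg$osteophyte_grade1_mm2[[site]]) +
    (area_mm2 >= cfg$osteophyte_grade2_mm2[[site]]) +
    (area_mm2 >= cfg$osteophyte_grade3_mm2)
}

#' Height-adjust a raw mJSW measurement
#'
#' Linear mean-adjustment: `adjusted = raw - slope * (height - reference)`.
#' At the reference height the adjusted value equals the raw value. A missing
#' height falls back to the raw value with a warning, so the record is graded
#' on unadjusted mJSW.
#'
#' @param mjsw_mm Raw mJSW in mm (vectorised).
#' @param height_cm Standing height in cm (vectorised or scalar; NA allowed).
#' @param cfg A [grading_config()] providing the height model.
#' @return Adjusted mJSW in mm.
#' @export
height_adjust_mjsw <- function(mjsw_mm, height_cm, cfg = grading_config()) {
  stopifnot(inherits(cfg, "grading_config"))
  if (any(mjsw_mm < 0, na.rm = TRUE)) {
    abort("mJSW must be non-negative", class = "rhoadx_domain_error")
  }
  hm <- cfg$height_model
  missing_h <- is.na(height_cm)
  if (any(missing_h)) {
    warn(sprintf("%d record(s) missing height: graded on raw mJSW", sum(missing_h)),
         class = "rhoadx_missing_covariate")
  }
  delta <- ifelse(missing_h, 0, hm$slope_mm_per_cm * (height_cm - hm$reference_height_cm))
  mjsw_mm - delta
}

#' Grade joint space narrowing
#'
#' Grade 3 when raw mJSW <= the grade-3 cut (1.5 mm by default); this rule
#' takes precedence over the adjusted-mJSW cuts. Otherwise grade 2, 1 or 0 by
#' the height-adjusted cuts (inclusive).
#'
#' @param mjsw_mm Raw mJSW in mm (vectorised).
#' @param adjusted_mjsw_mm Height-adjusted mJSW in mm.
#' @param cfg A [grading_config()].
#' @return Integer grade(s) 0-3, monotone non-increasing in adjusted mJSW.
#' @export
grade_jsn <- function(mjsw_mm, adjusted_mjsw_mm, cfg = grading_config()) {
  stopifnot(inherits(cfg, "grading_config"))
  if (any(c(mjsw_mm, adjusted_mjsw_mm) < 0, na.rm = TRUE)) {
    abort("mJSW values must be non-negative", class = "rhoadx_domain_error")
  }
  ifelse(mjsw_mm <= cfg$jsn_grade3_mjsw_mm, 3L,
         ifelse(adjusted_mjsw_mm <= cfg$jsn_grade2_adjusted_cut, 2L,
                ifelse(adjusted_mjsw_mm <= cfg$jsn_grade1_adjusted_cut, 1L, 0L)))
}

#' Composite rHOA grade from component grades
#'
#' Sums the three osteophyte grades and the JSN grade (each 0-3, so the sum
#' is 0-12) and maps the sum through the configured cut-offs:
#' 0 -> grade 0, 1 -> grade 1, 2-3 -> grade 2, 4-6 -> grade 3,
#' 7-12 -> grade 4.
#'
#' @param osteophyte_grade_acetabular,osteophyte_grade_superior,osteophyte_grade_inferior,jsn_grade
#'   Component grades, each in 0-3 (vectorised).
#' @param cfg A [grading_config()].
#' @return Integer composite grade(s) 0-4.
#' @examples
#' composite_rhoa(1, 1, 0, 1) # sum 3 -> grade 2
#' @export
composite_rhoa <- function(osteophyte_grade_acetabular, osteophyte_grade_superior,
                           osteophyte_grade_inferior, jsn_grade,
                           cfg = grading_config()) {
  stopifnot(inherits(cfg, "grading_config"))
  g <- cbind(osteophyte_grade_acetabular, osteophyte_grade_superior,
             osteophyte_grade_inferior, jsn_grade)
  if (any(is.na(g)) || any(g < 0 | g > 3) || any(g != round(g))) {
    abort("component grades must be integers in 0..3", class = "rhoadx_domain_error")
  }
  cfg$composite_cuts[rowSums(g) + 1L]
}

#' Grade one annotated hip
#'
#' Full per-participant grading: osteophyte areas and grades at the three
#' sites (absent polygons score area 0, grade 0), raw and height-adjusted
#' mJSW, JSN grade, the grade sum and the composite rHOA grade.
#'
#' @param ann A [hip_annotation()] with `qc_flag == "ok"`.
#' @param height_cm Participant standing height in cm (NA allowed: grading
#'   falls back to raw mJSW).
#' @param cfg A [grading_config()].
#' @return A one-row tibble with columns `participant_id`,
#'   `osteophyte_area_*_mm2`, `osteophyte_grade_*`, `mjsw_mm`,
#'   `mjsw_height_adjusted`, `jsn_grade`, `grade_sum`, `rhoa_grade`.
#' @export
grade_annotation <- function(ann, height_cm = NA_real_, cfg = grading_config()) {
  stopifnot(inherits(ann, "hip_annotation"))
  if (ann$qc_flag != "ok") {
    abort(sprintf("annotation %s is QC-excluded (%s) and cannot be graded",
                  ann$participant_id, ann$qc_flag),
          class = "rhoadx_excluded_record")
  }
  areas <- setNames(numeric(3), osteophyte_sites())
  for (poly in ann$osteophytes) areas[[poly$site]] <- polygon_area(poly)
  grades <- vapply(osteophyte_sites(),
                   function(s) grade_osteophyte(areas[[s]], s, cfg), numeric(1))
  mjsw <- compute_mjsw(ann$landmarks)
  adj <- height_adjust_mjsw(mjsw, height_cm, cfg)
  jsn <- grade_jsn(mjsw, adj, cfg)
  gsum <- sum(grades) + jsn
  tibble::tibble(
    participant_id = ann$participant_id,
    osteophyte_area_acetabular_mm2 = areas[["acetabular"]],
    osteophyte_area_superior_mm2 = areas[["superior_femoral"]],
    osteophyte_area_inferior_mm2 = areas[["inferior_femoral"]],
    osteophyte_grade_acetabular = as.integer(grades[["acetabular"]]),
    osteophyte_grade_superior = as.integer(grades[["superior_femoral"]]),
    osteophyte_grade_inferior = as.integer(grades[["inferior_femoral"]]),
    mjsw_mm = mjsw,
    mjsw_height_adjusted = adj,
    jsn_grade = as.integer(jsn),
    grade_sum = as.integer(gsum),
    rhoa_grade = composite_rhoa(grades[["acetabular"]], grades[["superior_femoral"]],
                                grades[["inferior_femoral"]], jsn, cfg)
  )
}

#' Grade a batch of annotations
#'
#' Applies [grade_annotation()] to every QC-passing annotation and reports
#' exclusion counts by reason; heights are joined from the cohort table by
#' participant id.
#'
#' @param annotations List of [hip_annotation()] objects.
#' @param heights Optional data frame with columns `id` and `height_cm`.
#' @param cfg A [grading_config()].
#' @return A tibble of per-participant grades (one row per included
#'   annotation) with an `exclusions` attribute: a named integer vector of
#'   QC-exclusion counts by reason.
#' @export
grade_annotations <- function(annotations, heights = NULL, cfg = grading_config()) {
  stopifnot(is.list(annotations))
  flags <- vapply(annotations, `[[`, character(1), "qc_flag")
  ids <- vapply(annotations, `[[`, character(1), "participant_id")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate participant id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "rhoadx_format_error")
  }
  excl <- table(factor(flags[flags != "ok"],
                       levels = c("hip_not_fully_visualized", "poor_quality", "duplicate")))
  if (sum(excl) > 0) {
    warn(sprintf("QC-excluded %d annotation(s): %s", sum(excl),
                 paste(sprintf("%s=%d", names(excl), excl), collapse = ", ")),
         class = "rhoadx_qc_exclusion")
  }
  keep <- annotations[flags == "ok"]
  lookup <- function(id) {
    if (is.null(heights)) return(NA_real_)
    m <- match(id, as.character(heights$id))
    if (is.na(m)) NA_real_ else as.numeric(heights$height_cm[m])
  }
  out <- purrr::map_dfr(keep, function(a) grade_annotation(a, lookup(a$participant_id), cfg))
  attr(out, "exclusions") <- setNames(as.integer(excl), names(excl))
  out
}
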
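#' Read and write landmark point files
#'
#' The plain-text points dialect: a `version: 1` header, `n_points: 85`, an
#' opening `{`, one `x y` pair per line, and a closing `}`. Pixel spacing
#' and the region map are not part of the points format; they are read from
#' a sidecar JSON (`<stem>.meta.json`, fields `pixel_spacing_mm`,
#' `region_map` with 0-based index arrays, optional `qc_flag`) unless
#' supplied directly.
#'
#' @param path Path to the points file.
#' @param pixel_spacing,region_map Override the sidecar values; `region_map`
#'   uses the in-memory (1-based) convention of [landmark_set()].
#' @return A [landmark_set()].
#' @export
read_landmark_file <- function(path, pixel_spacing = NULL, region_map = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("landmark file not found: %s", path), class = "rhoadx_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  get_header <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (!length(ln)) {
      abort(sprintf("%s: missing '%s:' header", path, key), class = "rhoadx_format_error")
    }
    trimws(sub(paste0("^", key, ":"), "", ln[1]))
  }
  n_declared <- suppressWarnings(as.integer(get_header("n_points")))
  open_i <- match("{", lines)
  close_i <- match("}", lines)
  if (is.na(open_i) || is.na(close_i) || close_i <= open_i) {
    abort(sprintf("%s: malformed points block", path), class = "rhoadx_format_error")
  }
  body <- lines[(open_i + 1L):(close_i - 1L)]
  body <- body[nzchar(body)]
  coords <- matrix(NA_real_, nrow = length(body), ncol = 2)
  for (i in seq_along(body)) {
    tok <- strsplit(body[i], "[[:space:]]+")[[1]]
    val <- suppressWarnings(as.numeric(tok))
    if (length(val) != 2L || anyNA(val)) {
      abort(sprintf("%s: non-numeric point on line %d of the block", path, i),
            class = "rhoadx_parse_error")
    }
    coords[i, ] <- val
  }
  if (is.na(n_declared) || n_declared != 85L || nrow(coords) != 85L) {
    abort(sprintf("%s: expected 85 points, header says %s, found %d",
                  path, n_declared, nrow(coords)),
          class = "rhoadx_format_error")
  }
  if (is.null(pixel_spacing) || is.null(region_map)) {
    meta <- read_landmark_sidecar(sidecar_path(path))
    pixel_spacing <- pixel_spacing %||% meta$pixel_spacing
    region_map <- region_map %||% meta$region_map
  }
  landmark_set(coords, pixel_spacing, region_map)
}

sidecar_path <- function(path) {
  paste0(sub("\\.[[:alnum:]]+$", "", path), ".meta.json")
}

read_landmark_sidecar <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf(
      "no pixel spacing / region map given and sidecar %s not found", path),
      class = "rhoadx_io_error")
  }
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(pixel_spacing = as.numeric(meta$pixel_spacing_mm),
       region_map = region_map_from_json(meta$region_map),
       qc_flag = meta$qc_flag %||% "ok")
}

# Serialized region maps are 0-based (image-annotation convention); the
# in-memory representation is 1-based.
region_map_from_json <- function(rm) lapply(rm, function(idx) as.integer(idx) + 1L)
region_map_to_json <- function(rm) lapply(rm, function(idx) as.integer(idx) - 1L)

#' @rdname read_landmark_file
#' @param landmarks A [landmark_set()] to write.
#' @param qc_flag QC flag recorded in the sidecar.
#' @param sidecar Also write `<stem>.meta.json`?
#' @export
write_landmark_file <- function(landmarks, path, qc_flag = "ok", sidecar = TRUE) {
  stopifnot(inherits(landmarks, "landmark_set"))
  lines <- c("version: 1", "n_points: 85", "{",
             sprintf("%.17g %.17g", landmarks$points[, 1], landmarks$points[, 2]),
             "}")
  atomic_write(path, function(tmp) writeLines(lines, tmp))
  if (sidecar) {
    atomic_write(sidecar_path(path), function(tmp) {
      jsonlite::write_json(
        list(pixel_spacing_mm = landmarks$pixel_spacing,
             region_map = region_map_to_json(landmarks$region_map),
             qc_flag = qc_flag),
        tmp, auto_unbox = TRUE, digits = NA)
    })
  }
  invisible(path)
}

#' Read and write osteophyte polygon files
#'
#' One JSON file per image:
#' `{"participant_id": ..., "pixel_spacing_mm": ..., "polygons":
#' [{"site": ..., "vertices": [[x, y], ...]}, ...]}`.
#'
#' @param path JSON file path.
#' @return `read_osteophyte_json()`: list with `participant_id`,
#'   `pixel_spacing_mm` and `polygons` (list of [osteophyte_polygon()]).
#' @export
read_osteophyte_json <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("osteophyte file not found: %s", path), class = "rhoadx_io_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spacing <- as.numeric(obj$pixel_spacing_mm)
  polys <- list()
  raw <- obj$polygons
  if (!is.null(raw) && length(raw)) {
    if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
    for (p in raw) {
      v <- p$vertices
      if (is.list(v) && length(v) == 1L &&
          (is.matrix(v[[1]]) || is.data.frame(v[[1]]))) {
        v <- v[[1]]
      }
      if (is.list(v) && !is.data.frame(v)) {
        v <- do.call(rbind, lapply(v, function(r) as.numeric(unlist(r))))
      }
      v <- as.matrix(v)
      storage.mode(v) <- "double"
      polys[[length(polys) + 1L]] <-
        osteophyte_polygon(v, p$site[[1]], spacing)
    }
  }
  list(participant_id = as.character(obj$participant_id),
       pixel_spacing_mm = spacing, polygons = polys)
}

#' @rdname read_osteophyte_json
#' @param ann A [hip_annotation()] whose polygons should be written.
#' @export
write_osteophyte_json <- function(ann, path) {
  stopifnot(inherits(ann, "hip_annotation"))
  polys <- lapply(ann$osteophytes, function(p) {
    list(site = p$site, vertices = unname(apply(p$vertices, 1, as.list, simplify = FALSE)))
  })
  atomic_write(path, function(tmp) {
    jsonlite::write_json(
      list(participant_id = ann$participant_id,
           pixel_spacing_mm = ann$landmarks$pixel_spacing,
           polygons = polys),
      tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}

#' Write and read a full hip annotation
#'
#' `write_annotation()` writes `<id>.pts`, its `.meta.json` sidecar and
#' `<id>.osteophytes.json` into `dir`; `read_annotation()` reads them back.
#'
#' @param ann A [hip_annotation()].
#' @param dir Directory for the annotation files.
#' @return The participant id, invisibly (`write`); a [hip_annotation()]
#'   (`read`).
#' @export
write_annotation <- function(ann, dir) {
  stopifnot(inherits(ann, "hip_annotation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, ann$participant_id)
  write_landmark_file(ann$landmarks, paste0(stem, ".pts"), qc_flag = ann$qc_flag)
  write_osteophyte_json(ann, paste0(stem, ".osteophytes.json"))
  invisible(ann$participant_id)
}

#' @rdname write_annotation
#' @param participant_id Id (file stem) to read.
#' @export
read_annotation <- function(dir, participant_id) {
  stem <- file.path(dir, participant_id)
  meta <- read_landmark_sidecar(sidecar_path(paste0(stem, ".pts")))
  lm <- read_landmark_file(paste0(stem, ".pts"))
  osteo_path <- paste0(stem, ".osteophytes.json")
  polys <- if (file.exists(osteo_path)) read_osteophyte_json(osteo_path)$polygons else list()
  hip_annotation(participant_id, lm, polys, qc_flag = meta$qc_flag)
}

#' Read and write the grading configuration
#'
#' JSON serialization of [grading_config()] with a `config_version` field.
#' The packaged default lives at
#' `system.file("extdata", "rhoa_v1.json", package = "rhoadx")`.
#'
#' @param path JSON file path.
#' @return A [grading_config()].
#' @export
read_grading_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("config_version", "osteophyte_grade1_mm2", "osteophyte_grade2_mm2",
                "osteophyte_grade3_mm2", "jsn_grade3_mjsw_mm",
                "jsn_grade1_adjusted_cut", "jsn_grade2_adjusted_cut",
                "composite_cuts", "height_model")
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    abort(sprintf("%s: config missing field(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "rhoadx_config_error")
  }
  grading_config(
    osteophyte_grade1_mm2 = unlist(obj$osteophyte_grade1_mm2),
    osteophyte_grade2_mm2 = unlist(obj$osteophyte_grade2_mm2),
    osteophyte_grade3_mm2 = obj$osteophyte_grade3_mm2,
    jsn_grade3_mjsw_mm = obj$jsn_grade3_mjsw_mm,
    jsn_grade1_adjusted_cut = obj$jsn_grade1_adjusted_cut,
    jsn_grade2_adjusted_cut = obj$jsn_grade2_adjusted_cut,
    composite_cuts = unlist(obj$composite_cuts),
    height_model = obj$height_model,
    config_version = obj$config_version)
}

#' @rdname read_grading_config
#' @param cfg A [grading_config()] to write.
#' @export
write_grading_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "grading_config"))
  obj <- unclass(cfg)
  # keep site names: jsonlite drops names on atomic vectors
  obj$osteophyte_grade1_mm2 <- as.list(obj$osteophyte_grade1_mm2)
  obj$osteophyte_grade2_mm2 <- as.list(obj$osteophyte_grade2_mm2)
  atomic_write(path, function(tmp) {
    jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}

#' Read and write cohort tables
#'
#' CSV dialect: UTF-8, comma separator, header row, `.` decimal; sex coded
#' `M`/`F` on disk (`male`/`female` in memory); binary flags 0/1.
#'
#' @param path CSV file path.
#' @return A cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"id" %in% names(d)) {
    abort(sprintf("%s: cohort CSV needs an 'id' column", path),
          class = "rhoadx_format_error")
  }
  d$id <- as.character(d$id)
  if ("sex" %in% names(d)) {
    d$sex <- dplyr::case_match(as.character(d$sex),
                               "M" ~ "male", "F" ~ "female",
                               .default = as.character(d$sex))
  }
  d
}

#' @rdname read_cohort_csv
#' @param cohort Cohort tibble to write.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  if ("sex" %in% names(out)) {
    out$sex <- dplyr::case_match(out$sex, "male" ~ "M", "female" ~ "F",
                                 .default = out$sex)
  }
  atomic_write(path, function(tmp) readr::write_csv(out, tmp, progress = FALSE))
  invisible(path)
}

#' Write a run manifest
#'
#' Every output directory gets exactly one `manifest.json` recording the
#' tool version, config version, input paths, seeds and QC-exclusion counts
#' by reason, so a run can be reproduced from its manifest.
#'
#' @param dir Output directory.
#' @param config_version Grading config version string.
#' @param inputs Named list / vector of input paths.
#' @param seed Seed(s) used.
#' @param exclusions Named counts by QC reason (subset of
#'   hip_not_fully_visualized, poor_quality, duplicate).
#' @return Path to the manifest, invisibly.
#' @export
write_manifest <- function(dir, config_version = NA_character_, inputs = list(),
                           seed = NA_integer_, exclusions = integer()) {
  allowed <- c("hip_not_fully_visualized", "poor_quality", "duplicate")
  if (length(exclusions) && !all(names(exclusions) %in% allowed)) {
    abort("exclusion reasons must be hip_not_fully_visualized, poor_quality or duplicate",
          class = "rhoadx_format_error")
  }
  path <- file.path(dir, "manifest.json")
  atomic_write(path, function(tmp) {
    jsonlite::write_json(
      list(tool = "rhoadx",
           tool_version = as.character(utils::packageVersion("rhoadx")),
           config_version = config_version,
           inputs = inputs, seed = seed,
           qc_exclusions = as.list(exclusions),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}

# write-temp-then-rename: writers are atomic and idempotent
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    abort(sprintf("could not move temporary file into place at %s", path),
          class = "rhoadx_io_error")
  }
  invisible(path)
}
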
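#' Forest plot of an association analysis
#'
#' Plots odds/hazard ratios with 95% CIs on a log scale, faceted by outcome,
#' one row per exposure-level contrast, in the layout conventionally used
#' for endophenotype and composite-grade association tables.
#'
#' @param object A `rhoa_analysis` tibble from [run_full_analysis()] (or any
#'   tibble with its columns).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rhoa_analysis <- function(object, ...) {
  d <- dplyr::filter(object, !is.na(.data$estimate), .data$stratum == "all")
  d$contrast <- factor(
    paste0(d$exposure, " [", d$level, "]"),
    levels = rev(unique(paste0(d$exposure, " [", d$level, "]"))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$contrast,
                                  colour = .data$adjusted)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.5), size = 0.3) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$outcome), nrow = 1) +
    ggplot2::labs(x = "OR / HR (log scale, Wald 95% CI)", y = NULL,
                  colour = "adjusted") +
    ggplot2::theme_minimal()
}

#' Bar chart of tabulated prevalences
#'
#' @param tab Output of [tabulate_prevalence()].
#' @return A ggplot object.
#' @export
plot_prevalence <- function(tab) {
  d <- dplyr::mutate(tab, label = paste0(.data$measure, " [", .data$level, "]"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pct, y = .data$label,
                                  fill = .data$stratum)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "prevalence (%)", y = NULL, fill = "stratum") +
    ggplot2::theme_minimal()
}

#' Sketch of a hip annotation
#'
#' Draws the outline regions and any osteophyte polygons in mm coordinates
#' (y axis reversed to match image space).
#'
#' @param object A [hip_annotation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hip_annotation <- function(object, ...) {
  lm <- object$landmarks
  regions <- setdiff(names(lm$region_map), "full_outline")
  pts <- purrr::map_dfr(regions, function(r) {
    xy <- extract_region(lm, r)
    tibble::tibble(x = xy[, 1], y = xy[, 2], part = r)
  })
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$part)) +
    ggplot2::geom_path() + ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = NULL) +
    ggplot2::theme_minimal()
  if (length(object$osteophytes)) {
    op <- purrr::map_dfr(object$osteophytes, function(o) {
      v <- o$vertices * o$pixel_spacing
      tibble::tibble(x = c(v[, 1], v[1, 1]), y = c(v[, 2], v[1, 2]),
                     part = paste0("osteophyte: ", o$site))
    })
    p <- p + ggplot2::geom_path(data = op)
  }
  p
}
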
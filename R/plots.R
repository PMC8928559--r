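#' Plot methods
#'
#' ggplot2 visualizations for the main result types: the ELC category map
#' (`autoplot.pc_elc`), per-algorithm TSS distributions
#' (`autoplot.pc_runs`), projected suitability with the selected subset
#' highlighted (`autoplot.pc_calibration`), variable importance
#' (`plot_importance`) and subset locations over the category map
#' (`plot_subsets`).
#'
#' @param object A predchar result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name predchar-plots
NULL

#' @rdname predchar-plots
#' @importFrom ggplot2 autoplot
#' @export
autoplot.pc_elc <- function(object, ...) {
  df <- grid_coords(object$category_grid)
  df$category <- factor(ifelse(df$value == 0, NA, df$value))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat, fill = .data$category)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = "Ecogeographic land characterization map",
      fill = "ELC category", x = "Longitude", y = "Latitude"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname predchar-plots
#' @export
autoplot.pc_runs <- function(object, ...) {
  ok <- object$runs[!object$runs$failed, ]
  ok$algorithm <- factor(ok$algorithm, levels = rev(object$summary$algorithm))
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$algorithm, y = .data$tss)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0.2, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      title = "Held-out TSS by algorithm",
      x = NULL, y = "True Skill Statistic"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname predchar-plots
#' @export
autoplot.pc_calibration <- function(object, ...) {
  if (object$verdict == "unmodelable") {
    abort("nothing to plot: trait was declared unmodelable", class = "predchar_spec_error")
  }
  df <- object$projections
  df$selected <- df$pop_id %in% object$top_subset$pop_id
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 1, alpha = 0.6) +
    ggplot2::geom_point(
      data = df[df$selected, ], shape = 21, size = 2.4,
      fill = NA, colour = "black", stroke = 0.8
    ) +
    ggplot2::labs(
      title = sprintf(
        "Projected suitability (%s, cutoff %.0f); selected subset circled",
        object$algorithm, object$cutoff
      ),
      colour = NULL, x = "Longitude", y = "Latitude"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname predchar-plots
#' @param calibration A `pc_calibration` with importance tables.
#' @export
plot_importance <- function(calibration) {
  stopifnot(inherits(calibration, "pc_calibration"))
  if (length(calibration$top3) == 0) {
    abort("no importance tables available", class = "predchar_spec_error")
  }
  df <- bind_rows(calibration$top3, .id = "algorithm")
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$variable, .data$importance),
    y = .data$importance
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~algorithm) +
    ggplot2::labs(
      title = "Permutation variable importance (best run per algorithm)",
      x = NULL, y = "Importance (0-1)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname predchar-plots
#' @param elc A `pc_elc` used as the background map.
#' @param ... Named `pc_subset` objects.
#' @export
plot_subsets <- function(elc, ...) {
  subsets <- list(...)
  base <- autoplot.pc_elc(elc)
  pts <- bind_rows(
    lapply(subsets, function(s) s$members[c("pop_id", "lon", "lat")]),
    .id = "trait"
  )
  base +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$lon, y = .data$lat, shape = .data$trait),
      inherit.aes = FALSE, size = 2
    ) +
    ggplot2::labs(shape = "Trait subset")
}
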
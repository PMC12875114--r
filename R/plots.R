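# ggplot2 visualizations for the main result types

#' Plot localizations colored by local density or cluster
#'
#' 2D (xy) scatter of a localization table, colored by local neighbor
#' density (the standard rendering of MINFLUX DNA maps) or, if present,
#' by cluster label.
#'
#' @param table Localization table.
#' @param color `"density"` or `"cluster"`.
#' @param radius Density radius in nm when `color = "density"`.
#' @return A ggplot object.
#' @export
plot_localizations <- function(table, color = c("density", "cluster"),
                               radius = 20) {
  color <- match.arg(color)
  df <- tibble::as_tibble(as.data.frame(table))
  if (color == "cluster" && "cluster" %in% names(df)) {
    df$color <- factor(df$cluster)
    lab <- "cluster"
  } else {
    df$color <- local_density(df, radius)
    lab <- sprintf("neighbors < %g nm", radius)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   color = .data$color)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", color = lab) +
    ggplot2::theme_minimal()
}

#' @describeIn compute_frc FRC curve with threshold and resolution mark.
#' @param object An `frc_curve`.
#' @param ... Unused.
#' @export
autoplot.frc_curve <- function(object, ...) {
  thr <- attr(object, "threshold")
  res <- attr(object, "resolution_nm")
  df <- tibble::as_tibble(as.data.frame(object))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$q_per_nm)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$frc), color = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), color = "steelblue") +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = expression(spatial ~ frequency ~ (nm^-1)), y = "FRC",
                  subtitle = sprintf("resolution %.1f nm at threshold %.3f",
                                     res, thr)) +
    ggplot2::theme_minimal()
  if (!isTRUE(attr(object, "not_crossed"))) {
    p <- p + ggplot2::geom_vline(xintercept = 1 / res, linetype = "dotted")
  }
  p
}

#' @describeIn fiber_summary Segment-diameter histogram.
#' @param object A `fiber_summary`.
#' @param ... Unused.
#' @export
autoplot.fiber_summary <- function(object, ...) {
  ggplot2::ggplot(object$diameter_histogram,
                  ggplot2::aes(x = .data$mid_nm, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_nm * 0.9, fill = "steelblue") +
    ggplot2::labs(x = "segment diameter (nm)", y = "segments") +
    ggplot2::theme_minimal()
}

#' @describeIn diameter_histogram Histogram with detected peaks marked.
#' @param object A `diameter_histogram`.
#' @param ... Unused.
#' @export
autoplot.diameter_histogram <- function(object, ...) {
  p <- ggplot2::ggplot(object$histogram,
                       ggplot2::aes(x = .data$mid_nm, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_nm * 0.9, fill = "indianred") +
    ggplot2::labs(x = "fitted diameter (nm)", y = "fits") +
    ggplot2::theme_minimal()
  if (length(object$peaks_nm)) {
    p <- p + ggplot2::geom_vline(xintercept = object$peaks_nm,
                                 linetype = "dotted")
  }
  p
}

#' @describeIn classify_region Stacked bar of the three fractions.
#' @param object A `region_classification`.
#' @param ... Unused.
#' @export
autoplot.region_classification <- function(object, ...) {
  df <- tibble::tibble(
    category = factor(c("scattered", "1-2 nucleosomes", ">=3 nucleosomes"),
                      levels = c("scattered", "1-2 nucleosomes",
                                 ">=3 nucleosomes")),
    fraction = c(object$fraction_scattered, object$fraction_1_2,
                 object$fraction_3plus)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$fraction)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(x = NULL, y = "fraction of localizations") +
    ggplot2::theme_minimal()
}
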
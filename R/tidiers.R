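# broom-style tidiers for the fitted-model objects

#' @describeIn fit_cylinder One row per parameter (broom convention).
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.cylinder_fit <- function(x, ...) {
  tibble::tibble(
    term = c("radius_nm", "diameter_nm", "length_nm",
             "axis_x", "axis_y", "axis_z"),
    estimate = c(x$radius, x$diameter, x$length, x$axis)
  )
}

#' @describeIn fit_cylinder One-row fit summary.
#' @export
glance.cylinder_fit <- function(x, ...) {
  tibble::tibble(diameter_nm = x$diameter, length_nm = x$length,
                 rms_radial_residual_nm = x$rms_radial_residual,
                 r_squared = x$r_squared, n = x$n)
}

#' @describeIn fit_ring One row per parameter.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.ring_fit <- function(x, ...) {
  tibble::tibble(
    term = c("radius_nm", "diameter_nm", "normal_x", "normal_y", "normal_z"),
    estimate = c(x$radius, x$diameter, x$normal)
  )
}

#' @describeIn fit_ring One-row fit summary.
#' @export
glance.ring_fit <- function(x, ...) {
  tibble::tibble(diameter_nm = x$diameter, r_squared = x$r_squared,
                 out_of_plane_rms_nm = x$out_of_plane_rms, n = x$n)
}

#' @describeIn fit_nucleosome One-row fit summary.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
glance.nucleosome_fit <- function(x, ...) {
  tibble::tibble(diameter_nm = x$diameter, height_nm = x$height,
                 n_points_total = x$n_points_total,
                 n_attached = x$n_attached,
                 r_squared = if (is.null(x$cylinder)) NA_real_ else
                   x$cylinder$r_squared,
                 accepted = x$accepted)
}

#' @describeIn fit_dimer One row per stacked nucleosome.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.dimer_fit <- function(x, ...) {
  if (!length(x$fits)) return(tibble::tibble())
  dplyr::mutate(
    dplyr::bind_rows(lapply(x$fits, glance)),
    unit = seq_along(x$fits), offset_nm = x$offset_nm,
    dimer_accepted = x$accepted, .before = 1
  )
}

#' @describeIn classify_region One-row summary of the region fractions.
#' @param x A classification object.
#' @param ... Unused.
#' @export
glance.region_classification <- function(x, ...) {
  tibble::tibble(n_locs = x$n_locs,
                 fraction_scattered = x$fraction_scattered,
                 fraction_1_2 = x$fraction_1_2,
                 fraction_3plus = x$fraction_3plus)
}

#' @describeIn compute_frc One-row summary with the resolution estimate.
#' @param x An `frc_curve`.
#' @param ... Unused.
#' @export
glance.frc_curve <- function(x, ...) {
  tibble::tibble(resolution_nm = attr(x, "resolution_nm"),
                 threshold = attr(x, "threshold"),
                 not_crossed = attr(x, "not_crossed"),
                 pixel_nm = attr(x, "pixel_nm"))
}
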
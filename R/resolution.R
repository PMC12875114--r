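#' Fourier ring correlation of a localization data set
#'
#' Splits the localizations into two half-sets (default: odd/even uid,
#' i.e. acquisition-order interleaving — deterministic and robust to
#' density gradients), renders each half as a 2D histogram image at
#' `pixel_nm`, and correlates the two Fourier transforms over rings of one
#' frequency-bin width:
#' `FRC(q) = Re(sum F1 F2*) / sqrt(sum |F1|^2 sum |F2|^2)`.
#' The curve is smoothed by a centered 3-bin moving average and the
#' resolution is read at the first crossing below the threshold (linear
#' interpolation between bins). 3D data are projected to xy.
#'
#' @param table Localization table (>= 2 records).
#' @param pixel_nm Rendering pixel size in nm.
#' @param threshold FRC threshold (default 1/7).
#' @param split `"odd_even"` (default) or `"random"`.
#' @param seed Seed for the random split.
#' @return Object of class `frc_curve`: a tibble
#'   `q_per_nm, frc, smoothed` with attributes `threshold`,
#'   `resolution_nm`, `not_crossed`, `pixel_nm`.
#' @export
compute_frc <- function(table, pixel_nm = 2, threshold = 1 / 7,
                        split = c("odd_even", "random"), seed = NULL) {
  split <- match.arg(split)
  if (pixel_nm <= 0) abort("`pixel_nm` must be > 0")
  xyz <- as_xyz(table)
  n <- nrow(xyz)
  if (n < 2) abort("FRC needs >= 2 localizations")
  uid <- if (is.data.frame(table) && "uid" %in% names(table)) table$uid else
    seq_len(n)
  half1 <- if (split == "odd_even") uid %% 2 == 1 else {
    if (!is.null(seed)) set.seed(seed)
    sample(c(TRUE, FALSE), n, replace = TRUE)
  }
  xr <- range(xyz[, 1]); yr <- range(xyz[, 2])
  extent <- max(xr[2] - xr[1], yr[2] - yr[1])
  if (extent < pixel_nm) {
    warn("degenerate image: all points within one pixel; resolution is pixel-limited")
  }
  npix <- max(8L, 2L * ceiling((extent / pixel_nm + 1) / 2))
  img <- function(pts) {
    ix <- pmin(npix, pmax(1, floor((pts[, 1] - xr[1]) / pixel_nm) + 1))
    iy <- pmin(npix, pmax(1, floor((pts[, 2] - yr[1]) / pixel_nm) + 1))
    matrix(tabulate(ix + (iy - 1) * npix, nbins = npix * npix), npix, npix)
  }
  f1 <- fft(img(xyz[half1, , drop = FALSE]))
  f2 <- fft(img(xyz[!half1, , drop = FALSE]))
  k <- c(0:(npix / 2), (npix / 2 - 1):1)   # centered frequency index
  kmag <- sqrt(outer(k^2, k^2, `+`))
  ring <- pmin(round(kmag), npix / 2)
  num <- rowsum(as.vector(Re(f1 * Conj(f2))), as.vector(ring))
  p1 <- rowsum(as.vector(Mod(f1)^2), as.vector(ring))
  p2 <- rowsum(as.vector(Mod(f2)^2), as.vector(ring))
  den <- sqrt(p1 * p2)
  frc <- ifelse(den > 0, num / den, 0)
  rings <- as.integer(rownames(num))
  q <- rings / (npix * pixel_nm)
  sm <- frc
  if (length(frc) >= 3) {
    inner <- (stats::filter(frc, rep(1 / 3, 3), sides = 2))
    sm[!is.na(inner)] <- inner[!is.na(inner)]
  }
  curve <- tibble::tibble(q_per_nm = q, frc = as.numeric(frc),
                          smoothed = as.numeric(sm))
  curve <- structure(curve, class = c("frc_curve", class(curve)),
                     threshold = threshold, pixel_nm = pixel_nm)
  res <- frc_resolution(curve, threshold)
  attr(curve, "resolution_nm") <- res$resolution_nm
  attr(curve, "not_crossed") <- res$not_crossed
  curve
}

#' Read a resolution from an FRC curve
#'
#' Finds the first downward crossing of the smoothed curve below the
#' threshold and converts the interpolated crossing frequency to real
#' space. If the curve never crosses, the Nyquist limit `2 * pixel_nm` is
#' returned with `not_crossed = TRUE`.
#'
#' @param curve An `frc_curve` (or tibble with `q_per_nm` and `smoothed`).
#' @param threshold Crossing threshold; defaults to the curve's own.
#' @return List with `resolution_nm` and `not_crossed`.
#' @export
frc_resolution <- function(curve, threshold = NULL) {
  if (is.null(threshold)) threshold <- attr(curve, "threshold") %||% 1 / 7
  pixel_nm <- attr(curve, "pixel_nm") %||% NA_real_
  q <- curve$q_per_nm
  s <- curve$smoothed
  if (!length(q)) abort("empty FRC curve")
  for (i in seq_along(q)[-1]) {
    if (s[i] < threshold && s[i - 1] >= threshold) {
      qi <- q[i - 1] + (threshold - s[i - 1]) * (q[i] - q[i - 1]) /
        (s[i] - s[i - 1])
      return(list(resolution_nm = 1 / qi, not_crossed = FALSE))
    }
  }
  list(resolution_nm = if (is.na(pixel_nm)) 1 / max(q) else 2 * pixel_nm,
       not_crossed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Localization precision from repeated sightings
#'
#' Pools, per axis, the within-group standard deviation over groups of
#' repeated sightings of the same emitter, and converts to FWHM via
#' `FWHM = 2 sqrt(2 log 2) sigma`. Singleton groups carry no spread
#' information and are ignored; if every group is a singleton the
#' precision is undefined and an error is raised.
#'
#' @param table Localization table.
#' @param group Grouping vector (emitter / truth-site id per record).
#' @return A tibble of class `precision_estimate`: one row per axis with
#'   `axis, sigma_nm, fwhm_nm`, plus attributes `n_sightings` and
#'   `n_groups`.
#' @export
estimate_precision <- function(table, group) {
  xyz <- as_xyz(table)
  if (length(group) != nrow(xyz)) abort("`group` must cover the table")
  keep <- !is.na(group)
  xyz <- xyz[keep, , drop = FALSE]
  group <- group[keep]
  sizes <- table(group)
  multi <- names(sizes)[sizes >= 2]
  if (!length(multi)) {
    abort("undefined precision: every sighting group is a singleton")
  }
  sel <- group %in% multi
  xyz <- xyz[sel, , drop = FALSE]
  group <- factor(group[sel])
  df_within <- sum(table(group) - 1)
  pooled <- vapply(1:3, function(ax) {
    gm <- tapply(xyz[, ax], group, mean)
    sqrt(sum((xyz[, ax] - gm[group])^2) / df_within)
  }, numeric(1))
  if (all(pooled == 0)) {
    warn("degenerate: zero spread within every group; FWHM = 0")
  }
  out <- tibble::tibble(axis = c("x", "y", "z"), sigma_nm = pooled,
                        fwhm_nm = sigma_to_fwhm(pooled))
  structure(out, class = c("precision_estimate", class(out)),
            n_sightings = nrow(xyz), n_groups = nlevels(group))
}
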
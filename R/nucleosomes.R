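#' Ring (circle-in-3D) fit at nucleosome scale
#'
#' Fits a circle to a nucleosome-scale point cloud. The fitting plane can
#' be chosen three ways:
#'
#' * `"principal"` (default): the two leading principal axes of the
#'   points. Rotation-equivariant, so the fitted diameter does not depend
#'   on the nucleosome's orientation.
#' * `"imaging"`: the fixed xy (focal) plane, with points projected along
#'   the optic axis and no correction for the disk's orientation angle.
#'   Because nucleosomal DNA is a superhelix whose rise is comparable to
#'   its radius, projecting a tilted nucleosome smears points outward and
#'   inflates the apparent diameter — the mechanism behind the secondary
#'   high-side peak in uncorrected diameter histograms.
#' * `"refined"`: plane normal refined by minimizing the full 3D
#'   geometric circle residual (tilt-corrected mode; also selected by
#'   `config$tilt_corrected`).
#'
#' In every mode the in-plane circle is an algebraic least-squares fit
#' refined by geometric residual minimization.
#'
#' @param points >= 5 non-collinear 3D points (nm).
#' @param plane `"principal"`, `"imaging"` or `"refined"`.
#' @param config A [chromaflux_config()].
#' @return Object of class `ring_fit`: `center` (3D), `normal`, `radius`,
#'   `diameter`, `r_squared` (uncentered, on in-plane radial distances),
#'   `out_of_plane_rms`, `n`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 9)[-9]
#' fit_ring(cbind(5.81 * cos(th), 5.81 * sin(th), 0))$diameter
#' @export
fit_ring <- function(points, plane = c("principal", "imaging", "refined"),
                     config = chromaflux_config()) {
  plane <- match.arg(plane)
  if (config$tilt_corrected && missing(plane)) plane <- "refined"
  xyz <- as_xyz(points)
  n <- nrow(xyz)
  if (n < 5) abort("ring fit needs >= 5 points")
  ctr <- colMeans(xyz)
  cm <- sweep(xyz, 2, ctr)
  eg <- eigen(crossprod(cm) / n, symmetric = TRUE)
  if (eg$values[2] < 1e-10 * max(eg$values[1], 1e-12)) {
    abort("degenerate input: points are collinear, ring radius unidentifiable",
          class = "chromaflux_degeneracy")
  }
  normal <- switch(plane,
    principal = eg$vectors[, 3],   # least-spread direction
    imaging = c(0, 0, 1),
    refined = eg$vectors[, 3]
  )
  if (plane == "refined") {
    obj <- function(th) {
      nrm <- axis_from_angles(th)
      b <- orthobasis(nrm)
      uv <- cbind(cm %*% b$u, cm %*% b$v)
      cf <- circle_fit_2d(uv, refine = FALSE)
      h <- drop(cm %*% nrm)
      sum((cf$distances - cf$radius)^2 + (h - mean(h))^2)
    }
    opt <- optim(angles_from_axis(normal), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 800))
    normal <- axis_from_angles(opt$par)
  }
  normal <- canonical_axis(normal)
  b <- orthobasis(normal)
  uv <- cbind(cm %*% b$u, cm %*% b$v)
  cf <- circle_fit_2d(uv, refine = TRUE)
  h <- drop(cm %*% normal)
  center3d <- ctr + cf$center[1] * b$u + cf$center[2] * b$v + mean(h) * normal
  structure(
    list(center = center3d, normal = normal, radius = cf$radius,
         diameter = 2 * cf$radius,
         r_squared = radial_r_squared(cf$distances, cf$radius),
         out_of_plane_rms = sqrt(mean((h - mean(h))^2)), n = n),
    class = "ring_fit"
  )
}

#' @export
print.ring_fit <- function(x, ...) {
  cat(sprintf("Ring fit: d = %.2f nm, R^2 = %.3f, out-of-plane rms = %.3f nm (n = %d)\n",
              x$diameter, x$r_squared, x$out_of_plane_rms, x$n))
  invisible(x)
}

# best axial window of width <= cap containing the most points
best_axial_window <- function(axial, cap) {
  o <- order(axial)
  s <- axial[o]
  n <- length(s)
  j <- 1; best <- c(1, 1); best_n <- 0
  for (i in seq_len(n)) {
    while (s[i] - s[j] > cap) j <- j + 1
    if (i - j + 1 > best_n) { best_n <- i - j + 1; best <- c(j, i) }
  }
  range <- c(s[best[1]], s[best[2]])
  axial >= range[1] - 1e-9 & axial <= range[2] + 1e-9
}

#' Cylinder-model fit of a single nucleosome
#'
#' Fits a constrained cylinder to a candidate point window: the radius is
#' restricted to the nucleosome range, the height is capped (points
#' outside the densest axial window of the cap width are unattached), and
#' probes count as attached when their radial residual is within
#' `attach_tol_nm` and their axial position lies in the height span. The
#' fit is accepted when at least 5 probes attach and the diameter falls in
#' the configured nucleosome band. A failed fit is returned with
#' `accepted = FALSE` (a "no-nucleosome" result), not an error.
#'
#' @param points >= 5 3D points in an ~18-nm candidate window.
#' @param axis Optional fixed cylinder axis (used by [fit_dimer()]).
#' @param config A [chromaflux_config()].
#' @return Object of class `nucleosome_fit`: `cylinder` ([fit_cylinder()]
#'   object), `diameter`, `height`, `n_points_total`, `n_attached`,
#'   `attached` (logical per point), `accepted`.
#' @export
fit_nucleosome <- function(points, axis = NULL, config = chromaflux_config()) {
  xyz <- as_xyz(points)
  n <- nrow(xyz)
  if (n < 5) abort("nucleosome fit needs >= 5 points")
  fit <- tryCatch(
    fit_cylinder(xyz, axis = axis, radius_bounds = config$radius_bounds_nm),
    chromaflux_degeneracy = function(e) NULL
  )
  reject <- function(cyl) {
    structure(list(cylinder = cyl, diameter = if (is.null(cyl)) NA_real_ else cyl$diameter,
                   height = NA_real_, n_points_total = n, n_attached = 0L,
                   attached = rep(FALSE, n), accepted = FALSE),
              class = "nucleosome_fit")
  }
  if (is.null(fit)) return(reject(NULL))
  in_height <- best_axial_window(fit$axial, config$height_cap_nm)
  if (sum(in_height) >= 5 && sum(in_height) < n) {
    refit <- tryCatch(
      fit_cylinder(xyz[in_height, , drop = FALSE], axis = axis,
                   radius_bounds = config$radius_bounds_nm),
      chromaflux_degeneracy = function(e) NULL
    )
    if (!is.null(refit)) {
      fit <- refit
      # recompute residuals of all points against the refitted cylinder
      cm <- sweep(xyz, 2, fit$base_point)
      ax <- drop(cm %*% fit$axis)
      rad <- sqrt(pmax(0, rowSums(cm^2) - ax^2))
      fit$radial_residuals <- rad - fit$radius
      fit$axial <- ax
      in_height <- best_axial_window(ax, config$height_cap_nm)
    }
  }
  attached <- in_height & abs(fit$radial_residuals) <= config$attach_tol_nm
  # trimmed refit: unattached scatterers drag the least-squares circle, so
  # refit on the current inlier set until the attachment set stabilizes
  for (iter in 1:3) {
    if (sum(attached) < 5 || sum(attached) == n) break
    refit <- tryCatch(
      fit_cylinder(xyz[attached, , drop = FALSE], axis = axis,
                   radius_bounds = config$radius_bounds_nm),
      chromaflux_degeneracy = function(e) NULL
    )
    if (is.null(refit)) break
    cm <- sweep(xyz, 2, refit$base_point)
    ax <- drop(cm %*% refit$axis)
    rad <- sqrt(pmax(0, rowSums(cm^2) - ax^2))
    refit$radial_residuals <- rad - refit$radius
    refit$axial <- ax
    fit <- refit
    in_height <- best_axial_window(ax, config$height_cap_nm)
    new_attached <- in_height &
      abs(fit$radial_residuals) <= config$attach_tol_nm
    if (identical(new_attached, attached)) break
    attached <- new_attached
  }
  height <- if (any(attached)) diff(range(fit$axial[attached])) else NA_real_
  band <- config$nucleosome_band_nm
  accepted <- sum(attached) >= 5 &&
    fit$diameter >= band[1] && fit$diameter <= band[2] &&
    (!is.na(height) && height < fit$diameter)
  structure(
    list(cylinder = fit, diameter = fit$diameter, height = height,
         n_points_total = n, n_attached = sum(attached),
         attached = attached, accepted = accepted),
    class = "nucleosome_fit"
  )
}

#' @export
print.nucleosome_fit <- function(x, ...) {
  cat(sprintf("Nucleosome fit: %s, d = %.2f nm, height = %.2f nm, %d/%d attached\n",
              if (x$accepted) "accepted" else "rejected",
              x$diameter, x$height, x$n_attached, x$n_points_total))
  invisible(x)
}

# exact 1D two-means partition: minimizes within-group sum of squares
split_two_means_1d <- function(v) {
  o <- order(v)
  s <- v[o]
  n <- length(s)
  csum <- cumsum(s); csq <- cumsum(s^2)
  best_k <- 1; best_ss <- Inf
  for (k in seq_len(n - 1)) {
    ss1 <- csq[k] - csum[k]^2 / k
    ss2 <- (csq[n] - csq[k]) - (csum[n] - csum[k])^2 / (n - k)
    if (ss1 + ss2 < best_ss) { best_ss <- ss1 + ss2; best_k <- k }
  }
  lower <- o[seq_len(best_k)]
  membership <- rep(2L, n)
  membership[lower] <- 1L
  membership
}

#' Fit a stacked nucleosome dimer
#'
#' A shared axis is fitted to all points; the points are split by an exact
#' 1D two-means partition of their axial coordinates, and each part is
#' fitted as a nucleosome with the shared axis held fixed. The dimer is
#' accepted only when both part fits accept.
#'
#' Because two stacked disks cannot interpenetrate, the fit is also
#' rejected when the axial center-to-center offset falls below
#' `min_offset_nm` (default 4.5 nm, just under a nucleosome's height):
#' splitting a single nucleosome's own points always produces two
#' well-populated halves, but their centers sit closer than any physical
#' stack.
#'
#' @param points >= 10 3D points in a window up to ~30 nm across.
#' @param min_offset_nm Minimum axial separation of the two disk centers.
#' @param config A [chromaflux_config()].
#' @return Object of class `dimer_fit`: `fits` (list of two
#'   [fit_nucleosome()] results), `axis`, `offset_nm` (center-to-center
#'   axial distance), `membership` (1/2 per point), `accepted`.
#' @export
fit_dimer <- function(points, min_offset_nm = 4.5,
                      config = chromaflux_config()) {
  xyz <- as_xyz(points)
  n <- nrow(xyz)
  if (n < 10) abort("dimer fit needs >= 10 points")
  no_dimer <- function(fits = list(), axis = NULL, membership = NULL) {
    structure(list(fits = fits, axis = axis, offset_nm = NA_real_,
                   membership = membership, accepted = FALSE),
              class = "dimer_fit")
  }
  shared <- tryCatch(fit_cylinder(xyz),
                     chromaflux_degeneracy = function(e) NULL)
  if (is.null(shared)) return(no_dimer())
  axis <- shared$axis
  cm <- sweep(xyz, 2, colMeans(xyz))
  axial <- drop(cm %*% axis)
  membership <- split_two_means_1d(axial)
  if (min(table(membership)) < 5) return(no_dimer(axis = axis,
                                                  membership = membership))
  fits <- lapply(1:2, function(g) {
    fit_nucleosome(xyz[membership == g, , drop = FALSE], axis = axis,
                   config = config)
  })
  if (!all(vapply(fits, function(f) f$accepted, logical(1)))) {
    return(no_dimer(fits = fits, axis = axis, membership = membership))
  }
  centers <- vapply(1:2, function(g) {
    mean(drop(xyz[membership == g, , drop = FALSE] %*% axis))
  }, numeric(1))
  offset <- abs(diff(centers))
  structure(
    list(fits = fits, axis = axis, offset_nm = offset,
         membership = membership, accepted = offset >= min_offset_nm),
    class = "dimer_fit"
  )
}

#' Histogram of fitted nucleosome diameters with peak detection
#'
#' Restricts accepted fitted diameters to below 13 nm, bins them, and
#' reports local maxima of the counts as peaks (a bin strictly greater
#' than one neighbor and not smaller than the other).
#'
#' @param fits List of accepted [fit_nucleosome()] / [fit_ring()] objects,
#'   or a numeric vector of diameters in nm.
#' @param bin_nm Bin width in nm (> 0).
#' @param max_nm Upper diameter cut (default 13 nm).
#' @return A list of class `diameter_histogram`: `histogram` (tibble
#'   `mid_nm, count`), `peaks_nm` (bin midpoints of local maxima, in
#'   decreasing count order), `bin_nm`.
#' @export
diameter_histogram <- function(fits, bin_nm = 0.5, max_nm = 13) {
  if (bin_nm <= 0) abort("`bin_nm` must be > 0")
  d <- if (is.numeric(fits)) fits else
    vapply(fits, function(f) f$diameter, numeric(1))
  d <- d[!is.na(d) & d < max_nm]
  if (!length(d)) {
    return(structure(list(
      histogram = tibble::tibble(mid_nm = numeric(), count = integer()),
      peaks_nm = numeric(), bin_nm = bin_nm
    ), class = "diameter_histogram"))
  }
  lo <- floor(min(d) / bin_nm) * bin_nm
  brk <- seq(lo, max_nm + bin_nm, by = bin_nm)
  cnt <- tabulate(findInterval(d, brk, all.inside = TRUE),
                  nbins = length(brk) - 1)
  mids <- brk[-length(brk)] + bin_nm / 2
  k <- length(cnt)
  is_peak <- vapply(seq_len(k), function(i) {
    left <- if (i > 1) cnt[i - 1] else -1
    right <- if (i < k) cnt[i + 1] else -1
    cnt[i] > 0 && cnt[i] >= left && cnt[i] >= right &&
      (cnt[i] > left || cnt[i] > right)
  }, logical(1))
  peaks <- mids[is_peak][order(cnt[is_peak], decreasing = TRUE)]
  structure(list(histogram = tibble::tibble(mid_nm = mids, count = cnt),
                 peaks_nm = peaks, bin_nm = bin_nm),
            class = "diameter_histogram")
}

#' Classify a region into scattered / 1-2 / >= 3 nucleosome fractions
#'
#' Noise-labeled localizations are scattered. Within each cluster,
#' nucleosomes are extracted greedily: repeatedly seed at the unclaimed
#' localization with the most unclaimed neighbors within half the
#' nucleosome window, fit a nucleosome to the unclaimed points in the
#' surrounding window, claim the attached points on acceptance, and stop
#' when no seed yields an accepted fit. Clusters with 1-2 accepted fits
#' contribute their localizations to the 1-2-nucleosome fraction, >= 3
#' fits to the polymer fraction, 0 fits to scattered; fractions are
#' localization-weighted over the region.
#'
#' @param table A localization table.
#' @param labels Integer cluster labels (`-1` noise); defaults to
#'   `table$cluster`.
#' @param config A [chromaflux_config()].
#' @return A list of class `region_classification`: `n_locs`,
#'   `fraction_scattered`, `fraction_1_2`, `fraction_3plus`,
#'   `fits_per_cluster` (tibble `cluster, n_locs, n_fits, category`),
#'   `fits` (list of accepted fits). Fractions are `NA` (flagged) when
#'   `n_locs` is 0.
#' @export
classify_region <- function(table, labels = NULL,
                            config = chromaflux_config()) {
  xyz <- as_xyz(table)
  n <- nrow(xyz)
  if (is.null(labels)) {
    if (!"cluster" %in% names(table)) abort("no `cluster` column or `labels`")
    labels <- table$cluster
  }
  if (length(labels) != n) abort("`labels` must cover the table")
  if (n == 0) {
    return(structure(list(
      n_locs = 0L, fraction_scattered = NA_real_, fraction_1_2 = NA_real_,
      fraction_3plus = NA_real_,
      fits_per_cluster = tibble::tibble(cluster = integer(),
                                        n_locs = integer(), n_fits = integer(),
                                        category = character()),
      fits = list(), empty = TRUE
    ), class = "region_classification"))
  }
  half <- config$nucleosome_window_nm / 2
  all_fits <- list()
  rows <- list()
  counts <- c(scattered = sum(labels == -1L), one_two = 0L, three_plus = 0L)
  for (id in sort(unique(labels[labels != -1L]))) {
    idx <- which(labels == id)
    sub <- xyz[idx, , drop = FALSE]
    nb <- grid_neighbors(sub, half)
    unclaimed <- rep(TRUE, length(idx))
    eligible <- rep(TRUE, length(idx))
    n_fits <- 0L
    repeat {
      dens <- vapply(seq_along(idx), function(i) {
        if (!unclaimed[i] || !eligible[i]) return(-1L)
        sum(unclaimed[nb[[i]]])
      }, integer(1))
      seed <- which.max(dens)
      if (dens[seed] < 4L) break   # need >= 5 points incl. seed
      in_win <- unclaimed &
        abs(sub[, 1] - sub[seed, 1]) <= half &
        abs(sub[, 2] - sub[seed, 2]) <= half &
        abs(sub[, 3] - sub[seed, 3]) <= half
      if (sum(in_win) < 5) { eligible[seed] <- FALSE; next }
      fit <- fit_nucleosome(sub[in_win, , drop = FALSE], config = config)
      if (fit$accepted) {
        claimed <- which(in_win)[fit$attached]
        unclaimed[claimed] <- FALSE
        n_fits <- n_fits + 1L
        all_fits[[length(all_fits) + 1]] <- fit
      } else {
        eligible[seed] <- FALSE
      }
    }
    category <- if (n_fits == 0) "scattered" else
      if (n_fits <= 2) "1-2" else "3plus"
    counts[c("scattered", "one_two", "three_plus")] <-
      counts + c(category == "scattered", category == "1-2",
                 category == "3plus") * length(idx)
    rows[[length(rows) + 1]] <- tibble::tibble(
      cluster = id, n_locs = length(idx), n_fits = n_fits,
      category = category
    )
  }
  fits_per_cluster <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(cluster = integer(), n_locs = integer(),
                   n_fits = integer(), category = character())
  structure(list(
    n_locs = n,
    fraction_scattered = unname(counts["scattered"] / n),
    fraction_1_2 = unname(counts["one_two"] / n),
    fraction_3plus = unname(counts["three_plus"] / n),
    fits_per_cluster = fits_per_cluster, fits = all_fits, empty = FALSE
  ), class = "region_classification")
}

#' @export
print.region_classification <- function(x, ...) {
  cat(sprintf(
    "Region: %d localizations | scattered %.1f%% | 1-2 nucleosomes %.1f%% | >=3 nucleosomes %.1f%%\n",
    x$n_locs, 100 * x$fraction_scattered, 100 * x$fraction_1_2,
    100 * x$fraction_3plus
  ))
  invisible(x)
}
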
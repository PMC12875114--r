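#' Least-squares cylinder fit to a 3D point cloud
#'
#' Fits an infinite-cylinder model (axis line + radius) by minimizing the
#' squared radial residuals of point-to-axis distances. The axis direction
#' is initialized from the first principal component and refined by
#' Nelder-Mead over its spherical angles; for each candidate direction the
#' axis position and radius are profiled out by a 2D circle fit of the
#' points projected onto the orthogonal plane. The cylinder length is the
#' projection range along the fitted axis. The axis sign is fixed to have
#' non-negative dot product with +z (ties: +y, then +x).
#'
#' The reported `r_squared` is computed on radial distances in uncentered
#' form, `1 - sum((d - r)^2) / sum(d^2)`: 1 for points exactly on the
#' surface, decreasing as the radial spread grows relative to the radius.
#'
#' @param points >= 5 non-collinear 3D points (nm); localization tibble or
#'   matrix.
#' @param axis Optional fixed axis direction; skips the orientation search
#'   (used for coaxial stacked fits).
#' @param radius_bounds Optional length-2 radius constraint in nm; the
#'   least-squares radius is clamped into the interval and residuals
#'   recomputed.
#' @return An object of class `cylinder_fit`: `base_point`, `axis`,
#'   `radius`, `diameter`, `length`, `rms_radial_residual`, `r_squared`,
#'   `n`, plus per-point `radial_residuals` and `axial` coordinates.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 21)[-21]
#' pts <- cbind(5.73 * cos(th), 5.73 * sin(th), seq(-10, 10, length.out = 20))
#' fit_cylinder(pts)$radius
#' @export
fit_cylinder <- function(points, axis = NULL, radius_bounds = NULL) {
  xyz <- as_xyz(points)
  n <- nrow(xyz)
  if (n < 5) abort("cylinder fit needs >= 5 points")
  ctr <- colMeans(xyz)
  cm <- sweep(xyz, 2, ctr)
  eg <- eigen(crossprod(cm) / n, symmetric = TRUE)
  if (eg$values[2] < 1e-10 * max(eg$values[1], 1e-12)) {
    abort("degenerate input: points are collinear, cylinder radius unidentifiable",
          class = "chromaflux_degeneracy")
  }
  profile_fit <- function(a) {
    b <- orthobasis(a)
    uv <- cbind(cm %*% b$u, cm %*% b$v)
    circle_fit_2d(uv, refine = FALSE)
  }
  if (is.null(axis)) {
    obj <- function(th) {
      cf <- profile_fit(axis_from_angles(th))
      sum((cf$distances - cf$radius)^2)
    }
    # the cylinder axis is the leading principal direction for elongated
    # clouds but the *smallest* one for disk-like stacks: multi-start
    scale2 <- sum(eg$values)
    best <- NULL
    for (k in 1:3) {
      th <- angles_from_axis(eg$vectors[, k])
      opt <- optim(th, obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 500))
      if (is.null(best) || opt$value < best$value) best <- opt
      if (best$value < 1e-14 * n * scale2) break
    }
    # polish restart so near-exact geometries reach ~1e-6 relative radius
    best <- optim(best$par, obj, method = "Nelder-Mead",
                  control = list(reltol = 1e-15, maxit = 500))
    a <- axis_from_angles(best$par)
  } else {
    a <- normalize_vec(axis)
  }
  a <- canonical_axis(a)
  b <- orthobasis(a)
  uv <- cbind(cm %*% b$u, cm %*% b$v)
  cf <- circle_fit_2d(uv, refine = TRUE)
  r <- cf$radius
  if (!is.null(radius_bounds)) r <- min(max(r, radius_bounds[1]), radius_bounds[2])
  d <- cf$distances
  resid <- d - r
  axial <- drop(cm %*% a)
  axis_center <- ctr + cf$center[1] * b$u + cf$center[2] * b$v
  base_point <- axis_center + min(axial) * a
  structure(
    list(
      base_point = base_point, axis = a, radius = r, diameter = 2 * r,
      length = diff(range(axial)),
      rms_radial_residual = sqrt(mean(resid^2)),
      r_squared = radial_r_squared(d, r),
      n = n, radial_residuals = resid, axial = axial - min(axial)
    ),
    class = "cylinder_fit"
  )
}

#' @export
print.cylinder_fit <- function(x, ...) {
  cat(sprintf(
    "Cylinder fit: d = %.2f nm, L = %.2f nm, rms = %.3f nm, R^2 = %.3f (n = %d)\n",
    x$diameter, x$length, x$rms_radial_residual, x$r_squared, x$n
  ))
  invisible(x)
}

#' Estimate DNA density of a fiber segment
#'
#' Each bound probe molecule marks `footprint_bp` of DNA, and probes can
#' cover at most `max_coverage_fraction` of the (AT-rich) DNA, so
#' `n_locs` localizations imply `n_locs * footprint / coverage` bp of DNA
#' inside the segment cylinder. Density is that DNA amount divided by the
#' cylinder volume, in Mbp per cubic micrometer.
#'
#' @param n_locs Number of localizations in the segment (> 0).
#' @param radius_nm,length_nm Cylinder radius and length in nm (> 0).
#' @param config A [chromaflux_config()] supplying `probe_footprint_bp`
#'   and `max_coverage_fraction`.
#' @return Density in Mbp/um^3.
#' @examples
#' dna_density(100, radius_nm = 15, length_nm = 100) # 21.22 Mbp/um^3
#' @export
dna_density <- function(n_locs, radius_nm, length_nm,
                        config = chromaflux_config()) {
  if (any(n_locs < 1)) abort("`n_locs` must be >= 1")
  if (any(radius_nm <= 0) || any(length_nm <= 0)) {
    abort("undefined density: cylinder volume must be > 0")
  }
  bp <- n_locs * config$probe_footprint_bp / config$max_coverage_fraction
  vol_um3 <- pi * radius_nm^2 * length_nm * 1e-9   # nm^3 -> um^3
  (bp / 1e6) / vol_um3
}

#' Segment a condensed cluster into cylinder-model fiber pieces
#'
#' Points are ordered by projection onto the cluster's first principal
#' axis and partitioned into contiguous axial windows of
#' `segment_window_nm` (a final window narrower than half the width is
#' merged into its neighbor, as is any window with fewer than 5 points).
#' A cylinder is fitted per window; adjacent windows whose diameters
#' differ by less than `merge_tol` (relative) are merged and refitted.
#'
#' @param points Cluster point set (localization tibble or matrix).
#' @param config A [chromaflux_config()] (uses `segment_window_nm`,
#'   `merge_tol`, and the density parameters).
#' @return An object of class `fiber`: `segments` (tibble with
#'   `segment, diameter_nm, length_nm, n_locs, density_mbp_um3,
#'   r_squared, rms_nm`), `total_length_nm`, `membership` (segment index
#'   per input point, `NA` if unsegmentable), `cylinders` (list), and
#'   `unsegmentable` flag.
#' @export
segment_fiber <- function(points, config = chromaflux_config()) {
  xyz <- as_xyz(points)
  n <- nrow(xyz)
  unseg <- function() {
    structure(list(
      segments = tibble::tibble(segment = integer(), diameter_nm = numeric(),
                                length_nm = numeric(), n_locs = integer(),
                                density_mbp_um3 = numeric(),
                                r_squared = numeric(), rms_nm = numeric()),
      total_length_nm = 0, membership = rep(NA_integer_, n),
      cylinders = list(), unsegmentable = TRUE
    ), class = "fiber")
  }
  if (n < 5) return(unseg())
  ctr <- colMeans(xyz)
  cm <- sweep(xyz, 2, ctr)
  eg <- eigen(crossprod(cm) / n, symmetric = TRUE)
  proj <- drop(cm %*% eg$vectors[, 1])
  w <- config$segment_window_nm
  span <- diff(range(proj))
  if (span < w) {
    breaks <- range(proj) + c(-1e-9, 1e-9)
  } else {
    k <- floor(span / w)
    breaks <- min(proj) + seq(0, k) * w
    # merge an undersized trailing window into its neighbor
    if (max(proj) - breaks[length(breaks)] < w / 2) {
      breaks[length(breaks)] <- max(proj) + 1e-9
    } else {
      breaks <- c(breaks, max(proj) + 1e-9)
    }
    breaks[1] <- breaks[1] - 1e-9
  }
  win <- findInterval(proj, breaks, all.inside = TRUE)
  # a cluster shorter than the window is a single free-axis cylinder fit
  if (length(breaks) == 2) {
    fit <- tryCatch(fit_cylinder(xyz), chromaflux_degeneracy = function(e) NULL)
    if (is.null(fit)) return(unseg())
    segments <- tibble::tibble(
      segment = 1L, diameter_nm = fit$diameter, length_nm = fit$length,
      n_locs = n,
      density_mbp_um3 = dna_density(n, fit$radius, fit$length, config),
      r_squared = fit$r_squared, rms_nm = fit$rms_radial_residual
    )
    return(structure(
      list(segments = segments, total_length_nm = fit$length,
           membership = rep(1L, n), cylinders = list(fit),
           unsegmentable = FALSE),
      class = "fiber"
    ))
  }
  # merge windows with < 5 points into the nearest populated neighbor
  repeat {
    cnt <- table(factor(win, levels = sort(unique(win))))
    small <- as.integer(names(cnt))[cnt < 5]
    if (!length(small) || length(unique(win)) == 1) break
    s <- small[1]
    others <- setdiff(sort(unique(win)), s)
    target <- others[which.min(abs(others - s))]
    win[win == s] <- target
  }
  ids <- sort(unique(win))
  if (length(ids) == 1 && sum(win == ids[1]) < 5) return(unseg())
  # window fits share the cluster's principal axis: a window narrower than
  # the fiber diameter is disk-like and a free axis fit is unidentifiable
  cluster_axis <- eg$vectors[, 1]
  fit_window <- function(mask) {
    tryCatch(fit_cylinder(xyz[mask, , drop = FALSE], axis = cluster_axis),
             chromaflux_degeneracy = function(e) NULL)
  }
  fits <- lapply(ids, function(id) fit_window(win == id))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) return(unseg())
  ids <- ids[ok]; fits <- fits[ok]
  # merge adjacent windows with similar diameters, refitting merged runs
  merged_groups <- list(1L)
  for (i in seq_along(ids)[-1]) {
    prev <- merged_groups[[length(merged_groups)]]
    d_prev <- fits[[prev[length(prev)]]]$diameter
    d_cur <- fits[[i]]$diameter
    if (abs(d_cur - d_prev) / mean(c(d_cur, d_prev)) < config$merge_tol) {
      merged_groups[[length(merged_groups)]] <- c(prev, i)
    } else {
      merged_groups[[length(merged_groups) + 1]] <- i
    }
  }
  # point masks per merged run
  masks <- lapply(merged_groups, function(g) win %in% ids[g])
  run_fits <- lapply(seq_along(merged_groups), function(g) {
    if (length(merged_groups[[g]]) > 1) fit_window(masks[[g]]) else
      fits[[merged_groups[[g]]]]
  })
  # a lone window sandwiched between two longer runs usually straddles a
  # diameter step: reassign its points to whichever neighbor cylinder
  # explains them better, then refit both neighbors
  if (length(masks) > 2) {
    resid_to <- function(fit, m) {
      cm <- sweep(xyz[m, , drop = FALSE], 2, fit$base_point)
      ax <- drop(cm %*% fit$axis)
      abs(sqrt(pmax(0, rowSums(cm^2) - ax^2)) - fit$radius)
    }
    repeat {
      lens <- lengths(merged_groups)
      lone <- which(lens == 1)
      lone <- lone[lone > 1 & lone < length(masks)]
      lone <- lone[vapply(lone, function(j) {
        lens[j - 1] > 1 && lens[j + 1] > 1 &&
          !is.null(run_fits[[j - 1]]) && !is.null(run_fits[[j + 1]])
      }, logical(1))]
      if (!length(lone)) break
      j <- lone[1]
      m <- masks[[j]]
      to_prev <- resid_to(run_fits[[j - 1]], m) <=
        resid_to(run_fits[[j + 1]], m)
      prev_mask <- masks[[j - 1]]; next_mask <- masks[[j + 1]]
      prev_mask[which(m)[to_prev]] <- TRUE
      next_mask[which(m)[!to_prev]] <- TRUE
      masks <- c(masks[seq_len(j - 2)], list(prev_mask, next_mask),
                 masks[setdiff(seq_along(masks), seq_len(j + 1))])
      merged_groups <- c(merged_groups[seq_len(j - 2)],
                         merged_groups[c(j - 1, j + 1)],
                         merged_groups[setdiff(seq_along(run_fits),
                                               seq_len(j + 1))])
      run_fits <- lapply(masks, fit_window)
    }
  }
  membership <- rep(NA_integer_, n)
  seg_rows <- list()
  cylinders <- list()
  for (g in seq_along(masks)) {
    mask <- masks[[g]]
    fit <- run_fits[[g]]
    if (is.null(fit)) next
    membership[mask] <- length(seg_rows) + 1L
    cylinders[[length(cylinders) + 1]] <- fit
    seg_rows[[length(seg_rows) + 1]] <- tibble::tibble(
      segment = length(seg_rows) + 1L,
      diameter_nm = fit$diameter, length_nm = fit$length,
      n_locs = sum(mask),
      density_mbp_um3 = dna_density(sum(mask), fit$radius, fit$length, config),
      r_squared = fit$r_squared, rms_nm = fit$rms_radial_residual
    )
  }
  if (!length(seg_rows)) return(unseg())
  segments <- dplyr::bind_rows(seg_rows)
  structure(
    list(segments = segments,
         total_length_nm = sum(segments$length_nm),
         membership = membership, cylinders = cylinders,
         unsegmentable = FALSE),
    class = "fiber"
  )
}

#' @export
print.fiber <- function(x, ...) {
  if (x$unsegmentable) {
    cat("Fiber: unsegmentable cluster\n")
  } else {
    cat(sprintf("Fiber: %d segment(s), total length %.1f nm\n",
                nrow(x$segments), x$total_length_nm))
    print(x$segments)
  }
  invisible(x)
}

#' Summarize a population of fibers
#'
#' @param fibers List of [segment_fiber()] results.
#' @param bin_nm Histogram bin width for segment diameters, nm.
#' @return A list of class `fiber_summary`: `fibers` (tibble
#'   `fiber, total_length_nm, n_segments`), `segments` (per-segment rows
#'   with a `fiber` column), `diameter_histogram` (tibble
#'   `mid_nm, count`), and `modal_diameter_nm` (midpoint of the fullest
#'   bin; `NA` when empty).
#' @export
fiber_summary <- function(fibers, bin_nm = 5) {
  if (bin_nm <= 0) abort("`bin_nm` must be > 0")
  fibers <- Filter(function(f) !f$unsegmentable, fibers)
  if (!length(fibers)) {
    return(structure(list(
      fibers = tibble::tibble(fiber = integer(), total_length_nm = numeric(),
                              n_segments = integer()),
      segments = tibble::tibble(fiber = integer(), segment = integer(),
                                diameter_nm = numeric(), length_nm = numeric(),
                                n_locs = integer(), density_mbp_um3 = numeric(),
                                r_squared = numeric(), rms_nm = numeric()),
      diameter_histogram = tibble::tibble(mid_nm = numeric(), count = integer()),
      modal_diameter_nm = NA_real_, bin_nm = bin_nm
    ), class = "fiber_summary"))
  }
  per_fiber <- dplyr::bind_rows(lapply(seq_along(fibers), function(i) {
    tibble::tibble(fiber = i, total_length_nm = fibers[[i]]$total_length_nm,
                   n_segments = nrow(fibers[[i]]$segments))
  }))
  per_seg <- dplyr::bind_rows(lapply(seq_along(fibers), function(i) {
    dplyr::mutate(fibers[[i]]$segments, fiber = i, .before = 1)
  }))
  d <- per_seg$diameter_nm
  lo <- floor(min(d) / bin_nm) * bin_nm
  brk <- seq(lo, max(d) + bin_nm, by = bin_nm)
  cnt <- tabulate(findInterval(d, brk, all.inside = TRUE),
                  nbins = length(brk) - 1)
  hist_tbl <- tibble::tibble(mid_nm = brk[-length(brk)] + bin_nm / 2,
                             count = cnt)
  structure(list(
    fibers = per_fiber, segments = per_seg, diameter_histogram = hist_tbl,
    modal_diameter_nm = hist_tbl$mid_nm[which.max(hist_tbl$count)],
    bin_nm = bin_nm
  ), class = "fiber_summary")
}
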
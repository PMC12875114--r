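#' Acquisition parameters for the localization simulator
#'
#' Captures the instrument-side characteristics of 3D MINFLUX acquisition
#' of a spontaneously blinking minor-groove DNA probe: near-nanometer
#' anisotropic Gaussian localization error, sub-100-microsecond
#' localization time, and (by default) at most one sighting per probe,
#' since blinking plus probe exchange makes re-localization of the same
#' probe at the same position rare.
#'
#' @param precision_fwhm Per-axis localization precision FWHM in nm
#'   (defaults 1.08 / 0.96 / 0.63 for x / y / z).
#' @param detection_prob Probability that a bound probe is localized at
#'   all (subsampling; lower in living cells than in fixed cells).
#' @param relocalization_rate Expected number of *extra* sightings per
#'   detected probe (Poisson); default 0.
#' @param background_rate False-positive background localizations per
#'   cubic micrometer.
#' @param t_per_loc_us Acquisition time per localization, microseconds.
#' @return A named list of class `acquisition_params`.
#' @export
acquisition_params <- function(precision_fwhm = c(x = 1.08, y = 0.96, z = 0.63),
                               detection_prob = 1,
                               relocalization_rate = 0,
                               background_rate = 0,
                               t_per_loc_us = 93.7) {
  stopifnot(length(precision_fwhm) == 3, all(precision_fwhm > 0))
  if (detection_prob < 0 || detection_prob > 1) {
    abort("`detection_prob` must be in [0, 1]")
  }
  if (relocalization_rate < 0 || background_rate < 0 || t_per_loc_us <= 0) {
    abort("rates must be >= 0 and `t_per_loc_us` > 0")
  }
  structure(
    list(precision_fwhm = precision_fwhm, detection_prob = detection_prob,
         relocalization_rate = relocalization_rate,
         background_rate = background_rate, t_per_loc_us = t_per_loc_us),
    class = "acquisition_params"
  )
}

# Superhelix path constants: ~1.65 left-handed turns of DNA over wrap_bp,
# center path radius 4.2 nm, total rise ~5.7 nm (the disk height).
SUPERHELIX_TURNS <- 1.65
SUPERHELIX_PATH_RADIUS <- 4.2
SUPERHELIX_RISE <- 5.7
# Radial band of probe positions on the DNA cross-section (minor-groove
# fluorophore near the outer envelope); calibrated so the mean probe radius
# of 5.75 nm reproduces the ~11.5-nm diameters measured from probe clouds.
PROBE_RADIAL_BAND <- c(5.0, 6.5)

#' Generate a ground-truth nucleosome with probe sites
#'
#' Probe sites are placed at 12-bp spacing along a left-handed superhelical
#' DNA path (1.65 turns, path radius 4.2 nm, rise 5.7 nm over `wrap_bp`),
#' each at a radial distance drawn uniformly from the probe band to emulate
#' minor-groove fluorophore positions on the DNA cross-section. Each site
#' is available for binding with probability `at_fraction` (AT-richness
#' draw); bound sites are then truncated to the coverage cap
#' `floor(wrap_bp * max_coverage_fraction / footprint)`.
#'
#' @param center Length-3 numeric, nucleosome center in nm.
#' @param axis Length-3 axis direction (normalized internally); random
#'   uniform orientation when `NULL`.
#' @param at_fraction Per-footprint probability that the site is AT-rich
#'   enough to bind the probe, in `[0, 1]`.
#' @param config A [chromaflux_config()].
#' @return A list of class `nucleosome_truth`: `center`, `axis`,
#'   `diameter_nm`, `wrap_bp`, and `sites` (tibble with `bp`, `x`, `y`,
#'   `z`, `bound`).
#' @export
make_nucleosome <- function(center = c(0, 0, 0), axis = NULL,
                            at_fraction = 0.6,
                            config = chromaflux_config()) {
  if (at_fraction < 0 || at_fraction > 1) abort("`at_fraction` must be in [0, 1]")
  if (is.null(axis)) axis <- runif_sphere(1)[1, ]
  axis <- normalize_vec(axis)
  fp <- config$probe_footprint_bp
  wrap <- config$wrap_bp
  n_sites <- floor(wrap / fp)
  bp <- (seq_len(n_sites) - 0.5) * fp          # footprint centers, >= fp apart
  frac <- bp / wrap
  angle <- -2 * pi * SUPERHELIX_TURNS * frac   # left-handed
  axial <- SUPERHELIX_RISE * (frac - 0.5)
  radial <- runif(n_sites, PROBE_RADIAL_BAND[1], PROBE_RADIAL_BAND[2])
  b <- orthobasis(axis)
  pos <- outer(radial * cos(angle), b$u) + outer(radial * sin(angle), b$v) +
    outer(axial, b$w)
  pos <- sweep(pos, 2, center, `+`)
  bound <- runif(n_sites) < at_fraction
  cap <- max_probes_per_nucleosome(config)
  if (sum(bound) > cap) {
    keep <- sample(which(bound), cap)
    bound <- seq_len(n_sites) %in% keep
  }
  structure(
    list(
      center = center, axis = axis,
      diameter_nm = config$nucleosome_diameter_nm, wrap_bp = wrap,
      sites = tibble::tibble(bp = bp, x = pos[, 1], y = pos[, 2],
                             z = pos[, 3], bound = bound)
    ),
    class = "nucleosome_truth"
  )
}

# Expected bound probes per nucleosome under the Bernoulli draw + cap.
expected_bound_probes <- function(at_fraction, config = chromaflux_config()) {
  n_sites <- floor(config$wrap_bp / config$probe_footprint_bp)
  cap <- max_probes_per_nucleosome(config)
  k <- 0:n_sites
  sum(pmin(k, cap) * dbinom(k, n_sites, at_fraction))
}

# Nucleosomes per nm of fiber that make the probe-count density estimator
# unbiased for `target_density` Mbp/um^3 in a cylinder of diameter `d` nm.
linear_density_for <- function(target_density, diameter_nm, at_fraction,
                               config = chromaflux_config()) {
  bp_per_nm <- target_density * pi * (diameter_nm / 2)^2 * 1e-3
  est_bp_per_nuc <- expected_bound_probes(at_fraction, config) *
    config$probe_footprint_bp / config$max_coverage_fraction
  bp_per_nm / est_bp_per_nuc
}

#' Generate a ground-truth chromatin fiber
#'
#' The centerline is a smoothed random walk honoring a maximum curvature;
#' the fiber is partitioned along its arc length into segments of given
#' diameters. Nucleosomes are placed solenoid-style on the shell of radius
#' diameter/2 around the centerline with random disk orientation, at a
#' linear density calibrated so that probe counts recover the target DNA
#' density.
#'
#' @param length_nm Total fiber length in nm.
#' @param diameter_profile Either a single diameter (nm) or a data frame /
#'   tibble with columns `length_nm` and `diameter_nm` partitioning the
#'   centerline. All diameters must exceed the nucleosome diameter.
#' @param curvature Maximum bend in radians per nm of arc length (0 gives
#'   a straight fiber).
#' @param target_density Target DNA density in Mbp/um^3.
#' @param at_fraction AT-availability per probe footprint.
#' @param start,direction Start point and initial direction.
#' @param config A [chromaflux_config()].
#' @return A list of class `fiber_truth`: `centerline` (matrix),
#'   `segments` (tibble `start_nm,end_nm,diameter_nm`), `nucleosomes`
#'   (list of [make_nucleosome()] results), `length_nm`.
#' @export
make_fiber <- function(length_nm, diameter_profile = 35, curvature = 0,
                       target_density = 34, at_fraction = 0.6,
                       start = c(0, 0, 0), direction = c(1, 0, 0),
                       config = chromaflux_config()) {
  if (length_nm <= 0) abort("`length_nm` must be > 0")
  if (is.numeric(diameter_profile) && is.null(dim(diameter_profile))) {
    diameter_profile <- tibble::tibble(length_nm = length_nm,
                                       diameter_nm = diameter_profile)
  }
  segs <- tibble::as_tibble(diameter_profile)
  if (!all(c("length_nm", "diameter_nm") %in% names(segs))) {
    abort("`diameter_profile` needs columns `length_nm` and `diameter_nm`")
  }
  if (any(segs$diameter_nm <= config$nucleosome_diameter_nm)) {
    abort("segment diameter must exceed the nucleosome diameter (cannot pack nucleosomes)")
  }
  segs$length_nm <- segs$length_nm * length_nm / sum(segs$length_nm)
  segs <- dplyr::mutate(segs,
                        end_nm = cumsum(.data$length_nm),
                        start_nm = .data$end_nm - .data$length_nm)

  # centerline: fixed 2-nm steps, bend angle <= curvature * step
  step <- 2
  n_steps <- ceiling(length_nm / step)
  dir <- normalize_vec(direction)
  pts <- matrix(0, n_steps + 1, 3)
  pts[1, ] <- start
  for (i in seq_len(n_steps)) {
    if (curvature > 0) {
      bend <- runif(1, 0, curvature * step)
      b <- orthobasis(dir)
      phi <- runif(1, 0, 2 * pi)
      perp <- cos(phi) * b$u + sin(phi) * b$v
      dir <- normalize_vec(cos(bend) * dir + sin(bend) * perp)
    }
    pts[i + 1, ] <- pts[i, ] + step * dir
  }
  arc <- seq(0, by = step, length.out = n_steps + 1)

  point_at <- function(s) {
    s <- min(max(s, 0), arc[length(arc)])
    i <- findInterval(s, arc, all.inside = TRUE)
    w <- (s - arc[i]) / step
    p <- (1 - w) * pts[i, ] + w * pts[i + 1, ]
    tangent <- normalize_vec(pts[i + 1, ] - pts[i, ])
    list(p = p, tangent = tangent)
  }

  nucleosomes <- list()
  for (si in seq_len(nrow(segs))) {
    d <- segs$diameter_nm[si]
    lam <- linear_density_for(target_density, d, at_fraction, config)
    n_nuc <- max(1L, round(lam * segs$length_nm[si]))
    # inset placements so the probe envelope straddles the nominal length
    # symmetrically (typical axial probe offsets are about half the outer
    # probe radius)
    inset <- min(PROBE_RADIAL_BAND[2] / 2, segs$length_nm[si] / 4)
    usable <- segs$length_nm[si] - 2 * inset
    s_pos <- segs$start_nm[si] + inset +
      (seq_len(n_nuc) - 0.5) * usable / n_nuc
    for (s in s_pos) {
      pa <- point_at(s)
      b <- orthobasis(pa$tangent)
      phi <- runif(1, 0, 2 * pi)
      ctr <- pa$p + (d / 2) * (cos(phi) * b$u + sin(phi) * b$v)
      nuc <- make_nucleosome(center = ctr, axis = NULL,
                             at_fraction = at_fraction, config = config)
      nuc$arc_pos <- s
      nucleosomes[[length(nucleosomes) + 1]] <- nuc
    }
  }
  structure(
    list(centerline = pts, arc = arc,
         segments = segs[, c("start_nm", "end_nm", "diameter_nm")],
         nucleosomes = nucleosomes, length_nm = length_nm,
         target_density = target_density, at_fraction = at_fraction),
    class = "fiber_truth"
  )
}

#' Ground-truth DNA density of a generated fiber, per segment
#'
#' Applies the probe-count density estimator ([dna_density()]) to the
#' generator's own truth: bound probe sites counted per segment, with the
#' segment's nominal cylinder (radius diameter/2, nominal length). At full
#' detection this is what a perfect analysis would measure, so it isolates
#' the generator calibration from fitting error.
#'
#' @param fiber A [make_fiber()] object.
#' @param config A [chromaflux_config()].
#' @return Tibble with `segment, diameter_nm, length_nm, n_bound_sites,
#'   density_mbp_um3`.
#' @export
fiber_truth_density <- function(fiber, config = chromaflux_config()) {
  segs <- fiber$segments
  arc_pos <- vapply(fiber$nucleosomes, function(nu) nu$arc_pos %||% NA_real_,
                    numeric(1))
  rows <- lapply(seq_len(nrow(segs)), function(si) {
    in_seg <- which(arc_pos >= segs$start_nm[si] & arc_pos < segs$end_nm[si])
    n_bound <- sum(vapply(fiber$nucleosomes[in_seg],
                          function(nu) sum(nu$sites$bound), integer(1)))
    tibble::tibble(
      segment = si, diameter_nm = segs$diameter_nm[si],
      length_nm = segs$end_nm[si] - segs$start_nm[si],
      n_bound_sites = n_bound,
      density_mbp_um3 = if (n_bound > 0) {
        dna_density(n_bound, segs$diameter_nm[si] / 2,
                    segs$end_nm[si] - segs$start_nm[si], config)
      } else 0
    )
  })
  dplyr::bind_rows(rows)
}

#' Assemble a synthetic scene
#'
#' A scene bundles ground-truth structures — fibers, free nucleosomes and
#' scattered single probe sites — in a simulation box, assigning globally
#' unique site ids so that every simulated localization can be linked back
#' to the truth site it came from.
#'
#' @param fibers List of [make_fiber()] objects.
#' @param nucleosomes List of [make_nucleosome()] objects (free, outside
#'   fibers).
#' @param n_scattered Number of scattered single probe sites, uniform in
#'   the box.
#' @param box 2 x 3 matrix of box limits in nm (rows min/max); `NULL`
#'   computes a bounding box with a 50-nm margin.
#' @return A list of class `chromaflux_scene` with a `sites` tibble
#'   (`site_id,x,y,z,bound,parent_type,parent_id`).
#' @export
make_scene <- function(fibers = list(), nucleosomes = list(),
                       n_scattered = 0, box = NULL) {
  take_sites <- function(obj, type, id) {
    s <- obj$sites
    tibble::tibble(x = s$x, y = s$y, z = s$z, bound = s$bound,
                   parent_type = type, parent_id = id)
  }
  parts <- list()
  for (i in seq_along(fibers)) {
    for (j in seq_along(fibers[[i]]$nucleosomes)) {
      parts[[length(parts) + 1]] <-
        take_sites(fibers[[i]]$nucleosomes[[j]], "fiber", i)
    }
  }
  for (i in seq_along(nucleosomes)) {
    parts[[length(parts) + 1]] <- take_sites(nucleosomes[[i]], "nucleosome", i)
  }
  sites <- if (length(parts)) dplyr::bind_rows(parts) else
    tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                   bound = logical(), parent_type = character(),
                   parent_id = integer())
  if (is.null(box)) {
    if (nrow(sites)) {
      m <- as_xyz(sites)
      box <- rbind(apply(m, 2, min) - 50, apply(m, 2, max) + 50)
    } else {
      box <- rbind(c(0, 0, 0), c(1000, 1000, 1000))
    }
  }
  if (n_scattered > 0) {
    sc <- tibble::tibble(
      x = runif(n_scattered, box[1, 1], box[2, 1]),
      y = runif(n_scattered, box[1, 2], box[2, 2]),
      z = runif(n_scattered, box[1, 3], box[2, 3]),
      bound = TRUE, parent_type = "scattered",
      parent_id = seq_len(n_scattered)
    )
    sites <- dplyr::bind_rows(sites, sc)
  }
  sites$site_id <- seq_len(nrow(sites))
  structure(
    list(fibers = fibers, nucleosomes = nucleosomes,
         sites = sites[, c("site_id", "x", "y", "z", "bound",
                           "parent_type", "parent_id")],
         box = box),
    class = "chromaflux_scene"
  )
}

#' Simulate MINFLUX localizations from a synthetic scene
#'
#' Each bound probe site is detected independently with
#' `detection_prob`; every detection (plus any Poisson re-sightings) is
#' displaced by independent per-axis Gaussian error with
#' `sigma = FWHM / (2 sqrt(2 log 2))`. Background false positives are drawn
#' uniformly in the box at `background_rate` per um^3. Timestamps are
#' assigned sequentially at `t_per_loc_us` spacing in randomized order.
#'
#' @param scene A [make_scene()] object.
#' @param acq An [acquisition_params()] object.
#' @return A [loc_table()] with a `truth` attribute: tibble
#'   `uid, site_id` (`NA` site for background).
#' @export
simulate_localizations <- function(scene, acq = acquisition_params()) {
  sites <- scene$sites[scene$sites$bound, , drop = FALSE]
  det <- sites[runif(nrow(sites)) < acq$detection_prob, , drop = FALSE]
  n_extra <- if (acq$relocalization_rate > 0 && nrow(det)) {
    rpois(nrow(det), acq$relocalization_rate)
  } else {
    rep(0L, nrow(det))
  }
  idx <- rep(seq_len(nrow(det)), 1 + n_extra)
  pos <- as_xyz(det)[idx, , drop = FALSE]
  site_id <- det$site_id[idx]
  vol_um3 <- prod(scene$box[2, ] - scene$box[1, ]) * 1e-9
  n_bg <- if (acq$background_rate > 0) rpois(1, acq$background_rate * vol_um3) else 0L
  if (n_bg > 0) {
    bg <- cbind(runif(n_bg, scene$box[1, 1], scene$box[2, 1]),
                runif(n_bg, scene$box[1, 2], scene$box[2, 2]),
                runif(n_bg, scene$box[1, 3], scene$box[2, 3]))
    pos <- rbind(pos, bg)
    site_id <- c(site_id, rep(NA_integer_, n_bg))
  }
  n <- nrow(pos)
  sig <- fwhm_to_sigma(acq$precision_fwhm)
  if (n > 0) {
    pos <- pos + cbind(rnorm(n, 0, sig[1]), rnorm(n, 0, sig[2]),
                       rnorm(n, 0, sig[3]))
  }
  ord <- if (n > 1) sample.int(n) else seq_len(n)
  pos <- pos[ord, , drop = FALSE]
  site_id <- site_id[ord]
  tbl <- loc_table(
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    t = seq_len(n) * acq$t_per_loc_us,
    photons = rep(100, n),
    precision_fwhm = acq$precision_fwhm
  )
  attr(tbl, "truth") <- tibble::tibble(uid = tbl$uid, site_id = site_id)
  tbl
}

#' Generate a 2D line-pattern localization table for resolution tests
#'
#' A known-structure target for Fourier ring correlation: parallel lines of
#' condensed localization clusters at a fixed pitch, with the clusters also
#' spaced at the pitch along each line, so the scene carries structure at
#' the pitch scale in both image directions. Cluster width defaults to a
#' 24-nm FWHM, within the range of condensed-spot widths seen in 2D
#' MINFLUX DNA imaging.
#'
#' Cluster centers are jittered about the lattice (a fifth of the pitch
#' by default): a mathematically perfect lattice has no spectral power
#' between its harmonics, which real chromatin does not share and which
#' makes threshold crossings erratic.
#'
#' @param field_nm Square field edge in nm.
#' @param pitch_nm Line and cluster spacing in nm.
#' @param blob_fwhm_nm Cluster FWHM in nm.
#' @param per_blob Mean localizations per cluster (Poisson).
#' @param center_jitter_nm Standard deviation of cluster-center jitter.
#' @return A [loc_table()] (2D).
#' @export
make_line_pattern <- function(field_nm = 600, pitch_nm = 30,
                              blob_fwhm_nm = 24, per_blob = 60,
                              center_jitter_nm = pitch_nm / 5) {
  sigma <- fwhm_to_sigma(blob_fwhm_nm)
  centers <- seq(pitch_nm / 2, field_nm, by = pitch_nm)
  grid <- expand.grid(cx = centers, cy = centers)
  grid$cx <- grid$cx + rnorm(nrow(grid), 0, center_jitter_nm)
  grid$cy <- grid$cy + rnorm(nrow(grid), 0, center_jitter_nm)
  counts <- rpois(nrow(grid), per_blob)
  n <- sum(counts)
  x <- rnorm(n, rep(grid$cx, times = counts), sigma)
  y <- rnorm(n, rep(grid$cy, times = counts), sigma)
  ord <- sample.int(n)
  loc_table(x = x[ord], y = y[ord])
}

#' Apply a TSA-like decompaction to a scene
#'
#' Emulates histone-deacetylase-inhibitor treatment: a fraction `severity`
#' of fibers is dissolved — their nucleosomes are released and dispersed to
#' random positions in the box, with a fraction of them re-scattered as
#' free single probes; surviving fibers are truncated to < 50 nm. Segment
#' diameters are left unchanged.
#'
#' @param scene A [make_scene()] object.
#' @param severity Fraction of fibers dissolved, in `[0, 1]`.
#' @param rescatter_fraction Fraction of released nucleosomes converted to
#'   scattered single probes.
#' @param config A [chromaflux_config()].
#' @return A new `chromaflux_scene`.
#' @export
apply_tsa <- function(scene, severity, rescatter_fraction = 0.5,
                      config = chromaflux_config()) {
  if (severity < 0 || severity > 1) abort("`severity` must be in [0, 1]")
  if (severity == 0) return(scene)
  box <- scene$box
  released <- list()
  survivors <- list()
  for (f in scene$fibers) {
    if (runif(1) < severity) {
      released <- c(released, f$nucleosomes)
    } else {
      keep_len <- runif(1, 30, 49)
      keep_nuc <- list()
      # retain nucleosomes within the kept arc length (placement order
      # follows arc position within each fiber)
      n_keep <- max(1L, floor(length(f$nucleosomes) * keep_len / f$length_nm))
      keep_nuc <- f$nucleosomes[seq_len(min(n_keep, length(f$nucleosomes)))]
      f$nucleosomes <- keep_nuc
      f$length_nm <- keep_len
      survivors[[length(survivors) + 1]] <- f
    }
  }
  n_rel <- length(released)
  free_nuc <- scene$nucleosomes
  n_scatter_extra <- 0L
  if (n_rel > 0) {
    scatter <- runif(n_rel) < rescatter_fraction
    for (i in which(!scatter)) {
      nuc <- released[[i]]
      new_ctr <- c(runif(1, box[1, 1], box[2, 1]),
                   runif(1, box[1, 2], box[2, 2]),
                   runif(1, box[1, 3], box[2, 3]))
      shift <- new_ctr - nuc$center
      nuc$center <- new_ctr
      nuc$sites$x <- nuc$sites$x + shift[1]
      nuc$sites$y <- nuc$sites$y + shift[2]
      nuc$sites$z <- nuc$sites$z + shift[3]
      free_nuc[[length(free_nuc) + 1]] <- nuc
    }
    n_scatter_extra <- sum(vapply(released[scatter],
                                  function(nu) sum(nu$sites$bound),
                                  integer(1)))
  }
  prev_scatter <- sum(scene$sites$parent_type == "scattered")
  make_scene(fibers = survivors, nucleosomes = free_nuc,
             n_scattered = prev_scatter + n_scatter_extra, box = box)
}
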
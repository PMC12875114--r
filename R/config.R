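#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis pipeline in one named
#' list, with defaults drawn from the biology of the probe and the imaging
#' mode: a minor-groove DNA dye occupies a 12-bp footprint and can cover at
#' most ~80% of AT-rich nucleosomal DNA; a nucleosome wraps 147 bp into an
#' ~11-nm disk; the dual-color spectral split uses a ratio threshold of
#' 0.415; Fourier ring correlation is read at the 1/7 threshold.
#'
#' @param dbscan_eps DBSCAN neighborhood radius in nm.
#' @param dbscan_min_pts Minimum neighbors (self included) for a core point.
#' @param probe_footprint_bp DNA footprint of one probe molecule, bp.
#' @param max_coverage_fraction Maximum fraction of nucleosomal DNA the probe
#'   can cover (AT-richness ceiling), in (0, 1].
#' @param nucleosomal_dna_bp Accessible nucleosomal DNA used for occupancy
#'   arithmetic, bp.
#' @param wrap_bp Total DNA wrapped per nucleosome, bp.
#' @param nucleosome_diameter_nm Nominal nucleosome disk diameter, nm.
#' @param ratio_threshold Spectral ratio ch1/(ch1+ch2) above which a
#'   localization is assigned to the DNA channel.
#' @param frc_threshold Fixed FRC resolution threshold.
#' @param frc_pixel_nm Pixel size used to render FRC half-images, nm.
#' @param attach_tol_nm Radial residual below which a probe counts as
#'   attached to a fitted nucleosome cylinder, nm (~3x localization sigma).
#' @param segment_window_nm Axial window width for fiber segmentation, nm.
#' @param merge_tol Relative diameter difference below which adjacent fiber
#'   segments are merged.
#' @param nucleosome_band_nm Accepted fitted-diameter band for nucleosome
#'   fits, nm (length-2).
#' @param radius_bounds_nm Radius constraint for nucleosome-scale cylinder
#'   fits, nm (length-2).
#' @param nucleosome_window_nm Candidate window edge for single-nucleosome
#'   fitting, nm.
#' @param height_cap_nm Maximum height of a nucleosome cylinder fit, nm.
#' @param two_pass If `TRUE`, cluster, drop noise, and re-cluster.
#' @param tilt_corrected If `TRUE`, ring fits minimize the full 3D geometric
#'   residual over the plane orientation instead of fixing the plane to the
#'   two leading principal axes.
#' @param rng_seed Optional integer seed recorded in run manifests.
#'
#' @return A named list of class `chromaflux_config`.
#' @examples
#' cfg <- chromaflux_config(dbscan_eps = 15)
#' cfg$dbscan_eps
#' @export
chromaflux_config <- function(dbscan_eps = 20,
                              dbscan_min_pts = 5,
                              probe_footprint_bp = 12,
                              max_coverage_fraction = 0.8,
                              nucleosomal_dna_bp = 140,
                              wrap_bp = 147,
                              nucleosome_diameter_nm = 11,
                              ratio_threshold = 0.415,
                              frc_threshold = 1 / 7,
                              frc_pixel_nm = 2,
                              attach_tol_nm = 1.5,
                              segment_window_nm = 25,
                              merge_tol = 0.2,
                              nucleosome_band_nm = c(9, 14),
                              radius_bounds_nm = c(4.5, 7),
                              nucleosome_window_nm = 18,
                              height_cap_nm = 8,
                              two_pass = FALSE,
                              tilt_corrected = FALSE,
                              rng_seed = NULL) {
  cfg <- list(
    dbscan_eps = dbscan_eps, dbscan_min_pts = dbscan_min_pts,
    probe_footprint_bp = probe_footprint_bp,
    max_coverage_fraction = max_coverage_fraction,
    nucleosomal_dna_bp = nucleosomal_dna_bp, wrap_bp = wrap_bp,
    nucleosome_diameter_nm = nucleosome_diameter_nm,
    ratio_threshold = ratio_threshold, frc_threshold = frc_threshold,
    frc_pixel_nm = frc_pixel_nm, attach_tol_nm = attach_tol_nm,
    segment_window_nm = segment_window_nm, merge_tol = merge_tol,
    nucleosome_band_nm = nucleosome_band_nm,
    radius_bounds_nm = radius_bounds_nm,
    nucleosome_window_nm = nucleosome_window_nm,
    height_cap_nm = height_cap_nm,
    two_pass = isTRUE(two_pass), tilt_corrected = isTRUE(tilt_corrected),
    rng_seed = rng_seed
  )
  validate_config(cfg)
  structure(cfg, class = "chromaflux_config")
}

validate_config <- function(cfg) {
  lengths_pos <- c(
    "dbscan_eps", "probe_footprint_bp", "nucleosomal_dna_bp", "wrap_bp",
    "nucleosome_diameter_nm", "frc_pixel_nm", "attach_tol_nm",
    "segment_window_nm", "nucleosome_window_nm", "height_cap_nm"
  )
  for (nm in lengths_pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      abort(paste0("`", nm, "` must be a single positive number"))
    }
  }
  if (cfg$dbscan_min_pts < 1) abort("`dbscan_min_pts` must be >= 1")
  if (cfg$max_coverage_fraction <= 0 || cfg$max_coverage_fraction > 1) {
    abort("`max_coverage_fraction` must be in (0, 1]")
  }
  if (cfg$ratio_threshold <= 0 || cfg$ratio_threshold >= 1) {
    abort("`ratio_threshold` must be in (0, 1)")
  }
  if (cfg$frc_threshold <= 0 || cfg$frc_threshold >= 1) {
    abort("`frc_threshold` must be in (0, 1)")
  }
  if (cfg$merge_tol < 0) abort("`merge_tol` must be >= 0")
  for (nm in c("nucleosome_band_nm", "radius_bounds_nm")) {
    b <- cfg[[nm]]
    if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1]) {
      abort(paste0("`", nm, "` must be an increasing positive pair"))
    }
  }
  invisible(cfg)
}

#' Read / write a flat key-value configuration file
#'
#' The on-disk format is one `key = value` pair per line (`#` comments
#' allowed). Numeric values are parsed; length-2 parameters are written as
#' comma-separated pairs. Keys not named in [chromaflux_config()] are
#' rejected, which catches typos before they silently fall back to defaults.
#'
#' @param path File path.
#' @param config A `chromaflux_config` object.
#' @return `read_config()` returns a `chromaflux_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  defaults <- chromaflux_config()
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) abort(paste0("malformed config line: '", ln, "'"))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults)) abort(paste0("unknown config key: ", key))
    parsed <- if (val %in% c("TRUE", "FALSE")) {
      as.logical(val)
    } else {
      as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
    }
    if (anyNA(parsed)) abort(paste0("non-numeric value for key ", key))
    args[[key]] <- parsed
  }
  do.call(chromaflux_config, args)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "chromaflux_config"))
  keep <- !vapply(config, is.null, logical(1))
  lines <- vapply(
    names(config)[keep],
    function(nm) paste0(nm, " = ", paste(config[[nm]], collapse = ",")),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Probe occupancy arithmetic
#'
#' A bound probe occupies `probe_footprint_bp` of DNA, so `n_probes` probes
#' occupy `n_probes * footprint` bp, and the fraction of nucleosomal DNA
#' they cover is that occupancy divided by `nucleosomal_dna_bp`. The number
#' of probes that can bind one nucleosome is capped by the AT-coverage
#' ceiling: `floor(wrap_bp * max_coverage_fraction / footprint)`.
#'
#' @param n_probes Number of bound probes.
#' @param config A [chromaflux_config()].
#' @return `occupied_bp()`: bp occupied. `occupied_fraction()`: fraction of
#'   nucleosomal DNA covered. `max_probes_per_nucleosome()`: integer cap.
#' @examples
#' occupied_bp(10)                 # 120 bp
#' occupied_fraction(5)            # 60/140 = 0.4286
#' max_probes_per_nucleosome()     # floor(147*0.8/12) = 9
#' @export
occupied_bp <- function(n_probes, config = chromaflux_config()) {
  n_probes * config$probe_footprint_bp
}

#' @rdname occupied_bp
#' @export
occupied_fraction <- function(n_probes, config = chromaflux_config()) {
  occupied_bp(n_probes, config) / config$nucleosomal_dna_bp
}

#' @rdname occupied_bp
#' @export
max_probes_per_nucleosome <- function(config = chromaflux_config()) {
  floor(config$wrap_bp * config$max_coverage_fraction /
          config$probe_footprint_bp)
}
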
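#' Run the full analysis pipeline on a localization table
#'
#' Executes clustering, fiber segmentation, nucleosome extraction and
#' region classification in order, returning every intermediate result.
#' Only clusters whose long axis reaches the segmentation window are
#' segmented as fibers.
#'
#' @param table Localization table.
#' @param config A [chromaflux_config()].
#' @return List of class `chromaflux_run`: `clustered` (table with
#'   `cluster` column), `geometry` (per-cluster tibble), `fibers` (list of
#'   [segment_fiber()] results, named by cluster), `fiber_summary`,
#'   `classification` ([classify_region()] result), `config`.
#' @export
run_pipeline <- function(table, config = chromaflux_config()) {
  clustered <- cluster_localizations(table, eps = config$dbscan_eps,
                                     min_pts = config$dbscan_min_pts,
                                     two_pass = config$two_pass)
  geom <- cluster_geometry(clustered)
  fibers <- list()
  for (i in seq_len(nrow(geom))) {
    if (geom$long_axis_length_nm[i] < config$segment_window_nm) next
    pts <- clustered[clustered$cluster == geom$cluster[i], , drop = FALSE]
    fibers[[as.character(geom$cluster[i])]] <- segment_fiber(pts, config)
  }
  structure(list(
    clustered = clustered, geometry = geom, fibers = fibers,
    fiber_summary = fiber_summary(fibers),
    classification = classify_region(clustered, config = config),
    config = config
  ), class = "chromaflux_run")
}

#' Write a report bundle of summary tables
#'
#' Writes the pipeline's summary tables as CSV plus a JSON run manifest
#' (configuration, seed, package version). Outputs are deterministic:
#' rerunning with the same inputs produces byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param fibers A [fiber_summary()] object (optional).
#' @param fits List of nucleosome/ring fits (optional).
#' @param classifications Data frame of per-region fractions (optional),
#'   e.g. rows of `glance()` over [classify_region()] results.
#' @param comparisons A [one_way_anova()] / [dunnett_test()] tibble
#'   (optional).
#' @param config A [chromaflux_config()] recorded in the manifest.
#' @param seed Seed recorded in the manifest.
#' @return Character vector of written file paths, invisibly.
#' @export
build_report <- function(dir, fibers = NULL, fits = NULL,
                         classifications = NULL, comparisons = NULL,
                         config = chromaflux_config(), seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(dir, name)
    readr::write_csv(df, path)
    written <<- c(written, path)
  }
  if (!is.null(fibers)) {
    emit(fibers$fibers, "fiber_lengths.csv")
    emit(fibers$segments, "segment_diameters.csv")
  }
  if (!is.null(fits) && length(fits)) {
    dh <- diameter_histogram(fits)
    emit(dh$histogram, "nucleosome_diameters.csv")
  }
  if (!is.null(classifications)) emit(tibble::as_tibble(classifications),
                                      "region_fractions.csv")
  if (!is.null(comparisons)) emit(tibble::as_tibble(comparisons),
                                  "group_comparisons.csv")
  manifest <- list(
    package = "chromaflux",
    version = as.character(utils::packageVersion("chromaflux")),
    seed = seed,
    config = unclass(config)[!vapply(config, is.null, logical(1))]
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  written <- c(written, manifest_path)
  invisible(written)
}
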
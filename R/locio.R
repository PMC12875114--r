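#' Build a validated localization table
#'
#' The central record set of the pipeline: one row per localization, with
#' 3D coordinates in nm, an acquisition timestamp in microseconds, a photon
#' count, and optional two-channel spectral counts for dual-color data.
#'
#' @param x,y,z Coordinates in nm. `z` may be omitted for 2D data (stored
#'   as 0 by convention).
#' @param t Acquisition timestamps in microseconds (optional).
#' @param photons Photon counts (optional, non-negative).
#' @param ch1,ch2 Spectral detector counts (optional, non-negative).
#' @param uid Unique record index; defaults to the row sequence.
#' @param precision_fwhm Per-axis localization precision FWHM in nm.
#'
#' @return A tibble of class `loc_table` with columns
#'   `uid, x, y, z, t, photons, ch1, ch2` and attributes `dim` (2 or 3),
#'   `precision_fwhm` and `units = "nm"`.
#' @examples
#' loc_table(x = rnorm(5), y = rnorm(5), z = rnorm(5))
#' @export
loc_table <- function(x, y, z = NULL, t = NULL, photons = NULL,
                      ch1 = NULL, ch2 = NULL, uid = NULL,
                      precision_fwhm = c(x = 1.08, y = 0.96, z = 0.63)) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length")
  dim <- if (is.null(z) || n == 0 || all(z == z[1])) 2L else 3L
  if (is.null(z)) z <- rep(0, n)
  if (is.null(uid)) uid <- seq_len(n)
  if (anyDuplicated(uid)) abort("`uid` must be unique within a table")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z))) {
    abort("coordinates must be finite")
  }
  if (!is.null(photons) && any(photons < 0, na.rm = TRUE)) {
    abort("`photons` must be non-negative")
  }
  for (ch in list(ch1, ch2)) {
    if (!is.null(ch) && any(ch < 0, na.rm = TRUE)) {
      abort("channel counts must be non-negative")
    }
  }
  na_col <- rep(NA_real_, n)
  tbl <- tibble::tibble(
    uid = as.integer(uid), x = as.numeric(x), y = as.numeric(y),
    z = as.numeric(z),
    t = if (is.null(t)) na_col else as.numeric(t),
    photons = if (is.null(photons)) na_col else as.numeric(photons),
    ch1 = if (is.null(ch1)) na_col else as.numeric(ch1),
    ch2 = if (is.null(ch2)) na_col else as.numeric(ch2)
  )
  new_loc_table(tbl, dim = dim, precision_fwhm = precision_fwhm)
}

new_loc_table <- function(tbl, dim = 3L,
                          precision_fwhm = c(x = 1.08, y = 0.96, z = 0.63)) {
  structure(tbl,
    class = c("loc_table", class(tibble::as_tibble(tbl))),
    loc_dim = as.integer(dim),
    precision_fwhm = precision_fwhm,
    units = "nm"
  )
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("# Localization table: %d records, %dD, units nm\n",
              nrow(x), attr(x, "loc_dim")))
  NextMethod()
}

loc_columns <- c("uid", "x", "y", "z", "t", "photons", "ch1", "ch2")

# Map a raw header name to a canonical column and a unit scale factor.
parse_loc_header <- function(nms, unit = NULL) {
  canon <- tolower(trimws(nms))
  map <- list(
    uid = c("uid", "id", "index"),
    x = c("x", "x_nm", "x_um", "loc_x"),
    y = c("y", "y_nm", "y_um", "loc_y"),
    z = c("z", "z_nm", "z_um", "loc_z"),
    t = c("t", "t_us", "time", "time_us"),
    photons = c("photons", "photon_count", "counts"),
    ch1 = c("ch1", "ch1_counts", "dcr1"),
    ch2 = c("ch2", "ch2_counts", "dcr2")
  )
  res <- setNames(rep(NA_character_, length(canon)), nms)
  for (target in names(map)) {
    hit <- which(canon %in% map[[target]])
    if (length(hit)) res[hit[1]] <- target
  }
  inferred_unit <- unit
  if (is.null(inferred_unit)) {
    if (any(grepl("_um$", canon[!is.na(res)]))) inferred_unit <- "um"
    else inferred_unit <- "nm"
  }
  list(map = res, unit = inferred_unit)
}

#' Read a localization table from delimited text
#'
#' The canonical dialect is a comma-separated file with a mandatory header
#' (`uid,x_nm,y_nm,z_nm,t_us,photons,ch1,ch2`, subsets allowed) and an
#' optional leading comment line `# units=nm` (or `um`). Coordinates are
#' converted to nm on load; a missing `z` column marks 2D data with z = 0.
#'
#' @param path Path to the file.
#' @param delim Field delimiter (default comma).
#' @param unit Coordinate unit, `"nm"` or `"um"`. Default `NULL` reads the
#'   `# units=` comment line or the header suffix, falling back to nm.
#' @return A [loc_table()].
#' @export
read_localizations <- function(path, delim = ",", unit = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readLines(path, n = 1)
  if (is.null(unit) && grepl("^#\\s*units\\s*=", first)) {
    unit <- trimws(sub("^#\\s*units\\s*=", "", first))
  }
  raw <- readr::read_delim(
    path, delim = delim, comment = "#", show_col_types = FALSE,
    trim_ws = TRUE, col_types = readr::cols(.default = readr::col_character())
  )
  hdr <- parse_loc_header(names(raw), unit)
  have <- hdr$map[!is.na(hdr$map)]
  for (req in c("x", "y")) {
    if (!req %in% have) {
      abort(paste0("format error: missing required coordinate column `",
                   req, "`"), class = "chromaflux_format_error")
    }
  }
  if (!hdr$unit %in% c("nm", "um")) {
    abort(paste0("unknown coordinate unit: ", hdr$unit))
  }
  scale <- if (hdr$unit == "um") 1000 else 1

  num <- function(target) {
    src <- names(have)[have == target]
    if (!length(src)) return(NULL)
    v <- raw[[src[1]]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v) & nzchar(v))
    if (length(bad)) {
      abort(sprintf("parse error: non-numeric value '%s' in column `%s`, row %d",
                    v[bad[1]], src[1], bad[1]),
            class = "chromaflux_parse_error")
    }
    out
  }
  x <- num("x") * scale
  y <- num("y") * scale
  z <- num("z"); if (!is.null(z)) z <- z * scale
  loc_table(
    x = x, y = y, z = z, t = num("t"), photons = num("photons"),
    ch1 = num("ch1"), ch2 = num("ch2"), uid = num("uid")
  )
}

#' Write a localization table to canonical CSV
#'
#' Writes the canonical header `uid,x_nm,y_nm,z_nm,t_us,photons,ch1,ch2`
#' preceded by a `# units=nm` comment line. Output is byte-stable for a
#' given table (fixed 15-significant-digit formatting), so write-read-write
#' round-trips are exact.
#'
#' @param table A [loc_table()] (or plain data frame with those columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  fmt <- function(v) {
    out <- vapply(v, function(x) {
      if (is.na(x)) "" else formatC(x, digits = 15, format = "g")
    }, character(1))
    out
  }
  n <- nrow(table)
  cols <- lapply(loc_columns, function(cn) {
    if (cn %in% names(table)) table[[cn]] else rep(NA_real_, n)
  })
  body <- if (n) {
    do.call(paste, c(lapply(cols, fmt), sep = ","))
  } else {
    character(0)
  }
  lines <- c("# units=nm",
             "uid,x_nm,y_nm,z_nm,t_us,photons,ch1,ch2",
             body)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Crop a localization table to an axis-aligned region of interest
#'
#' The box is half-open per axis: a record is kept when
#' `min <= coord < max`. Half-open boxes make tiling partitions exact (a
#' point on a shared face belongs to exactly one tile).
#'
#' @param table A localization table.
#' @param xlim,ylim,zlim Length-2 numeric ranges in nm; `zlim = NULL`
#'   leaves z unconstrained.
#' @return The filtered table, original order preserved.
#' @export
filter_roi <- function(table, xlim, ylim, zlim = NULL) {
  check_lim <- function(l, nm) {
    if (!is.null(l) && (length(l) != 2 || !(l[1] < l[2]))) {
      abort(paste0("degenerate ROI: `", nm, "` must satisfy min < max"))
    }
  }
  check_lim(xlim, "xlim"); check_lim(ylim, "ylim"); check_lim(zlim, "zlim")
  keep <- table$x >= xlim[1] & table$x < xlim[2] &
    table$y >= ylim[1] & table$y < ylim[2]
  if (!is.null(zlim)) keep <- keep & table$z >= zlim[1] & table$z < zlim[2]
  out <- table[keep, , drop = FALSE]
  if (inherits(table, "loc_table")) {
    out <- new_loc_table(out, dim = attr(table, "loc_dim"),
                         precision_fwhm = attr(table, "precision_fwhm"))
  }
  out
}
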
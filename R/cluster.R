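#' Density-based clustering of localizations (DBSCAN)
#'
#' Standard DBSCAN on Euclidean 3D coordinates: a point with at least
#' `min_pts` neighbors within `eps` (itself included) is a core point;
#' density-reachable core points share a cluster; non-core points within
#' `eps` of a core point become border points of the first cluster that
#' reaches them in ascending uid order (deterministic, bit-reproducible);
#' everything else is noise, labeled `-1`. Cluster labels are consecutive
#' integers starting at 1.
#'
#' @param table A localization table (or anything [as_xyz()] accepts).
#' @param eps Neighborhood radius in nm.
#' @param min_pts Minimum neighborhood size (self included) of a core
#'   point.
#' @param two_pass If `TRUE`, cluster, drop noise points, and re-cluster
#'   the remainder (an optional second pass; off by default).
#' @return The input with a `cluster` integer column appended (a tibble).
#'   The raw label vector is available as `attr(, "labels")`.
#' @examples
#' pts <- tibble::tibble(x = c(rnorm(20), rnorm(20) + 100),
#'                       y = rnorm(40), z = rnorm(40))
#' table(cluster_localizations(pts, eps = 15, min_pts = 5)$cluster)
#' @export
cluster_localizations <- function(table, eps = 20, min_pts = 5,
                                  two_pass = FALSE) {
  xyz <- as_xyz(table)
  labels <- dbscan_labels(xyz, eps, min_pts)
  if (isTRUE(two_pass)) {
    keep <- labels != -1L
    relab <- rep(-1L, length(labels))
    if (any(keep)) relab[keep] <- dbscan_labels(xyz[keep, , drop = FALSE],
                                                eps, min_pts)
    labels <- relab
  }
  out <- tibble::as_tibble(as.data.frame(table))
  out$cluster <- labels
  attr(out, "labels") <- labels
  attr(out, "eps") <- eps
  attr(out, "min_pts") <- min_pts
  out
}

# Core DBSCAN labeling. Core points are labeled by connected components
# of the core-core eps-graph (seeded in ascending uid order, so cluster
# ids are deterministic); border points take the label of their lowest-uid
# core neighbor; everything else is noise (-1).
dbscan_labels <- function(xyz, eps, min_pts) {
  if (eps <= 0) abort("`eps` must be > 0")
  if (min_pts < 1) abort("`min_pts` must be >= 1")
  n <- nrow(xyz)
  if (n == 0) return(integer(0))
  nb <- grid_neighbors(xyz, eps)
  core <- (lengths(nb) + 1L) >= min_pts   # neighborhood includes self
  labels <- rep(-1L, n)
  cl <- 0L
  queue <- integer(n)
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue[1] <- i; qh <- 1L; qt <- 1L
    while (qh <= qt) {
      j <- queue[qh]; qh <- qh + 1L
      for (k in nb[[j]]) {
        if (core[k] && labels[k] == -1L) {
          labels[k] <- cl
          qt <- qt + 1L
          if (qt > length(queue)) queue <- c(queue, integer(n))
          queue[qt] <- k
        }
      }
    }
  }
  for (i in which(!core)) {
    cn <- nb[[i]][core[nb[[i]]]]
    if (length(cn)) labels[i] <- labels[cn[1]]   # neighbors are ascending
  }
  labels
}

#' Per-cluster geometry
#'
#' For every cluster: centroid, principal axes (eigenvectors of the member
#' covariance, ordered by decreasing spread) and the projection extent
#' along each axis. The long-axis length — the spec of "length of the
#' condensed signals" — is the full projection range along the first
#' principal axis. Clusters with fewer than 3 members in 3D are flagged
#' degenerate; their geometry is still returned with zero minor extents.
#'
#' @param table A clustered localization table (output of
#'   [cluster_localizations()]), or any point set plus a `labels` vector.
#' @param labels Optional integer labels overriding `table$cluster`.
#' @return A tibble with one row per cluster: `cluster, n, cx, cy, cz,
#'   long_axis_length_nm, mid_extent_nm, minor_extent_nm, degenerate`, and
#'   an `axes` list-column of 3 x 3 matrices (columns = axes).
#' @export
cluster_geometry <- function(table, labels = NULL) {
  xyz <- as_xyz(table)
  if (is.null(labels)) {
    if (!"cluster" %in% names(table)) abort("no `cluster` column or `labels`")
    labels <- table$cluster
  }
  ids <- sort(unique(labels[labels != -1L]))
  rows <- lapply(ids, function(id) {
    m <- xyz[labels == id, , drop = FALSE]
    n <- nrow(m)
    ctr <- colMeans(m)
    degenerate <- n < 3
    if (n == 1) {
      axes <- diag(3)
      ext <- c(0, 0, 0)
    } else {
      cm <- sweep(m, 2, ctr)
      eg <- eigen(crossprod(cm) / n, symmetric = TRUE)
      axes <- eg$vectors
      proj <- cm %*% axes
      ext <- apply(proj, 2, function(p) diff(range(p)))
    }
    tibble::tibble(
      cluster = id, n = n, cx = ctr[1], cy = ctr[2], cz = ctr[3],
      long_axis_length_nm = ext[1], mid_extent_nm = ext[2],
      minor_extent_nm = ext[3], degenerate = degenerate,
      axes = list(axes)
    )
  })
  if (!length(rows)) {
    return(tibble::tibble(
      cluster = integer(), n = integer(), cx = numeric(), cy = numeric(),
      cz = numeric(), long_axis_length_nm = numeric(),
      mid_extent_nm = numeric(), minor_extent_nm = numeric(),
      degenerate = logical(), axes = list()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Local neighbor density per localization
#'
#' Counts, for each localization, the number of other localizations within
#' the closed ball of the given radius (self excluded) — the quantity used
#' to color-code density in rendered MINFLUX maps.
#'
#' @param table A localization table or point matrix.
#' @param radius Ball radius in nm.
#' @return Integer vector of neighbor counts, one per record.
#' @export
local_density <- function(table, radius) {
  if (radius <= 0) abort("`radius` must be > 0")
  xyz <- as_xyz(table)
  lengths(grid_neighbors(xyz, radius))
}
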
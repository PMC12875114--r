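# Independent oracles and fixture builders used across the suite.

# MINFLUX-scale localization noise: FWHM 1.08 / 0.96 / 0.63 nm per axis.
minflux_sigma <- chromaflux::fwhm_to_sigma(c(1.08, 0.96, 0.63))

add_loc_noise <- function(m, sigma = minflux_sigma) {
  m + cbind(rnorm(nrow(m), 0, sigma[1]),
            rnorm(nrow(m), 0, sigma[2]),
            rnorm(nrow(m), 0, sigma[3]))
}

# Points exactly on a cylinder surface, arbitrary orientation.
cylinder_points <- function(n, radius, length, axis = c(0, 0, 1),
                            center = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis; u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  th <- runif(n, 0, 2 * pi)
  h <- runif(n, -length / 2, length / 2)
  sweep(radius * outer(cos(th), u) + radius * outer(sin(th), v) +
          outer(h, axis), 2, center, `+`)
}

circle_points_3d <- function(n, radius, normal = c(0, 0, 1),
                             center = c(0, 0, 0), jitter_angles = TRUE) {
  th <- if (jitter_angles) sort(runif(n, 0, 2 * pi)) else
    seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  normal <- normal / sqrt(sum(normal^2))
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * normal) * normal; u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  sweep(radius * outer(cos(th), u) + radius * outer(sin(th), v),
        2, center, `+`)
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3))) * sample(c(-1, 1), 1)
}

# Brute-force DBSCAN oracle: O(n^2) density reachability. Core points are
# labeled by connected components of the core-core eps graph; border
# points take the label of their lowest-index core neighbor.
dbscan_oracle <- function(xyz, eps, min_pts) {
  n <- nrow(xyz)
  d <- as.matrix(dist(xyz))
  adj <- d <= eps
  core <- rowSums(adj) >= min_pts   # includes self (diagonal is 0 <= eps)
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    frontier <- i
    labels[i] <- cl
    while (length(frontier)) {
      nxt <- integer(0)
      for (j in frontier) {
        reach <- which(adj[j, ] & core & labels == -1L)
        labels[reach] <- cl
        nxt <- c(nxt, reach)
      }
      frontier <- nxt
    }
  }
  for (i in which(!core)) {
    cn <- which(adj[i, ] & core)
    cn <- cn[cn != i]
    if (length(cn)) labels[i] <- labels[min(cn)]
  }
  labels
}

# Check two labelings define the same partition (up to label renaming),
# including the noise set.
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == -1L, b == -1L)) return(FALSE)
  keep <- a != -1L
  if (!any(keep)) return(TRUE)
  tab <- table(a[keep], b[keep])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Scene with a controlled share of localizations in >= 3-nucleosome
# fibers; remaining mass split between isolated nucleosomes and
# scattered single probes. Returns the scene plus the constructed shares.
build_classification_scene <- function(fiber_share = 0.6, n_fibers = 3,
                                       fiber_length = 150) {
  fibers <- lapply(seq_len(n_fibers), function(i) {
    make_fiber(fiber_length, 35, start = c(0, (i - 1) * 500, 0),
               at_fraction = 0.8)
  })
  n_fiber_sites <- sum(vapply(fibers, function(f) {
    sum(vapply(f$nucleosomes, function(nu) sum(nu$sites$bound), integer(1)))
  }, integer(1)))
  n_other <- round(n_fiber_sites * (1 - fiber_share) / fiber_share)
  target_nuc_sites <- round(n_other / 2)
  free_nuc <- list()
  got <- 0L
  slot <- 0L
  while (got < target_nuc_sites) {
    slot <- slot + 1L
    nuc <- make_nucleosome(
      center = c(-300 - 80 * (slot %% 12), 60 * (slot %/% 12), 100),
      at_fraction = 0.85
    )
    free_nuc[[slot]] <- nuc
    got <- got + sum(nuc$sites$bound)
  }
  n_scatter <- n_other - got
  scene <- make_scene(fibers = fibers, nucleosomes = free_nuc,
                      n_scattered = max(0L, n_scatter))
  total <- n_fiber_sites + got + max(0L, n_scatter)
  list(scene = scene, fiber_share = n_fiber_sites / total,
       n_total_sites = total)
}
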
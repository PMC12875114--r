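# Internal geometry and neighbor-search helpers shared across modules.

# Coerce a localization tibble / matrix / data.frame to an n x 3 matrix.
as_xyz <- function(points) {
  if (is.matrix(points)) {
    if (ncol(points) == 2) points <- cbind(points, 0)
    if (ncol(points) != 3) abort("point matrix must have 2 or 3 columns")
    m <- points
  } else if (is.data.frame(points)) {
    if (!all(c("x", "y") %in% names(points))) {
      abort("point data frame must have `x` and `y` columns")
    }
    z <- if ("z" %in% names(points)) points$z else rep(0, nrow(points))
    m <- cbind(points$x, points$y, z)
  } else {
    abort("`points` must be a matrix or data frame")
  }
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y", "z")
  if (nrow(m) && !all(is.finite(m))) abort("coordinates must be finite")
  m
}

normalize_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) abort("zero-length direction vector")
  v / n
}

# Two unit vectors orthogonal to `axis` (right-handed frame u, v, axis).
orthobasis <- function(axis) {
  axis <- normalize_vec(axis)
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- normalize_vec(u)
  v <- c(
    axis[2] * u[3] - axis[3] * u[2],
    axis[3] * u[1] - axis[1] * u[3],
    axis[1] * u[2] - axis[2] * u[1]
  )
  list(u = u, v = v, w = axis)
}

angles_from_axis <- function(a) c(acos(max(-1, min(1, a[3]))), atan2(a[2], a[1]))
axis_from_angles <- function(th) {
  c(sin(th[1]) * cos(th[2]), sin(th[1]) * sin(th[2]), cos(th[1]))
}

# Fix axis sign: non-negative dot product with +z; ties broken on +y then +x.
canonical_axis <- function(a) {
  s <- sign(a[3])
  if (s == 0) s <- sign(a[2])
  if (s == 0) s <- sign(a[1])
  if (s == 0) s <- 1
  a * s
}

# Random uniform unit vectors (n x 3).
runif_sphere <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Least-squares circle in 2D: Kasa algebraic fit then geometric refinement
# of the center (radius profiled out as the mean radial distance).
circle_fit_2d <- function(xy, refine = TRUE) {
  n <- nrow(xy)
  if (n < 3) abort("circle fit needs >= 3 points")
  A <- cbind(2 * xy[, 1], 2 * xy[, 2], 1)
  qa <- qr(A)
  if (qa$rank < 3) {
    # collinear (or coincident) projections: radius unidentifiable
    abort("degenerate input: points are collinear, circle radius unidentifiable",
          class = "chromaflux_degeneracy")
  }
  sol <- qr.coef(qa, xy[, 1]^2 + xy[, 2]^2)
  ctr <- sol[1:2]
  obj <- function(cc) {
    d <- sqrt((xy[, 1] - cc[1])^2 + (xy[, 2] - cc[2])^2)
    sum((d - mean(d))^2)
  }
  if (refine) {
    opt <- optim(ctr, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 500))
    ctr <- opt$par
  }
  d <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
  list(center = unname(ctr), radius = mean(d), distances = d)
}

# Uncentered R^2 on radial distances: 1 for exact geometry, degrades with
# radial spread relative to the radius itself.
radial_r_squared <- function(distances, radius) {
  ss_tot <- sum(distances^2)
  if (ss_tot < 1e-300) return(1)
  1 - sum((distances - radius)^2) / ss_tot
}

# Neighbor lists within radius r via uniform-grid bucketing; O(n * local
# density). Returns a list of integer vectors (ascending), self excluded.
grid_neighbors <- function(xyz, r) {
  n <- nrow(xyz)
  out <- vector("list", n)
  if (n == 0) return(out)
  lo <- apply(xyz, 2, min)
  cell <- floor(sweep(xyz, 2, lo) / r)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  buckets <- split(seq_len(n), key)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  r2 <- r * r
  for (k in names(buckets)) {
    idx <- buckets[[k]]
    ck <- cell[idx[1], ]
    cand <- integer(0)
    for (o in seq_len(27)) {
      nk <- paste(ck[1] + offsets[o, 1], ck[2] + offsets[o, 2],
                  ck[3] + offsets[o, 3], sep = ",")
      b <- buckets[[nk]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- sort(cand)
    cx <- xyz[cand, 1]; cy <- xyz[cand, 2]; cz <- xyz[cand, 3]
    for (i in idx) {
      d2 <- (cx - xyz[i, 1])^2 + (cy - xyz[i, 2])^2 + (cz - xyz[i, 3])^2
      nb <- cand[d2 <= r2]
      out[[i]] <- nb[nb != i]
    }
  }
  out
}
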
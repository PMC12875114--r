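test_that("dbscan labels satisfy the basic semantics", {
  pts <- matrix(0, 10, 3)
  lab <- attr(cluster_localizations(pts, eps = 1, min_pts = 5), "labels")
  expect_equal(lab, rep(1L, 10))   # one cluster, no noise

  two <- rbind(matrix(rnorm(30, 0, 2), ncol = 3),
               matrix(rnorm(30, 100, 2), ncol = 3))
  lab2 <- attr(cluster_localizations(two, eps = 15, min_pts = 5), "labels")
  expect_equal(sort(unique(lab2)), c(1L, 2L))
  expect_equal(length(unique(lab2[1:10])), 1)

  expect_equal(nrow(cluster_localizations(matrix(0, 0, 3), 10, 5)), 0)
})

test_that("dbscan matches the brute-force density-reachability oracle", {
  set.seed(301)
  for (rep in 1:50) {
    n <- sample(20:200, 1)
    # mixture of clumps and uniform background to exercise border cases
    n_clump <- sample(1:4, 1)
    pts <- do.call(rbind, c(
      lapply(seq_len(n_clump), function(i) {
        matrix(rnorm(3 * sample(5:30, 1), runif(1, 0, 200), 4), ncol = 3)
      }),
      list(matrix(runif(3 * n, 0, 200), ncol = 3))
    ))
    eps <- runif(1, 5, 15)
    min_pts <- sample(3:6, 1)
    mine <- attr(cluster_localizations(pts, eps, min_pts), "labels")
    oracle <- dbscan_oracle(pts, eps, min_pts)
    expect_true(same_partition(mine, oracle))
  }
})

test_that("core-point partition is invariant under point permutation", {
  set.seed(302)
  pts <- rbind(matrix(rnorm(90, 0, 5), ncol = 3),
               matrix(rnorm(90, 40, 5), ncol = 3),
               matrix(runif(60, -50, 100), ncol = 3))
  lab <- attr(cluster_localizations(pts, 10, 4), "labels")
  perm <- sample(nrow(pts))
  lab_p <- attr(cluster_localizations(pts[perm, ], 10, 4), "labels")
  # compare partitions on the original indexing
  back <- integer(nrow(pts)); back[perm] <- lab_p
  nb <- chromaflux:::grid_neighbors(pts, 10)
  core <- (lengths(nb) + 1L) >= 4
  expect_true(same_partition(lab[core], back[core]))
})

test_that("two-pass mode drops noise before re-clustering", {
  set.seed(303)
  pts <- rbind(matrix(rnorm(60, 0, 3), ncol = 3),
               matrix(runif(30, -400, 400), ncol = 3))
  one <- attr(cluster_localizations(pts, 12, 5), "labels")
  two <- attr(cluster_localizations(pts, 12, 5, two_pass = TRUE), "labels")
  expect_true(all(two[one == -1L] == -1L))
  expect_true(same_partition(one, two) ||
                sum(two != -1L) <= sum(one != -1L))
})

test_that("cluster geometry reports centroid, extents and degeneracy", {
  # collinear points spanning 80 nm
  line <- cbind(seq(0, 80, length.out = 20), 0, 0)
  g <- cluster_geometry(line, labels = rep(1L, 20))
  expect_equal(g$long_axis_length_nm, 80, tolerance = 1e-9)
  expect_equal(g$minor_extent_nm, 0, tolerance = 1e-9)

  # points on a sphere of radius r: all extents near 2r
  set.seed(304)
  sph <- 25 * chromaflux:::runif_sphere(4000)
  gs <- cluster_geometry(sph, labels = rep(1L, 4000))
  expect_equal(gs$long_axis_length_nm, 50, tolerance = 0.02)
  expect_equal(gs$minor_extent_nm, 50, tolerance = 0.02)

  # long-axis length is invariant under rigid rotation
  set.seed(305)
  cloud <- matrix(rnorm(90, 0, c(10, 3, 1)), ncol = 3, byrow = TRUE)
  g1 <- cluster_geometry(cloud, labels = rep(1L, 30))
  g2 <- cluster_geometry(cloud %*% random_rotation(), labels = rep(1L, 30))
  expect_equal(g1$long_axis_length_nm, g2$long_axis_length_nm,
               tolerance = 1e-6)

  # < 3 members in 3D: degenerate but still reported
  gd <- cluster_geometry(rbind(c(0, 0, 0), c(3, 4, 0)),
                         labels = c(1L, 1L))
  expect_true(gd$degenerate)
  expect_equal(gd$long_axis_length_nm, 5)
  expect_equal(gd$minor_extent_nm, 0)
})

test_that("cluster long-axis length recovers a straight fiber's extent", {
  set.seed(306)
  fb <- make_fiber(100, 35, at_fraction = 0.9, target_density = 60)
  loc <- simulate_localizations(make_scene(fibers = list(fb)))
  cl <- cluster_localizations(loc)
  g <- cluster_geometry(cl)
  expect_equal(nrow(g), 1)
  expect_gt(g$long_axis_length_nm, 90)
  expect_lt(g$long_axis_length_nm, 106)
})

test_that("local density counts neighbors within the closed ball", {
  expect_equal(local_density(matrix(c(0, 0, 0), 1), 10), 0)
  five <- matrix(0, 5, 3)
  expect_equal(local_density(five, 1), rep(4L, 5))

  set.seed(307)
  n <- 500; L <- 100; r <- 10
  pts <- matrix(runif(3 * n, 0, L), ncol = 3)
  counts <- local_density(pts, r)
  # Poisson expectation away from edges; use an interior subset
  interior <- pts[, 1] > r & pts[, 1] < L - r & pts[, 2] > r &
    pts[, 2] < L - r & pts[, 3] > r & pts[, 3] < L - r
  lambda <- (n - 1) * (4 / 3) * pi * r^3 / L^3
  se <- sqrt(lambda / sum(interior))
  expect_lt(abs(mean(counts[interior]) - lambda), 3 * se * sqrt(lambda))
})
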
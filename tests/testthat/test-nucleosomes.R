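test_that("ring fit recovers exact circles and flags degeneracy", {
  pts <- circle_points_3d(8, 5.81, jitter_angles = FALSE)
  r <- fit_ring(pts)
  expect_equal(r$radius, 5.81, tolerance = 1e-6)
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  expect_equal(r$out_of_plane_rms, 0, tolerance = 1e-9)
  expect_error(fit_ring(cbind(1:10, 1:10, 1:10)),
               class = "chromaflux_degeneracy")
  expect_error(fit_ring(pts[1:4, ]), ">= 5")
})

test_that("ring fit is equivariant and recovers tilted noisy circles", {
  set.seed(501)
  pts <- circle_points_3d(10, 5.81) + matrix(rnorm(30, 0, 0.3), ncol = 3)
  f0 <- fit_ring(pts)
  f1 <- fit_ring(sweep(pts %*% t(random_rotation()), 2, c(5, 6, 7), `+`))
  expect_equal(f1$radius, f0$radius, tolerance = 1e-6)

  # tilted 30 degrees with acquisition noise: 100-replicate mean within 0.5 nm
  set.seed(502)
  nrm <- c(sin(pi / 6), 0, cos(pi / 6))
  ds <- replicate(100, {
    p <- add_loc_noise(circle_points_3d(10, 5.81, normal = nrm))
    fit_ring(p)$diameter
  })
  expect_lt(abs(mean(ds) - 11.62), 0.5)

  # uniform disk: fit quality markedly below the exact-circle case
  set.seed(503)
  th <- runif(300, 0, 2 * pi); rr <- 6 * sqrt(runif(300))
  disk <- cbind(rr * cos(th), rr * sin(th), 0)
  expect_lt(fit_ring(disk)$r_squared, 0.95)
})

test_that("nucleosome fits count attached probes and apply the acceptance band", {
  # 8 on-cylinder probes + 6 scatterers >= 3 nm away: n_attached = 8
  set.seed(504)
  on_cyl <- cylinder_points(8, 5.73, 4)
  far <- cylinder_points(6, 5.73 + 3.5, 4)
  fit <- fit_nucleosome(rbind(on_cyl, far), axis = c(0, 0, 1))
  expect_equal(fit$n_attached, 8)
  expect_true(all(fit$attached[1:8]))
  expect_true(fit$accepted)
  expect_equal(fit$diameter, 11.46, tolerance = 0.05)
  expect_error(fit_nucleosome(matrix(rnorm(12), 4)), ">= 5")

  # simgen nucleosomes with 5-10 bound probes at acquisition noise: >= 80%
  # accepted, mean diameter within 0.6 nm of the 11-nm truth envelope
  set.seed(505)
  acc <- 0; tried <- 0; dsum <- c()
  for (i in 1:150) {
    nuc <- make_nucleosome(at_fraction = runif(1, 0.43, 0.81))
    s <- nuc$sites[nuc$sites$bound, ]
    if (nrow(s) < 5) next
    tried <- tried + 1
    f <- fit_nucleosome(add_loc_noise(cbind(s$x, s$y, s$z)))
    if (f$accepted) { acc <- acc + 1; dsum <- c(dsum, f$diameter) }
  }
  expect_gte(tried, 100)
  expect_gte(acc / tried, 0.8)
  expect_lt(abs(mean(dsum) - 11.0), 0.6)
  # accepted diameters concentrate in the nucleosome range
  expect_gt(mean(dsum >= 10.5 & dsum <= 12.5), 0.75)
  expect_true(all(dsum >= 9 & dsum <= 14))
})

test_that("dimer fits split coaxial stacks and reject single nucleosomes", {
  ring1 <- circle_points_3d(6, 5.75, center = c(0, 0, 0),
                            jitter_angles = FALSE)
  ring2 <- circle_points_3d(6, 5.75, center = c(0, 0, 6),
                            jitter_angles = FALSE)
  dm <- fit_dimer(rbind(ring1, ring2))
  expect_true(dm$accepted)
  expect_equal(dm$offset_nm, 6, tolerance = 1e-6)
  expect_equal(sort(unique(dm$membership)), 1:2)

  # simgen dimer with noise: both diameters near the nucleosome scale
  set.seed(506)
  ok <- 0; ds <- c()
  for (i in 1:30) {
    ax <- chromaflux:::runif_sphere(1)[1, ]
    n1 <- make_nucleosome(axis = ax, at_fraction = 0.8)
    n2 <- make_nucleosome(center = 6.5 * ax, axis = ax, at_fraction = 0.8)
    s <- dplyr::bind_rows(n1$sites[n1$sites$bound, ], n2$sites[n2$sites$bound, ])
    if (nrow(s) < 10) next
    dmx <- fit_dimer(add_loc_noise(cbind(s$x, s$y, s$z)))
    if (dmx$accepted) {
      ok <- ok + 1
      ds <- c(ds, vapply(dmx$fits, function(f) f$diameter, numeric(1)))
    }
  }
  expect_gt(ok, 10)
  expect_true(all(ds > 9.9 & ds < 13.1))

  # a single nucleosome's points yield no dimer
  set.seed(507)
  one <- make_nucleosome(at_fraction = 1)
  s1 <- one$sites[one$sites$bound, ]
  # duplicate sightings to pass the 10-point precondition
  p1 <- add_loc_noise(rbind(cbind(s1$x, s1$y, s1$z),
                            cbind(s1$x, s1$y, s1$z)))
  expect_false(fit_dimer(p1)$accepted)
})

test_that("diameter histograms detect constructed peaks", {
  dh <- diameter_histogram(rep(11.5, 40), bin_nm = 0.5)
  expect_equal(dh$peaks_nm, 11.75)
  dh2 <- diameter_histogram(c(rep(11.5, 40), rep(12.5, 25)), bin_nm = 0.5)
  expect_length(dh2$peaks_nm, 2)
  expect_setequal(round(dh2$peaks_nm, 2), c(11.75, 12.75))
  expect_equal(nrow(diameter_histogram(numeric(0))$histogram), 0)
  # values at or above the cut are excluded
  expect_equal(sum(diameter_histogram(c(11, 15))$histogram$count), 1)
})

test_that("uncorrected imaging-plane ring fits reproduce the orientation-angle inflation", {
  set.seed(508)
  ds <- numeric(0)
  for (i in 1:1500) {
    nuc <- make_nucleosome(at_fraction = runif(1, 0.43, 0.81))
    s <- nuc$sites[nuc$sites$bound, ]
    if (nrow(s) < 5 || nrow(s) > 10) next
    r <- try(fit_ring(add_loc_noise(cbind(s$x, s$y, s$z)),
                      plane = "imaging"), silent = TRUE)
    if (!inherits(r, "try-error")) ds <- c(ds, r$diameter)
  }
  dh <- diameter_histogram(ds, bin_nm = 1, max_nm = 25)
  peaks <- dh$peaks_nm
  expect_gt(length(peaks), 1)
  expect_true(any(peaks[-1] > peaks[1]))   # secondary peak above primary
  # the rotation-invariant principal-plane fit shows no such inflation:
  # its diameters concentrate near the truth
  set.seed(509)
  dp <- replicate(200, {
    nuc <- make_nucleosome(at_fraction = 0.8)
    s <- nuc$sites[nuc$sites$bound, ]
    fit_ring(add_loc_noise(cbind(s$x, s$y, s$z)))$diameter
  })
  expect_lt(mean(dp > 13), 0.02)
})

test_that("region classification separates scattered, small and polymer regions", {
  # pure background: everything scattered
  set.seed(510)
  bg <- tibble::tibble(x = runif(200, 0, 2000), y = runif(200, 0, 2000),
                       z = runif(200, 0, 2000))
  cl <- cluster_localizations(bg)
  r <- classify_region(cl)
  expect_equal(r$fraction_scattered, 1)
  expect_equal(r$fraction_1_2 + r$fraction_3plus, 0)

  # one isolated nucleosome cluster amid background
  set.seed(511)
  nuc <- make_nucleosome(center = c(1000, 1000, 1000), at_fraction = 0.9)
  s <- nuc$sites[nuc$sites$bound, ]
  tb <- dplyr::bind_rows(
    bg, tibble::tibble(x = s$x, y = s$y, z = s$z)
  )
  tb$uid <- seq_len(nrow(tb))
  r2 <- classify_region(cluster_localizations(tb))
  expect_equal(r2$fraction_1_2, nrow(s) / nrow(tb), tolerance = 1e-9)

  # empty region flagged
  r0 <- classify_region(tibble::tibble(x = numeric(), y = numeric(),
                                       z = numeric()),
                        labels = integer(0))
  expect_true(r0$empty)
  expect_true(is.na(r0$fraction_scattered))

  # greedy extraction claims each localization at most once
  set.seed(512)
  fb <- make_fiber(100, 35, at_fraction = 0.8)
  loc <- simulate_localizations(make_scene(fibers = list(fb)))
  rc <- classify_region(cluster_localizations(loc))
  n_claimed <- sum(vapply(rc$fits, function(f) f$n_attached, integer(1)))
  expect_lte(n_claimed, nrow(loc))
  expect_gte(sum(rc$fits_per_cluster$n_fits), 3)
})
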
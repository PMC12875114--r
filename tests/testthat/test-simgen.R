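test_that("nucleosome probe sites respect footprint spacing, envelope and coverage cap", {
  set.seed(201)
  cfg <- chromaflux_config()
  for (i in 1:20) {
    nuc <- make_nucleosome(center = rnorm(3, 0, 100), at_fraction = 1)
    s <- nuc$sites
    expect_true(all(diff(s$bp) >= cfg$probe_footprint_bp))
    # all sites within diameter/2 + 1 nm of the axis
    rel <- sweep(cbind(s$x, s$y, s$z), 2, nuc$center)
    ax <- drop(rel %*% nuc$axis)
    rad <- sqrt(rowSums(rel^2) - ax^2)
    expect_true(all(rad <= nuc$diameter_nm / 2 + 1 + 1e-9))
    # coverage cap: floor(147 * 0.8 / 12) = 9 bound sites at most
    expect_lte(sum(s$bound), 9)
  }
  expect_equal(sum(make_nucleosome(at_fraction = 0)$sites$bound), 0)
})

test_that("bound-probe counts follow the capped binomial expectation", {
  set.seed(202)
  at <- 0.6
  draws <- replicate(1000, sum(make_nucleosome(at_fraction = at)$sites$bound))
  # closed-form expectation of min(Binomial(12, at), 9)
  k <- 0:12
  mu <- sum(pmin(k, 9) * dbinom(k, 12, at))
  sigma <- sqrt(sum((pmin(k, 9) - mu)^2 * dbinom(k, 12, at)))
  expect_lt(abs(mean(draws) - mu), 3 * sigma / sqrt(1000))
})

test_that("fibers honor curvature, geometry and density calibration", {
  set.seed(203)
  fb <- make_fiber(100, 35, curvature = 0)
  # straight centerline
  expect_lt(max(abs(fb$centerline[, 2:3])), 1e-9)
  # nucleosome centers on the diameter/2 shell around the axis
  ctrs <- t(vapply(fb$nucleosomes, function(nu) nu$center, numeric(3)))
  rad <- sqrt(ctrs[, 2]^2 + ctrs[, 3]^2)
  expect_true(all(rad <= 35 / 2 + 1e-9))

  # two-segment fiber: radial RMS of truth sites differs between halves
  fb2 <- make_fiber(200, tibble::tibble(length_nm = c(100, 100),
                                        diameter_nm = c(20, 50)))
  sites <- dplyr::bind_rows(lapply(fb2$nucleosomes, function(nu) nu$sites))
  first_half <- sites$x < 100
  rms <- function(m) sqrt(mean(m$y^2 + m$z^2))
  expect_lt(rms(sites[first_half, ]), rms(sites[!first_half, ]))

  # generator-target density recovered from truth sites within 20%
  for (rho in c(8.87, 20, 34, 50, 69.87)) {
    f <- make_fiber(300, 35, target_density = rho)
    est <- fiber_truth_density(f)$density_mbp_um3
    expect_lt(abs(est - rho) / rho, 0.2)
  }
  expect_error(make_fiber(100, 10), "nucleosome diameter")
})

test_that("simulated localizations implement detection, noise and truth links", {
  # FWHM -> sigma closed form
  expect_equal(fwhm_to_sigma(1.08), 1.08 / 2.3548, tolerance = 1e-4)
  expect_equal(sigma_to_fwhm(fwhm_to_sigma(2)), 2)

  set.seed(204)
  nucs <- lapply(1:40, function(i) {
    make_nucleosome(center = c(100 * i, 0, 0), at_fraction = 1)
  })
  scene <- make_scene(nucleosomes = nucs)
  # full detection, zero noise: localizations equal truth sites exactly
  acq0 <- acquisition_params(precision_fwhm = c(1e-12, 1e-12, 1e-12))
  loc0 <- simulate_localizations(scene, acq0)
  truth <- attr(loc0, "truth")
  expect_false(anyNA(truth$site_id))
  m <- merge(as.data.frame(loc0), truth, by = "uid")
  m <- merge(m, as.data.frame(scene$sites), by = "site_id",
             suffixes = c("", ".site"))
  expect_equal(m$x, m$x.site, tolerance = 1e-6)
  expect_equal(sort(m$site_id), sort(scene$sites$site_id[scene$sites$bound]))

  # binomial detection: count within 3 sqrt(npq) of n p
  set.seed(205)
  many <- make_scene(nucleosomes = lapply(1:900, function(i) {
    make_nucleosome(center = c(50 * i, 0, 0), at_fraction = 1)
  }))
  n_sites <- sum(many$sites$bound)
  expect_gt(n_sites, 7000)
  loc5 <- simulate_localizations(many, acquisition_params(detection_prob = 0.5))
  expect_lt(abs(nrow(loc5) - 0.5 * n_sites), 3 * sqrt(n_sites * 0.25))

  # timestamps sequential at the configured pace
  expect_equal(sort(loc5$t), seq_len(nrow(loc5)) * 93.7)
})

test_that("noise calibration: empirical per-axis FWHM matches configuration within 5%", {
  set.seed(206)
  one_site <- make_scene(nucleosomes = list(make_nucleosome(at_fraction = 1)))
  acq <- acquisition_params(relocalization_rate = 9)
  locs <- list()
  for (i in 1:160) locs[[i]] <- simulate_localizations(one_site, acq)
  reps <- dplyr::bind_rows(lapply(seq_along(locs), function(i) {
    tr <- attr(locs[[i]], "truth")
    d <- as.data.frame(locs[[i]])
    d$site <- paste(i, tr$site_id[match(d$uid, tr$uid)])
    d
  }))
  expect_gt(nrow(reps), 1e4)
  pe <- estimate_precision(reps, reps$site)
  expect_equal(pe$fwhm_nm, c(1.08, 0.96, 0.63), tolerance = 0.05)
})

test_that("TSA decompaction dissolves fibers and conserves the survivors' diameters", {
  set.seed(207)
  mk <- function() lapply(1:100, function(i) {
    make_fiber(120, 35, start = c(0, 300 * i, 0), target_density = 15)
  })
  scene <- make_scene(fibers = mk())
  expect_identical(apply_tsa(scene, 0), scene)

  gone <- apply_tsa(scene, 1)
  expect_length(gone$fibers, 0)

  part <- apply_tsa(scene, 0.9)
  n_surv <- length(part$fibers)
  expect_lt(abs(n_surv - 10), 3 * sqrt(100 * 0.9 * 0.1) + 1)
  for (f in part$fibers) {
    expect_lt(f$length_nm, 50)
    expect_equal(f$segments$diameter_nm, 35)
  }
  # conservation: every localization has a truth link or is background
  loc <- simulate_localizations(part, acquisition_params(background_rate = 5))
  tr <- attr(loc, "truth")
  expect_equal(nrow(tr), nrow(loc))
  linked <- tr$site_id[!is.na(tr$site_id)]
  expect_true(all(linked %in% part$sites$site_id))
})
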
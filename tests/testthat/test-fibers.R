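test_that("cylinder fit recovers exact surface geometry to 1e-6 relative", {
  set.seed(401)
  for (rep in 1:5) {
    axis <- chromaflux:::runif_sphere(1)[1, ]
    ctr <- rnorm(3, 0, 50)
    pts <- cylinder_points(40, 5.73, 30, axis = axis, center = ctr)
    fit <- fit_cylinder(pts)
    expect_equal(fit$radius, 5.73, tolerance = 1e-6)
    expect_lt(fit$rms_radial_residual, 1e-5)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_equal(abs(sum(fit$axis * axis)), 1, tolerance = 1e-6)
    expect_gte(fit$axis[3], 0)   # canonical sign
  }
})

test_that("cylinder fit is equivariant under rigid motions", {
  set.seed(402)
  pts <- cylinder_points(60, 12, 80)
  pts <- pts + matrix(rnorm(180, 0, 0.4), ncol = 3)
  f0 <- fit_cylinder(pts)
  R <- random_rotation()
  shift <- c(20, -70, 15)
  f1 <- fit_cylinder(sweep(pts %*% t(R), 2, shift, `+`))
  expect_equal(f1$radius, f0$radius, tolerance = 1e-6)
  expect_equal(f1$length, f0$length, tolerance = 1e-6)
  expect_equal(f1$rms_radial_residual, f0$rms_radial_residual,
               tolerance = 1e-6)
})

test_that("noisy diameter recovery is unbiased at MINFLUX precision", {
  set.seed(403)
  # nucleosome scale: d = 11.46
  d_nuc <- replicate(100, {
    pts <- add_loc_noise(cylinder_points(14, 11.46 / 2, 4.7))
    fit_cylinder(pts)$diameter
  })
  expect_lt(abs(mean(d_nuc) - 11.46), 0.5)
  # fiber scale: d = 35
  d_fib <- replicate(100, {
    pts <- add_loc_noise(cylinder_points(60, 17.5, 100))
    fit_cylinder(pts)$diameter
  })
  expect_lt(abs(mean(d_fib) - 35), 2)
})

test_that("degenerate and unstructured inputs are reported as such", {
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fit_cylinder(line), class = "chromaflux_degeneracy")
  expect_error(fit_cylinder(matrix(rnorm(12), 4)), ">= 5")
  # uniform ball: residuals large, fit quality well below the exact case
  set.seed(404)
  ball <- 10 * chromaflux:::runif_sphere(200) * runif(200)^(1 / 3)
  fb <- fit_cylinder(ball)
  expect_gt(fb$rms_radial_residual, 1)
  exact <- fit_cylinder(cylinder_points(200, 10, 30))
  expect_lt(fb$r_squared, exact$r_squared - 0.05)
})

test_that("dna density follows the probe-count formula", {
  # hand oracle: 100 locs * 12 bp / 0.8 = 1500 bp;
  # volume = pi * 15^2 * 100 nm^3 = 7.0686e-5 um^3 -> 21.22 Mbp/um^3
  expect_equal(dna_density(100, 15, 100), 21.22, tolerance = 1e-3)
  expect_equal(dna_density(200, 15, 100), 2 * dna_density(100, 15, 100))
  expect_error(dna_density(0, 15, 100), "n_locs")
  expect_error(dna_density(10, 15, 0), "volume")
})

test_that("segmentation recovers constant and stepped diameter profiles", {
  set.seed(405)
  fb <- make_fiber(200, 35)
  loc <- simulate_localizations(make_scene(fibers = list(fb)))
  seg <- segment_fiber(loc)
  expect_equal(nrow(seg$segments), 1)
  expect_equal(seg$segments$diameter_nm, 35, tolerance = 2 / 35)
  expect_equal(seg$total_length_nm, 200, tolerance = 5 / 200)
  # conservation: every point belongs to exactly one segment
  expect_false(anyNA(seg$membership))

  fb2 <- make_fiber(200, tibble::tibble(length_nm = c(100, 100),
                                        diameter_nm = c(20, 50)),
                    target_density = 80)
  loc2 <- simulate_localizations(make_scene(fibers = list(fb2)))
  seg2 <- segment_fiber(loc2)
  expect_equal(nrow(seg2$segments), 2)
  expect_equal(seg2$segments$diameter_nm[1], 20, tolerance = 3 / 20)
  expect_equal(seg2$segments$diameter_nm[2], 50, tolerance = 3 / 50)
  expect_false(anyNA(seg2$membership))

  # cluster shorter than the window: single segment = plain cylinder fit
  set.seed(406)
  short <- add_loc_noise(cylinder_points(40, 17.5, 20))
  seg3 <- segment_fiber(short)
  expect_equal(nrow(seg3$segments), 1)
  ref <- fit_cylinder(short)
  expect_equal(seg3$segments$diameter_nm, ref$diameter, tolerance = 0.05)

  # hopeless input: unsegmentable result, not an exception
  expect_true(segment_fiber(matrix(rnorm(9), 3))$unsegmentable)
})

test_that("fiber summaries aggregate lengths, diameters and the modal bin", {
  expect_equal(nrow(fiber_summary(list())$fibers), 0)
  set.seed(407)
  fibers <- lapply(1:6, function(i) {
    fb <- make_fiber(120, 35, start = c(0, 400 * i, 0))
    segment_fiber(simulate_localizations(make_scene(fibers = list(fb))))
  })
  fs <- fiber_summary(fibers)
  expect_equal(nrow(fs$fibers), 6)
  expect_equal(fs$fibers$total_length_nm,
               vapply(fibers, function(f) f$total_length_nm, numeric(1)))
  # modal histogram bin contains the generated 35-nm diameter mode
  expect_lte(abs(fs$modal_diameter_nm - 35), fs$bin_nm)
})
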
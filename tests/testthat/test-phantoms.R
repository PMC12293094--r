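test_that("phantom specs validate family structure", {
  fam <- function(o) list(orientation = o, period = 12, amplitude = 1)
  expect_error(phantom_spec(families = list(fam(10), fam(50), fam(90),
                                            fam(130))), "1 and 3")
  expect_error(phantom_spec(families = list()), "1 and 3")
  expect_error(
    phantom_spec(families = list(list(orientation = 10, period = 1,
                                      amplitude = 1))), "period")
  expect_error(
    phantom_spec(families = list(list(orientation = 10, period = 8,
                                      amplitude = -1))), "amplitude")
  sp <- phantom_spec(families = list(fam(45)))
  expect_s3_class(sp, "phantom_spec")
  expect_equal(sp$families[[1]]$waviness, 0)
})

test_that("identical spec and seed give bit-identical images", {
  sp <- phantom_spec(size = c(64, 64),
                     families = list(list(orientation = 30, period = 10,
                                          amplitude = 1)),
                     noise = "poisson", noise_mean = 20, seed = 5)
  img1 <- make_fiber_image(sp)
  img2 <- make_fiber_image(sp)
  expect_identical(img1$pixels, img2$pixels)
  sp2 <- sp; sp2$seed <- 6L
  expect_false(identical(make_fiber_image(sp2)$pixels, img1$pixels))
  # generators must not disturb the caller's RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(make_fiber_image(sp)); after <- runif(3)
  expect_identical(before, after)
})

test_that("a 45-degree fiber family drives the dominant bin to 135", {
  img <- grating_image(45)
  expect_true(img$normalized)
  expect_equal(img$ground_truth$families[[1]]$orientation, 45)
  res <- analyze_image(img, R = 1, t_fraction = 0.1, B = 5, k = 1)
  peak <- res$pdf$bin_centers[which.max(res$pdf$density)]
  # gradients are perpendicular to the fiber axis; 135 lies on a bin edge so
  # either adjacent bin closure may carry the maximum
  expect_lte(circ_dist(peak, 135), 2.5)
  expect_lte(circ_dist(res$model$b[1], 135), 2.5)
})

test_that("background-only phantoms have no oriented structure", {
  sp <- phantom_spec(size = c(32, 32),
                     families = list(list(orientation = 45, period = 8,
                                          amplitude = 0)),
                     background = 0.5)
  img <- make_fiber_image(sp)
  f <- compute_gradient(img, R = 1)
  expect_false(any(f$valid_mask))
  expect_error(build_pdf(f, B = 5), "empty")
})

test_that("two patch-composed families produce two recoverable normals", {
  sp <- phantom_spec(size = c(192, 192),
                     families = list(
                       list(orientation = 30, period = 12, amplitude = 1),
                       list(orientation = 120, period = 12, amplitude = 1)))
  res <- analyze_image(make_fiber_image(sp), R = 2, t_fraction = 0.1, B = 5)
  expect_equal(res$model$k, 2L)
  got <- sort(res$model$b)
  expect_lte(circ_dist(got[1], fold_expect(120 + 90)), 5)  # normal at 30
  expect_lte(circ_dist(got[2], fold_expect(30 + 90)), 5)   # normal at 120
})

test_that("waviness broadens the fitted orientation width", {
  widths <- vapply(c(0, 10, 25), function(wv) {
    r <- analyze_image(grating_image(40, size = 160L, waviness = wv),
                       R = 2, t_fraction = 0.1, B = 5, k = 1)
    r$model$c[1]
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("noise images are iid with the requested value type", {
  pois <- make_noise_image(c(48, 48), "poisson", mean = 2, seed = 7)
  expect_true(all(pois$pixels == round(pois$pixels)))  # photon counts
  expect_true(all(pois$pixels >= 0))
  expect_equal(mean(pois$pixels), 2, tolerance = 0.1)
  expect_identical(make_noise_image(c(48, 48), "poisson", mean = 2,
                                    seed = 7)$pixels, pois$pixels)
  gaus <- make_noise_image(c(48, 48), "gaussian", mean = 5, sd = 1, seed = 7)
  expect_false(all(gaus$pixels == round(gaus$pixels)))
  expect_true(all(gaus$pixels >= 0))
})

test_that("integer-count noise spikes at multiples of 45 fade with R", {
  img <- normalize_image(make_noise_image(c(128, 128), "poisson", mean = 2,
                                          seed = 13))
  spike_mass <- function(R) {
    f <- compute_gradient(img, R = R)
    p <- build_pdf(f, B = 1)
    sum(p$density[p$bin_centers %in% (c(45, 90, 135, 180) - 0.5)])
  }
  m1 <- spike_mass(1)
  m3 <- spike_mass(3)
  expect_gt(m1, 5 * 4 / 180)    # R = 1: far above a flat density
  expect_lt(m3, 0.75 * m1)      # averaging spreads the exact ties
  # continuous-valued noise produces no exact-tie spikes at R = 1
  gimg <- normalize_image(make_noise_image(c(128, 128), "gaussian", mean = 5,
                                           sd = 1, seed = 13))
  fg <- compute_gradient(gimg, R = 1)
  pg <- build_pdf(fg, B = 1)
  sp <- pg$bin_centers %in% (c(45, 90, 135, 180) - 0.5)
  expect_lt(max(pg$density[sp]), 3 * median(pg$density[!sp]))
})

test_that("the model-parameter sampler reproduces its ground truth", {
  # uniform-only density: every bin near 1/180
  pdf_u <- sample_orientation_pdf(0, 90, 10, 1 / 180, n = 2e5, B = 5,
                                  seed = 31)
  expect_lt(max(abs(pdf_u$density - 1 / 180)), 0.15 / 180)
  # deviation shrinks with n (law of large numbers)
  pdf_small <- sample_orientation_pdf(0, 90, 10, 1 / 180, n = 2e3, B = 5,
                                      seed = 31)
  expect_lt(max(abs(pdf_u$density - 1 / 180)),
            max(abs(pdf_small$density - 1 / 180)))
  # determinism and ground-truth attachment
  pdf_a <- sample_orientation_pdf(0.01, 60, 15, 0.001, n = 1e4, B = 5,
                                  seed = 77)
  pdf_b <- sample_orientation_pdf(0.01, 60, 15, 0.001, n = 1e4, B = 5,
                                  seed = 77)
  expect_identical(pdf_a$counts, pdf_b$counts)
  expect_equal(pdf_a$ground_truth$b, 60)
  expect_error(sample_orientation_pdf(0, 90, 10, 0, n = 10, B = 5, seed = 1),
               "all-zero")
  # unit area like any orientation PDF
  expect_lt(abs(sum(pdf_a$density) * 5 - 1), 1e-9)
})

test_that("rotation equivariance holds across the half-circle", {
  for (phi in c(0, 45, 105, 150)) {
    f <- compute_gradient(grating_image(phi), R = 2)
    p <- build_pdf(f, T = threshold_from_fraction(f, 0.1), B = 5)
    peak <- p$bin_centers[which.max(p$density)]
    expect_lte(circ_dist(peak, fold_expect(phi + 90)), 5)
  }
})

test_that("phantoms round-trip through 16-bit TIFF with sidecar", {
  sp <- phantom_spec(size = c(48, 48),
                     families = list(list(orientation = 60, period = 10,
                                          amplitude = 1)), seed = 2)
  img <- make_fiber_image(sp)
  path <- file.path(tempdir(), "phantom_rt.tif")
  write_phantom(img, path)
  back <- load_image(path)
  expect_equal(normalize_image(back)$pixels, img$pixels, tolerance = 2e-4)
  gt <- jsonlite::read_json(sub("\\.tif$", ".json", path))
  expect_equal(gt$families[[1]]$orientation, 60)
  expect_equal(gt$seed, 2)
})
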
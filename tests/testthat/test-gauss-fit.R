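test_that("model evaluation follows the Gaussian-plus-pedestal form", {
  m1 <- list(a = 0.01, b = 80, c = 20, d = 0.002)
  expect_equal(evaluate_model(m1, 80), 0.012)          # peak: a + d
  expect_equal(evaluate_model(m1, 80 + 50 * 20), 0.002)  # far tail: d
  # one-sigma offset evaluates to d + a*exp(-1/2)
  m2 <- list(a = 0.0108, b = 98.2, c = 25.0, d = 0.0018)
  expect_equal(evaluate_model(m2, 123.2), 0.0018 + 0.0108 * exp(-0.5))
  expect_equal(evaluate_model(m2, 123.2), 0.00835, tolerance = 1e-3)
  # components add
  m3 <- list(a = c(0.01, 0.02), b = c(40, 40), c = c(10, 10), d = 0)
  expect_equal(evaluate_model(m3, 40), 0.03)
})

test_that("R-squared matches the coefficient-of-determination arithmetic", {
  obs <- c(1, 2, 3)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_equal(r_squared(obs, c(1, 2, 4)), 0.5)  # 1 - 1/2
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("an exact model PDF is recovered to machine-level precision", {
  a <- 0.011; b <- 97; c <- 24; d <- 0.0015
  pdf <- exact_model_pdf(a, b, c, d, B = 5L)
  fit <- fit_gaussians(pdf, k = 1)
  expect_gte(fit$r_squared, 0.999999)
  # normalization rescales heights: compare shape parameters directly and
  # amplitude parameters up to the common area factor
  expect_equal(fit$b[1], b, tolerance = 1e-5)
  expect_equal(fit$c[1], c, tolerance = 1e-5)
  expect_equal(fit$a[1] / fit$d, a / d, tolerance = 1e-4)
})

test_that("sampled mixtures are recovered within sampling tolerance", {
  # single family: Gaussian mass 0.8 at 60 deg, width 15, uniform mass 0.2
  a <- 0.8 / (15 * sqrt(2 * pi))
  pdf <- sample_orientation_pdf(a, 60, 15, 0.2 / 180, n = 1e5, B = 5, seed = 3)
  fit <- fit_gaussians(pdf, k = 1)
  expect_lt(abs(fit$b[1] - 60), 2)
  expect_lt(abs(fit$c[1] - 15) / 15, 0.10)
  expect_gt(fit$r_squared, 0.98)
  # crossed families at 40 and 130 degrees
  a2 <- 0.35 / (15 * sqrt(2 * pi))
  pdf2 <- sample_orientation_pdf(c(a2, a2), c(40, 130), c(15, 15), 0.3 / 180,
                                 n = 1e5, B = 5, seed = 4)
  fit2 <- fit_gaussians(pdf2, k = 2)
  expect_lt(abs(fit2$b[1] - 40), 3)
  expect_lt(abs(fit2$b[2] - 130), 3)
})

test_that("confidence half-widths are finite and cover sampling error", {
  pdf <- sample_orientation_pdf(0.01, 75, 18, 0.001, n = 5e4, B = 5, seed = 9)
  fit <- fit_gaussians(pdf, k = 1)
  expect_true(all(is.finite(fit$ci95$a)))
  expect_true(all(is.finite(fit$ci95$b)))
  expect_true(all(fit$ci95$c > 0))
  expect_length(fit$ci95$d, 1L)
  # center CI of a well-sampled unimodal PDF is tight (well under a bin)
  expect_lt(fit$ci95$b[1], 5)
})

test_that("fits fail loudly when k is too large for the bin count", {
  pdf <- sample_orientation_pdf(0.01, 90, 15, 0.001, n = 1e4, B = 45, seed = 1)
  expect_error(fit_gaussians(pdf, k = 2), "bins")
})

test_that("best attainable R-squared is non-decreasing in k", {
  a2 <- 0.35 / (15 * sqrt(2 * pi))
  pdf <- sample_orientation_pdf(c(a2, a2), c(50, 140), c(12, 12), 0.3 / 180,
                                n = 5e4, B = 5, seed = 12)
  r2 <- vapply(1:3, function(k) fit_gaussians(pdf, k = k)$r_squared,
               numeric(1))
  expect_true(all(diff(r2) >= -1e-6))
})

test_that("order selection prefers the smallest adequate k", {
  # one family -> k = 1
  a <- 0.8 / (15 * sqrt(2 * pi))
  pdf1 <- sample_orientation_pdf(a, 70, 15, 0.2 / 180, n = 1e5, B = 5,
                                 seed = 21)
  sel1 <- select_k(pdf1, k_max = 3)
  expect_equal(sel1$k, 1L)
  expect_false(sel1$no_dominant_orientation)
  expect_length(sel1$r2_by_k, 3L)
  # two well-separated families -> k = 2
  a2 <- 0.35 / (15 * sqrt(2 * pi))
  pdf2 <- sample_orientation_pdf(c(a2, a2), c(40, 130), c(15, 15), 0.3 / 180,
                                 n = 1e5, B = 5, seed = 22)
  sel2 <- select_k(pdf2, k_max = 3)
  expect_equal(sel2$k, 2L)
  expect_lte(circ_dist(sel2$b[1], 40), 5)
  expect_lte(circ_dist(sel2$b[2], 130), 5)
})

test_that("a uniform PDF is flagged as having no dominant orientation", {
  pdf <- sample_orientation_pdf(0, 90, 15, 1 / 180, n = 1e5, B = 5, seed = 30)
  sel <- select_k(pdf, k_max = 2)
  # pedestal-only density: component height indistinguishable from zero
  expect_true(sel$no_dominant_orientation)
  expect_lt(sel$a[which.max(sel$a)], 0.002)  # far below any real peak
  expect_gt(sel$d, 1 / 180 * 0.7)
})

test_that("fitted centers are reported in the unshifted frame", {
  # a peak near the domain edge: fitting happens on a rotated axis but b
  # comes back in (0, 180]
  a <- 0.9 / (10 * sqrt(2 * pi))
  pdf <- sample_orientation_pdf(a, 172, 10, 0.1 / 180, n = 1e5, B = 5,
                                seed = 40)
  fit <- fit_gaussians(pdf, k = 1)
  expect_lte(circ_dist(fit$b[1], 172), 3)
  expect_true(fit$b[1] > 0 && fit$b[1] <= 180)
  expect_true(fit$shift_applied != 0)
})

test_that("model JSON export round-trips the parameters", {
  pdf <- sample_orientation_pdf(0.01, 60, 15, 0.001, n = 2e4, B = 5, seed = 8)
  fit <- fit_gaussians(pdf, k = 1)
  path <- tempfile(fileext = ".json")
  write_model_json(fit, path)
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(out$k, 1L)
  expect_equal(out$b, fit$b)
  expect_equal(out$r_squared, fit$r_squared)
  expect_equal(out$shift_applied, fit$shift_applied)
})
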
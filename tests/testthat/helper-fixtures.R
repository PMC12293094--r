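# Shared fixtures built in code.

# circular distance between two orientations on the 180-degree circle
circ_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# fold an angle the way the pipeline does, for expectations
fold_expect <- function(theta) {
  t <- theta %% 180
  ifelse(t == 0, 180, t)
}

# an orientation_pdf holding the exact Gaussian-plus-pedestal density
# evaluated at the bin centers (normalized to unit area); counts are scaled
# to a large pseudo-sample so the density field is exact up to rounding
exact_model_pdf <- function(a, b, c, d, B = 5L) {
  centers <- seq(B / 2, 180 - B / 2, by = B)
  dens <- evaluate_model(list(a = a, b = b, c = c, d = d), centers)
  dens <- dens / (sum(dens) * B)
  n <- 1e7
  fiborient:::new_orientation_pdf(dens * n * B, B, n_vectors = n, shift = 0)
}

# a minimal gradient_field with prescribed magnitudes/orientations, for
# operations that only read magnitude/valid_mask/theta_folded
toy_field <- function(magnitude, theta_folded = NULL) {
  magnitude <- as.matrix(magnitude)
  if (is.null(theta_folded)) {
    theta_folded <- matrix(90, nrow(magnitude), ncol(magnitude))
  }
  valid <- magnitude > 0
  theta_folded[!valid] <- NA_real_
  structure(
    list(gx = magnitude, gy = magnitude * 0, magnitude = magnitude,
         theta_raw = theta_folded, theta_folded = theta_folded,
         valid_mask = valid, R = 1L),
    class = "gradient_field"
  )
}

# single-family grating phantom, the workhorse input
grating_image <- function(orientation, size = 128L, period = 12,
                          waviness = 0, ...) {
  make_fiber_image(phantom_spec(
    size = c(size, size),
    families = list(list(orientation = orientation, period = period,
                         amplitude = 1, waviness = waviness)),
    ...
  ))
}
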
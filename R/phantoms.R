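# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  code
}

#' Describe a synthetic fiber phantom
#'
#' A phantom is a sum of oriented sinusoidal fiber gratings over a constant
#' background, with optional waviness (sinusoidal modulation of the local
#' fiber angle) and a noise model, all reproducible from a seed. Gratings
#' are used because their intensity gradient is analytically perpendicular
#' to the fiber axis, giving exact ground truth for the pipeline.
#'
#' @param size Integer vector `c(height, width)` in pixels.
#' @param families List of 1 to 3 fiber families; each a list with
#'   `orientation` (fiber-axis angle in degrees), `period` (grating period in
#'   pixels, >= 2), `amplitude` (relative intensity, >= 0), and optionally
#'   `waviness` (max local angle deviation in degrees, default 0, straight
#'   fibers) and `waviness_period` (pixels per undulation, default
#'   `10 * period`).
#' @param patch Block edge length in pixels for multi-family phantoms: the
#'   image is tiled into `patch` x `patch` blocks and each block renders one
#'   family (cycling through them checkerboard-fashion), emulating stacked
#'   fiber sheets that occupy distinct regions of the frame. A transparent
#'   sum of two gratings would instead concentrate gradient orientations at
#'   the bisectors of the two normals (the vector-sum direction where both
#'   slopes peak), which is not how crossed fiber families appear in tissue.
#'   Ignored for a single family. Default `min(size) %/% 4`.
#' @param noise One of `"none"` (default), `"gaussian"`, `"poisson"`.
#' @param noise_mean Mean photon count for `"poisson"` (image scaled so its
#'   mean intensity equals this count before drawing), or additive mean for
#'   `"gaussian"`.
#' @param noise_sd Standard deviation for `"gaussian"` noise, on the relative
#'   intensity scale.
#' @param background Constant background level (relative units).
#' @param seed Integer seed; identical spec + seed give a bit-identical image.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = c(256L, 256L), families, patch = NULL,
                         noise = c("none", "gaussian", "poisson"),
                         noise_mean = 0, noise_sd = 0,
                         background = 0, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(length(size) == 2L, all(size >= 2))
  if (!is.list(families) || length(families) < 1L || length(families) > 3L) {
    stop("between 1 and 3 fiber families are supported", call. = FALSE)
  }
  if (!all(vapply(families, is.list, logical(1)))) {
    stop("`families` must be a list of family lists", call. = FALSE)
  }
  families <- lapply(families, function(f) {
    stopifnot(is.numeric(f$orientation), is.numeric(f$period),
              is.numeric(f$amplitude))
    if (f$period < 2) stop("family period must be >= 2 pixels", call. = FALSE)
    if (f$amplitude < 0) stop("family amplitude must be >= 0", call. = FALSE)
    f$waviness <- if (is.null(f$waviness)) 0 else f$waviness
    stopifnot(f$waviness >= 0, f$waviness < 90)
    f$waviness_period <-
      if (is.null(f$waviness_period)) 10 * f$period else f$waviness_period
    f
  })
  stopifnot(background >= 0, noise_mean >= 0, noise_sd >= 0)
  if (is.null(patch)) patch <- max(min(size) %/% 4L, 8L)
  stopifnot(patch >= 4)
  structure(
    list(size = as.integer(size), families = families,
         patch = as.integer(patch), noise = noise,
         noise_mean = noise_mean, noise_sd = noise_sd,
         background = background, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a synthetic fiber image from a phantom spec
#'
#' Renders each family as a sinusoidal grating whose stripes run along the
#' family orientation; waviness bends the stripes by phase-modulating the
#' perpendicular coordinate so the local fiber angle oscillates by up to the
#' stated amplitude. With several families the image is tiled into
#' `patch`-sized blocks, each rendering one family (see [phantom_spec()]).
#' Background and noise are added, values clipped to non-negative and
#' max-normalized. The generating spec is attached as `$ground_truth` for
#' downstream comparison.
#'
#' @param spec A `phantom_spec`.
#' @return A normalized `gray_image` with a `ground_truth` field.
#' @export
make_fiber_image <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$size[1L]; w <- spec$size[2L]
  xj <- matrix(rep(seq_len(w), each = h), h, w)   # column coordinate
  yi <- matrix(rep(seq_len(h), times = w), h, w)  # row coordinate
  I <- matrix(spec$background, h, w)
  nfam <- length(spec$families)
  if (nfam > 1L) {
    bx <- (xj - 1L) %/% spec$patch
    by <- (yi - 1L) %/% spec$patch
    assign_fam <- ((bx + by) %% nfam) + 1L
  }
  for (fi in seq_len(nfam)) {
    f <- spec$families[[fi]]
    phi <- f$orientation * pi / 180
    u <- -xj * sin(phi) + yi * cos(phi)  # perpendicular to the fiber axis
    v <- xj * cos(phi) + yi * sin(phi)   # along the fiber axis
    if (f$waviness > 0) {
      lam <- f$waviness_period
      # du/dv amplitude tan(waviness) -> local angle deviation up to waviness
      u <- u + (lam * tan(f$waviness * pi / 180) / (2 * pi)) *
        sin(2 * pi * v / lam)
    }
    pat <- f$amplitude * 0.5 * (1 + sin(2 * pi * u / f$period))
    if (nfam > 1L) pat[assign_fam != fi] <- 0
    I <- I + pat
  }
  I <- with_seed(spec$seed, {
    if (spec$noise == "gaussian" && (spec$noise_sd > 0 || spec$noise_mean > 0)) {
      I + matrix(stats::rnorm(h * w, spec$noise_mean, spec$noise_sd), h, w)
    } else if (spec$noise == "poisson" && spec$noise_mean > 0) {
      mu <- mean(I)
      lam <- if (mu > 0) I * (spec$noise_mean / mu) else
        matrix(spec$noise_mean, h, w)
      matrix(as.numeric(stats::rpois(h * w, lam)), h, w)
    } else {
      I
    }
  })
  I[I < 0] <- 0
  img <- normalize_image(gray_image(I))
  img$ground_truth <- spec
  img
}

#' Generate a pure noise image
#'
#' An iid noise field with no fiber structure: Poisson for integer-valued
#' photon-count emulation (the regime where single-pixel gradients produce
#' spurious orientation spikes at 0/45/90/135 degrees), or Gaussian for
#' continuous-valued noise.
#'
#' @param size Integer vector `c(height, width)`.
#' @param distribution `"poisson"` or `"gaussian"`.
#' @param mean Poisson mean count, or Gaussian mean.
#' @param sd Gaussian standard deviation (ignored for Poisson).
#' @param seed Integer seed.
#' @return An unnormalized `gray_image` (pass through [normalize_image()]
#'   before analysis).
#' @export
make_noise_image <- function(size = c(256L, 256L),
                             distribution = c("poisson", "gaussian"),
                             mean = 2, sd = 1, seed = 1L) {
  distribution <- match.arg(distribution)
  stopifnot(length(size) == 2L, all(size >= 2))
  h <- as.integer(size[1L]); w <- as.integer(size[2L])
  px <- with_seed(seed, {
    if (distribution == "poisson") {
      matrix(as.numeric(stats::rpois(h * w, mean)), h, w)
    } else {
      m <- matrix(stats::rnorm(h * w, mean, sd), h, w)
      m[m < 0] <- 0
      m
    }
  })
  gray_image(px)
}

#' Sample an orientation PDF from known model parameters
#'
#' Draws `n` angles from the normalized Gaussian-plus-pedestal density with
#' the given parameters: each component contributes with probability
#' proportional to its area (`a_k * c_k * sqrt(2*pi)`; the pedestal with
#' `d * 180`), Gaussian draws are wrapped onto (0, 180] (the folded domain is
#' circular), and the pedestal is uniform. Angles are then binned exactly as
#' [build_pdf()] bins gradient orientations. Ground truth is attached as
#' `$ground_truth`.
#'
#' @param a,b,c Numeric vectors of component heights, centers (degrees) and
#'   widths (degrees); equal lengths.
#' @param d Pedestal level (per-degree density).
#' @param n Number of angles to draw.
#' @param B Bin width in degrees (divides 180).
#' @param seed Integer seed.
#' @return An `orientation_pdf` with a `ground_truth` field.
#' @export
sample_orientation_pdf <- function(a, b, c, d, n = 1e5, B = 5L, seed = 1L) {
  stopifnot(length(a) == length(b), length(b) == length(c),
            all(a >= 0), all(c > 0), length(d) == 1L, d >= 0, n >= 1)
  B <- as.integer(B)
  stopifnot(B >= 1L, B <= 180L, 180L %% B == 0L)
  wts <- c(a * c * sqrt(2 * pi), d * 180)
  if (sum(wts) == 0) stop("all-zero density: nothing to sample", call. = FALSE)
  wts <- wts / sum(wts)
  kc <- length(a)
  theta <- with_seed(seed, {
    comp <- sample.int(kc + 1L, n, replace = TRUE, prob = wts)
    th <- numeric(n)
    for (j in seq_len(kc)) {
      nj <- sum(comp == j)
      if (nj > 0) th[comp == j] <- stats::rnorm(nj, b[j], c[j])
    }
    nped <- sum(comp == kc + 1L)
    if (nped > 0) th[comp == kc + 1L] <- stats::runif(nped, 0, 180)
    th
  })
  theta <- fold_angle(theta)
  nbins <- 180L %/% B
  idx <- as.integer(ceiling(theta / B))
  idx[idx < 1L] <- 1L
  idx[idx > nbins] <- nbins
  pdf <- new_orientation_pdf(tabulate(idx, nbins = nbins), B,
                             n_vectors = n, shift = 0)
  pdf$ground_truth <- list(a = a, b = b, c = c, d = d, weights = wts)
  pdf
}

#' Write a phantom image as 16-bit TIFF with a ground-truth sidecar
#'
#' @param img A `gray_image` from [make_fiber_image()] (values in [0, 1]).
#' @param path Output TIFF path; the ground-truth spec is written next to it
#'   with extension `.json`.
#' @return Invisibly, the TIFF path.
#' @export
write_phantom <- function(img, path) {
  stopifnot(inherits(img, "gray_image"))
  tiff::writeTIFF(img$pixels, path, bits.per.sample = 16L)
  gt <- img$ground_truth
  if (!is.null(gt)) {
    jsonlite::write_json(unclass(gt), sub("\\.tiff?$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
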
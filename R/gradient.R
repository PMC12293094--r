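#' Fold an orientation onto the (0, 180] degree half-plane
#'
#' Gradient vectors are axial for fiber detection: a bright fiber produces
#' antiparallel gradients on its two flanks (a fiber at 45 deg yields
#' gradients at 135 deg and -45 deg, both perpendicular to the fiber axis).
#' Folding maps every direction onto its positive-half-plane parallel so the
#' two flanks reinforce a single orientation. 180-degree periodic; under the
#' half-open (0, 180] convention 0 maps to 180.
#'
#' @param theta Numeric vector of finite angles in degrees (any range).
#' @return Angles in (0, 180].
#' @export
#' @examples
#' fold_angle(c(-45, 315, 0, 180))  # 135 135 180 180
fold_angle <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta))) {
    stop("`theta` must be finite; zero-magnitude vectors carry no orientation",
         call. = FALSE)
  }
  t <- theta %% 180
  t[t == 0] <- 180
  t
}

#' Compute the span-averaged intensity gradient field
#'
#' Estimates the gradient of a normalized image with resolution `R`: the
#' centered intensity change over a span of `R` pixels on either side,
#' divided by the span length, averaged over `R` adjacent parallel lines:
#' \deqn{g_x(i,j) = \frac{1}{R}\sum_{m} \frac{I(i+m,\, j+R) - I(i+m,\, j-R)}{2R}}
#' and symmetrically for `gy` (transverse offsets m are the R integers
#' centered on 0). The centered span difference divided by 2R equals the mean
#' of the 2R successive one-pixel differences across the span (telescoping),
#' so each component is the intensity change per pixel averaged along R
#' pixels in every direction. `R = 1` is the plain pixel-to-pixel centered
#' difference. Larger R averages more single-pixel changes, which is what
#' suppresses the spurious 0/45/90/135-degree orientation ties that
#' integer-valued photon-count noise produces at R = 1 (on iid noise the
#' transverse averaging is essential: an unaveraged span difference has the
#' same value distribution at every R).
#'
#' The valid region excludes the R-pixel border where the span leaves the
#' image. Raw orientation is atan2(gy, gx) in (-180, 180] with y along
#' increasing row index; orientations are additionally folded onto (0, 180].
#' Pixels with zero gradient magnitude have no orientation and are excluded
#' from `valid_mask`.
#'
#' @param img A normalized `gray_image` (see [normalize_image()]).
#' @param R Integer averaging span in pixels; the valid region must be
#'   non-empty, i.e. `2R < min(height, width)`.
#' @return A `gradient_field` with matrices `gx`, `gy`, `magnitude`,
#'   `theta_raw`, `theta_folded` (degrees, `NA` where undefined), logical
#'   `valid_mask`, and the span `R`.
#' @export
compute_gradient <- function(img, R = 1L) {
  stopifnot(inherits(img, "gray_image"))
  if (!img$normalized) {
    stop("image must be normalized before gradient computation", call. = FALSE)
  }
  R <- as.integer(R)
  if (length(R) != 1L || is.na(R) || R < 1L ||
      2L * R >= min(img$height, img$width)) {
    stop("`R` must be an integer >= 1 with 2R < min(height, width)",
         call. = FALSE)
  }
  I <- img$pixels
  h <- img$height - 2L * R
  w <- img$width - 2L * R
  ii <- seq_len(h) + R  # valid rows
  jj <- seq_len(w) + R  # valid columns
  offs <- (0:(R - 1L)) - (R - 1L) %/% 2L  # R transverse offsets around 0
  gx <- matrix(0, h, w)
  gy <- matrix(0, h, w)
  for (m in offs) {
    gx <- gx + I[ii + m, jj + R, drop = FALSE] - I[ii + m, jj - R, drop = FALSE]
    gy <- gy + I[ii + R, jj + m, drop = FALSE] - I[ii - R, jj + m, drop = FALSE]
  }
  gx <- gx / (2 * R * R)
  gy <- gy / (2 * R * R)
  magnitude <- sqrt(gx^2 + gy^2)
  valid_mask <- magnitude > 0
  theta_raw <- matrix(NA_real_, h, w)
  theta_raw[valid_mask] <- atan2(gy[valid_mask], gx[valid_mask]) * 180 / pi
  # atan2 returns (-180, 180]; map the -180 endpoint onto +180
  theta_raw[!is.na(theta_raw) & theta_raw <= -180] <- 180
  theta_folded <- matrix(NA_real_, h, w)
  theta_folded[valid_mask] <- fold_angle(theta_raw[valid_mask])
  structure(
    list(
      gx = gx, gy = gy, magnitude = magnitude,
      theta_raw = theta_raw, theta_folded = theta_folded,
      valid_mask = valid_mask, R = R
    ),
    class = "gradient_field"
  )
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf(
    "<gradient_field> %d x %d valid region (R = %d), %d/%d oriented pixels, max |g| = %g\n",
    nrow(x$gx), ncol(x$gx), x$R, sum(x$valid_mask), length(x$valid_mask),
    max(x$magnitude)
  ))
  invisible(x)
}

#' Raw orientation map for visualization
#'
#' Per-pixel raw (unfolded) gradient orientation in (-180, 180] degrees over
#' the valid region, with a sentinel where the orientation is undefined
#' (zero-magnitude pixels). Intended for color-map export and visual QC of
#' the gradient stage.
#'
#' @param field A `gradient_field`.
#' @param sentinel Value placed at pixels with no orientation (default `NA`).
#' @return Numeric matrix of raw orientations.
#' @export
orientation_map <- function(field, sentinel = NA_real_) {
  stopifnot(inherits(field, "gradient_field"))
  m <- field$theta_raw
  m[!field$valid_mask] <- sentinel
  m
}

#' Export an orientation map as a color-mapped PNG
#'
#' Orientation is encoded as hue over the (-180, 180] range; undefined pixels
#' are rendered black.
#'
#' @param field A `gradient_field`.
#' @param path Output PNG path.
#' @return Invisibly, the path.
#' @export
write_orientation_png <- function(field, path) {
  stopifnot(inherits(field, "gradient_field"))
  m <- orientation_map(field)
  hue <- (m + 180) / 360  # (-180,180] -> (0,1]
  rgb <- array(0, dim = c(nrow(m), ncol(m), 3L))
  ok <- !is.na(hue)
  if (any(ok)) {
    cols <- grDevices::hsv(h = pmin(hue[ok], 1), s = 1, v = 1)
    rgbv <- grDevices::col2rgb(cols) / 255
    for (ch in 1:3) {
      plane <- matrix(0, nrow(m), ncol(m))
      plane[ok] <- rgbv[ch, ]
      rgb[, , ch] <- plane
    }
  }
  png::writePNG(rgb, target = path)
  invisible(path)
}

#' Export gradient orientations and magnitudes as CSV
#'
#' One row per valid pixel: `i`, `j` (1-based row/column in the valid
#' region), `theta_raw` (degrees), `magnitude`.
#'
#' @param field A `gradient_field`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_orientation_csv <- function(field, path) {
  stopifnot(inherits(field, "gradient_field"))
  idx <- which(field$valid_mask, arr.ind = TRUE)
  df <- data.frame(
    i = idx[, 1L], j = idx[, 2L],
    theta_raw = field$theta_raw[field$valid_mask],
    magnitude = field$magnitude[field$valid_mask]
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
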
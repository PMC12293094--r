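#' Construct a grayscale image object
#'
#' Wraps a numeric matrix of non-negative intensities as a `gray_image`, the
#' container every pipeline stage operates on. Rows index the vertical image
#' coordinate i, columns the horizontal coordinate j.
#'
#' @param pixels Numeric matrix of non-negative intensities (rows = i,
#'   columns = j). Must be at least 2 x 2.
#' @param normalized Logical; `TRUE` only if the maximum intensity is exactly 1.
#' @return A `gray_image` object with fields `pixels`, `height`, `width`,
#'   `normalized`.
#' @export
gray_image <- function(pixels, normalized = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    stop("image must be at least 2 x 2 pixels", call. = FALSE)
  }
  if (anyNA(pixels)) stop("image contains missing values", call. = FALSE)
  if (any(pixels < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (isTRUE(normalized) && max(pixels) != 1) {
    stop("`normalized = TRUE` requires max intensity exactly 1", call. = FALSE)
  }
  structure(
    list(
      pixels = pixels,
      height = nrow(pixels),
      width = ncol(pixels),
      normalized = isTRUE(normalized)
    ),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d, intensity range [%g, %g]%s\n",
    x$height, x$width, min(x$pixels), max(x$pixels),
    if (x$normalized) ", normalized" else ""
  ))
  invisible(x)
}

#' Read a grayscale micrograph from TIFF or PNG
#'
#' Reads 8- or 16-bit TIFF and PNG files. Intensities are kept on the scale
#' the reader returns (relative values preserved; bit depth is irrelevant
#' downstream because images are max-normalized before analysis).
#' Multichannel images require an explicit `channel`; there is no silent
#' luminance conversion.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param channel Integer channel index for multichannel inputs (1-based).
#' @return A `gray_image` with `normalized = FALSE`.
#' @export
load_image <- function(path, channel = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file '%s' does not exist", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    png = png::readPNG(path),
    stop(sprintf("unsupported image format '.%s' (TIFF or PNG expected)", ext),
         call. = FALSE)
  )
  if (is.list(arr)) arr <- arr[[1L]]  # multi-page TIFF: first frame
  if (length(dim(arr)) == 3L) {
    if (is.null(channel)) {
      stop(sprintf(
        "image has %d channels; select one with `channel`", dim(arr)[3L]
      ), call. = FALSE)
    }
    if (channel < 1L || channel > dim(arr)[3L]) {
      stop("`channel` out of range", call. = FALSE)
    }
    arr <- arr[, , channel]
  }
  storage.mode(arr) <- "double"
  gray_image(arr, normalized = FALSE)
}

#' Normalize image intensities to a maximum of 1
#'
#' Divides every pixel by the image maximum so that magnitude thresholds are
#' comparable across images. Idempotent; preserves the relative ordering of
#' intensities.
#'
#' @param img A `gray_image`.
#' @param probs Optional quantile in (0, 1] used instead of the maximum (a
#'   robust normalizer for images with photon-count outliers); values above
#'   the quantile are clipped to 1. Default `NULL` uses the true maximum.
#' @return A `gray_image` with max intensity 1 and `normalized = TRUE`.
#' @export
normalize_image <- function(img, probs = NULL) {
  stopifnot(inherits(img, "gray_image"))
  m <- max(img$pixels)
  if (m == 0) {
    stop("degenerate all-zero image: no structure to analyze", call. = FALSE)
  }
  if (is.null(probs)) {
    px <- img$pixels / m
    px[px > 1] <- 1  # guard against FP overshoot
  } else {
    stopifnot(is.numeric(probs), length(probs) == 1L, probs > 0, probs <= 1)
    q <- stats::quantile(img$pixels, probs = probs, names = FALSE)
    if (q <= 0) stop("normalization quantile is zero", call. = FALSE)
    px <- pmin(img$pixels / q, 1)
  }
  # force exact unit maximum (division can leave max at 1 - eps)
  px[which.max(px)] <- 1
  gray_image(px, normalized = TRUE)
}
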
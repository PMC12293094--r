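#' Magnitude threshold as a fraction of the field maximum
#'
#' Convenience rule for choosing the magnitude threshold T: a fixed fraction
#' of the largest gradient magnitude in the field (commonly 10%), which keeps
#' noise sensitivity comparable across images of different contrast.
#'
#' @param field A `gradient_field` with at least one oriented pixel.
#' @param fraction Fraction of the maximum magnitude, in (0, 1].
#' @return The threshold value `fraction * max(magnitude)`.
#' @export
threshold_from_fraction <- function(field, fraction = 0.10) {
  stopifnot(inherits(field, "gradient_field"))
  if (!any(field$valid_mask)) {
    stop("gradient field has no oriented pixels", call. = FALSE)
  }
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction > 0, fraction <= 1)
  fraction * max(field$magnitude[field$valid_mask])
}

#' Build the orientation probability density function
#'
#' Discards gradient vectors with magnitude below `T`, assigns the surviving
#' folded orientations to half-open angular bins (0, B], (B, 2B], ...,
#' (180 - B, 180], and converts counts to a per-degree probability density
#' with unit area: density_i = count_i / (n * B), so that
#' sum(density) * B = 1.
#'
#' @param field A `gradient_field` computed on a normalized image.
#' @param T Magnitude threshold on the normalized-intensity gradient scale
#'   (vectors with magnitude < T are discarded). Default 0 keeps all oriented
#'   vectors.
#' @param B Angular bin width in degrees; an integer that divides 180.
#' @return An `orientation_pdf` with fields `bin_edges` (length nbins + 1),
#'   `bin_centers`, `counts`, `density` (per degree), `bin_width`,
#'   `n_vectors`, `shift` (degrees, 0 here).
#' @export
build_pdf <- function(field, T = 0, B = 5L) {
  stopifnot(inherits(field, "gradient_field"))
  B <- as.integer(B)
  if (length(B) != 1L || is.na(B) || B < 1L || B > 180L || 180L %% B != 0L) {
    stop("`B` must be an integer in [1, 180] dividing 180", call. = FALSE)
  }
  stopifnot(is.numeric(T), length(T) == 1L, T >= 0)
  keep <- field$valid_mask & field$magnitude >= T
  theta <- field$theta_folded[keep]
  n <- length(theta)
  if (n == 0L) {
    stop("no gradient vectors survive the threshold: empty orientation PDF",
         call. = FALSE)
  }
  nbins <- 180L %/% B
  # theta in (0, 180]: bin index = ceiling(theta / B) in 1..nbins
  idx <- as.integer(ceiling(theta / B))
  idx[idx < 1L] <- 1L          # guard FP underflow at the 0+ boundary
  idx[idx > nbins] <- nbins
  counts <- tabulate(idx, nbins = nbins)
  new_orientation_pdf(counts, B, n_vectors = n, shift = 0)
}

new_orientation_pdf <- function(counts, B, n_vectors, shift) {
  nbins <- length(counts)
  structure(
    list(
      bin_edges = seq(0, 180, by = B),
      bin_centers = seq_len(nbins) * B - B / 2,
      counts = counts,
      density = counts / (n_vectors * B),
      bin_width = B,
      n_vectors = n_vectors,
      shift = shift
    ),
    class = "orientation_pdf"
  )
}

#' @export
print.orientation_pdf <- function(x, ...) {
  peak <- x$bin_centers[which.max(x$density)]
  cat(sprintf(
    "<orientation_pdf> %d bins of %g deg, %d vectors, peak bin at %g deg%s\n",
    length(x$counts), x$bin_width, x$n_vectors, peak,
    if (x$shift != 0) sprintf(", shifted %+g deg", x$shift) else ""
  ))
  invisible(x)
}

#' Circularly shift a PDF so its peak sits at a chosen angle
#'
#' Rotates the bins of the orientation PDF (which is circular with period
#' 180 deg after folding) so that the maximum-density bin lands in the bin
#' containing `center`. Centering the peak keeps the Gaussian fit away from
#' the domain seam and is standard practice before fitting; the applied shift
#' is recorded (and composed with any previous shift) so fitted centers can
#' be mapped back to the original frame. Under exact ties the leftmost
#' (smallest-angle) maximal bin is chosen, for determinism.
#'
#' @param pdf An `orientation_pdf`.
#' @param center Target angle in degrees, default 90 (mid-range).
#' @return The shifted `orientation_pdf`; densities unchanged as a multiset.
#' @export
shift_pdf <- function(pdf, center = 90) {
  stopifnot(inherits(pdf, "orientation_pdf"))
  stopifnot(is.numeric(center), length(center) == 1L,
            center > 0, center <= 180)
  max_idx <- which.max(pdf$density)  # leftmost maximum under ties
  target_idx <- as.integer(ceiling(center / pdf$bin_width))
  rotate_pdf(pdf, target_idx - max_idx)
}

#' Rotate a PDF so its least-populated bin abuts the domain seam
#'
#' Alternative framing rule to [shift_pdf()]: circularly rotates the bins so
#' the global minimum-density bin (leftmost under ties) becomes the first
#' bin, placing the 0/180 seam inside the orientation gap. For a unimodal
#' PDF this leaves the peak near mid-range like the classic peak-centering
#' shift; for multimodal PDFs it avoids parking a secondary peak on the
#' seam, where a non-circular Gaussian fit would split its tails.
#'
#' @param pdf An `orientation_pdf`.
#' @return The rotated `orientation_pdf`, shift recorded.
#' @export
shift_pdf_gap <- function(pdf) {
  stopifnot(inherits(pdf, "orientation_pdf"))
  rotate_pdf(pdf, 1L - which.min(pdf$density))
}

# circular rotation by k bins (content at angle t moves to t + k*B mod 180),
# composing the recorded shift
rotate_pdf <- function(pdf, k) {
  nbins <- length(pdf$counts)
  B <- pdf$bin_width
  k <- ((k %% nbins) + nbins) %% nbins
  shift_deg <- (k * B + 90) %% 180 - 90  # wrapped to (-90, 90]
  if (k == 0L) return(pdf)
  perm <- ((seq_len(nbins) - 1L - k) %% nbins) + 1L  # new[i] = old[i - k]
  out <- new_orientation_pdf(pdf$counts[perm], B, pdf$n_vectors,
                             shift = pdf$shift + shift_deg)
  out$ground_truth <- pdf$ground_truth
  out
}

#' Export an orientation PDF as CSV with a JSON metadata sidecar
#'
#' The CSV has columns `bin_lo`, `bin_hi`, `bin_center`, `count`, `density`.
#' If `meta` is supplied, a JSON block with the analysis parameters
#' (R, T, B, n_vectors, shift, and anything else passed) is written next to
#' the CSV with extension `.json`.
#'
#' @param pdf An `orientation_pdf`.
#' @param path Output CSV path.
#' @param meta Optional named list of run parameters for the sidecar.
#' @return Invisibly, the CSV path.
#' @export
write_pdf_csv <- function(pdf, path, meta = NULL) {
  stopifnot(inherits(pdf, "orientation_pdf"))
  nbins <- length(pdf$counts)
  df <- data.frame(
    bin_lo = pdf$bin_edges[seq_len(nbins)],
    bin_hi = pdf$bin_edges[seq_len(nbins) + 1L],
    bin_center = pdf$bin_centers,
    count = pdf$counts,
    density = pdf$density
  )
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(meta)) {
    meta <- c(meta, list(n_vectors = pdf$n_vectors, shift = pdf$shift,
                         bin_width = pdf$bin_width))
    jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
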
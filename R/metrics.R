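#' Areas under the Gaussian components
#'
#' Each component's area is the exact full-line Gaussian integral
#' `a_k * c_k * sqrt(2*pi)` (height times width, up to the fixed constant);
#' the total is the algebraic sum over components. Because the PDF has unit
#' area, component areas are directly interpretable as the fraction of
#' gradient vectors belonging to each oriented fiber family.
#'
#' @param model A `gauss_pedestal_fit`.
#' @return List with `component_areas` (length k) and `total`.
#' @export
gaussian_areas <- function(model) {
  areas <- model$a * model$c * sqrt(2 * pi)
  list(component_areas = areas, total = sum(areas))
}

#' Area under the pedestal
#'
#' The pedestal is constant over the whole 180-degree orientation range, so
#' its area is `d * 180`. It measures the fraction of gradient vectors with
#' no preferred orientation — noise or structureless image regions.
#'
#' @param model A `gauss_pedestal_fit`.
#' @return Pedestal area (dimensionless).
#' @export
pedestal_area <- function(model) {
  model$d * 180
}

#' Ratio of Gaussian area to pedestal area
#'
#' Total Gaussian area divided by pedestal area: large values indicate
#' well-ordered fibrous structure, small values a noise-dominated or
#' structureless image (the ratio is an inverse noise indicator). A zero
#' pedestal yields `Inf`, reported as such.
#'
#' @param model A `gauss_pedestal_fit`.
#' @return The ratio (possibly `Inf`).
#' @export
area_ratio <- function(model) {
  ped <- pedestal_area(model)
  tot <- gaussian_areas(model)$total
  if (ped == 0) {
    if (tot == 0) return(NaN)
    return(Inf)
  }
  tot / ped
}

#' Pairwise separations between Gaussian centers
#'
#' Plain absolute differences `|b_j - b_i|` in degrees for every component
#' pair, the arithmetic used when reporting the angle between two fiber
#' families. Not applicable for single-component models (`NA` returned).
#'
#' @param model A `gauss_pedestal_fit`.
#' @return For k >= 2, a named numeric vector of pairwise separations
#'   (`"1-2"`, ...); for k = 1, `NA_real_`.
#' @export
peak_separation <- function(model) {
  k <- length(model$b)
  if (k < 2L) return(NA_real_)
  pairs <- utils::combn(k, 2L)
  stats::setNames(
    abs(model$b[pairs[2L, ]] - model$b[pairs[1L, ]]),
    paste(pairs[1L, ], pairs[2L, ], sep = "-")
  )
}

#' Full set of order metrics for a fitted model
#'
#' Collects the derived organization metrics: component and total Gaussian
#' areas, pedestal area, their ratio, pairwise peak separations, the dominant
#' component's height and width, and the composite peak-height-to-width
#' ratio `(a_dom + d) / c_dom` (total model peak height over Gaussian width).
#'
#' @param model A `gauss_pedestal_fit`.
#' @return An `order_metrics` list.
#' @export
order_metrics <- function(model) {
  ga <- gaussian_areas(model)
  dom <- which.max(model$a)
  structure(
    list(
      k = model$k,
      component_areas = ga$component_areas,
      total_gaussian_area = ga$total,
      pedestal_area = pedestal_area(model),
      gaussian_to_pedestal_ratio = area_ratio(model),
      peak_separations = peak_separation(model),
      gaussian_height = model$a[dom],
      gaussian_width = model$c[dom],
      composite_height_width = (model$a[dom] + model$d) / model$c[dom],
      r_squared = model$r_squared
    ),
    class = "order_metrics"
  )
}

#' @export
print.order_metrics <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<order_metrics> k = %d | Gaussian area %s | pedestal %s | ratio %s | R^2 %.3f\n",
    x$k, signif(x$total_gaussian_area, digits), signif(x$pedestal_area, digits),
    signif(x$gaussian_to_pedestal_ratio, digits), x$r_squared
  ))
  invisible(x)
}

#' Longitudinal panel of single-Gaussian metrics for a time series
#'
#' For a time-ordered set of single-Gaussian fits (e.g. a tissue healing
#' series), tabulates per time point the goodness of fit, the Gaussian
#' height and width, and the composite height-to-width ratio
#' `(a + d) / c`, optionally normalized by the first (control) time point.
#' Recovery of organization over time shows as R-squared rising back above
#' the `r2_threshold` while the width falls.
#'
#' @param models List of `gauss_pedestal_fit` objects, each with k = 1, in
#'   temporal order.
#' @param time_points Optional labels (default `"t1"`, `"t2"`, ...; the
#'   first point is taken as the control for normalization).
#' @param r2_threshold Goodness threshold flagged in the output
#'   (default 0.75, a working boundary for a very good single-Gaussian fit).
#' @param normalize Normalize `composite_height_width` by the first time
#'   point (default TRUE).
#' @return A data.frame with one row per time point: `time_point`,
#'   `r_squared`, `r2_above_threshold`, `gaussian_height`, `gaussian_width`,
#'   `composite_height_width` (normalized if requested).
#' @export
healing_panel <- function(models, time_points = NULL, r2_threshold = 0.75,
                          normalize = TRUE) {
  if (!is.list(models) || length(models) == 0L) {
    stop("`models` must be a non-empty list of fits", call. = FALSE)
  }
  ok <- vapply(models, inherits, logical(1), "gauss_pedestal_fit")
  if (!all(ok)) stop("all elements must be `gauss_pedestal_fit`", call. = FALSE)
  if (any(vapply(models, function(m) m$k, integer(1)) != 1L)) {
    stop("healing panel requires single-Gaussian (k = 1) fits", call. = FALSE)
  }
  if (is.null(time_points)) {
    time_points <- paste0("t", seq_along(models))
  }
  stopifnot(length(time_points) == length(models))
  comp <- vapply(models, function(m) (m$a[1L] + m$d) / m$c[1L], numeric(1))
  if (normalize) comp <- comp / comp[1L]
  data.frame(
    time_point = time_points,
    r_squared = vapply(models, function(m) m$r_squared, numeric(1)),
    r2_above_threshold =
      vapply(models, function(m) m$r_squared >= r2_threshold, logical(1)),
    gaussian_height = vapply(models, function(m) m$a[1L], numeric(1)),
    gaussian_width = vapply(models, function(m) m$c[1L], numeric(1)),
    composite_height_width = comp,
    stringsAsFactors = FALSE
  )
}
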
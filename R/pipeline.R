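#' Run the full orientation analysis on one image
#'
#' Chains the four pipeline stages: normalize the image, compute the
#' span-averaged gradient field, build the thresholded unit-area orientation
#' PDF, and fit the Gaussian-plus-pedestal model (fixed order `k`, or order
#' selection up to `k_max`). Defaults follow common practice for fibrous
#' micrographs: threshold at 10% of the maximum gradient magnitude, 5-degree
#' bins, a 2-pixel gradient span.
#'
#' @param img A `gray_image` (normalized or not) or a path readable by
#'   [load_image()].
#' @param R Gradient averaging span in pixels.
#' @param T Absolute magnitude threshold; give exactly one of `T` and
#'   `t_fraction`. If neither is given, `t_fraction = 0.10` is used.
#' @param t_fraction Threshold as a fraction of the maximum gradient
#'   magnitude (see [threshold_from_fraction()]).
#' @param B Angular bin width in degrees.
#' @param k Fixed number of Gaussian components; `NULL` (default) selects
#'   the order with [select_k()].
#' @param k_max Maximum order for selection when `k` is `NULL`.
#' @param shift Fit framing rule (see [fit_gaussians()]): `"gap"` (default),
#'   `"peak"`, or `"none"`.
#' @param shift_center Angle the PDF peak is rotated to when
#'   `shift = "peak"`.
#' @param channel Channel index when `img` is a path to a multichannel file.
#' @return A `fiber_analysis` list: `image`, `field`, `pdf`, `model`,
#'   `metrics`, `params`.
#' @export
analyze_image <- function(img, R = 2L, T = NULL, t_fraction = NULL, B = 5L,
                          k = NULL, k_max = 3L,
                          shift = c("gap", "peak", "none"), shift_center = 90,
                          channel = NULL) {
  shift <- match.arg(shift)
  if (is.character(img)) img <- load_image(img, channel = channel)
  stopifnot(inherits(img, "gray_image"))
  if (!is.null(T) && !is.null(t_fraction)) {
    stop("give exactly one of `T` and `t_fraction`", call. = FALSE)
  }
  if (is.null(T) && is.null(t_fraction)) t_fraction <- 0.10
  if (!img$normalized) img <- normalize_image(img)
  field <- compute_gradient(img, R = R)
  T_used <- if (is.null(T)) threshold_from_fraction(field, t_fraction) else T
  pdf <- build_pdf(field, T = T_used, B = B)
  model <- if (is.null(k)) {
    select_k(pdf, k_max = k_max, shift = shift, shift_center = shift_center)
  } else {
    fit_gaussians(pdf, k = k, shift = shift, shift_center = shift_center)
  }
  structure(
    list(
      image = img, field = field, pdf = pdf, model = model,
      metrics = order_metrics(model),
      params = list(R = as.integer(R), T = T_used,
                    t_fraction = if (is.null(T)) t_fraction else NULL,
                    B = as.integer(B), k = model$k, k_max = k_max,
                    shift = shift, shift_center = shift_center)
    ),
    class = "fiber_analysis"
  )
}

#' @export
print.fiber_analysis <- function(x, ...) {
  cat(sprintf("<fiber_analysis> R = %d, T = %.4g, B = %d\n",
              x$params$R, x$params$T, x$params$B))
  print(x$model)
  print(x$metrics)
  invisible(x)
}

write_metrics_csv <- function(metrics, path) {
  seps <- metrics$peak_separations
  rows <- data.frame(
    metric = c("k", paste0("component_area_", seq_along(metrics$component_areas)),
               "total_gaussian_area", "pedestal_area",
               "gaussian_to_pedestal_ratio",
               if (!all(is.na(seps))) paste0("peak_separation_", names(seps)),
               "gaussian_height", "gaussian_width", "composite_height_width",
               "r_squared"),
    value = c(metrics$k, metrics$component_areas,
              metrics$total_gaussian_area, metrics$pedestal_area,
              metrics$gaussian_to_pedestal_ratio,
              if (!all(is.na(seps))) unname(seps),
              metrics$gaussian_height, metrics$gaussian_width,
              metrics$composite_height_width, metrics$r_squared),
    stringsAsFactors = FALSE
  )
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Analyze one or more images from the command line
#'
#' For every input image, writes into `out_dir`: a color-mapped raw
#' orientation PNG, a per-pixel orientation CSV, the orientation PDF CSV
#' with a JSON parameter sidecar, the fitted model JSON, and a metrics CSV.
#' A run log records all parameters and the package version. With
#' `series = TRUE` the inputs are treated as a time-ordered series, each is
#' fitted with k = 1, and a longitudinal panel CSV ([healing_panel()]) is
#' written as well.
#'
#' @param inputs Character vector of image paths, or a directory (all
#'   TIFF/PNG files inside, sorted by name).
#' @param out_dir Output directory, created if missing.
#' @param series Treat inputs as a time series (forces k = 1 fits).
#' @param quiet Suppress progress messages.
#' @inheritParams analyze_image
#' @return Invisibly, the list of `fiber_analysis` results.
#' @export
cmd_analyze <- function(inputs, out_dir, R = 2L, T = NULL, t_fraction = NULL,
                        B = 5L, k = NULL, k_max = 3L,
                        shift = c("gap", "peak", "none"), shift_center = 90,
                        channel = NULL, series = FALSE, quiet = FALSE) {
  shift <- match.arg(shift)
  if (length(inputs) == 1L && dir.exists(inputs)) {
    inputs <- sort(list.files(inputs, pattern = "\\.(tiff?|png)$",
                              ignore.case = TRUE, full.names = TRUE))
  }
  if (length(inputs) == 0L) stop("no input images", call. = FALSE)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("input not found: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (series) k <- 1L
  results <- vector("list", length(inputs))
  for (ii in seq_along(inputs)) {
    path <- inputs[ii]
    stem <- tools::file_path_sans_ext(basename(path))
    if (!quiet) message("analyzing ", basename(path))
    res <- analyze_image(path, R = R, T = T, t_fraction = t_fraction, B = B,
                         k = k, k_max = k_max, shift = shift,
                         shift_center = shift_center, channel = channel)
    write_orientation_png(res$field, file.path(out_dir, paste0(stem, "_orientation.png")))
    write_orientation_csv(res$field, file.path(out_dir, paste0(stem, "_orientation.csv")))
    write_pdf_csv(res$pdf, file.path(out_dir, paste0(stem, "_pdf.csv")),
                  meta = res$params)
    write_model_json(res$model, file.path(out_dir, paste0(stem, "_model.json")))
    write_metrics_csv(res$metrics, file.path(out_dir, paste0(stem, "_metrics.csv")))
    results[[ii]] <- res
  }
  if (series) {
    panel <- healing_panel(lapply(results, `[[`, "model"),
                           time_points = tools::file_path_sans_ext(basename(inputs)))
    utils::write.csv(panel, file.path(out_dir, "series_panel.csv"),
                     row.names = FALSE)
  }
  log <- c(
    sprintf("fiborient %s", as.character(utils::packageVersion("fiborient"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("inputs: %s", paste(inputs, collapse = ", ")),
    sprintf("R = %d, T = %s, t_fraction = %s, B = %d, k = %s, k_max = %d, shift_center = %g, series = %s",
            as.integer(R),
            if (is.null(T)) "auto" else format(T),
            if (is.null(t_fraction)) if (is.null(T)) "0.1" else "-" else format(t_fraction),
            as.integer(B), if (is.null(k)) "auto" else k, as.integer(k_max),
            shift_center, series)
  )
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(results)
}

#' Generate phantom images from a JSON spec file
#'
#' The spec file holds one phantom spec object or an array of them, each
#' with the fields of [phantom_spec()] (`size`, `families`, `noise`,
#' `noise_mean`, `noise_sd`, `background`, `seed`, optional `name`). Each
#' phantom is written as a 16-bit TIFF with a ground-truth JSON sidecar;
#' identical specs always reproduce identical images.
#'
#' @param spec_file Path to the JSON spec.
#' @param out_dir Output directory, created if missing.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the vector of written TIFF paths.
#' @export
cmd_simulate <- function(spec_file, out_dir, quiet = FALSE) {
  if (!file.exists(spec_file)) {
    stop("spec file not found: ", spec_file, call. = FALSE)
  }
  raw <- jsonlite::read_json(spec_file, simplifyVector = FALSE)
  if (!is.null(raw$families)) raw <- list(raw)  # single spec object
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(raw))
  for (ii in seq_along(raw)) {
    s <- raw[[ii]]
    spec <- phantom_spec(
      size = unlist(s$size %||% c(256L, 256L)),
      families = s$families,
      noise = s$noise %||% "none",
      noise_mean = s$noise_mean %||% 0,
      noise_sd = s$noise_sd %||% 0,
      background = s$background %||% 0,
      seed = s$seed %||% 1L
    )
    name <- s$name %||% sprintf("phantom_%02d", ii)
    img <- make_fiber_image(spec)
    paths[ii] <- file.path(out_dir, paste0(name, ".tif"))
    write_phantom(img, paths[ii])
    if (!quiet) message("wrote ", paths[ii])
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
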
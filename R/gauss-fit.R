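#' Evaluate the k-Gaussian-plus-pedestal density model
#'
#' The orientation density model is a sum of k Gaussian components over a
#' constant pedestal:
#' \deqn{PDF(\theta) = \sum_k a_k \exp\!\left(-\frac{(\theta-b_k)^2}{2 c_k^2}\right) + d}
#' where `a_k` is the component height above the pedestal (per-degree density
#' units), `b_k` its center angle (the dominant fiber-gradient orientation,
#' degrees), `c_k` its width (degrees), and `d` the pedestal (per-degree
#' density), which captures image fractions with no defined structure.
#'
#' @param model A `gauss_pedestal_fit`, or any list with numeric fields
#'   `a`, `b`, `c` (equal lengths) and scalar `d`.
#' @param theta Numeric vector of angles in degrees.
#' @return Model density at each `theta`.
#' @export
evaluate_model <- function(model, theta) {
  stopifnot(is.numeric(theta))
  a <- model$a; b <- model$b; cc <- model$c; d <- model$d
  stopifnot(length(a) == length(b), length(b) == length(cc),
            length(d) == 1L, all(cc > 0))
  out <- rep(d, length(theta))
  for (k in seq_along(a)) {
    out <- out + a[k] * exp(-(theta - b[k])^2 / (2 * cc[k]^2))
  }
  out
}

#' Coefficient of determination of a fit
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the mean
#' of the observed values. Equals the squared Pearson correlation between
#' observed and fitted values for a least-squares fit with an intercept-like
#' term (here the pedestal); can be negative for a fit worse than the mean.
#'
#' @param observed,fitted Numeric vectors of equal length (at least 2).
#' @return R-squared value in (-Inf, 1].
#' @export
r_squared <- function(observed, fitted) {
  stopifnot(is.numeric(observed), is.numeric(fitted),
            length(observed) == length(fitted), length(observed) >= 2L)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("R-squared undefined: observed values are constant", call. = FALSE)
  }
  1 - sum((observed - fitted)^2) / ss_tot
}

# Initial parameter guesses from the k highest local maxima of a circular
# 3-bin moving average of the density. Width guess from the half-maximum
# crossing around each peak.
init_from_peaks <- function(pdf, k) {
  y <- pdf$density
  n <- length(y)
  sm <- (y + y[c(n, seq_len(n - 1L))] + y[c(seq_len(n - 1L) + 1L, 1L)]) / 3
  left <- sm[c(n, seq_len(n - 1L))]
  right <- sm[c(seq_len(n - 1L) + 1L, 1L)]
  is_peak <- sm >= left & sm >= right
  peaks <- which(is_peak)[order(sm[is_peak], decreasing = TRUE)]
  # drop adjacent duplicates of an already-chosen peak (plateaus)
  sel <- integer(0)
  for (p in peaks) {
    if (!any(pmin(abs(p - sel), n - abs(p - sel)) <= 1L)) sel <- c(sel, p)
    if (length(sel) == k) break
  }
  if (length(sel) < k) {
    extra <- setdiff(order(sm, decreasing = TRUE), sel)
    sel <- c(sel, extra[seq_len(k - length(sel))])
  }
  d0 <- max(min(y), 0)
  B <- pdf$bin_width
  a0 <- pmax(sm[sel] - d0, max(sm) * 0.05)
  c0 <- vapply(sel, function(p) {
    half <- d0 + (sm[p] - d0) / 2
    r <- 0L
    while (r < n %/% 2 && sm[((p - 1L + r) %% n) + 1L] > half &&
           sm[((p - 1L - r) %% n) + 1L] > half) r <- r + 1L
    max(r * B / 1.177, B)  # half width at half maximum -> sigma
  }, numeric(1))
  list(a = a0, b = pdf$bin_centers[sel], c = c0, d = d0)
}

#' Fit the orientation PDF to k Gaussians over a pedestal
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, [minpack.lm::nls.lm])
#' of the model in [evaluate_model()] against the (bin center, density) pairs
#' of an orientation PDF. The fit is performed on a shifted axis and fitted
#' center angles are mapped back to the original (0, 180] frame afterwards.
#' The default framing rule (`shift = "gap"`) rotates the least-populated
#' bin to the domain seam, which keeps every peak interior; `shift = "peak"`
#' is the classic rule that centers the maximum bin at `shift_center`
#' (identical behavior for unimodal PDFs, but it can park a secondary peak
#' on the seam when peaks are about 90 degrees apart); `shift = "none"`
#' fits the PDF as given.
#'
#' Bounds: `a_k >= 0`, `b_k` in `[-90, 270]` (peaks may sit near the shifted
#' axis edges), `c_k` in `[B/2, 180]`, `d >= 0`. Initialization takes the k
#' highest local maxima of a 3-bin circular moving average of the density;
#' up to four additional deterministic restarts perturb the initial widths
#' and centers, and the best converged solution (smallest residual norm) is
#' kept. 95% confidence half-widths are computed by linearization (Jacobian
#' covariance with a t quantile at n - p degrees of freedom).
#'
#' @param pdf An `orientation_pdf`.
#' @param k Number of Gaussian components (integer >= 1). The PDF must have
#'   at least `3k + 2` bins.
#' @param shift Framing rule before fitting: `"gap"` (default), `"peak"`,
#'   or `"none"` (see Details).
#' @param shift_center Angle the maximum bin is rotated to when
#'   `shift = "peak"`.
#' @return A `gauss_pedestal_fit` with fields `k`, `a`, `b`, `c`, `d`
#'   (components sorted by center angle; `b` in the original (0, 180] frame),
#'   `r_squared`, `ci95` (list of half-widths for `a`, `b`, `c`, `d`),
#'   `shift_applied` (degrees), `fitted` (model values at the shifted-axis
#'   bin centers), `diagnostics` (iterations, residual norm, restarts,
#'   message).
#' @export
fit_gaussians <- function(pdf, k = 1L, shift = c("gap", "peak", "none"),
                          shift_center = 90) {
  stopifnot(inherits(pdf, "orientation_pdf"))
  shift <- match.arg(shift)
  k <- as.integer(k)
  stopifnot(length(k) == 1L, k >= 1L)
  nbins <- length(pdf$density)
  if (nbins < 3L * k + 2L) {
    stop(sprintf("k = %d needs at least %d bins; PDF has %d", k, 3 * k + 2,
                 nbins), call. = FALSE)
  }
  work <- switch(shift,
    gap = shift_pdf_gap(pdf),
    peak = shift_pdf(pdf, center = shift_center),
    none = pdf
  )
  x <- work$bin_centers
  y <- work$density
  B <- work$bin_width

  lower <- c(rep(0, k), rep(-90, k), rep(B / 2, k), 0)
  upper <- c(rep(Inf, k), rep(270, k), rep(180, k), Inf)
  resid_fn <- function(p) {
    m <- list(a = p[seq_len(k)], b = p[k + seq_len(k)],
              c = p[2L * k + seq_len(k)], d = p[3L * k + 1L])
    evaluate_model(m, x) - y
  }

  init <- init_from_peaks(work, k)
  # deterministic multi-start: perturb widths and centers around the
  # peak-based initialization
  perturb <- list(
    c(cs = 1.0, bs = 0),
    c(cs = 0.5, bs = 0),
    c(cs = 2.0, bs = 0),
    c(cs = 1.0, bs = B),
    c(cs = 1.5, bs = -B)
  )
  best <- NULL
  tried <- 0L
  for (pt in perturb) {
    p0 <- c(init$a,
            pmin(pmax(init$b + pt[["bs"]], -90), 270),
            pmin(pmax(init$c * pt[["cs"]], B / 2), 180),
            init$d)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) NULL
    )
    tried <- tried + 1L
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (best$deviance <= 1e-24) break
  }
  if (is.null(best)) {
    stop(sprintf("fit failed to converge for k = %d after %d restarts",
                 k, tried), call. = FALSE)
  }

  p <- best$par
  a <- p[seq_len(k)]; b <- p[k + seq_len(k)]
  cw <- p[2L * k + seq_len(k)]; d <- p[3L * k + 1L]
  fitted_y <- evaluate_model(list(a = a, b = b, c = cw, d = d), x)
  r2 <- r_squared(y, fitted_y)
  ci <- ci95_linearized(resid_fn, p, n = nbins)

  # map centers back through the total recorded shift to the original frame
  b_orig <- fold_angle(b - work$shift)
  ord <- order(b_orig)
  structure(
    list(
      k = k,
      a = a[ord], b = b_orig[ord], c = cw[ord], d = d,
      r_squared = r2,
      ci95 = list(a = ci[seq_len(k)][ord], b = ci[k + seq_len(k)][ord],
                  c = ci[2L * k + seq_len(k)][ord], d = ci[3L * k + 1L]),
      shift_applied = work$shift,
      bin_width = B,
      fitted = fitted_y,
      observed = y,
      bin_centers = x,
      diagnostics = list(
        iterations = best$niter,
        residual_norm = sqrt(best$deviance),
        restarts = tried,
        message = best$message
      )
    ),
    class = "gauss_pedestal_fit"
  )
}

# Linearized 95% confidence half-widths: sigma^2 * (J'J)^-1 with a numeric
# forward-difference Jacobian of the residual function at the solution.
# Parameters lying in a (near-)null direction of J'J -- e.g. the center and
# width of a component whose height collapsed to zero -- are unidentifiable
# and get an infinite half-width.
ci95_linearized <- function(resid_fn, p, n) {
  np <- length(p)
  dof <- n - np
  if (dof < 1L) return(rep(NA_real_, np))
  r0 <- resid_fn(p)
  J <- matrix(0, length(r0), np)
  for (i in seq_len(np)) {
    h <- max(abs(p[i]), 1e-4) * 1e-6
    pp <- p; pp[i] <- pp[i] + h
    J[, i] <- (resid_fn(pp) - r0) / h
  }
  sigma2 <- sum(r0^2) / dof
  ev <- eigen(crossprod(J), symmetric = TRUE)
  pos <- ev$values > max(ev$values, 0) * 1e-10
  if (!any(pos)) return(rep(Inf, np))
  V <- ev$vectors
  variances <- sigma2 * colSums(t(V[, pos, drop = FALSE]^2) / ev$values[pos])
  if (any(!pos)) {
    null_weight <- rowSums(V[, !pos, drop = FALSE]^2)
    variances[null_weight > 1e-8] <- Inf
  }
  stats::qt(0.975, dof) * sqrt(pmax(variances, 0))
}

#' @export
print.gauss_pedestal_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<gauss_pedestal_fit> k = %d, R^2 = %.4f\n", x$k, x$r_squared))
  tab <- data.frame(
    a = signif(x$a, digits), b = signif(x$b, digits),
    c = signif(x$c, digits)
  )
  print(tab, row.names = paste0("  comp", seq_len(x$k)))
  cat(sprintf("  pedestal d = %s, shift applied = %g deg\n",
              signif(x$d, digits), x$shift_applied))
  invisible(x)
}

#' Select the model order k by the maximum-R-squared rule
#'
#' Fits k = 1, ..., `k_max` components and returns the smallest k whose
#' R-squared is within `epsilon` of the maximum attained — extra components
#' that do not improve the fit are rejected. A fit where the dominant
#' component height is not distinguishable from zero (a < 2 x its 95%
#' confidence half-width) is flagged `no_dominant_orientation` (pedestal-only
#' density, e.g. an unstructured image).
#'
#' @param pdf An `orientation_pdf`.
#' @param k_max Maximum number of components to try (default 3).
#' @param epsilon R-squared tolerance for preferring a smaller k
#'   (default 0.02).
#' @param ... Passed to [fit_gaussians()].
#' @return The selected `gauss_pedestal_fit`, with extra fields
#'   `r2_by_k` (named vector over the orders tried) and
#'   `no_dominant_orientation` (logical).
#' @export
select_k <- function(pdf, k_max = 3L, epsilon = 0.02, ...) {
  stopifnot(inherits(pdf, "orientation_pdf"))
  k_max <- as.integer(k_max)
  stopifnot(k_max >= 1L, epsilon >= 0)
  fits <- vector("list", k_max)
  r2 <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    fits[[k]] <- tryCatch(fit_gaussians(pdf, k = k, ...),
                          error = function(e) NULL)
    if (!is.null(fits[[k]])) r2[k] <- fits[[k]]$r_squared
  }
  if (all(is.na(r2))) {
    stop("all fits failed for k = 1..", k_max, call. = FALSE)
  }
  best_r2 <- max(r2, na.rm = TRUE)
  k_sel <- which(!is.na(r2) & r2 >= best_r2 - epsilon)[1L]
  model <- fits[[k_sel]]
  model$r2_by_k <- stats::setNames(r2, paste0("k", seq_len(k_max)))
  dom <- which.max(model$a)
  ci_a <- model$ci95$a[dom]
  # height indistinguishable from zero (or unidentifiable): pedestal-only
  model$no_dominant_orientation <- is.na(ci_a) || model$a[dom] < 2 * ci_a
  model
}

#' Export a fitted model as JSON
#'
#' Writes k, parameters, R-squared, confidence half-widths, the applied
#' shift, and fit diagnostics with full numeric precision.
#'
#' @param model A `gauss_pedestal_fit`.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "gauss_pedestal_fit"))
  out <- list(
    k = model$k, a = model$a, b = model$b, c = model$c, d = model$d,
    r_squared = model$r_squared, ci95 = model$ci95,
    shift_applied = model$shift_applied,
    diagnostics = model$diagnostics
  )
  if (!is.null(model$r2_by_k)) out$r2_by_k <- as.list(model$r2_by_k)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
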
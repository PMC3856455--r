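#' LOESS spatial correction
#'
#' Fits a locally weighted polynomial regression (degree-1 LOESS, tricube
#' weights, robust `"symmetric"` family so sparse true CNV probes do not
#' drag the surface) of the log2 ratio on the array grid coordinates
#' `(grid_x, grid_y)` and subtracts the fitted surface, recentred to mean
#' zero so the global ratio level is preserved. The correction is applied
#' to the test-channel log intensity and the ratio recomputed, so both
#' channels stay consistent for later QC.
#'
#' @param scan an `array_scan`.
#' @param layout the matching probe layout (source of grid coordinates).
#' @param span LOESS span in `(0, 1]`; fraction of probes in each local
#'   fit. Default 0.3.
#' @return corrected `array_scan`, stage `"spatial"`; the attribute
#'   `norm_report` gains `spatial_rms` (RMS of the removed surface).
#' @export
spatial_correct <- function(scan, layout, span = 0.3) {
  .check_scan_layout(scan, layout)
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  n <- nrow(scan)
  if (n * span < 10)
    stop("too few probes (", n, ") for local fitting at span ", span,
         "; increase span")
  df <- data.frame(r = scan$log2ratio,
                   gx = as.numeric(layout$grid_x),
                   gy = as.numeric(layout$grid_y))
  if (stats::var(df$r) < 1e-20) {
    surf <- numeric(n)                 # constant input: nothing to remove
  } else {
    # robust (symmetric) family so sparse true CNV probes do not drag the
    # surface; its M-step divides by the residual MAD, which is 0 when the
    # surface explains the data exactly -- fall back to least squares then
    fit <- tryCatch(
      stats::loess(r ~ gx + gy, data = df, degree = 1, span = span,
                   family = "symmetric",
                   control = stats::loess.control(surface = "interpolate")),
      error = function(e)
        stats::loess(r ~ gx + gy, data = df, degree = 1, span = span,
                     control = stats::loess.control(surface = "interpolate")))
    surf <- stats::fitted(fit)
    surf <- surf - mean(surf)
  }
  out <- scan
  out$test <- 2^(log2(scan$test) - surf)
  out$log2ratio <- scan$log2ratio - surf
  attr(out, "stage") <- "spatial"
  rep0 <- attr(scan, "norm_report")
  attr(out, "norm_report") <- c(rep0, list(spatial_rms = sqrt(mean(surf^2))))
  out
}

#' Quantile-spline (q-spline) dye-bias normalization
#'
#' Two-channel dye normalization by quantile matching: a monotone cubic
#' spline (Hyman-filtered) is interpolated through `n_quantile_knots`
#' matched quantiles of the log2 test and reference intensities and
#' applied to the reference channel, putting both channels on a common
#' intensity scale; log2 ratios are recomputed from the adjusted
#' channels. The mapping is monotone non-decreasing, so within-channel
#' intensity ranks are preserved.
#'
#' @param scan an `array_scan` with positive intensities.
#' @param n_quantile_knots number of evenly spaced quantile knots
#'   (>= 3). Default 100.
#' @return normalized `array_scan`, stage `"normalized"`; `norm_report`
#'   gains `max_quantile_shift` (largest knot adjustment, log2 units).
#' @export
qspline_normalize <- function(scan, n_quantile_knots = 100) {
  stopifnot(inherits(scan, "data.frame"))
  if (n_quantile_knots < 3) stop("n_quantile_knots must be >= 3")
  bad <- which(!(scan$test > 0) | !(scan$ref > 0))
  if (length(bad))
    stop("non-positive intensity at probe ", scan$probe_id[bad[1]])
  tl <- log2(scan$test)
  rl <- log2(scan$ref)
  p <- seq(0, 1, length.out = n_quantile_knots)
  qt <- stats::quantile(tl, p, names = FALSE)
  qr <- stats::quantile(rl, p, names = FALSE)
  keep <- !duplicated(qr)
  qr <- qr[keep]; qt <- qt[keep]
  if (length(qr) < 2) {           # degenerate: constant reference channel
    rl2 <- rl + (mean(tl) - mean(rl))
    shift <- abs(mean(tl) - mean(rl))
  } else {
    f <- stats::splinefun(qr, qt, method = "hyman")
    rl2 <- f(rl)
    shift <- max(abs(qt - qr))
  }
  out <- scan
  out$ref <- 2^rl2
  out$log2ratio <- tl - rl2
  attr(out, "stage") <- "normalized"
  rep0 <- attr(scan, "norm_report")
  attr(out, "norm_report") <- c(rep0, list(max_quantile_shift = shift))
  out
}

#' Retrieve the normalization report of a scan
#'
#' @param scan an `array_scan` that has passed through
#'   [spatial_correct()] and/or [qspline_normalize()].
#' @return named list of non-negative correction magnitudes
#'   (`spatial_rms`, `max_quantile_shift`), or an empty list.
#' @export
norm_report <- function(scan) {
  r <- attr(scan, "norm_report")
  if (is.null(r)) list() else r
}

# internal: scan and layout must describe the same probes in order
.check_scan_layout <- function(scan, layout) {
  .need_cols(scan, c("probe_id", "test", "ref", "log2ratio"), "scan")
  .need_cols(layout, c("probe_id", "chrom", "start"), "layout")
  if (nrow(scan) != nrow(layout) ||
      !identical(scan$probe_id, layout$probe_id))
    stop("scan and layout describe different probe sets")
  invisible(TRUE)
}
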
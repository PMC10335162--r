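#' Least-squares circle fit (Kasa + Gauss-Newton refinement)
#'
#' Fits a circle to boundary points by the algebraic Kasa least-squares
#' solution, then applies one Gauss-Newton step on the geometric (radial)
#' residuals. The algebraic fit is exact on noise-free circle samples; the
#' geometric step removes the algebraic fit's small-arc bias, which matters
#' when eyelids occlude the upper and lower limbus and only lateral arcs
#' remain.
#'
#' @param points Numeric n x 2 matrix (or data.frame) of boundary points,
#'   n >= 3, not all collinear.
#' @return A list of class `circle_fit` with `center` (x, y), `radius_px`,
#'   `diameter_px`, `rms_residual_px`, and `n_points`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 17)[-17]
#' fit_circle(cbind(100 + 50 * cos(th), 100 + 50 * sin(th)))
#' @export
fit_circle <- function(points) {
  m <- as.matrix(points)
  if (ncol(m) != 2 || nrow(m) < 3)
    fm_geometry_error("circle fit needs >= 3 points with columns (x, y)")
  storage.mode(m) <- "double"
  x <- m[, 1]; y <- m[, 2]
  # Kasa: minimise sum((x^2 + y^2 - 2ax - 2by - c)^2), linear in (a, b, c)
  A <- cbind(2 * x, 2 * y, 1)
  z <- x^2 + y^2
  qr_A <- qr(A)
  if (qr_A$rank < 3)
    fm_geometry_error("degenerate geometry: points are collinear")
  sol <- qr.coef(qr_A, z)
  a <- sol[1]; b <- sol[2]
  r2 <- sol[3] + a^2 + b^2
  if (!is.finite(r2) || r2 <= 0)
    fm_geometry_error("degenerate geometry: no circle through points")
  r <- sqrt(r2)
  # One Gauss-Newton step on residuals d_i = |p_i - c| - r
  di <- sqrt((x - a)^2 + (y - b)^2)
  if (all(di > 0)) {
    J <- cbind(-(x - a) / di, -(y - b) / di, rep(-1, length(di)))
    res <- di - r
    step <- tryCatch(qr.coef(qr(J), -res), error = function(e) NULL)
    if (!is.null(step) && all(is.finite(step))) {
      a <- a + step[1]; b <- b + step[2]; r <- r + step[3]
    }
  }
  di <- sqrt((x - a)^2 + (y - b)^2)
  structure(list(center = c(x = unname(a), y = unname(b)),
                 radius_px = unname(r),
                 diameter_px = unname(2 * r),
                 rms_residual_px = sqrt(mean((di - r)^2)),
                 n_points = nrow(m)),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit> center (%.2f, %.2f), diameter %.2f px, rms %.3g px (n=%d)\n",
              x$center[1], x$center[2], x$diameter_px, x$rms_residual_px,
              x$n_points))
  invisible(x)
}

#' Mean white-to-white diameter across the two eyes
#'
#' The subject-level white-to-white (WTW) corneal diameter is the
#' arithmetic mean of the left- and right-eye fitted diameters.
#'
#' @param left,right Either `circle_fit` objects or positive pixel
#'   diameters.
#' @return Mean diameter in pixels.
#' @export
wtw_mean <- function(left, right) {
  d <- vapply(list(left, right), function(e) {
    if (inherits(e, "circle_fit")) e$diameter_px else as.numeric(e)
  }, numeric(1))
  if (any(!is.finite(d)) || any(d <= 0))
    fm_param_error("WTW diameters must be positive")
  mean(d)
}

#' Pixel-to-millimetre calibration from the corneal diameter
#'
#' Every in-image pixel distance is divided by the subject's mean WTW
#' diameter in pixels and multiplied by the published population WTW
#' diameter in millimetres (default 11.71 mm, the Caucasian average), so
#' `mm_per_px = wtw_reference_mm / wtw_px_mean`.
#'
#' @param wtw_px_mean Subject mean WTW diameter in pixels (> 0).
#' @param wtw_reference_mm Reference corneal diameter in millimetres.
#' @param wtw_px_left,wtw_px_right Optional per-eye diameters, recorded for
#'   audit output.
#' @return A list of class `calibration` with `mm_per_px`,
#'   `wtw_px_mean`, `wtw_reference_mm` and the per-eye diameters (NA when
#'   not supplied).
#' @examples
#' cal <- make_calibration(100)        # 100 px <-> 11.71 mm
#' calibrate_px(cal, 100)              # 11.71
#' @export
make_calibration <- function(wtw_px_mean, wtw_reference_mm = 11.71,
                             wtw_px_left = NA_real_, wtw_px_right = NA_real_) {
  if (!is.finite(wtw_px_mean) || wtw_px_mean <= 0)
    fm_param_error("wtw_px_mean must be a positive number")
  if (!is.finite(wtw_reference_mm) || wtw_reference_mm <= 0)
    fm_param_error("wtw_reference_mm must be a positive number")
  structure(list(wtw_px_left = wtw_px_left,
                 wtw_px_right = wtw_px_right,
                 wtw_px_mean = wtw_px_mean,
                 wtw_reference_mm = wtw_reference_mm,
                 mm_per_px = wtw_reference_mm / wtw_px_mean),
            class = "calibration")
}

#' @rdname make_calibration
#' @param calib A `calibration`.
#' @param px Pixel distance(s).
#' @return `calibrate_px`: millimetre distance(s).
#' @export
calibrate_px <- function(calib, px) {
  stopifnot(inherits(calib, "calibration"))
  px * calib$mm_per_px
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> WTW %.2f px == %.2f mm (%.4f mm/px)\n",
              x$wtw_px_mean, x$wtw_reference_mm, x$mm_per_px))
  invisible(x)
}
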
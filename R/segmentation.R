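#' Segmentation settings for the iris active contour
#'
#' @param iterations Maximum number of region-update sweeps (default 200;
#'   the piecewise-constant update usually converges in well under 20).
#' @param smoothing Number of 3 x 3 mean-filter smoothing passes applied to
#'   the region indicator each sweep (curvature-penalty analogue; default 1).
#' @param trim_vertical Drop boundary points in the top/bottom 25% of the
#'   contour's vertical extent before circle fitting. WTW is a horizontal
#'   diameter and the upper/lower limbus is routinely occluded by eyelids,
#'   so lateral arcs carry the signal.
#' @param min_area_px Minimum foreground area (default 8 px) below which
#'   segmentation is declared failed.
#' @return A list of settings for [segment_iris()].
#' @export
seg_config <- function(iterations = 200L, smoothing = 1L,
                       trim_vertical = TRUE, min_area_px = 8L) {
  if (iterations < 1) fm_param_error("iterations must be >= 1")
  if (smoothing < 0) fm_param_error("smoothing must be >= 0")
  list(iterations = as.integer(iterations), smoothing = as.integer(smoothing),
       trim_vertical = isTRUE(trim_vertical),
       min_area_px = as.integer(min_area_px))
}

# 3x3 box mean filter with replicated borders (vectorised shifts).
box_mean3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up    <- m[c(1, seq_len(h - 1)), , drop = FALSE]
  down  <- m[c(seq_len(h - 1) + 1, h), , drop = FALSE]
  acc <- m + up + down
  left  <- acc[, c(1, seq_len(w - 1)), drop = FALSE]
  right <- acc[, c(seq_len(w - 1) + 1, w), drop = FALSE]
  (acc + left + right) / 9
}

# Connected component of `mask` containing (row0, col0), by iterative
# geodesic dilation (4-connectivity).
flood_component <- function(mask, row0, col0) {
  h <- nrow(mask); w <- ncol(mask)
  comp <- matrix(FALSE, h, w)
  if (row0 < 1 || row0 > h || col0 < 1 || col0 > w || !mask[row0, col0])
    return(comp)
  comp[row0, col0] <- TRUE
  repeat {
    up    <- comp[c(1, seq_len(h - 1)), , drop = FALSE]
    down  <- comp[c(seq_len(h - 1) + 1, h), , drop = FALSE]
    left  <- comp[, c(1, seq_len(w - 1)), drop = FALSE]
    right <- comp[, c(seq_len(w - 1) + 1, w), drop = FALSE]
    grown <- mask & (comp | up | down | left | right)
    if (identical(grown, comp)) break
    comp <- grown
  }
  comp
}

# Boundary pixels of a mask (foreground with a 4-neighbour background or
# frame edge), returned as (x, y) ordered by polar angle about the centroid.
mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  up    <- rbind(FALSE, mask[seq_len(h - 1), , drop = FALSE])
  down  <- rbind(mask[-1, , drop = FALSE], FALSE)
  left  <- cbind(FALSE, mask[, seq_len(w - 1), drop = FALSE])
  right <- cbind(mask[, -1, drop = FALSE], FALSE)
  bnd <- mask & !(up & down & left & right)
  idx <- which(bnd, arr.ind = TRUE)
  pts <- cbind(x = idx[, "col"], y = idx[, "row"])
  cx <- mean(pts[, 1]); cy <- mean(pts[, 2])
  pts[order(atan2(pts[, 2] - cy, pts[, 1] - cx)), , drop = FALSE]
}

#' Segment the iris with a region-based active contour
#'
#' Implements a two-phase piecewise-constant (Chan-Vese-type) region
#' evolution seeded from the canthal points: the contour is initialised as
#' a circle at the canthal midpoint with radius one quarter of the
#' inter-canthal distance, then evolved by alternating (i) the optimal
#' piecewise-constant region update -- assign each pixel to the phase whose
#' mean intensity is closer -- with (ii) indicator smoothing passes that
#' play the role of the curvature penalty. The pigmented iris is the dark
#' phase; the component connected to the canthal midpoint is kept.
#'
#' @param img Numeric matrix, grayscale intensities (rows = y, cols = x).
#' @param endocanthion,exocanthion Pilot points `c(x, y)` in image
#'   coordinates; both must lie inside the image.
#' @param cfg Settings from [seg_config()].
#' @return Object of class `boundary_points`: list with `points` (n x 2
#'   matrix of ordered boundary pixels), `area_px`, and `iterations_used`.
#' @seealso [fit_circle()] to obtain the WTW diameter from the boundary.
#' @export
segment_iris <- function(img, endocanthion, exocanthion, cfg = seg_config()) {
  img <- as.matrix(img)
  h <- nrow(img); w <- ncol(img)
  inside <- function(p) p[1] >= 1 && p[1] <= w && p[2] >= 1 && p[2] <= h
  if (!inside(endocanthion) || !inside(exocanthion))
    fm_param_error("canthus pilot points must lie inside the image")
  mid <- (endocanthion + exocanthion) / 2
  icd <- sqrt(sum((endocanthion - exocanthion)^2))
  if (icd == 0) fm_param_error("canthus points coincide")
  r0 <- 0.25 * icd

  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  phi <- (xs - mid[1])^2 + (ys - mid[2])^2 <= r0^2
  if (!any(phi)) fm_segmentation_failure("initial contour contains no pixels")

  used <- 0L
  for (it in seq_len(cfg$iterations)) {
    used <- it
    if (!any(phi) || all(phi))
      fm_segmentation_failure("contour collapsed during evolution")
    c1 <- mean(img[phi]); c2 <- mean(img[!phi])
    if (abs(c1 - c2) < 1e-9)
      fm_segmentation_failure("no foreground/background contrast")
    # dark iris: inside phase is the darker one
    if (c1 > c2) { tmp <- c1; c1 <- c2; c2 <- tmp }
    score <- (img - c2)^2 - (img - c1)^2
    newphi <- score > 0
    if (cfg$smoothing > 0) {
      sm <- newphi + 0
      for (k in seq_len(cfg$smoothing)) sm <- box_mean3(sm)
      newphi <- sm > 0.5
    }
    if (identical(newphi, phi)) { phi <- newphi; break }
    phi <- newphi
  }
  seed <- c(round(mid[2]), round(mid[1]))
  comp <- flood_component(phi, seed[1], seed[2])
  if (!any(comp)) {
    # seed fell on background (e.g. strong noise speck); keep the largest
    # dark component instead
    comp <- largest_component(phi)
  }
  area <- sum(comp)
  if (area < cfg$min_area_px)
    fm_segmentation_failure(sprintf(
      "segmented area %d px below minimum %d px", area, cfg$min_area_px))
  pts <- mask_boundary(comp)
  if (nrow(pts) < 8)
    fm_segmentation_failure("fewer than 8 boundary points")
  structure(list(points = pts, area_px = area, iterations_used = used),
            class = "boundary_points")
}

largest_component <- function(mask) {
  best <- matrix(FALSE, nrow(mask), ncol(mask))
  left <- mask
  while (any(left)) {
    ij <- which(left, arr.ind = TRUE)[1, ]
    comp <- flood_component(left, ij[1], ij[2])
    if (sum(comp) > sum(best)) best <- comp
    left <- left & !comp
  }
  best
}

#' @export
print.boundary_points <- function(x, ...) {
  cat(sprintf("<boundary_points> %d points, area %d px (converged in %d sweeps)\n",
              nrow(x$points), x$area_px, x$iterations_used))
  invisible(x)
}

#' White-to-white diameter of one eye crop
#'
#' Convenience wrapper: [segment_iris()] then [fit_circle()], optionally
#' trimming eyelid-occluded (top/bottom) boundary points per
#' `cfg$trim_vertical`.
#'
#' @inheritParams segment_iris
#' @return A `circle_fit`.
#' @export
wtw_from_image <- function(img, endocanthion, exocanthion, cfg = seg_config()) {
  bnd <- segment_iris(img, endocanthion, exocanthion, cfg)
  pts <- bnd$points
  if (cfg$trim_vertical) {
    ylo <- min(pts[, 2]); yhi <- max(pts[, 2])
    ext <- yhi - ylo
    keep <- pts[, 2] > ylo + 0.25 * ext & pts[, 2] < yhi - 0.25 * ext
    if (sum(keep) >= 8) pts <- pts[keep, , drop = FALSE]
  }
  fit <- fit_circle(pts)
  # boundary pixel centres lie half a pixel inside the region edge;
  # correct the rasterisation offset (one pixel on the diameter)
  fit$radius_px <- fit$radius_px + 0.5
  fit$diameter_px <- fit$diameter_px + 1
  fit
}
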
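# Internal geometry / RNG helpers shared across modules.

# Rotate points (n x 2 matrix, image frame: y down) clockwise in the
# viewer's frame by `deg` about `center`. Clockwise here means the chin of
# an upright face moves toward the viewer's right, matching the sign
# convention of facial_rotation().
rotate_points <- function(pts, deg, center = c(0, 0)) {
  th <- deg * pi / 180
  ct <- cos(th); st <- sin(th)
  x <- pts[, 1] - center[1]
  y <- pts[, 2] - center[2]
  cbind(x * ct + y * st + center[1],
        -x * st + y * ct + center[2])
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# Unsigned angle (degrees, in [0, 180]) between two 2-D vectors.
vec_angle_deg <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    fm_geometry_error("angle undefined for zero-length vector")
  cosa <- sum(u * v) / (nu * nv)
  rad2deg(acos(max(-1, min(1, cosa))))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
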
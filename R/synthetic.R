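#' Generating specification for a synthetic cohort
#'
#' Describes the marginal distributions (mean, SD) of the facial
#' measurements a synthetic cohort is drawn from, plus the imaging nuisance
#' parameters: pixel scale (px/mm), in-plane head rotation, and the
#' white-to-white (WTW) corneal diameter used both to place the iris
#' landmarks and to calibrate. Defaults are the published norms for
#' attractive Caucasian female faces; [dimorphism_norms()] returns the
#' female and male presets.
#'
#' All length parameters are centimetres, angles degrees. Each `m*` / `s*`
#' pair is a Gaussian mean/SD; proportions are sampled jointly (see
#' [sample_cohort()]).
#'
#' @param group Group label (e.g. `"F"` or `"M"`).
#' @param facial_height,bizygomatic,bigonial,nose_height,alar_width,interpupillary,canthal_tilt,medial_brow,lateral_brow,brow_angle_1,brow_angle_3
#'   Length-2 numeric `c(mean, sd)`.
#' @param horizontal_thirds,vertical_thirds Lists with `mean` (length 3,
#'   summing to 1 within 0.01) and `sd` (length 3) for the compositional
#'   proportion triplets. Horizontal order: upper, middle, lower; vertical
#'   order: left, middle, right (anatomical).
#' @param ratio_fh_bigonial `c(mean, sd)` of the facial-height/bigonial
#'   ratio; used only when `bigonial_mode = "ratio"`.
#' @param bigonial_mode `"direct"` samples bigonial width from its own
#'   marginal; `"ratio"` samples the FH/bigonial ratio and derives bigonial
#'   width from the sampled facial height (useful when the ratio itself is
#'   the quantity under study).
#' @param wtw_mm `c(mean, sd)` of the true corneal WTW diameter in mm.
#' @param scale_range Uniform range of pixel scale, px per mm.
#' @param rotation_range Uniform range of in-plane head rotation, degrees
#'   (positive = clockwise in the viewer's frame).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(group = "F",
                        facial_height = c(17.94, 1.14),
                        bizygomatic = c(13.05, 0.75),
                        bigonial = c(11.13, 0.70),
                        nose_height = c(3.82, 0.34),
                        alar_width = c(3.21, 0.37),
                        interpupillary = c(6.17, 0.38),
                        canthal_tilt = c(8.50, 2.10),
                        medial_brow = c(3.04, 0.27),
                        lateral_brow = c(1.62, 0.30),
                        brow_angle_1 = c(12.43, 8.68),
                        brow_angle_3 = c(32.45, 19.78),
                        horizontal_thirds = list(mean = c(0.324, 0.344, 0.332),
                                                 sd = c(0.023, 0.020, 0.017)),
                        vertical_thirds = list(mean = c(0.311, 0.374, 0.315),
                                               sd = c(0.012, 0.017, 0.010)),
                        ratio_fh_bigonial = c(1.613, 0.063),
                        bigonial_mode = c("direct", "ratio"),
                        wtw_mm = c(11.71, 0.42),
                        scale_range = c(5, 15),
                        rotation_range = c(-10, 10)) {
  bigonial_mode <- match.arg(bigonial_mode)
  spec <- list(group = group, facial_height = facial_height,
               bizygomatic = bizygomatic, bigonial = bigonial,
               nose_height = nose_height, alar_width = alar_width,
               interpupillary = interpupillary, canthal_tilt = canthal_tilt,
               medial_brow = medial_brow, lateral_brow = lateral_brow,
               brow_angle_1 = brow_angle_1, brow_angle_3 = brow_angle_3,
               horizontal_thirds = horizontal_thirds,
               vertical_thirds = vertical_thirds,
               ratio_fh_bigonial = ratio_fh_bigonial,
               bigonial_mode = bigonial_mode, wtw_mm = wtw_mm,
               scale_range = scale_range, rotation_range = rotation_range)
  gaussians <- c("facial_height", "bizygomatic", "bigonial", "nose_height",
                 "alar_width", "interpupillary", "canthal_tilt",
                 "medial_brow", "lateral_brow", "brow_angle_1",
                 "brow_angle_3", "ratio_fh_bigonial", "wtw_mm")
  for (nm in gaussians) {
    v <- spec[[nm]]
    if (length(v) != 2 || any(!is.finite(v)) || v[2] < 0)
      fm_param_error(paste0(nm, " must be c(mean, sd) with sd >= 0"))
  }
  for (nm in c("horizontal_thirds", "vertical_thirds")) {
    tr <- spec[[nm]]
    if (length(tr$mean) != 3 || length(tr$sd) != 3 || any(tr$sd < 0))
      fm_param_error(paste0(nm, " needs mean/sd triplets with sd >= 0"))
    if (abs(sum(tr$mean) - 1) > 0.01)
      fm_param_error(paste0(nm, " means must sum to 1 within 0.01"))
  }
  if (any(scale_range <= 0) || scale_range[2] < scale_range[1])
    fm_param_error("scale_range must be positive and increasing")
  if (rotation_range[2] < rotation_range[1])
    fm_param_error("rotation_range must be increasing")
  class(spec) <- "cohort_spec"
  spec
}

#' Published-norm cohort presets
#'
#' Per-group generating distributions matching the published celebrity
#' cohort summaries (n = 21 per group).
#'
#' @param group `"female"` or `"male"`.
#' @param bigonial_mode Passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
dimorphism_norms <- function(group = c("female", "male"),
                             bigonial_mode = "direct") {
  group <- match.arg(group)
  if (group == "female")
    cohort_spec(group = "F", bigonial_mode = bigonial_mode)
  else
    cohort_spec(group = "M",
                facial_height = c(19.29, 1.24),
                bizygomatic = c(13.90, 0.80),
                bigonial = c(12.34, 0.77),
                nose_height = c(4.17, 0.38),
                alar_width = c(3.60, 0.37),
                interpupillary = c(6.38, 0.33),
                canthal_tilt = c(6.51, 2.67),
                medial_brow = c(3.39, 0.43),
                lateral_brow = c(1.71, 0.29),
                brow_angle_1 = c(9.90, 5.42),
                brow_angle_3 = c(38.67, 10.08),
                horizontal_thirds = list(mean = c(0.308, 0.329, 0.363),
                                         sd = c(0.023, 0.017, 0.022)),
                vertical_thirds = list(mean = c(0.314, 0.371, 0.315),
                                       sd = c(0.013, 0.020, 0.013)),
                ratio_fh_bigonial = c(1.566, 0.085),
                bigonial_mode = bigonial_mode)
}

# Fixed vertical layout constants (cm) of the synthetic face. These are
# nuisance placements: they position landmarks that the battery only uses
# through distances whose truth is recorded analytically.
.layout <- list(nasion_drop = 0.6,   # glabella -> nasion
                eye_drop    = 1.1,   # glabella -> pupil line
                brow_rise   = 1.6,   # pupil line -> brow apex
                zygion_drop = 3.3,   # glabella -> zygion line
                gonion_frac = 0.86,  # gonion at this fraction of face height
                lid_overlap = 0.05)  # iris sits this far below the lid (cm)

rnorm_trunc <- function(mean, sd, lower = -Inf) {
  if (sd == 0) return(max(mean, lower))
  repeat {
    v <- stats::rnorm(1, mean, sd)
    if (v >= lower) return(v)
  }
}

runif_range <- function(range) {
  if (range[1] == range[2]) range[1] else stats::runif(1, range[1], range[2])
}

# Compositional triplet: independent truncated Gaussians renormalised to
# sum to 1 (means must already sum to ~1).
sample_composition <- function(mean, sd) {
  g <- vapply(1:3, function(i) rnorm_trunc(mean[i], sd[i], lower = 0.02),
              numeric(1))
  g / sum(g)
}

#' Full measurement-record column set
#'
#' Column names shared by [measure_subject()] records and generator truth
#' tables, in canonical order.
#'
#' @return Character vector.
#' @export
measurement_fields <- function() {
  c("facial_height_cm", "bizygomatic_width_cm", "bigonial_width_cm",
    "nose_height_cm", "alar_width_cm", "interpupillary_distance_cm",
    "palpebral_fissure_length_cm", "canthal_tilt_deg", "facial_rotation_deg",
    "upper_third_cm", "middle_third_cm", "lower_third_cm",
    "upper_third_prop", "middle_third_prop", "lower_third_prop",
    "left_vertical_third_prop", "middle_vertical_third_prop",
    "right_vertical_third_prop",
    "brow_angle_1_deg", "brow_angle_2_deg", "brow_angle_3_deg",
    "medial_brow_length_cm", "lateral_brow_length_cm", "total_brow_length_cm",
    "medial_canthus_to_medial_brow_cm", "lateral_canthus_to_lateral_brow_cm",
    "scleral_show_flag", "scleral_show_signed_mm",
    "ratio_fh_bigonial", "ratio_fh_bizygomatic", "ratio_bizygomatic_bigonial")
}

# Build one subject's landmark geometry in cm (midline x = 0, trichion at
# y = 0, y down) together with its analytic truth record.
build_subject_geometry <- function(spec) {
  L <- .layout
  FH  <- rnorm_trunc(spec$facial_height[1], spec$facial_height[2], 5)
  BZ  <- rnorm_trunc(spec$bizygomatic[1], spec$bizygomatic[2], 3)
  if (spec$bigonial_mode == "ratio") {
    ratio <- rnorm_trunc(spec$ratio_fh_bigonial[1], spec$ratio_fh_bigonial[2],
                         0.5)
    BG <- FH / ratio
  } else {
    BG <- rnorm_trunc(spec$bigonial[1], spec$bigonial[2], 3)
  }
  NH  <- rnorm_trunc(spec$nose_height[1], spec$nose_height[2], 0.5)
  AW  <- rnorm_trunc(spec$alar_width[1], spec$alar_width[2], 0.5)
  IPD <- rnorm_trunc(spec$interpupillary[1], spec$interpupillary[2], 2)
  tilt <- stats::rnorm(1, spec$canthal_tilt[1], spec$canthal_tilt[2])
  if (spec$canthal_tilt[2] == 0) tilt <- spec$canthal_tilt[1]
  Lm <- rnorm_trunc(spec$medial_brow[1], spec$medial_brow[2], 0.2)
  Ll <- rnorm_trunc(spec$lateral_brow[1], spec$lateral_brow[2], 0.2)
  th1 <- rnorm_trunc(spec$brow_angle_1[1], spec$brow_angle_1[2], 0.5)
  th3 <- rnorm_trunc(spec$brow_angle_3[1], spec$brow_angle_3[2], 0.5)
  hp <- sample_composition(spec$horizontal_thirds$mean,
                           spec$horizontal_thirds$sd)
  vp <- sample_composition(spec$vertical_thirds$mean, spec$vertical_thirds$sd)
  wtw <- rnorm_trunc(spec$wtw_mm[1], spec$wtw_mm[2], 8)

  y_gla <- hp[1] * FH
  y_sub <- (hp[1] + hp[2]) * FH
  y_eye <- y_gla + L$eye_drop
  y_nas <- y_gla + L$nasion_drop

  # canthi: exocanthion span W chosen so the canthal midpoints (pupils)
  # realise the sampled interpupillary distance
  W <- 2 * IPD / (1 + vp[2])
  tau <- deg2rad(tilt)
  x_exoR <- -W / 2
  x_endR <- x_exoR + vp[3] * W
  x_endL <- W / 2 - vp[1] * W
  x_exoL <- W / 2
  spanL <- x_exoL - x_endL
  spanR <- x_endR - x_exoR
  y_exoL <- y_eye - spanL * tan(tau)
  y_exoR <- y_eye - spanR * tan(tau)
  x_pupL <- (x_endL + x_exoL) / 2
  x_pupR <- (x_endR + x_exoR) / 2

  wtw_cm <- wtw / 10
  y_irisL <- y_eye + wtw_cm / 2
  y_lid   <- function(y_iris) y_iris - L$lid_overlap

  y_brow <- y_eye - L$brow_rise
  r1 <- deg2rad(th1); r3 <- deg2rad(th3)
  # left brow: medial = -x, lateral = +x; right mirrored
  apL <- c(x_exoL, y_brow)
  mdL <- apL + Lm * c(-cos(r1),  sin(r1))
  ltL <- apL + Ll * c( cos(r3),  sin(r3))
  apR <- c(-x_exoL, y_brow)
  mdR <- apR + Lm * c( cos(r1),  sin(r1))
  ltR <- apR + Ll * c(-cos(r3),  sin(r3))

  pts <- list(
    trichion = c(0, 0), glabella = c(0, y_gla), nasion = c(0, y_nas),
    pronasale = c(0, y_nas + NH), subnasale = c(0, y_sub),
    menton = c(0, FH),
    zygion_L = c(BZ / 2, y_gla + L$zygion_drop),
    zygion_R = c(-BZ / 2, y_gla + L$zygion_drop),
    gonion_L = c(BG / 2, L$gonion_frac * FH),
    gonion_R = c(-BG / 2, L$gonion_frac * FH),
    alare_L = c(AW / 2, y_sub), alare_R = c(-AW / 2, y_sub),
    endocanthion_L = c(x_endL, y_eye), endocanthion_R = c(x_endR, y_eye),
    exocanthion_L = c(x_exoL, y_exoL), exocanthion_R = c(x_exoR, y_exoR),
    pupil_L = c(x_pupL, y_eye), pupil_R = c(x_pupR, y_eye),
    brow_medial_L = mdL, brow_apex_L = apL, brow_lateral_L = ltL,
    brow_medial_R = mdR, brow_apex_R = apR, brow_lateral_R = ltR,
    iris_inferior_L = c(x_pupL, y_irisL), iris_inferior_R = c(x_pupR, y_irisL),
    lowerlid_margin_L = c(x_pupL, y_lid(y_irisL)),
    lowerlid_margin_R = c(x_pupR, y_lid(y_irisL)))

  fissure <- (spanL + spanR) / (2 * cos(tau))
  # realized vertical-third proportions: projection of the canthi onto the
  # line through the exocanthions (the battery's definition); with unequal
  # eye spans this differs from the sampled x-composition by O(tan(tilt)^2)
  u <- pts$exocanthion_L - pts$exocanthion_R
  u <- u / sqrt(sum(u^2))
  tp <- vapply(list(pts$exocanthion_R, pts$endocanthion_R,
                    pts$endocanthion_L, pts$exocanthion_L),
               function(p) sum(p * u), numeric(1))
  seg <- diff(tp)
  vp_real <- c(right = seg[1] / sum(seg), middle = seg[2] / sum(seg))
  vp_real <- c(left = 1 - (vp_real[["right"]] + vp_real[["middle"]]), vp_real)
  truth <- list(
    facial_height_cm = FH, bizygomatic_width_cm = BZ, bigonial_width_cm = BG,
    nose_height_cm = NH, alar_width_cm = AW, interpupillary_distance_cm = IPD,
    palpebral_fissure_length_cm = fissure,
    canthal_tilt_deg = tilt, facial_rotation_deg = 0,
    upper_third_cm = hp[1] * FH, middle_third_cm = hp[2] * FH,
    lower_third_cm = hp[3] * FH,
    upper_third_prop = hp[1], middle_third_prop = hp[2],
    lower_third_prop = hp[3],
    left_vertical_third_prop = vp_real[["left"]],
    middle_vertical_third_prop = vp_real[["middle"]],
    right_vertical_third_prop = vp_real[["right"]],
    brow_angle_1_deg = th1, brow_angle_2_deg = 180 - th1 - th3,
    brow_angle_3_deg = th3,
    medial_brow_length_cm = Lm, lateral_brow_length_cm = Ll,
    total_brow_length_cm = Lm + Ll,
    medial_canthus_to_medial_brow_cm =
      (sqrt(sum((pts$endocanthion_L - mdL)^2)) +
         sqrt(sum((pts$endocanthion_R - mdR)^2))) / 2,
    lateral_canthus_to_lateral_brow_cm =
      (sqrt(sum((pts$exocanthion_L - ltL)^2)) +
         sqrt(sum((pts$exocanthion_R - ltR)^2))) / 2,
    scleral_show_flag = FALSE,
    scleral_show_signed_mm = -10 * .layout$lid_overlap,
    ratio_fh_bigonial = FH / BG, ratio_fh_bizygomatic = FH / BZ,
    ratio_bizygomatic_bigonial = BZ / BG)
  list(points_cm = pts, truth = truth, wtw_mm = wtw)
}

#' Sample a synthetic cohort with known ground truth
#'
#' Draws `n` subjects from a [cohort_spec()]: each subject's millimetre
#' geometry is constructed from independently sampled marginals (midline
#' landmarks spaced by the sampled horizontal-third proportions of the
#' sampled facial height; paired landmarks placed symmetrically to realise
#' the sampled widths and canthal tilt), then a uniform in-plane rotation
#' and a uniform pixel scale are applied to produce the observed landmark
#' set. `truth` records the pre-rotation, pre-scale geometry.
#'
#' @param spec A `cohort_spec`.
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed; the draw is deterministic given (spec, n, seed).
#' @param render_eyes If `TRUE`, also rasterise left/right eye crops with
#'   the subject's iris diameter at the subject's pixel scale (see
#'   [render_eye()]).
#' @param eye_noise_sd Additive Gaussian intensity noise SD for rendered
#'   eyes (intensity units, image contrast is 0.7).
#' @return List of `synthetic_subject` objects: fields `landmarks`
#'   ([landmark_set]), `truth` (named list), `scale_px_per_mm`,
#'   `rotation_deg`, `wtw_mm`, `wtw_px`, and optionally `eyes`.
#' @export
sample_cohort <- function(spec, n, seed = NULL, render_eyes = FALSE,
                          eye_noise_sd = 0) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.numeric(n) || n < 1) fm_param_error("n must be >= 1")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      g <- build_subject_geometry(spec)
      rot <- runif_range(spec$rotation_range)
      scale <- runif_range(spec$scale_range)
      m_cm <- do.call(rbind, g$points_cm)
      px <- m_cm * 10 * scale                   # cm -> mm -> px
      gla <- px[rownames(px) == "glabella", , drop = TRUE]
      px <- rotate_points(px, rot, center = gla)
      off <- c(40, 40) - apply(px, 2, min)      # keep raster-positive
      px <- sweep(px, 2, off, "+")
      rownames(px) <- names(g$points_cm)
      g$truth$facial_rotation_deg <- rot
      subj <- list(
        landmarks = landmark_set(sprintf("%s%03d", spec$group, i), px),
        truth = g$truth,
        scale_px_per_mm = scale,
        rotation_deg = rot,
        wtw_mm = g$wtw_mm,
        wtw_px = g$wtw_mm * scale)
      if (render_eyes) {
        d_px <- g$wtw_mm * scale
        size <- as.integer(ceiling(d_px * 2.4))
        ctr <- c((size + 1) / 2, (size + 1) / 2)
        subj$eyes <- list(
          L = render_eye(ctr, d_px, size, noise_sd = eye_noise_sd,
                         seed = NULL),
          R = render_eye(ctr, d_px, size, noise_sd = eye_noise_sd,
                         seed = NULL))
      }
      class(subj) <- "synthetic_subject"
      subj
    })
  })
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject> %s: scale %.2f px/mm, rotation %+.2f deg, WTW %.2f mm\n",
              x$landmarks$subject_id, x$scale_px_per_mm, x$rotation_deg,
              x$wtw_mm))
  invisible(x)
}

#' Rasterise a synthetic eye crop
#'
#' Dark iris disc (intensity 0.15) on a bright scleral background (0.85)
#' with one-pixel linear edge antialiasing and optional additive Gaussian
#' noise. The rendered image records its own ground truth.
#'
#' @param center Iris centre `c(x, y)` in pixel coordinates.
#' @param diameter_px Iris diameter in pixels (>= 8).
#' @param image_size Side length of the square crop, or `c(width, height)`.
#' @param noise_sd Additive noise SD in intensity units (contrast is 0.7).
#' @param seed Optional integer seed (NULL = use current RNG stream).
#' @param fg,bg Iris / sclera intensities.
#' @return Object of class `eye_image`: `img` matrix plus `center`,
#'   `diameter_px`, `noise_sd` ground truth.
#' @export
render_eye <- function(center, diameter_px, image_size = 128, noise_sd = 0,
                       seed = NULL, fg = 0.15, bg = 0.85) {
  if (diameter_px < 8) fm_param_error("diameter_px must be >= 8")
  sz <- if (length(image_size) == 1) c(image_size, image_size) else image_size
  w <- as.integer(sz[1]); h <- as.integer(sz[2])
  r <- diameter_px / 2
  if (center[1] - r < 1 || center[1] + r > w ||
      center[2] - r < 1 || center[2] + r > h)
    fm_geometry_error("iris disc exceeds the image frame")
  with_seed(seed, {
    xs <- matrix(seq_len(w), h, w, byrow = TRUE)
    ys <- matrix(seq_len(h), h, w)
    d <- sqrt((xs - center[1])^2 + (ys - center[2])^2)
    cover <- pmin(pmax(r + 0.5 - d, 0), 1)   # 1 inside, 0 outside, linear edge
    img <- bg + (fg - bg) * cover
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(w * h, 0, noise_sd), h, w)
    structure(list(img = img, center = c(x = center[1], y = center[2]),
                   diameter_px = diameter_px, noise_sd = noise_sd),
              class = "eye_image")
  })
}

#' @export
print.eye_image <- function(x, ...) {
  cat(sprintf("<eye_image> %d x %d px, iris d=%.1f px at (%.1f, %.1f), noise %.3g\n",
              ncol(x$img), nrow(x$img), x$diameter_px, x$center[1],
              x$center[2], x$noise_sd))
  invisible(x)
}

#' Ground-truth table for a synthetic cohort
#'
#' @param subjects List of `synthetic_subject`s from [sample_cohort()].
#' @return data.frame: one row per subject, `subject_id` plus one column
#'   per [measurement_fields()] entry.
#' @export
ground_truth_table <- function(subjects) {
  if (length(subjects) == 0) fm_param_error("subjects must be non-empty")
  rows <- lapply(subjects, function(s) {
    tr <- s$truth[measurement_fields()]
    cbind(data.frame(subject_id = s$landmarks$subject_id,
                     stringsAsFactors = FALSE),
          as.data.frame(tr))
  })
  do.call(rbind, rows)
}
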
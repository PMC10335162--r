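#' In-plane facial rotation angle
#'
#' Angle between the median face vector (glabella to menton) and the true
#' vertical, in degrees; positive when the chin deviates toward the
#' viewer's right (clockwise rotation in the viewer's frame). With image
#' coordinates (y down) this is `atan2(menton.x - glabella.x,
#' menton.y - glabella.y)`, folded into (-90, 90].
#'
#' @param ls A [landmark_set] containing `glabella` and `menton`.
#' @return Rotation in degrees.
#' @export
facial_rotation <- function(ls) {
  g <- landmark_point(ls, "glabella")
  m <- landmark_point(ls, "menton")
  if (all(g == m))
    fm_geometry_error("glabella and menton coincide; rotation undefined")
  r <- rad2deg(atan2(m[1] - g[1], m[2] - g[2]))
  if (r > 90) r <- r - 180
  if (r <= -90) r <- r + 180
  r
}

# raw tilt of one eye: angle of endocanthion -> exocanthion against the
# lateral horizontal, positive when the exocanthion is superior (smaller y).
raw_tilt_eye <- function(ls, side) {
  en <- landmark_point(ls, paste0("endocanthion_", side))
  ex <- landmark_point(ls, paste0("exocanthion_", side))
  lat_sign <- if (side == "L") 1 else -1   # subject's left appears at +x
  rad2deg(atan2(en[2] - ex[2], (ex[1] - en[1]) * lat_sign))
}

#' Rotation-corrected canthal tilt
#'
#' Per eye, the raw tilt is the angle of the endocanthion-to-exocanthion
#' line against the horizontal (positive = exocanthion superior). A rigid
#' clockwise head rotation adds the rotation angle to the left eye's raw
#' tilt and subtracts it from the right eye's, so the correction is applied
#' with opposite signs per side before averaging; the mean tilt of a
#' rigidly rotated face is therefore invariant.
#'
#' @param ls A [landmark_set] with all four canthi.
#' @param rotation Facial rotation in degrees (from [facial_rotation()]).
#' @return Mean corrected canthal tilt, degrees.
#' @export
canthal_tilt <- function(ls, rotation = facial_rotation(ls)) {
  left  <- raw_tilt_eye(ls, "L") - rotation
  right <- raw_tilt_eye(ls, "R") + rotation
  (left + right) / 2
}

dist_px <- function(ls, a, b) {
  pa <- landmark_point(ls, a); pb <- landmark_point(ls, b)
  sqrt(sum((pa - pb)^2))
}

px_to_cm <- function(calib, px) calibrate_px(calib, px) / 10

#' Calibrated landmark distances
#'
#' `midline_distance` is the Euclidean distance between two single
#' landmarks; `paired_width` the distance between the `_L` and `_R`
#' instances of one landmark (e.g. bizygomatic width from `zygion`);
#' `bilateral_distance` the left/right mean of a same-side landmark pair
#' (e.g. canthus-to-brow distances). All return centimetres.
#'
#' @param ls A [landmark_set].
#' @param name_a,name_b Landmark names (base names without side suffix for
#'   `bilateral_distance`).
#' @param name Base landmark name for `paired_width`.
#' @param calib A `calibration` from [make_calibration()].
#' @return Distance in cm.
#' @export
midline_distance <- function(ls, name_a, name_b, calib) {
  px_to_cm(calib, dist_px(ls, name_a, name_b))
}

#' @rdname midline_distance
#' @export
paired_width <- function(ls, name, calib) {
  px_to_cm(calib, dist_px(ls, paste0(name, "_L"), paste0(name, "_R")))
}

#' @rdname midline_distance
#' @export
bilateral_distance <- function(ls, name_a, name_b, calib) {
  d <- vapply(c("L", "R"), function(s)
    dist_px(ls, paste0(name_a, "_", s), paste0(name_b, "_", s)), numeric(1))
  px_to_cm(calib, mean(d))
}

#' Horizontal facial thirds
#'
#' Trichion, glabella, subnasale and menton are projected onto the median
#' axis (the glabella-to-menton direction); the upper, middle and lower
#' thirds are the successive projected segment lengths, and each proportion
#' is that segment over the sum of the three, so the proportions sum to 1
#' exactly.
#'
#' @param ls A [landmark_set].
#' @param calib A `calibration`.
#' @return List with `lengths_cm` and `props`, each named
#'   (upper, middle, lower).
#' @export
horizontal_thirds <- function(ls, calib) {
  nm <- c("trichion", "glabella", "subnasale", "menton")
  pts <- t(vapply(nm, function(n) landmark_point(ls, n), numeric(2)))
  u <- pts["menton", ] - pts["glabella", ]
  nu <- sqrt(sum(u^2))
  if (nu == 0) fm_geometry_error("median axis undefined")
  t_proj <- as.numeric(pts %*% (u / nu))
  if (any(diff(t_proj) <= 0))
    fm_geometry_error("midline landmarks out of order along the median axis")
  seg_px <- diff(t_proj)
  seg_cm <- px_to_cm(calib, seg_px)
  p1 <- seg_px[1] / sum(seg_px); p2 <- seg_px[2] / sum(seg_px)
  # third component as the complement of the (exactly representable)
  # partial sum so the triplet sums to 1 exactly
  props <- c(upper = p1, middle = p2, lower = 1 - (p1 + p2))
  list(lengths_cm = stats::setNames(seg_cm, c("upper", "middle", "lower")),
       props = props)
}

#' Vertical facial thirds
#'
#' The four canthi are projected onto the line through the two
#' exocanthions; proportions are the successive projected segments (right
#' exocanthion to right endocanthion, endocanthion to endocanthion, left
#' endocanthion to left exocanthion) over the full exocanthion span, and
#' sum to 1 exactly.
#'
#' @param ls A [landmark_set].
#' @return Named proportions (left, middle, right), anatomical sides.
#' @export
vertical_thirds <- function(ls) {
  nm <- c("exocanthion_R", "endocanthion_R", "endocanthion_L", "exocanthion_L")
  pts <- t(vapply(nm, function(n) landmark_point(ls, n), numeric(2)))
  u <- pts["exocanthion_L", ] - pts["exocanthion_R", ]
  nu <- sqrt(sum(u^2))
  if (nu == 0) fm_geometry_error("exocanthion span undefined")
  t_proj <- as.numeric(pts %*% (u / nu))
  if (any(diff(t_proj) <= 0))
    fm_geometry_error("canthi out of order along the ocular axis")
  seg <- diff(t_proj)
  # complement goes in the last-summed slot so left + middle + right == 1
  # exactly in IEEE arithmetic
  left <- seg[3] / sum(seg); middle <- seg[2] / sum(seg)
  c(left = left, middle = middle, right = 1 - (left + middle))
}

#' Brow angles and lengths
#'
#' Angles follow the three-point construction at the brow apex, referenced
#' to the interpupillary (IP) line so head tilt cancels: angle 1 is between
#' the apex-to-medial-brow limb and the IP-parallel ray pointing medially;
#' angle 2 is the included angle medial-apex-lateral; angle 3 is between
#' the apex-to-lateral-brow limb and the IP-parallel ray pointing
#' laterally. Lengths are Euclidean; total = medial + lateral. Everything
#' is averaged over the two sides.
#'
#' @param ls A [landmark_set].
#' @param calib A `calibration`.
#' @return List with `angles_deg` (angle_1..3), `lengths_cm` (medial,
#'   lateral, total) and `canthus_brow_cm` (medial, lateral).
#' @export
brow_metrics <- function(ls, calib) {
  ip <- landmark_point(ls, "pupil_L") - landmark_point(ls, "pupil_R")
  if (all(ip == 0)) fm_geometry_error("interpupillary line undefined")
  per_side <- function(side) {
    md <- landmark_point(ls, paste0("brow_medial_", side))
    ap <- landmark_point(ls, paste0("brow_apex_", side))
    lt <- landmark_point(ls, paste0("brow_lateral_", side))
    med_dir <- if (side == "L") -ip else ip   # toward the midline
    lat_dir <- -med_dir
    v_md <- md - ap; v_lt <- lt - ap
    if (all(v_md == 0) || all(v_lt == 0))
      fm_geometry_error("coincident brow landmarks")
    c(a1 = vec_angle_deg(v_md, med_dir),
      a2 = vec_angle_deg(v_md, v_lt),
      a3 = vec_angle_deg(v_lt, lat_dir),
      med = sqrt(sum(v_md^2)), lat = sqrt(sum(v_lt^2)),
      d_med = dist_px(ls, paste0("endocanthion_", side),
                      paste0("brow_medial_", side)),
      d_lat = dist_px(ls, paste0("exocanthion_", side),
                      paste0("brow_lateral_", side)))
  }
  m <- (per_side("L") + per_side("R")) / 2
  med_cm <- px_to_cm(calib, m[["med"]])
  lat_cm <- px_to_cm(calib, m[["lat"]])
  list(angles_deg = c(angle_1 = m[["a1"]], angle_2 = m[["a2"]],
                      angle_3 = m[["a3"]]),
       lengths_cm = c(medial = med_cm, lateral = lat_cm,
                      total = med_cm + lat_cm),
       canthus_brow_cm = c(medial = px_to_cm(calib, m[["d_med"]]),
                           lateral = px_to_cm(calib, m[["d_lat"]])))
}

#' Scleral show
#'
#' Signed vertical gap between the lower-lid margin and the most inferior
#' iris point, measured in the rotation-corrected frame: positive
#' millimetres mean the inferior iris border sits above the lid margin
#' (visible sclera). The flag is true if either eye shows a positive gap.
#'
#' @param ls A [landmark_set].
#' @param calib A `calibration`.
#' @param rotation Facial rotation (degrees) used to de-rotate.
#' @return List with `left_mm`, `right_mm`, `combined_mm` (mean) and `flag`.
#' @export
scleral_show <- function(ls, calib, rotation = facial_rotation(ls)) {
  gap <- vapply(c("L", "R"), function(side) {
    iris <- landmark_point(ls, paste0("iris_inferior_", side))
    lid  <- landmark_point(ls, paste0("lowerlid_margin_", side))
    p <- rotate_points(rbind(iris, lid), -rotation)
    (p[2, 2] - p[1, 2]) * calib$mm_per_px
  }, numeric(1))
  list(left_mm = gap[["L"]], right_mm = gap[["R"]],
       combined_mm = mean(gap), flag = any(gap > 0))
}

#' Aesthetic facial ratios
#'
#' Quotients of calibrated values from a measurement record: facial height
#' over bigonial width (the ratio compared against the golden ratio 1.618),
#' facial height over bizygomatic width, and bizygomatic over bigonial
#' width.
#'
#' @param rec A one-row measurement record (list or data.frame) with
#'   `facial_height_cm`, `bigonial_width_cm`, `bizygomatic_width_cm`.
#' @return Named numeric vector of the three ratios.
#' @export
facial_ratios <- function(rec) {
  fh <- rec$facial_height_cm; bg <- rec$bigonial_width_cm
  bz <- rec$bizygomatic_width_cm
  if (any(c(bg, bz) <= 0)) fm_param_error("width denominators must be > 0")
  c(ratio_fh_bigonial = fh / bg,
    ratio_fh_bizygomatic = fh / bz,
    ratio_bizygomatic_bigonial = bz / bg)
}

#' Measure one subject
#'
#' Runs the full battery on a calibrated landmark set: facial rotation,
#' rotation-corrected canthal tilt, midline and paired distances, facial
#' thirds, brow geometry, scleral show and the aesthetic ratios. Bilateral
#' quantities are left/right means.
#'
#' @param ls A [landmark_set]; all [core_landmarks()] must be present.
#' @param calib A `calibration` from [make_calibration()].
#' @return One-row data.frame with [measurement_fields()] columns plus
#'   `subject_id`.
#' @export
measure_subject <- function(ls, calib) {
  miss <- validate_core(ls)
  if (length(miss))
    fm_schema_error(paste0("subject ", ls$subject_id,
                           " missing core landmark(s): ",
                           paste(miss, collapse = ", ")))
  rot <- facial_rotation(ls)
  ht <- horizontal_thirds(ls, calib)
  vt <- vertical_thirds(ls)
  bw <- brow_metrics(ls, calib)
  ss <- scleral_show(ls, calib, rot)
  rec <- data.frame(
    subject_id = ls$subject_id,
    facial_height_cm = midline_distance(ls, "trichion", "menton", calib),
    bizygomatic_width_cm = paired_width(ls, "zygion", calib),
    bigonial_width_cm = paired_width(ls, "gonion", calib),
    nose_height_cm = midline_distance(ls, "nasion", "pronasale", calib),
    alar_width_cm = paired_width(ls, "alare", calib),
    interpupillary_distance_cm = paired_width(ls, "pupil", calib),
    palpebral_fissure_length_cm =
      bilateral_distance(ls, "endocanthion", "exocanthion", calib),
    canthal_tilt_deg = canthal_tilt(ls, rot),
    facial_rotation_deg = rot,
    upper_third_cm = ht$lengths_cm[["upper"]],
    middle_third_cm = ht$lengths_cm[["middle"]],
    lower_third_cm = ht$lengths_cm[["lower"]],
    upper_third_prop = ht$props[["upper"]],
    middle_third_prop = ht$props[["middle"]],
    lower_third_prop = ht$props[["lower"]],
    left_vertical_third_prop = vt[["left"]],
    middle_vertical_third_prop = vt[["middle"]],
    right_vertical_third_prop = vt[["right"]],
    brow_angle_1_deg = bw$angles_deg[["angle_1"]],
    brow_angle_2_deg = bw$angles_deg[["angle_2"]],
    brow_angle_3_deg = bw$angles_deg[["angle_3"]],
    medial_brow_length_cm = bw$lengths_cm[["medial"]],
    lateral_brow_length_cm = bw$lengths_cm[["lateral"]],
    total_brow_length_cm = bw$lengths_cm[["total"]],
    medial_canthus_to_medial_brow_cm = bw$canthus_brow_cm[["medial"]],
    lateral_canthus_to_lateral_brow_cm = bw$canthus_brow_cm[["lateral"]],
    scleral_show_flag = ss$flag,
    scleral_show_signed_mm = ss$combined_mm,
    stringsAsFactors = FALSE)
  rec <- cbind(rec, as.data.frame(as.list(facial_ratios(rec))))
  rec
}
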
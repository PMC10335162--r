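# Shared fixtures, all built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Degenerate generating spec: every SD zero, no rotation, fixed scale.
flat_spec <- function(group = "F", scale = 10, rotation = 0, ...) {
  defaults <- list(
    group = group,
    facial_height = c(18, 0), bizygomatic = c(13, 0), bigonial = c(11, 0),
    nose_height = c(3.8, 0), alar_width = c(3.2, 0),
    interpupillary = c(6.2, 0), canthal_tilt = c(8, 0),
    medial_brow = c(3, 0), lateral_brow = c(1.6, 0),
    brow_angle_1 = c(12, 0), brow_angle_3 = c(32, 0),
    horizontal_thirds = list(mean = c(0.324, 0.344, 0.332), sd = c(0, 0, 0)),
    vertical_thirds = list(mean = c(0.311, 0.374, 0.315), sd = c(0, 0, 0)),
    ratio_fh_bigonial = c(1.6, 0), wtw_mm = c(11.71, 0),
    scale_range = c(scale, scale), rotation_range = c(rotation, rotation))
  do.call(cohort_spec, utils::modifyList(defaults, list(...)))
}

# Exact calibration for a synthetic subject (known WTW pixels and mm).
exact_calibration <- function(subject) {
  make_calibration(subject$wtw_px, subject$wtw_mm)
}

# Minimal landmark set with only the eye landmarks needed for tilt tests.
eye_only_set <- function(tilt_rise = 1) {
  landmark_set("eyes", list(
    endocanthion_L = c(2, 0), exocanthion_L = c(12, -tilt_rise),
    endocanthion_R = c(-2, 0), exocanthion_R = c(-12, -tilt_rise)))
}

# Numeric truth comparison across the full record.
expect_record_matches_truth <- function(rec, truth, tol = 1e-6) {
  flds <- setdiff(measurement_fields(), "scleral_show_flag")
  for (f in flds)
    expect_equal(rec[[f]], truth[[f]], tolerance = tol,
                 ignore_attr = TRUE, label = f)
  expect_identical(rec$scleral_show_flag, truth$scleral_show_flag)
}
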
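test_that("facial rotation follows the glabella-menton vertical convention", {
  ls <- landmark_set("r", list(glabella = c(100, 50), menton = c(100, 250)))
  expect_equal(facial_rotation(ls), 0)

  ls2 <- landmark_set("r", list(glabella = c(100, 50), menton = c(120, 250)))
  expect_equal(facial_rotation(ls2), atan2(20, 200) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(facial_rotation(ls2), 5.7106, tolerance = 1e-4)

  # equivariance: rotating the whole face adds exactly theta
  set.seed(14)
  for (theta in c(-25, -5, 3, 18)) {
    base <- matrix(c(100, 50, 108, 250), 2, 2, byrow = TRUE,
                   dimnames = list(c("glabella", "menton"), NULL))
    r0 <- facial_rotation(landmark_set("a", base))
    rot <- facemetrics:::rotate_points(base, theta, center = c(50, 70))
    rownames(rot) <- rownames(base)
    expect_equal(facial_rotation(landmark_set("a", rot)), r0 + theta,
                 tolerance = 1e-9)
  }
  expect_error(facial_rotation(landmark_set("x", list(glabella = c(1, 1),
                                                      menton = c(1, 1)))),
               class = "fm_geometry_error")
})

test_that("canthal tilt: sign convention, rotation invariance, generator truth", {
  # exocanthion one px superior over 10 px lateral -> +5.71 deg per eye
  expect_equal(canthal_tilt(eye_only_set(1), rotation = 0),
               atan(1 / 10) * 180 / pi, tolerance = 1e-9)
  # inferior exocanthion -> negative tilt
  expect_lt(canthal_tilt(eye_only_set(-1), rotation = 0), 0)

  # rigid rotation of a zero-tilt face leaves corrected mean tilt at 0
  flat_eyes <- eye_only_set(0)
  for (theta in c(-12, 4, 9)) {
    pts <- facemetrics:::rotate_points(flat_eyes$points, theta)
    rownames(pts) <- rownames(flat_eyes$points)
    expect_equal(canthal_tilt(landmark_set("e", pts), rotation = theta), 0,
                 tolerance = 1e-9)
  }

  # generator truth: tilt 8.5 deg survives a 7 deg head rotation
  spec <- flat_spec(canthal_tilt = c(8.5, 0), rotation = 7)
  s <- sample_cohort(spec, 1, seed = 2)[[1]]
  rot <- facial_rotation(s$landmarks)
  expect_equal(rot, 7, tolerance = 1e-9)
  expect_equal(canthal_tilt(s$landmarks, rot), 8.5, tolerance = 1e-6)

  expect_error(canthal_tilt(landmark_set("x", list(endocanthion_L = c(0, 0))),
                            rotation = 0),
               class = "fm_schema_error")
})

test_that("calibrated distances: worked example, invariance, generator truth", {
  ls <- landmark_set("d", list(trichion = c(0, 0), menton = c(0, 1800)))
  cal <- make_calibration(117.1)           # mm_per_px = 0.1
  expect_equal(midline_distance(ls, "trichion", "menton", cal), 18.00,
               tolerance = 1e-9)

  # rigid rotation leaves distances unchanged to 1e-9 cm
  s <- sample_cohort(flat_spec(), 1, seed = 3)[[1]]
  cal2 <- exact_calibration(s)
  d0 <- paired_width(s$landmarks, "gonion", cal2)
  pts <- facemetrics:::rotate_points(s$landmarks$points, 23,
                                     center = c(300, 400))
  rownames(pts) <- rownames(s$landmarks$points)
  d1 <- paired_width(landmark_set("rot", pts), "gonion", cal2)
  expect_equal(d0, d1, tolerance = 1e-9)

  # generator truth for a male bigonial width of 12.34 cm
  spec <- flat_spec(group = "M", bigonial = c(12.34, 0))
  sm <- sample_cohort(spec, 1, seed = 4)[[1]]
  expect_equal(paired_width(sm$landmarks, "gonion", exact_calibration(sm)),
               12.34, tolerance = 1e-6)

  expect_error(midline_distance(ls, "trichion", "nasion", cal),
               class = "fm_schema_error")
})

test_that("horizontal thirds: symmetry, generator truth, rotation invariance", {
  ls <- landmark_set("t", list(trichion = c(0, 0), glabella = c(0, 60),
                               subnasale = c(0, 120), menton = c(0, 180)))
  cal <- make_calibration(117.1)
  ht <- horizontal_thirds(ls, cal)
  expect_equal(unname(ht$props), rep(1 / 3, 3), tolerance = 1e-12)
  expect_identical(sum(ht$props), 1)

  s <- sample_cohort(flat_spec(rotation = 10), 1, seed = 6)[[1]]
  ht2 <- horizontal_thirds(s$landmarks, exact_calibration(s))
  expect_equal(unname(ht2$props), c(0.324, 0.344, 0.332), tolerance = 1e-6)
  expect_identical(sum(ht2$props), 1)

  bad <- landmark_set("b", list(trichion = c(0, 100), glabella = c(0, 60),
                                subnasale = c(0, 120), menton = c(0, 180)))
  expect_error(horizontal_thirds(bad, cal), class = "fm_geometry_error")
})

test_that("vertical thirds reproduce canthal spacing proportions", {
  ls <- landmark_set("v", list(exocanthion_R = c(0, 5),
                               endocanthion_R = c(31.1, 5),
                               endocanthion_L = c(68.5, 5),
                               exocanthion_L = c(100, 5)))
  vt <- vertical_thirds(ls)
  expect_equal(unname(vt), c(0.315, 0.374, 0.311), tolerance = 1e-12)
  expect_equal(vt[["right"]], 0.311)
  expect_equal(vt[["left"]], 0.315)
  expect_identical(sum(vt), 1)

  # equal spacing and rigid-rotation invariance
  eq <- landmark_set("v", list(exocanthion_R = c(0, 0),
                               endocanthion_R = c(30, 0),
                               endocanthion_L = c(60, 0),
                               exocanthion_L = c(90, 0)))
  expect_equal(unname(vertical_thirds(eq)), rep(1 / 3, 3), tolerance = 1e-12)
  pts <- facemetrics:::rotate_points(eq$points, -17, center = c(45, 0))
  rownames(pts) <- rownames(eq$points)
  expect_equal(vertical_thirds(landmark_set("v", pts)), vertical_thirds(eq),
               tolerance = 1e-9)

  crossed <- landmark_set("v", list(exocanthion_R = c(40, 0),
                                    endocanthion_R = c(30, 0),
                                    endocanthion_L = c(60, 0),
                                    exocanthion_L = c(90, 0)))
  expect_error(vertical_thirds(crossed), class = "fm_geometry_error")
})

test_that("brow metrics follow the apex construction against the IP line", {
  cal <- make_calibration(117.1)
  base <- list(pupil_L = c(50, 100), pupil_R = c(-50, 100))
  # flat brows collinear with the IP direction -> 0 / 180 / 0
  flat <- landmark_set("b", c(base, list(
    brow_medial_L = c(20, 50), brow_apex_L = c(45, 50),
    brow_lateral_L = c(60, 50),
    brow_medial_R = c(-20, 50), brow_apex_R = c(-45, 50),
    brow_lateral_R = c(-60, 50),
    endocanthion_L = c(20, 95), exocanthion_L = c(60, 95),
    endocanthion_R = c(-20, 95), exocanthion_R = c(-60, 95))))
  bm <- brow_metrics(flat, cal)
  expect_equal(unname(bm$angles_deg), c(0, 180, 0), tolerance = 1e-9)

  # both limbs descending 30 deg from the apex -> 30 / 120 / 30
  r3 <- sqrt(3) / 2
  peaked <- landmark_set("b", c(base, list(
    brow_medial_L = c(45 - 20 * r3, 50 + 10), brow_apex_L = c(45, 50),
    brow_lateral_L = c(45 + 10 * r3, 50 + 5),
    brow_medial_R = c(-45 + 20 * r3, 50 + 10), brow_apex_R = c(-45, 50),
    brow_lateral_R = c(-45 - 10 * r3, 50 + 5),
    endocanthion_L = c(20, 95), exocanthion_L = c(60, 95),
    endocanthion_R = c(-20, 95), exocanthion_R = c(-60, 95))))
  bm2 <- brow_metrics(peaked, cal)
  expect_equal(unname(bm2$angles_deg), c(30, 120, 30), tolerance = 1e-9)

  # additivity: total = medial + lateral (3.0 + 1.6 cm)
  s <- sample_cohort(flat_spec(medial_brow = c(3.0, 0),
                               lateral_brow = c(1.6, 0)), 1, seed = 9)[[1]]
  bm3 <- brow_metrics(s$landmarks, exact_calibration(s))
  expect_equal(bm3$lengths_cm[["medial"]], 3.0, tolerance = 1e-6)
  expect_equal(bm3$lengths_cm[["total"]], 4.6, tolerance = 1e-6)
  expect_identical(bm3$lengths_cm[["total"]],
                   bm3$lengths_cm[["medial"]] + bm3$lengths_cm[["lateral"]])

  degen <- landmark_set("b", c(base, list(
    brow_medial_L = c(45, 50), brow_apex_L = c(45, 50),
    brow_lateral_L = c(60, 50),
    brow_medial_R = c(-45, 50), brow_apex_R = c(-45, 50),
    brow_lateral_R = c(-60, 50),
    endocanthion_L = c(20, 95), exocanthion_L = c(60, 95),
    endocanthion_R = c(-20, 95), exocanthion_R = c(-60, 95))))
  expect_error(brow_metrics(degen, cal), class = "fm_geometry_error")
})

test_that("scleral show sign convention and cohort-level absence", {
  cal <- make_calibration(117.1)       # mm_per_px = 0.1
  ls <- landmark_set("s", list(
    glabella = c(0, -100), menton = c(0, 100),
    iris_inferior_L = c(10, 48), lowerlid_margin_L = c(10, 50),
    iris_inferior_R = c(-10, 48), lowerlid_margin_R = c(-10, 50)))
  ss <- scleral_show(ls, cal, rotation = 0)
  expect_equal(ss$left_mm, 0.2, tolerance = 1e-9)
  expect_true(ss$flag)

  on_margin <- landmark_set("s", list(
    iris_inferior_L = c(10, 50), lowerlid_margin_L = c(10, 50),
    iris_inferior_R = c(-10, 50), lowerlid_margin_R = c(-10, 50)))
  ss0 <- scleral_show(on_margin, cal, rotation = 0)
  expect_equal(ss0$combined_mm, 0)
  expect_false(ss0$flag)

  # default generator cohorts never show sclera: 0/42 flagged
  subs <- c(sample_cohort(dimorphism_norms("female"), 21, seed = 71),
            sample_cohort(dimorphism_norms("male"), 21, seed = 72))
  flags <- vapply(subs, function(s)
    measure_subject(s$landmarks, exact_calibration(s))$scleral_show_flag,
    logical(1))
  expect_identical(sum(flags), 0L)
})

test_that("facial ratios are plain quotients (golden-ratio worked example)", {
  rec <- list(facial_height_cm = 16.18, bigonial_width_cm = 10.00,
              bizygomatic_width_cm = 16.18)
  r <- facial_ratios(rec)
  expect_equal(r[["ratio_fh_bigonial"]], 1.618)
  expect_equal(r[["ratio_fh_bizygomatic"]], 1.0)
  expect_error(facial_ratios(list(facial_height_cm = 1, bigonial_width_cm = 0,
                                  bizygomatic_width_cm = 1)),
               class = "fm_param_error")

  s <- sample_cohort(flat_spec(facial_height = c(17.743, 0),
                               bigonial = c(11, 0)), 1, seed = 10)[[1]]
  rec2 <- measure_subject(s$landmarks, exact_calibration(s))
  expect_equal(rec2$ratio_fh_bigonial, 1.613, tolerance = 1e-4)
})

test_that("measure_subject equals generator truth and is invariant to pose", {
  for (grp in c("female", "male")) {
    subs <- sample_cohort(dimorphism_norms(grp), 4, seed = 33)
    for (s in subs) {
      rec <- measure_subject(s$landmarks, exact_calibration(s))
      expect_record_matches_truth(rec, s$truth)
    }
  }

  # rotating 8 deg more and rescaling x2 (with WTW px doubled) changes nothing
  s <- sample_cohort(dimorphism_norms("female"), 1, seed = 44)[[1]]
  rec0 <- measure_subject(s$landmarks, exact_calibration(s))
  pts <- facemetrics:::rotate_points(s$landmarks$points * 2, 8,
                                     center = c(100, 100))
  rownames(pts) <- rownames(s$landmarks$points)
  cal2 <- make_calibration(2 * s$wtw_px, s$wtw_mm)
  rec1 <- measure_subject(landmark_set(s$landmarks$subject_id, pts), cal2)
  flds <- setdiff(measurement_fields(), c("scleral_show_flag",
                                          "facial_rotation_deg"))
  for (f in flds)
    expect_equal(rec1[[f]], rec0[[f]], tolerance = 1e-6, label = f)
  expect_equal(rec1$facial_rotation_deg, rec0$facial_rotation_deg + 8,
               tolerance = 1e-9)

  # missing core landmark propagates a schema error naming the subject
  broken <- landmark_set("victim",
                         s$landmarks$points[rownames(s$landmarks$points) !=
                                              "pupil_L", ])
  expect_error(measure_subject(broken, exact_calibration(s)), "victim",
               class = "fm_schema_error")
})
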
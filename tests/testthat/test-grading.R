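cfg <- grading_config()

test_that("osteophyte grading applies inclusive per-site thresholds", {
  expect_equal(grade_osteophyte(0.5, "acetabular", cfg), 0)
  expect_equal(grade_osteophyte(1.0, "acetabular", cfg), 1) # inclusive boundary
  expect_equal(grade_osteophyte(50.0, "superior_femoral", cfg), 3) # inclusive
  # same area, different site-specific grade-2 cut
  expect_equal(grade_osteophyte(12.0, "acetabular", cfg), 2)
  expect_equal(grade_osteophyte(12.0, "superior_femoral", cfg), 1)
  expect_equal(grade_osteophyte(12.0, "inferior_femoral", cfg), 1)
  expect_equal(grade_osteophyte(15.0, "inferior_femoral", cfg), 2)
  expect_error(grade_osteophyte(-1, "acetabular", cfg), class = "rhoadx_domain_error")
  expect_error(grade_osteophyte(5, "femur", cfg))
})

test_that("osteophyte and JSN grades are step functions with inclusive bounds", {
  eps <- 1e-9
  for (site in osteophyte_sites()) {
    cuts <- c(cfg$osteophyte_grade1_mm2[[site]], cfg$osteophyte_grade2_mm2[[site]],
              cfg$osteophyte_grade3_mm2)
    for (k in seq_along(cuts)) {
      expect_equal(grade_osteophyte(cuts[k], site, cfg) -
                     grade_osteophyte(cuts[k] - eps, site, cfg), 1)
    }
  }
  # monotone non-decreasing in area
  areas <- sort(runif(50, 0, 60))
  g <- grade_osteophyte(areas, "acetabular", cfg)
  expect_true(all(diff(g) >= 0))
  # JSN: crossing each cut from above changes the grade by exactly 1
  expect_equal(grade_jsn(cfg$jsn_grade3_mjsw_mm, 3, cfg), 3)
  expect_equal(grade_jsn(cfg$jsn_grade3_mjsw_mm + eps, 3, cfg), 0)
  expect_equal(grade_jsn(2.8, cfg$jsn_grade1_adjusted_cut, cfg), 1)
  expect_equal(grade_jsn(2.8, cfg$jsn_grade1_adjusted_cut + eps, cfg), 0)
  expect_equal(grade_jsn(2.8, cfg$jsn_grade2_adjusted_cut, cfg), 2)
  expect_equal(grade_jsn(2.8, cfg$jsn_grade2_adjusted_cut + eps, cfg), 1)
  # monotone non-increasing in adjusted width
  adj <- sort(runif(50, 0, 4))
  gj <- grade_jsn(rep(2.8, 50), adj, cfg)
  expect_true(all(diff(gj) <= 0))
})

test_that("the raw-mJSW grade-3 rule takes precedence over adjusted cuts", {
  expect_equal(grade_jsn(1.5, 3.5, cfg), 3)
  expect_equal(grade_jsn(1.2, 3.5, cfg), 3)
  expect_error(grade_jsn(-0.1, 1, cfg), class = "rhoadx_domain_error")
})

test_that("height adjustment is the documented linear form", {
  cfg0 <- grading_config(height_model = list(slope_mm_per_cm = 0,
                                             reference_height_cm = 170.1))
  expect_equal(height_adjust_mjsw(2.5, 190, cfg0), 2.5) # zero slope: identity
  cfg1 <- grading_config(height_model = list(slope_mm_per_cm = 0.01,
                                             reference_height_cm = 170))
  expect_equal(height_adjust_mjsw(2.5, 180, cfg1), 2.4)
  expect_equal(height_adjust_mjsw(2.5, 170, cfg1), 2.5) # at reference: raw
  expect_warning(out <- height_adjust_mjsw(2.5, NA, cfg1),
                 class = "rhoadx_missing_covariate")
  expect_equal(out, 2.5)
})

test_that("a height slope planted in simulated widths is recovered by regression", {
  set.seed(31)
  n <- 5000
  height <- rnorm(n, 170, 8)
  slope_true <- 0.012
  mjsw <- 2.89 + slope_true * (height - 170) + rnorm(n, 0, 0.5)
  fit <- lm(mjsw ~ height)
  se <- summary(fit)$coefficients["height", "Std. Error"]
  expect_lt(abs(coef(fit)[["height"]] - slope_true), 2 * se)
  # adjusting with the fitted slope removes the height dependence
  cfg_fit <- grading_config(height_model = list(
    slope_mm_per_cm = coef(fit)[["height"]], reference_height_cm = 170))
  adj <- height_adjust_mjsw(mjsw, height, cfg_fit)
  expect_lt(abs(cor(adj, height)), 0.05)
})

test_that("composite grade matches the brute-force mapping for all 256 combinations", {
  combos <- expand.grid(a = 0:3, s = 0:3, i = 0:3, j = 0:3)
  got <- composite_rhoa(combos$a, combos$s, combos$i, combos$j, cfg)
  want <- vapply(rowSums(combos), composite_lookup_oracle, integer(1))
  expect_equal(got, want)
  # monotone non-decreasing in every component
  bump <- composite_rhoa(pmin(combos$a + 1, 3), combos$s, combos$i, combos$j, cfg)
  expect_true(all(bump >= got))
  expect_error(composite_rhoa(4, 0, 0, 0, cfg), class = "rhoadx_domain_error")
  expect_error(composite_rhoa(-1, 0, 0, 0, cfg), class = "rhoadx_domain_error")
})

test_that("printed composite examples map as published", {
  expect_equal(composite_rhoa(0, 0, 0, 0, cfg), 0) # sum 0
  expect_equal(composite_rhoa(1, 1, 0, 1, cfg), 2) # sum 3
  expect_equal(composite_rhoa(3, 3, 3, 3, cfg), 4) # sum 12
})

test_that("grading config rejects inconsistent thresholds", {
  expect_error(grading_config(osteophyte_grade2_mm2 = c(
    acetabular = 0.5, superior_femoral = 19, inferior_femoral = 15)),
    class = "rhoadx_config_error")
  expect_error(grading_config(jsn_grade1_adjusted_cut = 1,
                              jsn_grade2_adjusted_cut = 2),
               class = "rhoadx_config_error")
  expect_error(grading_config(composite_cuts = rep(0, 12)),
               class = "rhoadx_config_error")
})

test_that("grade_annotation composes measurements into consistent grades", {
  clean <- generate_synthetic_hip(synthetic_hip_spec(
    mjsw_mm = 3.5, seed = 2, participant_id = "clean"))
  g <- grade_annotation(clean, height_cm = 170.1, cfg = cfg)
  expect_equal(g$rhoa_grade, 0)
  expect_equal(g$grade_sum, 0)
  severe <- generate_synthetic_hip(synthetic_hip_spec(
    mjsw_mm = 1.4, osteophyte_areas_mm2 = c(superior_femoral = 55),
    seed = 3, participant_id = "severe"))
  gs <- grade_annotation(severe, height_cm = 170.1, cfg = cfg)
  expect_equal(gs$osteophyte_grade_superior, 3L)
  expect_equal(gs$jsn_grade, 3L)
  expect_gte(gs$grade_sum, 6L)
  expect_equal(gs$rhoa_grade, 3) # sum 6 sits at the top of the grade-3 band
  # invariant: sum of components and consistency with the composite map
  expect_equal(gs$grade_sum, gs$osteophyte_grade_acetabular +
                 gs$osteophyte_grade_superior + gs$osteophyte_grade_inferior +
                 gs$jsn_grade)
  expect_equal(gs$rhoa_grade, cfg$composite_cuts[gs$grade_sum + 1L])
})

test_that("QC-excluded annotations cannot be graded and are counted by reason", {
  bad <- generate_synthetic_hip(synthetic_hip_spec(seed = 4, participant_id = "bad"),
                                qc_flag = "poor_quality")
  expect_error(grade_annotation(bad, 170), class = "rhoadx_excluded_record")
  anns <- list(
    generate_synthetic_hip(synthetic_hip_spec(seed = 5, participant_id = "a")),
    generate_synthetic_hip(synthetic_hip_spec(seed = 6, participant_id = "b"),
                           qc_flag = "hip_not_fully_visualized"),
    generate_synthetic_hip(synthetic_hip_spec(seed = 7, participant_id = "c"),
                           qc_flag = "duplicate"))
  expect_warning(
    out <- suppressWarnings(grade_annotations(anns),
                            classes = "rhoadx_missing_covariate"),
    class = "rhoadx_qc_exclusion")
  expect_equal(nrow(out), 1)
  excl <- attr(out, "exclusions")
  expect_equal(excl[["hip_not_fully_visualized"]], 1L)
  expect_equal(excl[["duplicate"]], 1L)
  expect_equal(excl[["poor_quality"]], 0L)
})

test_that("duplicate participant ids are rejected in batch grading", {
  anns <- list(
    generate_synthetic_hip(synthetic_hip_spec(seed = 8, participant_id = "dup")),
    generate_synthetic_hip(synthetic_hip_spec(seed = 9, participant_id = "dup")))
  expect_error(grade_annotations(anns), "dup", class = "rhoadx_format_error")
})
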
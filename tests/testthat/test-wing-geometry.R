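test_that("shoelace area is exact on analytic shapes", {
  rect <- rbind(c(0, 0), c(1, 0), c(1, 0.1), c(0, 0.1))
  expect_equal(polygon_area(rect), 0.1)
  tri <- rbind(c(0, 0), c(2, 0), c(0, 3))
  expect_equal(polygon_area(tri), 3)
  # orientation does not matter
  expect_equal(polygon_area(rect[4:1, ]), 0.1)
})

test_that("polygon area is rigid-motion invariant and scales quadratically", {
  withr::with_seed(42, {
    for (i in 1:20) {
      poly <- random_convex_polygon(sample(4:10, 1))
      a0 <- polygon_area(poly)
      th <- runif(1, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      moved <- poly %*% R + matrix(rnorm(2), nrow(poly), 2, byrow = TRUE)
      expect_equal(polygon_area(moved), a0, tolerance = 1e-12)
      expect_equal(polygon_area(2 * poly), 4 * a0, tolerance = 1e-12)
    }
  })
})

test_that("explicit wing geometry passes through with Ra = b^2/S", {
  sp <- specimen("t", "x", 0.3,
                 wing_geometry = list(MFW = list(span_m = 1, area_m2 = 0.1)))
  pf <- build_wing_model(sp, "MFW")
  expect_equal(pf$span_b_m, 1)
  expect_equal(pf$area_S_m2, 0.1)
  expect_equal(pf$aspect_ratio_Ra, 10, tolerance = 1e-12)
})

test_that("template planforms obey the documented area ordering", {
  for (sp in list(toy_specimen(), toy_specimen(scale = 1.7),
                  get_specimen(builtin_fixtures(), "STM 31-2"))) {
    areas <- vapply(c("FRW", "MFW", "PTW", "BBW"), function(m)
      build_wing_model(sp, m)$area_S_m2, numeric(1))
    expect_lt(areas["FRW"], areas["MFW"])
    expect_lte(areas["MFW"], areas["PTW"])
    expect_lte(areas["MFW"], areas["BBW"])
  }
})

test_that("template planform scales as a geometry should", {
  pf1 <- build_wing_model(toy_specimen(), "MFW")
  pf2 <- build_wing_model(toy_specimen(scale = 2), "MFW")
  expect_equal(pf2$span_b_m, 2 * pf1$span_b_m, tolerance = 1e-12)
  expect_equal(pf2$area_S_m2, 4 * pf1$area_S_m2, tolerance = 1e-12)
  expect_equal(pf2$aspect_ratio_Ra, pf1$aspect_ratio_Ra, tolerance = 1e-12)
})

test_that("missing template anchors produce a named error", {
  sp <- specimen("t", "x", 0.3, segments_m = list(humerus = 0.08))
  expect_error(build_wing_model(sp, "MFW"), "styliform")
  # BBW additionally needs the hindlimb anchor
  sp2 <- toy_specimen()
  sp2$segments_m$hindlimb_total <- NULL
  expect_error(build_wing_model(sp2, "BBW"), "hindlimb_total")
})

test_that("wing loading arithmetic and thresholds are exact", {
  pf <- wing_planform("MFW", span_b_m = 4, area_m2 = 9.81)
  expect_equal(wing_loading(1, pf, g = 9.81)$wing_loading_N_m2, 1)

  wl_at <- function(target) {
    # geometry chosen so m g / S equals the target loading exactly
    wing_loading(target / 9.81, wing_planform("MFW", 4, 1), g = 9.81)
  }
  expect_true(wl_at(244)$flight_possible)
  expect_true(wl_at(245)$flight_possible)   # inclusive bound
  expect_false(wl_at(246)$flight_possible)
  expect_true(wl_at(9)$in_glider_envelope)
  expect_true(wl_at(143)$in_glider_envelope)
  expect_false(wl_at(8.9)$in_glider_envelope)
  expect_false(wl_at(157)$in_glider_envelope) # extinct outlier loading
})

test_that("wing loading is homogeneous in mass and area", {
  pf <- toy_planform()
  base <- wing_loading(0.3, pf)$wing_loading_N_m2
  expect_equal(wing_loading(0.6, pf)$wing_loading_N_m2, 2 * base)
  pf2 <- wing_planform("MFW", pf$span_b_m, 2 * pf$area_S_m2)
  expect_equal(wing_loading(0.3, pf2)$wing_loading_N_m2, base / 2)
})

test_that("anatomical ratios match their definitions", {
  sp <- specimen("t", "x", 0.3,
                 segments_m = list(humerus = 1, ulna = 1, styliform = 1))
  r <- anatomical_ratios(sp)
  expect_equal(r$styliform_fraction, 1 / 3)
  expect_true(is.na(r$crural_index))  # absent segments give NA, not error
  expect_true(is.na(r$pi_digit_IV))

  # forelimb/femur under both definitions
  sp2 <- toy_specimen()
  r2 <- anatomical_ratios(sp2)
  seg <- sp2$segments_m
  expect_equal(r2$forelimb_femur,
               (seg$humerus + seg$ulna + seg$styliform) / seg$femur)
  r3 <- anatomical_ratios(sp2, include_manus = TRUE)
  expect_gt(r3$forelimb_femur, r2$forelimb_femur)
  expect_equal(r3$forelimb_femur,
               (seg$humerus + seg$ulna + seg$styliform +
                  seg$metacarpal_IV + seg$phalanges_IV) / seg$femur)
})

test_that("fixture skeletons reproduce the published comparative ratios", {
  fx <- builtin_fixtures()
  yi <- anatomical_ratios(get_specimen(fx, "STM 31-2"))
  am <- anatomical_ratios(get_specimen(fx, "IVPP V24192"))
  expect_equal(yi$styliform_fraction, 0.42, tolerance = 1e-3)
  expect_equal(am$styliform_fraction, 0.32, tolerance = 1e-3)
  expect_equal(yi$forelimb_femur, 4.65, tolerance = 1e-3)
  expect_equal(am$forelimb_femur, 4.65, tolerance = 1e-3)
  expect_equal(yi$dpc_fraction, 0.19, tolerance = 1e-3)
  expect_equal(am$dpc_fraction, 0.22, tolerance = 1e-3)
  expect_equal(yi$pi_digit_III, 1.7, tolerance = 1e-3)
  expect_equal(yi$pi_digit_IV, 4.35, tolerance = 1e-3)
  mi <- anatomical_ratios(get_specimen(fx, "BMNHC PH881"))
  ar <- anatomical_ratios(get_specimen(fx, "Berlin"))
  expect_equal(mi$dpc_fraction, 0.29, tolerance = 1e-2)
  expect_equal(ar$dpc_fraction, 0.34, tolerance = 1e-2)
  ep1 <- anatomical_ratios(get_specimen(fx, "IVPP V12653"))
  ep2 <- anatomical_ratios(get_specimen(fx, "IVPP V15471"))
  expect_equal(ep1$crural_index, 1.17, tolerance = 1e-3)
  expect_equal(ep2$crural_index, 1.25, tolerance = 1e-3)
})

test_that("zero-length denominators are rejected", {
  sp <- toy_specimen()
  sp$segments_m$femur <- 0
  # bypass constructor validation to hit the ratio-level check
  expect_error(anatomical_ratios(sp), "denominator")
})
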
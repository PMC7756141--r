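test_that("specimen validation enforces the type invariants", {
  expect_s3_class(toy_specimen(), "specimen")
  expect_error(specimen("t", "x", c(0.3, -0.1)), "positive")
  expect_error(specimen("t", "x", c(0.3, 0.3)), "duplicate")
  expect_error(specimen("t", "x", 0.3, flight_muscle_fraction = 0), "0, 1")
  expect_error(specimen("t", "x", 0.3, segments_m = list(femur = -1)),
               "femur")
  expect_error(
    specimen("t", "x", 0.3,
             wing_geometry = list(MFW = list(span_m = 1, area_m2 = 2))),
    "aspect ratio")
  # FRW is exempt from the aspect-ratio bound
  expect_s3_class(
    specimen("t", "x", 0.3,
             wing_geometry = list(FRW = list(span_m = 1, area_m2 = 2))),
    "specimen")
  # mass hypotheses come back sorted ascending
  expect_equal(specimen("t", "x", c(0.7, 0.38, 0.45))$mass_hypotheses_kg,
               c(0.38, 0.45, 0.7))
})

test_that("specimen tables reject duplicate ids", {
  expect_error(specimen_table(list(toy_specimen("A"), toy_specimen("A"))),
               "duplicate")
  expect_silent(specimen_table(list(toy_specimen("A"), toy_specimen("B"))))
})

test_that("write -> load round-trips losslessly in CSV and JSON", {
  sp1 <- specimen(
    "Testus exemplaris", "TX-1", c(0.123456789012345, 0.7),
    flight_muscle_fraction = 0.08,
    segments_m = list(humerus = 0.0812345678901, femur = 1 / 3),
    wing_geometry = list(MFW = list(span_m = 0.65, area_m2 = 0.0521),
                         BBW = list(span_m = 0.65, area_m2 = 0.0833)),
    geometry_source = "placeholder",
    notes = "free text survives",
    metadata = list(locality = "unit-test"))
  sp2 <- toy_specimen("TX-2", masses = c(0.2, 0.4))
  tbl <- specimen_table(list(sp1, sp2))
  for (fmt in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_specimens(tbl, path)
    back <- load_specimens(path)
    expect_length(back$rows, 2)
    for (i in 1:2) {
      a <- tbl$rows[[i]]; b <- back$rows[[i]]
      expect_identical(b$taxon, a$taxon)
      expect_identical(b$specimen_id, a$specimen_id)
      expect_equal(b$mass_hypotheses_kg, a$mass_hypotheses_kg,
                   tolerance = 1e-15)
      expect_equal(b$flight_muscle_fraction, a$flight_muscle_fraction)
      expect_equal(b$segments_m[order(names(b$segments_m))],
                   a$segments_m[order(names(a$segments_m))],
                   tolerance = 1e-15)
      expect_length(b$wing_geometry, length(a$wing_geometry))
      if (length(a$wing_geometry)) {
        expect_equal(b$wing_geometry[order(names(b$wing_geometry))],
                     a$wing_geometry[order(names(a$wing_geometry))],
                     tolerance = 1e-15)
      }
      expect_identical(b$geometry_source, a$geometry_source)
      expect_identical(b$notes, a$notes)
    }
    expect_identical(back$rows[[1]]$metadata$locality, "unit-test")
  }
})

test_that("loader errors name the missing field and the offending row", {
  path <- tempfile(fileext = ".csv")
  writeLines("taxon,specimen_id\nt,x", path)
  expect_error(load_specimens(path), "mass_kg_list")

  path2 <- tempfile(fileext = ".csv")
  writeLines(c("taxon,specimen_id,mass_kg_list,seg:femur_m",
               "t,ok,0.3,0.06", "t,bad,0.3,-0.06"), path2)
  expect_error(load_specimens(path2), "bad")
  expect_error(load_specimens(tempfile()), "not found")
})

test_that("a units comment line converts mm/g input to SI", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("# units: mm g",
               "taxon,specimen_id,mass_kg_list,seg:femur_m,wing:MFW_span_m,wing:MFW_area_m2",
               "t,U-1,380;450,65,700,60000"), path)
  tbl <- load_specimens(path)
  sp <- tbl$rows[[1]]
  expect_equal(sp$mass_hypotheses_kg, c(0.38, 0.45))
  expect_equal(sp$segments_m$femur, 0.065)
  expect_equal(sp$wing_geometry$MFW$span_m, 0.7)
  expect_equal(sp$wing_geometry$MFW$area_m2, 0.06)
})

test_that("built-in fixtures carry the published mass hypotheses", {
  fx <- builtin_fixtures()
  expect_equal(get_specimen(fx, "STM 31-2")$mass_hypotheses_kg,
               c(0.38, 0.45, 0.7))
  expect_equal(get_specimen(fx, "IVPP V24192")$mass_hypotheses_kg,
               c(0.23, 0.31, 0.38))
  expect_equal(get_specimen(fx, "Berlin")$mass_hypotheses_kg, 0.2)
  expect_equal(get_specimen(fx, "BMNHC PH881")$mass_hypotheses_kg,
               c(0.18, 0.24))
  expect_equal(get_specimen(fx, "IVPP V13352")$mass_hypotheses_kg,
               c(0.5, 0.95))
})

test_that("every fixture passes validation and is flagged placeholder", {
  fx <- builtin_fixtures()
  for (sp in fx$rows) {
    expect_silent(validate_specimen(sp))
    expect_identical(sp$geometry_source, "placeholder")
  }
  # round-trip of the whole fixture table is lossless
  path <- tempfile(fileext = ".csv")
  write_specimens(fx, path)
  back <- load_specimens(path)
  expect_equal(length(back$rows), length(fx$rows))
  expect_equal(get_specimen(back, "STM 31-2")$segments_m$styliform,
               get_specimen(fx, "STM 31-2")$segments_m$styliform,
               tolerance = 1e-15)
})

test_that("an override file replaces fixture geometry and marks it measured", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("taxon,specimen_id,mass_kg_list,wing:MFW_span_m,wing:MFW_area_m2",
               "Yi qi,STM 31-2,0.38;0.45;0.7,0.8,0.04"), path)
  fx <- builtin_fixtures(override_path = path)
  yi <- get_specimen(fx, "STM 31-2")
  expect_identical(yi$geometry_source, "measured")
  expect_equal(yi$wing_geometry$MFW$area_m2, 0.04)
  pf <- build_wing_model(yi, "MFW")
  expect_equal(pf$span_b_m, 0.8)
})
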
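#' Built-in specimen fixtures
#'
#' Returns the comparative set used throughout the package: the
#' membrane-winged scansoriopterygids *Yi qi* (STM 31-2) and *Ambopteryx
#' longibrachium*, the feathered paravians *Archaeopteryx* (Berlin) and
#' *Microraptor gui* (BMNHC PH881, IVPP V13352), plus the scansoriopterygid
#' outgroups *Epidendrosaurus* and *Epidexipteryx* used only for hindlimb
#' ratios.
#'
#' Body-mass hypotheses and muscle fractions are published values. Skeletal
#' segment lengths and wing geometry are \strong{placeholders}
#' (\code{geometry_source = "placeholder"}): they are constructed to honour
#' the published anatomical ratios (styliform fraction 0.42 in *Yi* vs 0.32
#' in *Ambopteryx*, forelimb = 4.65 femur lengths, deltopectoral crest
#' fractions 0.19/0.22/0.29/0.34, phalangeal indices 1.7 and 4.35 for *Yi*
#' digits III/IV, crural indices 1.17/1.25 for the outgroups) but are not
#' primary measurements. Supply real measurements with \code{override_path},
#' a CSV/JSON file in the [load_specimens()] dialect whose records replace
#' fixtures with matching \code{specimen_id} (and are marked
#' \code{"measured"}).
#'
#' @param override_path Optional path to a specimen file overriding fixture
#'   records by \code{specimen_id}.
#' @return A \code{specimen_table}.
#' @examples
#' fx <- builtin_fixtures()
#' fx$rows[[1]]$mass_hypotheses_kg
#' @export
builtin_fixtures <- function(override_path = NULL) {
  yi <- specimen(
    taxon = "Yi qi", specimen_id = "STM 31-2",
    mass_hypotheses_kg = c(0.38, 0.45, 0.7),
    flight_muscle_fraction = 0.10,
    segments_m = list(
      humerus = 0.0800, ulna = 0.095305, radius = 0.0877,
      styliform = 0.126945,
      metacarpal_III = 0.025, phalanges_III = 0.0425,
      metacarpal_IV = 0.028, phalanges_IV = 0.1218,
      dpc_length = 0.0152,
      femur = 0.065, tibia = 0.078, metatarsus = 0.036,
      hindlimb_total = 0.179, glenoid_height = 0.18),
    geometry_source = "placeholder",
    notes = paste("wrist-fold radiale angle ~40 deg (early-paravian model)",
                  "or ~50 deg (pennaraptoran model); metadata only"))

  ambo <- specimen(
    taxon = "Ambopteryx longibrachium", specimen_id = "IVPP V24192",
    mass_hypotheses_kg = c(0.23, 0.31, 0.38),
    flight_muscle_fraction = 0.10,
    segments_m = list(
      humerus = 0.0780, ulna = 0.086424, radius = 0.0795,
      styliform = 0.077376,
      metacarpal_III = 0.021, phalanges_III = 0.0336,
      metacarpal_IV = 0.024, phalanges_IV = 0.0960,
      dpc_length = 0.01716,
      femur = 0.052, tibia = 0.0634, metatarsus = 0.030,
      hindlimb_total = 0.1454, glenoid_height = 0.16),
    geometry_source = "placeholder",
    notes = "femur reduced relative to distal hindlimb")

  archaeo <- specimen(
    taxon = "Archaeopteryx", specimen_id = "Berlin",
    mass_hypotheses_kg = 0.2,
    flight_muscle_fraction = 0.10,
    segments_m = list(
      humerus = 0.063, ulna = 0.056, radius = 0.052,
      dpc_length = 0.02142,
      femur = 0.060, tibia = 0.074, metatarsus = 0.032,
      hindlimb_total = 0.166, glenoid_height = 0.17),
    wing_geometry = list(MFW = list(span_m = 0.58, area_m2 = 0.0479)),
    geometry_source = "placeholder",
    notes = "feathered forewing; explicit geometry placeholder")

  micro_small <- specimen(
    taxon = "Microraptor gui", specimen_id = "BMNHC PH881",
    mass_hypotheses_kg = c(0.18, 0.24),
    flight_muscle_fraction = 0.10,
    segments_m = list(
      humerus = 0.083, ulna = 0.073, radius = 0.069,
      dpc_length = 0.02407,
      femur = 0.097, tibia = 0.126, metatarsus = 0.058,
      hindlimb_total = 0.281, glenoid_height = 0.23),
    wing_geometry = list(MFW = list(span_m = 0.70, area_m2 = 0.0550)),
    geometry_source = "placeholder",
    notes = "feathered forewing; explicit geometry placeholder")

  micro_large <- specimen(
    taxon = "Microraptor gui", specimen_id = "IVPP V13352",
    mass_hypotheses_kg = c(0.5, 0.95),
    flight_muscle_fraction = 0.10,
    segments_m = list(
      humerus = 0.102, ulna = 0.092, radius = 0.087,
      dpc_length = 0.02958,
      femur = 0.122, tibia = 0.158, metatarsus = 0.071,
      hindlimb_total = 0.351, glenoid_height = 0.28),
    wing_geometry = list(MFW = list(span_m = 0.92, area_m2 = 0.1000)),
    geometry_source = "placeholder",
    notes = "feathered forewing; explicit geometry placeholder")

  epidendro <- specimen(
    taxon = "Epidendrosaurus ninchengensis", specimen_id = "IVPP V12653",
    mass_hypotheses_kg = 0.028,
    flight_muscle_fraction = 0.10,
    segments_m = list(femur = 0.0120, tibia = 0.01404),
    geometry_source = "placeholder",
    notes = "juvenile; hindlimb ratios only")

  epidex <- specimen(
    taxon = "Epidexipteryx hui", specimen_id = "IVPP V15471",
    mass_hypotheses_kg = 0.22,
    flight_muscle_fraction = 0.10,
    segments_m = list(femur = 0.0540, tibia = 0.0675),
    geometry_source = "placeholder",
    notes = "terrestrial clade member; hindlimb ratios only")

  tbl <- specimen_table(
    list(yi, ambo, archaeo, micro_small, micro_large, epidendro, epidex),
    provenance = list(source = "paleoflight built-in fixtures"))

  if (!is.null(override_path)) {
    ov <- load_specimens(override_path)
    by_id <- stats::setNames(ov$rows,
                             vapply(ov$rows, `[[`, character(1),
                                    "specimen_id"))
    rows <- lapply(tbl$rows, function(sp) {
      if (sp$specimen_id %in% names(by_id)) by_id[[sp$specimen_id]] else sp
    })
    extra <- by_id[setdiff(names(by_id),
                           vapply(tbl$rows, `[[`, character(1),
                                  "specimen_id"))]
    tbl <- specimen_table(c(rows, unname(extra)),
                          provenance = list(
                            source = "built-in fixtures + override",
                            override = ov$provenance))
  }
  tbl
}

#' Fetch one specimen from a table by id
#'
#' @param tbl A \code{specimen_table}.
#' @param specimen_id Identifier to look up.
#' @return A \code{specimen}.
#' @export
get_specimen <- function(tbl, specimen_id) {
  stopifnot(inherits(tbl, "specimen_table"))
  ids <- vapply(tbl$rows, `[[`, character(1), "specimen_id")
  i <- match(specimen_id, ids)
  if (is.na(i)) stop("no specimen with id '", specimen_id, "'", call. = FALSE)
  tbl$rows[[i]]
}
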
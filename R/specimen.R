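#' Construct a specimen record
#'
#' A specimen bundles everything the pipeline needs for one fossil or extant
#' individual: the taxon, the set of body-mass hypotheses, the flight-muscle
#' mass fraction, named skeletal segment lengths, and (optionally) explicit
#' wing geometry per wing model. All units are SI: metres and kilograms.
#'
#' @param taxon Taxon name.
#' @param specimen_id Unique specimen identifier.
#' @param mass_hypotheses_kg Numeric vector of body-mass hypotheses in kg;
#'   sorted ascending on construction, duplicates are an error.
#' @param flight_muscle_fraction Flight-muscle mass as a fraction of body
#'   mass, in (0, 1]. Default 0.10; 0.08 is the common conservative
#'   alternative.
#' @param segments_m Named list/vector of skeletal segment lengths in metres.
#'   Recognised names include \code{humerus}, \code{ulna}, \code{radius},
#'   \code{styliform}, \code{metacarpal_III}, \code{metacarpal_IV},
#'   \code{phalanges_III}, \code{phalanges_IV}, \code{dpc_length},
#'   \code{femur}, \code{tibia}, \code{metatarsus}, \code{hindlimb_total},
#'   \code{glenoid_height}.
#' @param wing_geometry Named list: per wing model (\code{MFW}, \code{BBW},
#'   \code{PTW}, \code{FRW}) a list with \code{span_m} and \code{area_m2}.
#'   When present it overrides the planform templates.
#' @param geometry_source \code{"measured"} or \code{"placeholder"}. Built-in
#'   fixtures use \code{"placeholder"} until real measurements are supplied.
#' @param notes Free-text metadata (e.g. wrist-fold model angles).
#' @param metadata Named list of extra fields preserved through round-trips.
#'
#' @return An object of class \code{specimen}.
#' @examples
#' sp <- specimen("Yi qi", "STM 31-2", c(0.38, 0.45, 0.7),
#'                segments_m = list(femur = 0.065, tibia = 0.078))
#' sp$mass_hypotheses_kg
#' @export
specimen <- function(taxon, specimen_id, mass_hypotheses_kg,
                     flight_muscle_fraction = 0.10,
                     segments_m = list(), wing_geometry = list(),
                     geometry_source = c("measured", "placeholder"),
                     notes = "", metadata = list()) {
  geometry_source <- match.arg(geometry_source)
  sp <- structure(
    list(taxon = as.character(taxon),
         specimen_id = as.character(specimen_id),
         mass_hypotheses_kg = sort(as.numeric(mass_hypotheses_kg)),
         flight_muscle_fraction = as.numeric(flight_muscle_fraction),
         segments_m = as.list(segments_m),
         wing_geometry = wing_geometry,
         geometry_source = geometry_source,
         notes = as.character(notes),
         metadata = metadata),
    class = "specimen")
  validate_specimen(sp)
  sp
}

#' Validate a specimen against its invariants
#'
#' Checks strict positivity of all masses and segment lengths, ascending
#' duplicate-free mass hypotheses, the muscle-fraction range, and that any
#' explicit wing geometry for the MFW/BBW/PTW models has aspect ratio > 1.
#'
#' @param sp A \code{specimen}.
#' @return The specimen, invisibly; errors describe the offending field.
#' @export
validate_specimen <- function(sp) {
  id <- sp$specimen_id
  fail <- function(...) stop("specimen '", id, "': ", ..., call. = FALSE)
  if (!nzchar(sp$taxon)) fail("taxon must be non-empty")
  if (!nzchar(id)) stop("specimen_id must be non-empty", call. = FALSE)
  m <- sp$mass_hypotheses_kg
  if (!length(m) || any(!is.finite(m)) || any(m <= 0)) {
    fail("mass_hypotheses_kg must be positive and finite")
  }
  if (anyDuplicated(m)) fail("duplicate mass hypotheses")
  if (is.unsorted(m)) fail("mass hypotheses must be sorted ascending")
  f <- sp$flight_muscle_fraction
  if (!is.finite(f) || f <= 0 || f > 1) {
    fail("flight_muscle_fraction must lie in (0, 1]")
  }
  segs <- unlist(sp$segments_m)
  if (length(segs)) {
    bad <- names(segs)[!is.finite(segs) | segs <= 0]
    if (length(bad)) fail("non-positive segment length(s): ",
                          paste(bad, collapse = ", "))
  }
  for (mod in names(sp$wing_geometry)) {
    wg <- sp$wing_geometry[[mod]]
    if (is.null(wg$span_m) || is.null(wg$area_m2)) {
      fail("wing_geometry for ", mod, " needs span_m and area_m2")
    }
    if (wg$span_m <= 0 || wg$area_m2 <= 0) {
      fail("wing_geometry for ", mod, " must be positive")
    }
    if (mod %in% c("MFW", "BBW", "PTW") && wg$area_m2 >= wg$span_m^2) {
      fail("wing_geometry for ", mod, " implies aspect ratio <= 1")
    }
  }
  invisible(sp)
}

#' @export
print.specimen <- function(x, ...) {
  cat("<specimen> ", x$taxon, " [", x$specimen_id, "]\n", sep = "")
  cat("  masses (kg): ", paste(x$mass_hypotheses_kg, collapse = ", "),
      "; muscle fraction ", x$flight_muscle_fraction, "\n", sep = "")
  cat("  segments:", length(x$segments_m), " wing models:",
      if (length(x$wing_geometry)) paste(names(x$wing_geometry),
                                         collapse = ", ") else "(templates)",
      " geometry:", x$geometry_source, "\n")
  invisible(x)
}

#' Construct a specimen table
#'
#' @param specimens List of \code{specimen} objects.
#' @param provenance Optional list describing the source (path, checksum).
#' @return An object of class \code{specimen_table}.
#' @export
specimen_table <- function(specimens, provenance = list(source = "in-memory")) {
  stopifnot(is.list(specimens))
  for (sp in specimens) {
    if (!inherits(sp, "specimen")) stop("all elements must be specimens",
                                        call. = FALSE)
    validate_specimen(sp)
  }
  ids <- vapply(specimens, `[[`, character(1), "specimen_id")
  if (anyDuplicated(ids)) {
    stop("duplicate specimen_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(rows = specimens, provenance = provenance),
            class = "specimen_table")
}

#' @export
print.specimen_table <- function(x, ...) {
  cat("<specimen_table> ", length(x$rows), " specimen(s)\n", sep = "")
  for (sp in x$rows) {
    cat("  - ", sp$taxon, " [", sp$specimen_id, "]  masses: ",
        paste(sp$mass_hypotheses_kg, collapse = "/"), " kg\n", sep = "")
  }
  invisible(x)
}

#' @export
length.specimen_table <- function(x) length(x$rows)

#' Turn a specimen table into a wide tibble
#'
#' One row per specimen, using the package CSV dialect column names
#' (\code{mass_kg_list} semicolon-separated, \code{seg:<name>_m},
#' \code{wing:<MODEL>_span_m} / \code{_area_m2}).
#'
#' @param tbl A \code{specimen_table}.
#' @return A tibble.
#' @export
specimens_as_tibble <- function(tbl) {
  stopifnot(inherits(tbl, "specimen_table"))
  rows <- lapply(tbl$rows, function(sp) {
    base <- list(
      taxon = sp$taxon,
      specimen_id = sp$specimen_id,
      mass_kg_list = paste(format(sp$mass_hypotheses_kg, digits = 17,
                                  trim = TRUE, scientific = FALSE),
                           collapse = ";"),
      muscle_fraction = sp$flight_muscle_fraction,
      geometry_source = sp$geometry_source,
      notes = sp$notes)
    for (nm in names(sp$segments_m)) {
      base[[paste0("seg:", nm, "_m")]] <- as.numeric(sp$segments_m[[nm]])
    }
    for (mod in names(sp$wing_geometry)) {
      base[[paste0("wing:", mod, "_span_m")]] <- sp$wing_geometry[[mod]]$span_m
      base[[paste0("wing:", mod, "_area_m2")]] <- sp$wing_geometry[[mod]]$area_m2
    }
    for (nm in names(sp$metadata)) base[[nm]] <- sp$metadata[[nm]]
    tibble::as_tibble(base)
  })
  dplyr::bind_rows(rows)
}

required_cols <- c("taxon", "specimen_id", "mass_kg_list")

row_to_specimen <- function(row) {
  nms <- names(row)
  seg_cols <- grep("^seg:.*_m$", nms, value = TRUE)
  wing_cols <- grep("^wing:(MFW|BBW|PTW|FRW)_(span_m|area_m2)$", nms,
                    value = TRUE)
  known <- c(required_cols, "muscle_fraction", "geometry_source", "notes",
             seg_cols, wing_cols)
  segments <- list()
  for (cl in seg_cols) {
    v <- row[[cl]]
    if (!is.na(v)) segments[[sub("^seg:(.*)_m$", "\\1", cl)]] <- as.numeric(v)
  }
  wg <- list()
  for (cl in wing_cols) {
    v <- row[[cl]]
    if (is.na(v)) next
    mod <- sub("^wing:([A-Z]+)_.*$", "\\1", cl)
    part <- sub("^wing:[A-Z]+_(span_m|area_m2)$", "\\1", cl)
    if (is.null(wg[[mod]])) wg[[mod]] <- list()
    wg[[mod]][[part]] <- as.numeric(v)
  }
  meta <- row[setdiff(nms, known)]
  meta <- meta[!vapply(meta, function(v) length(v) == 1 && is.na(v),
                       logical(1))]
  specimen(
    taxon = row$taxon,
    specimen_id = row$specimen_id,
    mass_hypotheses_kg = as.numeric(strsplit(as.character(row$mass_kg_list),
                                             ";")[[1]]),
    flight_muscle_fraction = if (!is.null(row$muscle_fraction) &&
                                 !is.na(row$muscle_fraction))
      as.numeric(row$muscle_fraction) else 0.10,
    segments_m = segments,
    wing_geometry = wg,
    geometry_source = if (!is.null(row$geometry_source) &&
                          !is.na(row$geometry_source))
      row$geometry_source else "measured",
    notes = if (!is.null(row$notes) && !is.na(row$notes)) row$notes else "",
    metadata = as.list(meta))
}

#' Load specimens from CSV or JSON
#'
#' Reads the package specimen dialect: one record per specimen with columns
#' \code{taxon}, \code{specimen_id}, \code{mass_kg_list}
#' (semicolon-separated), optional \code{muscle_fraction},
#' \code{geometry_source}, \code{notes}, \code{seg:<name>_m} segment lengths
#' and \code{wing:<MODEL>_span_m} / \code{wing:<MODEL>_area_m2} geometry.
#' Unknown columns are preserved as per-specimen metadata. A leading comment
#' line such as \code{# units: mm g} declares millimetre/gram inputs, which
#' are converted to metres and kilograms on load.
#'
#' @param path File path.
#' @param format \code{"csv"} or \code{"json"}; default guessed from the
#'   extension.
#' @return A \code{specimen_table}; its \code{provenance} records the path
#'   and an MD5 checksum.
#' @export
load_specimens <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  scale_len <- 1; scale_mass <- 1
  if (format == "csv") {
    first <- readLines(path, n = 1)
    if (startsWith(first, "#")) {
      toks <- strsplit(tolower(first), "[^a-z]+")[[1]]
      if ("mm" %in% toks) scale_len <- 1e-3
      if ("g" %in% toks && !"kg" %in% toks) scale_mass <- 1e-3
    }
    df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  } else {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (!is.null(recs$units)) {
      if (identical(recs$units$length, "mm")) scale_len <- 1e-3
      if (identical(recs$units$mass, "g")) scale_mass <- 1e-3
      recs <- recs$specimens
    }
    df <- tibble::as_tibble(recs)
  }
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("missing required field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  specs <- lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, ])
    seg_cols <- grep("^seg:.*_m$", names(row), value = TRUE)
    for (cl in seg_cols) row[[cl]] <- row[[cl]] * scale_len
    wspan <- grep("^wing:.*_span_m$", names(row), value = TRUE)
    for (cl in wspan) row[[cl]] <- row[[cl]] * scale_len
    warea <- grep("^wing:.*_area_m2$", names(row), value = TRUE)
    for (cl in warea) row[[cl]] <- row[[cl]] * scale_len^2
    if (scale_mass != 1) {
      row$mass_kg_list <- paste(
        as.numeric(strsplit(as.character(row$mass_kg_list), ";")[[1]]) *
          scale_mass,
        collapse = ";")
    }
    tryCatch(row_to_specimen(row), error = function(e) {
      stop("row ", i, " (", row$specimen_id, "): ", conditionMessage(e),
           call. = FALSE)
    })
  })
  specimen_table(specs, provenance = list(source = normalizePath(path),
                                          md5 = unname(tools::md5sum(path))))
}

#' Write specimens to CSV or JSON
#'
#' Inverse of [load_specimens()]; the written file round-trips losslessly at
#' full double precision.
#'
#' @param tbl A \code{specimen_table}.
#' @param path Output path.
#' @param format \code{"csv"} or \code{"json"}; default guessed from the
#'   extension.
#' @return \code{path}, invisibly.
#' @export
write_specimens <- function(tbl, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(tbl, "specimen_table"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- specimens_as_tibble(tbl)
  if (format == "csv") {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}
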
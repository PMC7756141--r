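#' Polygon area by the shoelace formula
#'
#' @param xy Two-column numeric matrix of vertices in order (open ring).
#' @return Absolute enclosed area.
#' @export
polygon_area <- function(xy) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 3)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Construct a wing planform object
#'
#' @param model Wing model id: \code{"MFW"} (maniraptoran forewing-only),
#'   \code{"BBW"} (bat-like fore+hindwing), \code{"PTW"} (pterosaur-like) or
#'   \code{"FRW"} (frog-like interdigital webbing).
#' @param span_b_m Full wingspan in m.
#' @param area_S_m2 Total lifting area (both wings plus any body strip), m^2.
#' @return An object of class \code{wing_planform} with fields \code{model},
#'   \code{span_b_m}, \code{area_S_m2} and \code{aspect_ratio_Ra}
#'   (= span^2 / area).
#' @examples
#' wing_planform("MFW", span_b_m = 1, area_m2 = 0.1)$aspect_ratio_Ra
#' @export
wing_planform <- function(model, span_b_m, area_m2) {
  model <- match.arg(model, c("MFW", "BBW", "PTW", "FRW"))
  if (!is.finite(span_b_m) || span_b_m <= 0) {
    stop("span_b_m must be positive", call. = FALSE)
  }
  if (!is.finite(area_m2) || area_m2 <= 0) {
    stop("area_m2 must be positive", call. = FALSE)
  }
  structure(list(model = model,
                 span_b_m = span_b_m,
                 area_S_m2 = area_m2,
                 aspect_ratio_Ra = span_b_m^2 / area_m2),
            class = "wing_planform")
}

#' @export
print.wing_planform <- function(x, ...) {
  cat(sprintf("<wing_planform> %s: b = %.3f m, S = %.4f m^2, Ra = %.2f\n",
              x$model, x$span_b_m, x$area_S_m2, x$aspect_ratio_Ra))
  invisible(x)
}

# Half-wing planform polygon template for one wing model.
# Coordinates: x spanwise from the glenoid toward the wingtip, y chordwise
# (negative posterior). The extended arm forms the leading edge; the
# styliform element sweeps posteriorly from the wrist; BBW/PTW deepen the
# root trailing edge toward a hindlimb (ankle) anchor; FRW keeps only the
# webbing distal to the wrist.
planform_polygon <- function(spec, model, config = aero_config()) {
  seg <- spec$segments_m
  need <- c("humerus", "ulna", "styliform", "metacarpal_IV", "phalanges_IV")
  if (model %in% c("BBW", "PTW")) need <- c(need, "hindlimb_total")
  missing <- setdiff(need, names(seg))
  if (length(missing)) {
    stop("specimen '", spec$specimen_id, "': planform template ", model,
         " needs missing segment(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  h <- seg$humerus; u <- seg$ulna; s <- seg$styliform
  tip_x <- h + u + seg$metacarpal_IV + seg$phalanges_IV
  a <- config$styliform_angle_deg * pi / 180
  sty <- c(h + u + s * cos(a), -s * sin(a))
  c_root <- s * sin(a)
  trail_depth <- switch(model,
    MFW = c_root,
    BBW = c_root + config$bbw_leg_frac * seg$hindlimb_total,
    PTW = c_root + config$ptw_leg_frac * seg$hindlimb_total,
    FRW = NA_real_)
  if (model == "FRW") {
    poly <- rbind(c(h + u, 0), c(tip_x, 0), sty)
  } else {
    poly <- rbind(c(0, 0), c(h, 0), c(h + u, 0), c(tip_x, 0), sty,
                  c(0, -trail_depth))
  }
  attr(poly, "halfspan") <- tip_x
  poly
}

#' Build a wing planform for a specimen
#'
#' If the specimen carries explicit \code{wing_geometry} for the requested
#' model it is passed through unchanged. Otherwise the planform is built
#' from the documented segment-anchored polygon template (glenoid, elbow,
#' wrist, styliform tip, digit IV tip; ankle anchor for BBW/PTW; webbing
#' only for FRW): the half-wing polygon area is computed by the shoelace
#' formula and doubled, a body strip (body width times mean chord) is added
#' for all models except FRW, and the span is twice the glenoid-to-wingtip
#' extent plus the body width.
#'
#' @param spec A \code{specimen}.
#' @param model Wing model id (\code{"MFW"}, \code{"BBW"}, \code{"PTW"},
#'   \code{"FRW"}).
#' @param config An [aero_config()].
#' @return A \code{wing_planform}.
#' @export
build_wing_model <- function(spec, model, config = aero_config()) {
  model <- match.arg(model, c("MFW", "BBW", "PTW", "FRW"))
  stopifnot(inherits(spec, "specimen"))
  wg <- spec$wing_geometry[[model]]
  if (!is.null(wg)) {
    return(wing_planform(model, wg$span_m, wg$area_m2))
  }
  poly <- planform_polygon(spec, model, config)
  halfspan <- attr(poly, "halfspan")
  half_area <- polygon_area(poly)
  body_width <- config$body_width_frac * halfspan
  span <- 2 * halfspan + body_width
  area <- 2 * half_area
  if (model != "FRW") {
    mean_chord <- half_area / halfspan
    area <- area + body_width * mean_chord
  }
  wing_planform(model, span, area)
}

#' Wing loading and threshold classification
#'
#' Wing loading is body weight per unit lifting area, \eqn{W/S = m g / S}
#' in N m^-2. Two inclusive thresholds are applied: flight of any kind is
#' considered possible at or below 245 N m^-2, and the extant-glider
#' envelope spans 9 to 143 N m^-2.
#'
#' @param mass_kg Body mass, kg.
#' @param planform A \code{wing_planform}.
#' @param g Gravitational acceleration, default 9.81.
#' @return A list with \code{wing_loading_N_m2}, \code{flight_possible} and
#'   \code{in_glider_envelope}.
#' @examples
#' pf <- wing_planform("MFW", 1, 0.1)
#' wing_loading(0.4, pf)$wing_loading_N_m2
#' @export
wing_loading <- function(mass_kg, planform, g = 9.81) {
  if (!is.finite(mass_kg) || mass_kg <= 0) {
    stop("mass_kg must be positive", call. = FALSE)
  }
  stopifnot(inherits(planform, "wing_planform"))
  wl <- mass_kg * g / planform$area_S_m2
  list(wing_loading_N_m2 = wl,
       flight_possible = wl <= 245,
       in_glider_envelope = wl >= 9 && wl <= 143)
}

#' Anatomical ratios of a specimen
#'
#' Computes the dimensionless skeletal indices used to compare
#' membrane-winged scansoriopterygids with paravians and with each other.
#' Each ratio is computed independently from the segments available; a
#' ratio whose segments are absent is returned as \code{NA} rather than an
#' error. A zero-length denominator is an error.
#'
#' @param spec A \code{specimen}.
#' @param include_manus Should the forelimb/femur ratio include the manus
#'   (metacarpal IV + digit IV phalanges)? Default \code{FALSE}: the
#'   forelimb is humerus + ulna + styliform.
#' @return A tibble with one row:
#'   \describe{
#'     \item{styliform_fraction}{styliform / (humerus + ulna + styliform).}
#'     \item{dpc_fraction}{deltopectoral crest length / humerus.}
#'     \item{forelimb_femur}{forelimb length / femur.}
#'     \item{crural_index}{tibia / femur.}
#'     \item{pi_digit_III, pi_digit_IV}{phalangeal index per digit: summed
#'       non-ungual phalanx lengths / metacarpal length.}
#'   }
#' @export
anatomical_ratios <- function(spec, include_manus = FALSE) {
  stopifnot(inherits(spec, "specimen"))
  seg <- spec$segments_m
  gets <- function(nm) if (is.null(seg[[nm]])) NA_real_ else seg[[nm]]
  ratio <- function(num, den) {
    if (is.na(num) || is.na(den)) return(NA_real_)
    if (den == 0) stop("specimen '", spec$specimen_id,
                       "': zero-length denominator", call. = FALSE)
    num / den
  }
  h <- gets("humerus"); u <- gets("ulna"); s <- gets("styliform")
  forelimb <- h + u + s
  if (include_manus) {
    forelimb <- forelimb + gets("metacarpal_IV") + gets("phalanges_IV")
  }
  tibble::tibble(
    specimen_id = spec$specimen_id,
    taxon = spec$taxon,
    styliform_fraction = ratio(s, h + u + s),
    dpc_fraction = ratio(gets("dpc_length"), h),
    forelimb_femur = ratio(forelimb, gets("femur")),
    crural_index = ratio(gets("tibia"), gets("femur")),
    pi_digit_III = ratio(gets("phalanges_III"), gets("metacarpal_III")),
    pi_digit_IV = ratio(gets("phalanges_IV"), gets("metacarpal_IV")))
}

#' Tidy wing-loading report
#'
#' One row per (specimen, mass hypothesis, wing model) combination with the
#' wing loading and its threshold classification.
#'
#' @param tbl A \code{specimen_table}.
#' @param models Wing models to evaluate; models whose template anchors are
#'   missing for a specimen are skipped for that specimen.
#' @param config An [aero_config()].
#' @return A tibble.
#' @export
loading_table <- function(tbl, models = c("MFW", "BBW", "PTW", "FRW"),
                          config = aero_config()) {
  stopifnot(inherits(tbl, "specimen_table"))
  out <- list()
  for (sp in tbl$rows) {
    for (mod in models) {
      pf <- tryCatch(build_wing_model(sp, mod, config), error = function(e) NULL)
      if (is.null(pf)) next
      for (m in sp$mass_hypotheses_kg) {
        cls <- wing_loading(m, pf, config$g_m_s2)
        out[[length(out) + 1]] <- tibble::tibble(
          taxon = sp$taxon, specimen_id = sp$specimen_id, model = mod,
          mass_kg = m, span_m = pf$span_b_m, area_m2 = pf$area_S_m2,
          aspect_ratio = pf$aspect_ratio_Ra,
          wing_loading_N_m2 = cls$wing_loading_N_m2,
          flight_possible = cls$flight_possible,
          in_glider_envelope = cls$in_glider_envelope,
          geometry_source = sp$geometry_source)
      }
    }
  }
  dplyr::bind_rows(out)
}
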
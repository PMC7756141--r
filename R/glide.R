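#' Sink speed in equilibrium glide
#'
#' Under the shallow-glide approximation (lift approximately equal to
#' weight, valid for glide ratios well above 1) the sink rate at airspeed
#' V is \eqn{V_s(V) = V D(V) / (m g)} with total drag
#' \deqn{D = \frac{k (m g)^2}{\tfrac12 \rho V^2 \pi b^2}
#'   + \tfrac12 \rho V^2 S_b C_{d,b}
#'   + \tfrac12 \rho V^2 S \, C_{d,pro}}
#' (induced, body and wing-profile drag), where the wing profile drag
#' coefficient is \code{profile_glide_scale * Cpro / Ra}.
#'
#' @param V Airspeed, m/s (vectorised, positive).
#' @param mass_kg Body mass, kg.
#' @param planform A \code{wing_planform}.
#' @param config An [aero_config()].
#' @param Cd_body Body drag coefficient; default the middle configured
#'   value.
#' @return Sink speed, m/s.
#' @export
glide_sink <- function(V, mass_kg, planform, config = aero_config(),
                       Cd_body = config$Cd_body_set[2]) {
  if (any(!is.finite(V)) || any(V <= 0)) {
    stop("airspeed V must be positive", call. = FALSE)
  }
  V * glide_drag(V, mass_kg, planform, config, Cd_body) /
    (mass_kg * config$g_m_s2)
}

glide_drag <- function(V, mass_kg, planform, config, Cd_body) {
  W <- mass_kg * config$g_m_s2
  rho <- config$rho_air_kg_m3
  Cd_pro <- config$profile_glide_scale * config$Cpro /
    planform$aspect_ratio_Ra
  ind <- config$k_induced * W^2 / (0.5 * rho * V^2 * pi * planform$span_b_m^2)
  par <- 0.5 * rho * V^2 * frontal_area(mass_kg, config) * Cd_body
  pro <- 0.5 * rho * V^2 * planform$area_S_m2 * Cd_pro
  ind + par + pro
}

#' Best glide and minimum sink
#'
#' The best glide speed maximises the glide ratio (horizontal distance per
#' unit height lost, \eqn{V / V_s}, equivalently minimises total drag) and
#' the minimum-sink speed minimises \eqn{V_s} itself. Both are found by
#' bounded Brent search after a coarse-grid unimodality check; the banked
#' turn radius at the configured bank angle completes the solution.
#'
#' @param mass_kg Body mass, kg.
#' @param planform A \code{wing_planform}.
#' @param config An [aero_config()].
#' @param Cd_body Body drag coefficient; default the middle configured
#'   value.
#' @return An object of class \code{glide_solution}: a list with
#'   \code{V_bestglide_m_s}, \code{sink_at_bestglide_m_s},
#'   \code{glide_ratio}, \code{V_minsink_m_s}, \code{sink_min_m_s},
#'   \code{turn_radius_m}, \code{bank_angle_deg}.
#' @examples
#' best_glide(0.38, wing_planform("MFW", 0.7, 0.06))
#' @export
best_glide <- function(mass_kg, planform, config = aero_config(),
                       Cd_body = config$Cd_body_set[2]) {
  stopifnot(mass_kg > 0, inherits(planform, "wing_planform"))
  drag <- function(V) glide_drag(V, mass_kg, planform, config, Cd_body)
  sink <- function(V) glide_sink(V, mass_kg, planform, config, Cd_body)
  check_unimodal(drag, config, what = "glide drag polar")
  opt_bg <- stats::optimize(drag, c(config$v_min_m_s, config$v_max_m_s),
                            tol = config$opt_rel_tol)
  check_unimodal(sink, config, what = "sink polar")
  opt_ms <- stats::optimize(sink, c(config$v_min_m_s, config$v_max_m_s),
                            tol = config$opt_rel_tol)
  V_bg <- opt_bg$minimum
  ratio <- mass_kg * config$g_m_s2 / opt_bg$objective
  structure(list(
    V_bestglide_m_s = V_bg,
    sink_at_bestglide_m_s = V_bg / ratio,
    glide_ratio = ratio,
    V_minsink_m_s = opt_ms$minimum,
    sink_min_m_s = opt_ms$objective,
    turn_radius_m = turn_radius(mass_kg, planform, config),
    bank_angle_deg = config$bank_deg),
    class = "glide_solution")
}

#' @export
print.glide_solution <- function(x, ...) {
  cat(sprintf(paste0("<glide_solution> best glide %.2f m/s (sink %.2f m/s,",
                     " ratio %.2f); min sink %.2f m/s at %.2f m/s;",
                     " turn radius %.2f m at %g deg bank\n"),
              x$V_bestglide_m_s, x$sink_at_bestglide_m_s, x$glide_ratio,
              x$sink_min_m_s, x$V_minsink_m_s, x$turn_radius_m,
              x$bank_angle_deg))
  invisible(x)
}

#' Stall-limited banked-turn radius
#'
#' \deqn{r = \frac{2 n (m/S)}{\rho \, C_{l,max} \tan\phi}}
#' with load factor \eqn{n = 1/\cos\phi} when
#' \code{config$banked_load_factor} is TRUE (default), else \eqn{n = 1}.
#' The radius depends on wing loading, the maximum lift coefficient and
#' the bank angle only; it is independent of any drag coefficient.
#'
#' @param mass_kg Body mass, kg.
#' @param planform A \code{wing_planform}.
#' @param config An [aero_config()].
#' @param Cl_max Maximum lift coefficient; default
#'   \code{config$Cl_max_turn}.
#' @param bank_deg Bank angle in degrees, strictly between 0 and 90;
#'   default \code{config$bank_deg} (24).
#' @return Turn radius, m.
#' @export
turn_radius <- function(mass_kg, planform, config = aero_config(),
                        Cl_max = config$Cl_max_turn,
                        bank_deg = config$bank_deg) {
  stopifnot(mass_kg > 0, inherits(planform, "wing_planform"), Cl_max > 0)
  if (bank_deg <= 0 || bank_deg >= 90) {
    stop("bank_deg must lie strictly between 0 and 90", call. = FALSE)
  }
  phi <- bank_deg * pi / 180
  n <- if (config$banked_load_factor) 1 / cos(phi) else 1
  2 * n * (mass_kg / planform$area_S_m2) /
    (config$rho_air_kg_m3 * Cl_max * tan(phi))
}

#' Height lost per unit horizontal distance
#'
#' The reciprocal of the glide ratio: how many metres of height an
#' equilibrium glide spends per metre travelled.
#'
#' @param glide_ratio Glide ratio (> 0).
#' @return Dimensionless height loss per distance.
#' @examples
#' height_loss_per_distance(13.3)
#' @export
height_loss_per_distance <- function(glide_ratio) {
  stopifnot(all(glide_ratio > 0))
  1 / glide_ratio
}

#' Gliding comparison table
#'
#' One row per (specimen, wing model, mass, Cd): best glide speed, sink at
#' best glide, glide ratio and banked-turn radius, for each configured
#' body drag coefficient in \code{Cd_set}.
#'
#' @param tbl A \code{specimen_table}.
#' @param models Wing models to evaluate.
#' @param config An [aero_config()].
#' @param Cd_set Body drag coefficients; default \code{c(0.4, 0.5)}.
#' @return A tibble.
#' @export
glide_table <- function(tbl, models = c("MFW", "BBW"),
                        config = aero_config(), Cd_set = c(0.4, 0.5)) {
  stopifnot(inherits(tbl, "specimen_table"))
  rows <- list()
  for (sp in tbl$rows) {
    for (mod in models) {
      pf <- tryCatch(build_wing_model(sp, mod, config), error = function(e) NULL)
      if (is.null(pf)) next
      for (m in sp$mass_hypotheses_kg) {
        for (cd in Cd_set) {
          gs <- best_glide(m, pf, config, cd)
          rows[[length(rows) + 1]] <- tibble::tibble(
            taxon = sp$taxon, specimen_id = sp$specimen_id, model = mod,
            mass_kg = m, Cd_body = cd,
            glide_m_s = gs$V_bestglide_m_s,
            sink_m_s = gs$sink_at_bestglide_m_s,
            glide_ratio = gs$glide_ratio,
            radius_m = gs$turn_radius_m)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}
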
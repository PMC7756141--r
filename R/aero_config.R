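#' Aerodynamic model configuration
#'
#' Collects the environmental constants, aerodynamic coefficients and
#' behavioural model parameters used throughout the pipeline. Every value can
#' be overridden by name; the defaults are documented below and in the methods
#' vignette.
#'
#' @param ... Named overrides of any default listed in Details.
#'
#' @details
#' Environment and airframe:
#' \describe{
#'   \item{rho_air_kg_m3}{Air density, default 1.225 (sea-level ISA).}
#'   \item{g_m_s2}{Gravitational acceleration, default 9.81.}
#'   \item{k_induced}{Induced-power factor, default 1.2.}
#'   \item{Cd_body_set}{Body drag coefficients evaluated in reports,
#'     default \code{c(0.1, 0.4, 0.5)}.}
#'   \item{Cl_set}{Lift coefficients evaluated in take-off reports,
#'     default \code{c(1.0, 1.5)}.}
#'   \item{Cpro}{Profile-power constant, divided by aspect ratio, default 8.4.}
#'   \item{frontal_area_coeff, frontal_area_exp}{Body frontal area allometry
#'     \eqn{S_b = a m^c} in m^2, defaults 0.00813 and 0.666.}
#' }
#' Muscle performance:
#' \describe{
#'   \item{muscle_power_coeff_W_kg, muscle_power_exp}{Mass-specific burst
#'     power of flight muscle, \eqn{s(m) = a m^c} W per kg muscle; defaults
#'     107.2215 and -0.2598293, a log-log least-squares calibration against
#'     reference burst-flyer power outputs (see vignette).}
#'   \item{lift_capacity_coeff_N_kg, lift_capacity_exp}{Burst lift capacity
#'     per kg of flight muscle, \eqn{c(m) = a m^e} N/kg; defaults 84 and
#'     -0.2598293 (provisional, see vignette).}
#' }
#' Flapping:
#' \describe{
#'   \item{wingbeat_model}{"bird" or "bat".}
#'   \item{freq_coeff_bird, freq_coeff_bat}{Leading constants of the
#'     allometric wingbeat frequency
#'     \eqn{f = C m^{3/8} g^{1/2} b^{-23/24} S^{-1/3} \rho^{-3/8}};
#'     defaults 1.08 and 0.80.}
#'   \item{flap_amplitude_rad}{Total stroke arc, default \code{pi/3}
#'     (a restricted, non-paravian shoulder).}
#'   \item{stroke_plane_deg}{Stroke-plane angle from horizontal, default 60;
#'     the forward thrust fraction of flap force is \code{cos} of this.}
#'   \item{Cl_flap}{Lift coefficient during flap-running, default 2.0.}
#' }
#' Gliding and turning:
#' \describe{
#'   \item{profile_glide_scale}{Wing profile drag coefficient in glide is
#'     \code{profile_glide_scale * Cpro / aspect_ratio}; default 0.012.}
#'   \item{Cl_max_turn}{Maximum lift coefficient limiting the banked turn,
#'     default 1.5.}
#'   \item{bank_deg}{Default bank angle, 24 degrees.}
#'   \item{banked_load_factor}{If TRUE (default) the turn uses load factor
#'     \eqn{n = 1/\cos\phi}; FALSE forces \eqn{n = 1}.}
#' }
#' Terrestrial locomotion:
#' \describe{
#'   \item{sprint_a, sprint_p, sprint_q}{Sprint speed allometry
#'     \eqn{v = a L^p m^q} with L the total hindlimb length in m; defaults
#'     11.9, 0.5, 0 (a Froude-number-16 ceiling on hip height, taken as
#'     0.9 L).}
#'   \item{hip_height_frac}{Hip height as a fraction of hindlimb length,
#'     default 0.9.}
#'   \item{leap_coeff}{Ballistic launch speed \eqn{v = c\sqrt{g h_{hip}}},
#'     default 1.41 (jump height roughly equal to hip height).}
#'   \item{leg_accel_m_s2}{Peak leg-drive acceleration at standstill,
#'     default 9.81, decaying linearly to zero at the sprint ceiling.}
#'   \item{dt_s, horizon_s}{Flap-run integration step and horizon, defaults
#'     0.01 and 20 s.}
#'   \item{wair_ref_speed_m_s}{Reference running speed for WAIR evaluation,
#'     default 1.5 (juvenile-chukar-like).}
#'   \item{wair_level1_frac, wair_level2_frac}{Lift fractions of body weight
#'     delimiting WAIR levels I and II, defaults 0.06 and 0.5 (provisional).}
#' }
#' Planform templates:
#' \describe{
#'   \item{styliform_angle_deg}{Posterior sweep of the styliform element from
#'     the spanwise axis, default 60.}
#'   \item{body_width_frac}{Body width as a fraction of half-span, default
#'     0.15; used for the span and the central body strip.}
#'   \item{bbw_leg_frac, ptw_leg_frac}{Posterior reach of the hindlimb
#'     membrane anchor as a fraction of hindlimb length for the bat-like and
#'     pterosaur-like models, defaults 0.75 and 0.6.}
#' }
#' Numerics:
#' \describe{
#'   \item{v_min_m_s, v_max_m_s}{Airspeed bracket for 1-D optimisation,
#'     defaults 0.1 and 100.}
#'   \item{opt_rel_tol}{Relative tolerance of the optimiser, default 1e-6.}
#'   \item{grid_n}{Coarse-grid size for the unimodality check, default 1000.}
#' }
#'
#' @return An object of class \code{aero_config} (a named list).
#' @examples
#' cfg <- aero_config(rho_air_kg_m3 = 1.1)
#' cfg$rho_air_kg_m3
#' @export
aero_config <- function(...) {
  defaults <- list(
    rho_air_kg_m3 = 1.225,
    g_m_s2 = 9.81,
    k_induced = 1.2,
    Cd_body_set = c(0.1, 0.4, 0.5),
    Cl_set = c(1.0, 1.5),
    Cpro = 8.4,
    frontal_area_coeff = 0.00813,
    frontal_area_exp = 0.666,
    muscle_power_coeff_W_kg = 107.2215,
    muscle_power_exp = -0.2598293,
    lift_capacity_coeff_N_kg = 84,
    lift_capacity_exp = -0.2598293,
    wingbeat_model = "bird",
    freq_coeff_bird = 1.08,
    freq_coeff_bat = 0.80,
    flap_amplitude_rad = pi / 3,
    stroke_plane_deg = 60,
    Cl_flap = 2.0,
    profile_glide_scale = 0.012,
    Cl_max_turn = 1.5,
    bank_deg = 24,
    banked_load_factor = TRUE,
    sprint_a = 11.9,
    sprint_p = 0.5,
    sprint_q = 0,
    hip_height_frac = 0.9,
    leap_coeff = 1.41,
    leg_accel_m_s2 = 9.81,
    dt_s = 0.01,
    horizon_s = 20,
    wair_ref_speed_m_s = 1.5,
    wair_level1_frac = 0.06,
    wair_level2_frac = 0.5,
    styliform_angle_deg = 60,
    body_width_frac = 0.15,
    bbw_leg_frac = 0.75,
    ptw_leg_frac = 0.6,
    v_min_m_s = 0.1,
    v_max_m_s = 100,
    opt_rel_tol = 1e-6,
    grid_n = 1000
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown aero_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(defaults, overrides)

  positive <- c("rho_air_kg_m3", "g_m_s2", "k_induced", "Cpro",
                "frontal_area_coeff", "frontal_area_exp",
                "muscle_power_coeff_W_kg", "lift_capacity_coeff_N_kg",
                "Cl_flap", "Cl_max_turn", "sprint_a", "hip_height_frac",
                "leg_accel_m_s2", "dt_s", "horizon_s", "v_min_m_s",
                "v_max_m_s")
  for (nm in positive) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 ||
        !is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("aero_config field '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  # zero is a meaningful limit here: no flapping at all
  for (nm in c("freq_coeff_bird", "freq_coeff_bat", "flap_amplitude_rad")) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 ||
        !is.finite(cfg[[nm]]) || cfg[[nm]] < 0) {
      stop("aero_config field '", nm, "' must be a single non-negative ",
           "number", call. = FALSE)
    }
  }
  if (!length(cfg$Cd_body_set) || any(cfg$Cd_body_set < 0)) {
    stop("Cd_body_set must be non-empty and non-negative", call. = FALSE)
  }
  if (!length(cfg$Cl_set) || any(cfg$Cl_set <= 0)) {
    stop("Cl_set must be non-empty and positive", call. = FALSE)
  }
  if (!cfg$wingbeat_model %in% c("bird", "bat")) {
    stop("wingbeat_model must be \"bird\" or \"bat\"", call. = FALSE)
  }
  if (cfg$bank_deg <= 0 || cfg$bank_deg >= 90) {
    stop("bank_deg must lie strictly between 0 and 90", call. = FALSE)
  }
  structure(cfg, class = "aero_config")
}

#' @export
print.aero_config <- function(x, ...) {
  cat("<aero_config>\n")
  cat("  rho =", x$rho_air_kg_m3, "kg/m^3, g =", x$g_m_s2, "m/s^2, k =",
      x$k_induced, "\n")
  cat("  Cd body set: {", paste(x$Cd_body_set, collapse = ", "), "}  Cl set: {",
      paste(x$Cl_set, collapse = ", "), "}\n")
  cat("  wingbeat model:", x$wingbeat_model, " flap amplitude:",
      round(x$flap_amplitude_rad, 3), "rad\n")
  invisible(x)
}

# body frontal area allometry, m^2
frontal_area <- function(mass_kg, config) {
  config$frontal_area_coeff * mass_kg^config$frontal_area_exp
}
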
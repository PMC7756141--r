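#' Allometric wingbeat frequency
#'
#' \deqn{f = C \, m^{3/8} g^{1/2} b^{-23/24} S^{-1/3} \rho^{-3/8}}
#' with leading constant C = 1.08 for the avian model and a lower constant
#' (default 0.80) for the bat model, reflecting the slower wingbeats of
#' membrane flyers of equal size.
#'
#' @param mass_kg Body mass, kg.
#' @param planform A \code{wing_planform}.
#' @param config An [aero_config()].
#' @param model \code{"bird"} or \code{"bat"}; default from the config.
#' @return Wingbeat frequency, Hz.
#' @export
wingbeat_frequency <- function(mass_kg, planform, config = aero_config(),
                               model = config$wingbeat_model) {
  model <- match.arg(model, c("bird", "bat"))
  C <- if (model == "bird") config$freq_coeff_bird else config$freq_coeff_bat
  C * mass_kg^(3 / 8) * config$g_m_s2^(1 / 2) *
    planform$span_b_m^(-23 / 24) * planform$area_S_m2^(-1 / 3) *
    config$rho_air_kg_m3^(-3 / 8)
}

# mean flapping speed of the wing evaluated at 2/3 semispan
flap_speed <- function(planform, freq_hz, config) {
  2 * config$flap_amplitude_rad * freq_hz * (2 / 3) * (planform$span_b_m / 2)
}

# aerodynamic force of the flapping wing at ground speed v:
# lift on the full resultant speed, forward thrust resolved through the
# stroke plane and weighted by the flapping share Vf/Vr of the resultant,
# so a non-flapping wing lifts but cannot propel
flap_forces <- function(v, Vf, planform, Cl, config) {
  Vr2 <- v^2 + Vf^2
  L <- 0.5 * config$rho_air_kg_m3 * planform$area_S_m2 * Cl * Vr2
  frac <- if (Vr2 > 0) Vf / sqrt(Vr2) else 0
  list(lift = L,
       thrust = L * cos(config$stroke_plane_deg * pi / 180) * frac)
}

#' Minimum (stall-limited) take-off speed
#'
#' \eqn{V_{to} = \sqrt{2 m g / (\rho S C_l)}}: the slowest speed at which
#' the wing can support body weight at lift coefficient Cl.
#'
#' @param mass_kg Body mass, kg.
#' @param planform A \code{wing_planform}.
#' @param Cl Lift coefficient (> 0).
#' @param config An [aero_config()].
#' @return Speed in m/s.
#' @examples
#' takeoff_speed(0.38, wing_planform("MFW", 0.7, 0.06), Cl = 1.5)
#' @export
takeoff_speed <- function(mass_kg, planform, Cl, config = aero_config()) {
  stopifnot(mass_kg > 0, Cl > 0, inherits(planform, "wing_planform"))
  sqrt(2 * mass_kg * config$g_m_s2 /
         (config$rho_air_kg_m3 * planform$area_S_m2 * Cl))
}

#' Maximum sprint speed
#'
#' Configurable allometric model \eqn{v = a L^p m^q} with L the total
#' hindlimb length (m). The defaults (a = 11.9, p = 0.5, q = 0) implement a
#' Froude-number-16 ceiling on hip height taken as 0.9 L, a standard upper
#' bound for bipedal running.
#'
#' @param spec A \code{specimen}; needs \code{hindlimb_total} or the three
#'   hindlimb segments (femur, tibia, metatarsus).
#' @param config An [aero_config()].
#' @param mass_kg Body mass used when the mass exponent q is non-zero;
#'   default the smallest mass hypothesis.
#' @return Speed in m/s.
#' @export
sprint_speed <- function(spec, config = aero_config(),
                         mass_kg = spec$mass_hypotheses_kg[1]) {
  stopifnot(inherits(spec, "specimen"))
  L <- hindlimb_length(spec)
  config$sprint_a * L^config$sprint_p * mass_kg^config$sprint_q
}

hindlimb_length <- function(spec) {
  seg <- spec$segments_m
  if (!is.null(seg$hindlimb_total)) return(seg$hindlimb_total)
  parts <- c("femur", "tibia", "metatarsus")
  if (all(parts %in% names(seg))) {
    return(seg$femur + seg$tibia + seg$metatarsus)
  }
  stop("specimen '", spec$specimen_id,
       "': hindlimb length unavailable (need hindlimb_total or ",
       "femur+tibia+metatarsus)", call. = FALSE)
}

#' Flap-assisted running take-off simulation
#'
#' Forward-Euler time integration of a ground run with flapping wings.
#' Leg drive accelerates the body toward the sprint ceiling (peak
#' acceleration \code{leg_accel_m_s2} decaying linearly to zero at
#' \eqn{V_{sprint}}, applied only while the animal is weight-supported on
#' the ground). The flapping wing sees a resultant speed
#' \eqn{V_r = \sqrt{V^2 + V_f^2}} with mean flapping speed
#' \eqn{V_f = 2 \Phi f \cdot \tfrac{2}{3} b/2}; it produces aerodynamic
#' force \eqn{F = \tfrac12 \rho S C_l V_r^2}, counted fully as weight
#' support and resolved forward through the stroke-plane angle, weighted by
#' the flapping share of the resultant, as thrust
#' \eqn{T = F \cos\beta \; V_f/V_r} (zero without flapping). Body drag is
#' subtracted. Take-off occurs when
#' lift first meets body weight; the horizon is
#' \code{config$horizon_s} (default 20 s).
#'
#' @param spec A \code{specimen}.
#' @param planform A \code{wing_planform}.
#' @param Cl Lift coefficient during flapping; default
#'   \code{config$Cl_flap}.
#' @param wingbeat_model \code{"bird"} or \code{"bat"}.
#' @param config An [aero_config()].
#' @param mass_kg Body mass; default the smallest hypothesis.
#' @param Cd_body Body drag coefficient during the run; default the middle
#'   configured value.
#' @param dt Integration step, s; default \code{config$dt_s}.
#' @return A list: \code{t_takeoff_s} (NA if never reached),
#'   \code{freq_hz}, \code{V_flap_m_s}, \code{V_takeoff_m_s} and
#'   \code{time_series} (tibble of t, V, lift_fraction).
#' @export
flap_run_simulate <- function(spec, planform, Cl = config$Cl_flap,
                              wingbeat_model = config$wingbeat_model,
                              config = aero_config(),
                              mass_kg = spec$mass_hypotheses_kg[1],
                              Cd_body = config$Cd_body_set[2],
                              dt = config$dt_s) {
  stopifnot(inherits(spec, "specimen"), inherits(planform, "wing_planform"),
            Cl > 0, dt > 0)
  g <- config$g_m_s2; rho <- config$rho_air_kg_m3
  W <- mass_kg * g
  f <- wingbeat_frequency(mass_kg, planform, config, wingbeat_model)
  Vf <- flap_speed(planform, f, config)
  Vsp <- sprint_speed(spec, config, mass_kg)
  Sb <- frontal_area(mass_kg, config)
  n <- ceiling(config$horizon_s / dt)
  t <- V <- lift_frac <- numeric(n + 1)
  v <- 0
  t_takeoff <- NA_real_
  for (i in 0:n) {
    ff <- flap_forces(v, Vf, planform, Cl, config)
    L <- ff$lift
    t[i + 1] <- i * dt
    V[i + 1] <- v
    lift_frac[i + 1] <- L / W
    if (L >= W) {
      t_takeoff <- i * dt
      t <- t[seq_len(i + 1)]; V <- V[seq_len(i + 1)]
      lift_frac <- lift_frac[seq_len(i + 1)]
      break
    }
    thrust <- ff$thrust
    drag <- 0.5 * rho * v^2 * Sb * Cd_body
    leg <- config$leg_accel_m_s2 * max(0, 1 - v / Vsp)
    a <- leg + (thrust - drag) / mass_kg
    v <- v + a * dt
    if (!is.finite(v)) stop("flap-run integration diverged", call. = FALSE)
    if (v < 0) v <- 0
  }
  list(t_takeoff_s = t_takeoff,
       freq_hz = f,
       V_flap_m_s = Vf,
       V_takeoff_m_s = takeoff_speed(mass_kg, planform, Cl, config),
       time_series = tibble::tibble(t = t, V = V, lift_fraction = lift_frac))
}

#' Leaping take-off check
#'
#' Ballistic launch speed \eqn{v = c_{leap} \sqrt{g h_{hip}}} (hip height a
#' configured fraction of hindlimb length). With flapping enabled, the
#' airspeed of one flap is added as the resultant
#' \eqn{\sqrt{v^2 + V_f^2}}. Take-off is achieved when the resulting
#' airspeed reaches the stall-limited minimum flight speed.
#'
#' @param spec A \code{specimen}.
#' @param planform A \code{wing_planform}.
#' @param config An [aero_config()].
#' @param with_flapping Add one flap's airspeed? Default FALSE.
#' @param mass_kg Body mass; default the smallest hypothesis.
#' @param Cl Lift coefficient for the minimum flight speed; default the
#'   largest configured Cl.
#' @return A list: \code{launch_velocity_m_s}, \code{effective_airspeed_m_s},
#'   \code{V_takeoff_m_s}, \code{achieves_takeoff}.
#' @export
leap_takeoff <- function(spec, planform, config = aero_config(),
                         with_flapping = FALSE,
                         mass_kg = spec$mass_hypotheses_kg[1],
                         Cl = max(config$Cl_set)) {
  stopifnot(inherits(spec, "specimen"), inherits(planform, "wing_planform"))
  hip <- config$hip_height_frac * hindlimb_length(spec)
  v_launch <- config$leap_coeff * sqrt(config$g_m_s2 * hip)
  v_eff <- v_launch
  if (with_flapping) {
    f <- wingbeat_frequency(mass_kg, planform, config)
    v_eff <- sqrt(v_launch^2 + flap_speed(planform, f, config)^2)
  }
  vto <- takeoff_speed(mass_kg, planform, Cl, config)
  list(launch_velocity_m_s = v_launch,
       effective_airspeed_m_s = v_eff,
       V_takeoff_m_s = vto,
       achieves_takeoff = v_eff >= vto)
}

#' Wing-assisted incline running (WAIR) capability
#'
#' Evaluates the flapping lift fraction of body weight at a low reference
#' running speed (juvenile-chukar-like, default 1.5 m/s) and classifies it
#' against configurable level thresholds: level I at
#' \code{wair_level1_frac} (default 0.06) and level II at
#' \code{wair_level2_frac} (default 0.5) of body weight.
#'
#' @param spec A \code{specimen}.
#' @param planform A \code{wing_planform}.
#' @param Cl Lift coefficient; default \code{config$Cl_flap}.
#' @param wingbeat_model \code{"bird"} or \code{"bat"}.
#' @param config An [aero_config()].
#' @param mass_kg Body mass; default the smallest hypothesis.
#' @param speed_m_s Reference running speed; default
#'   \code{config$wair_ref_speed_m_s}.
#' @return A list with \code{lift_fraction_of_weight} and \code{level}
#'   (\code{"none"}, \code{"I"} or \code{"II"}).
#' @export
wair_capability <- function(spec, planform, Cl = config$Cl_flap,
                            wingbeat_model = config$wingbeat_model,
                            config = aero_config(),
                            mass_kg = spec$mass_hypotheses_kg[1],
                            speed_m_s = config$wair_ref_speed_m_s) {
  stopifnot(inherits(spec, "specimen"), inherits(planform, "wing_planform"),
            Cl > 0, speed_m_s >= 0)
  f <- wingbeat_frequency(mass_kg, planform, config, wingbeat_model)
  Vr2 <- speed_m_s^2 + flap_speed(planform, f, config)^2
  L <- 0.5 * config$rho_air_kg_m3 * planform$area_S_m2 * Cl * Vr2
  frac <- L / (mass_kg * config$g_m_s2)
  level <- if (frac >= config$wair_level2_frac) "II"
           else if (frac >= config$wair_level1_frac) "I"
           else "none"
  list(lift_fraction_of_weight = frac, level = level)
}

#' Terrestrial take-off report
#'
#' One row per (specimen, wing model, mass, Cl, wingbeat model)
#' permutation: minimum take-off speed, sprint speed, their ratio, the
#' flap-run time to take-off (NA when never achieved), leaping outcome and
#' WAIR level.
#'
#' @param tbl A \code{specimen_table}.
#' @param models Wing models to evaluate.
#' @param config An [aero_config()].
#' @param Cl_set Lift coefficients to sweep; default
#'   \code{sort(unique(c(config$Cl_set, config$Cl_flap)))}.
#' @param freq_models Wingbeat models to sweep; default both.
#' @return A tibble.
#' @export
takeoff_table <- function(tbl, models = c("MFW", "BBW"),
                          config = aero_config(),
                          Cl_set = sort(unique(c(config$Cl_set,
                                                 config$Cl_flap))),
                          freq_models = c("bird", "bat")) {
  stopifnot(inherits(tbl, "specimen_table"))
  rows <- list()
  for (sp in tbl$rows) {
    has_legs <- !inherits(try(hindlimb_length(sp), silent = TRUE),
                          "try-error")
    if (!has_legs) next
    for (mod in models) {
      pf <- tryCatch(build_wing_model(sp, mod, config), error = function(e) NULL)
      if (is.null(pf)) next
      for (m in sp$mass_hypotheses_kg) {
        vsp <- sprint_speed(sp, config, m)
        for (cl in Cl_set) {
          vto <- takeoff_speed(m, pf, cl, config)
          for (fm in freq_models) {
            fr <- flap_run_simulate(sp, pf, Cl = cl, wingbeat_model = fm,
                                    config = config, mass_kg = m)
            leap <- leap_takeoff(sp, pf, config, with_flapping = TRUE,
                                 mass_kg = m, Cl = cl)
            wair <- wair_capability(sp, pf, Cl = cl, wingbeat_model = fm,
                                    config = config, mass_kg = m)
            rows[[length(rows) + 1]] <- tibble::tibble(
              taxon = sp$taxon, specimen_id = sp$specimen_id, model = mod,
              mass_kg = m, Cl = cl, freq_model = fm,
              V_takeoff_m_s = vto, V_sprint_m_s = vsp,
              ratio_takeoff_sprint = vto / vsp,
              run_alone_achieves = vsp >= vto,
              t_takeoff_s = fr$t_takeoff_s,
              leap_achieves = leap$achieves_takeoff,
              wair_lift_fraction = wair$lift_fraction_of_weight,
              wair_level = wair$level)
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}
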
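#' Mechanical power required for level flapping flight
#'
#' The classical three-term decomposition at airspeed V:
#' \deqn{P(V) = P_{ind} + P_{par} + P_{pro}}
#' with induced power \eqn{P_{ind} = k (m g)^2 / (2 \rho V S_d)} over the
#' wing disc \eqn{S_d = \pi b^2/4}, parasite power
#' \eqn{P_{par} = \tfrac12 \rho V^3 S_b C_{d,b}} with body frontal area
#' \eqn{S_b} from the configured allometry, and a speed-independent profile
#' power \eqn{P_{pro} = (C_{pro}/Ra) \, P_{am}} where \eqn{P_{am}} is the
#' absolute minimum of \eqn{P_{ind} + P_{par}} over speed.
#'
#' @param V Airspeed, m/s (vectorised). Must be positive.
#' @param mass_kg Body mass, kg.
#' @param planform A \code{wing_planform}.
#' @param config An [aero_config()].
#' @param Cd_body Body drag coefficient; default the middle entry of
#'   \code{config$Cd_body_set}.
#' @return Mechanical power in W, same length as \code{V}.
#' @examples
#' pf <- wing_planform("MFW", 0.6, 0.05)
#' power_required(6, 0.2, pf)
#' @export
power_required <- function(V, mass_kg, planform, config = aero_config(),
                           Cd_body = config$Cd_body_set[2]) {
  if (any(!is.finite(V)) || any(V <= 0)) {
    stop("airspeed V must be positive", call. = FALSE)
  }
  stopifnot(inherits(planform, "wing_planform"), mass_kg > 0)
  cf <- power_coefs(mass_kg, planform, config, Cd_body)
  cf$A / V + cf$B * V^3 + cf$Ppro
}

# A/V + B V^3 decomposition; Ppro is the V-independent profile term.
power_coefs <- function(mass_kg, planform, config, Cd_body) {
  W <- mass_kg * config$g_m_s2
  Sd <- pi * planform$span_b_m^2 / 4
  A <- config$k_induced * W^2 / (2 * config$rho_air_kg_m3 * Sd)
  B <- 0.5 * config$rho_air_kg_m3 * frontal_area(mass_kg, config) * Cd_body
  if (B > 0) {
    Vam <- (A / (3 * B))^0.25
    Pam <- A / Vam + B * Vam^3
  } else {
    Pam <- 0 # no parasite drag: induced power alone has no interior minimum
  }
  list(A = A, B = B, Ppro = (config$Cpro / planform$aspect_ratio_Ra) * Pam)
}

#' Minimum power and minimum-power speed
#'
#' Minimises [power_required()] over airspeed by bounded Brent search
#' (relative tolerance \code{config$opt_rel_tol}) on
#' \code{[config$v_min_m_s, config$v_max_m_s]}, after a coarse-grid scan
#' that errors if the sampled curve is not U-shaped (a single interior
#' minimum).
#'
#' @inheritParams power_required
#' @return A list with \code{Vmp_m_s} (minimising speed) and \code{Pmin_W}.
#' @export
min_power <- function(mass_kg, planform, config = aero_config(),
                      Cd_body = config$Cd_body_set[2]) {
  f <- function(V) power_required(V, mass_kg, planform, config, Cd_body)
  check_unimodal(f, config, what = "power curve")
  opt <- stats::optimize(f, c(config$v_min_m_s, config$v_max_m_s),
                         tol = config$opt_rel_tol)
  list(Vmp_m_s = opt$minimum, Pmin_W = opt$objective)
}

# coarse-grid unimodality diagnostic shared by min_power and best_glide
check_unimodal <- function(f, config, what) {
  V <- seq(config$v_min_m_s, config$v_max_m_s, length.out = config$grid_n)
  y <- f(V)
  d <- diff(y)
  sign_changes <- sum(diff(sign(d[d != 0])) != 0)
  if (sign_changes > 1) {
    stop(what, " is not unimodal on the sampled bracket", call. = FALSE)
  }
  invisible(TRUE)
}

#' Burst muscle power available
#'
#' \eqn{P_{avail} = f \, m \, s(m)} where f is the flight-muscle mass
#' fraction and \eqn{s(m) = a m^c} the mass-specific burst power of
#' vertebrate flight muscle in W per kg muscle. The default coefficients
#' (107.22 W/kg, exponent -0.2598) are a log-log least-squares calibration
#' against published burst power outputs of flyers spanning 0.18-0.95 kg
#' (see vignette).
#'
#' @param mass_kg Body mass, kg.
#' @param muscle_fraction Flight-muscle mass fraction in (0, 1]; 0 is
#'   permitted and yields 0 W.
#' @param config An [aero_config()].
#' @return Power available in W.
#' @examples
#' power_available(0.38, 0.10)
#' @export
power_available <- function(mass_kg, muscle_fraction, config = aero_config()) {
  stopifnot(mass_kg > 0, muscle_fraction >= 0, muscle_fraction <= 1)
  s <- config$muscle_power_coeff_W_kg * mass_kg^config$muscle_power_exp
  muscle_fraction * mass_kg * s
}

#' Specific-lift criterion for take-off
#'
#' A burst take-off demands that the flight muscle produce at least body
#' weight in lift: capable iff
#' \eqn{f \, m \, c \ge m g}, i.e. capacity \eqn{c \ge g/f} N per kg
#' muscle. By default the capacity declines allometrically with body mass
#' (\code{lift_capacity_coeff_N_kg * m^lift_capacity_exp}), mirroring the
#' decline of burst muscle performance with size, so heavier mass
#' hypotheses can fail where lighter ones pass.
#'
#' @param mass_kg Body mass, kg.
#' @param muscle_fraction Flight-muscle mass fraction.
#' @param lift_capacity_N_per_kg_muscle Burst lift capacity; default
#'   \code{NULL} uses the configured allometry.
#' @param config An [aero_config()].
#' @return A list with \code{capable} (logical) and \code{margin_N}
#'   (lift minus weight, N).
#' @export
specific_lift_check <- function(mass_kg, muscle_fraction,
                                lift_capacity_N_per_kg_muscle = NULL,
                                config = aero_config()) {
  stopifnot(mass_kg > 0, muscle_fraction > 0)
  cap <- lift_capacity_N_per_kg_muscle
  if (is.null(cap)) {
    cap <- config$lift_capacity_coeff_N_kg * mass_kg^config$lift_capacity_exp
  }
  stopifnot(cap > 0)
  margin <- muscle_fraction * mass_kg * cap - mass_kg * config$g_m_s2
  list(capable = margin >= 0, margin_N = margin)
}

#' Powered-flight verdict for one specimen and wing model
#'
#' Assembles, for every body-mass hypothesis, the power available and the
#' minimum mechanical power required under each configured body drag
#' coefficient; a (mass, Cd) permutation is feasible when available power
#' meets or exceeds the requirement.
#'
#' @param spec A \code{specimen}.
#' @param model Wing model id.
#' @param config An [aero_config()].
#' @return An object of class \code{power_verdict}: a tibble with one row
#'   per (mass, Cd) with columns \code{P_available_W}, \code{Vmp_m_s},
#'   \code{Pmin_W}, \code{feasible}.
#' @export
powered_flight_verdict <- function(spec, model, config = aero_config()) {
  stopifnot(inherits(spec, "specimen"))
  pf <- build_wing_model(spec, model, config)
  rows <- list()
  for (m in spec$mass_hypotheses_kg) {
    pav <- power_available(m, spec$flight_muscle_fraction, config)
    for (cd in config$Cd_body_set) {
      mp <- min_power(m, pf, config, cd)
      rows[[length(rows) + 1]] <- tibble::tibble(
        taxon = spec$taxon, specimen_id = spec$specimen_id, model = model,
        mass_kg = m, Cd_body = cd, P_available_W = pav,
        Vmp_m_s = mp$Vmp_m_s, Pmin_W = mp$Pmin_W,
        feasible = pav >= mp$Pmin_W)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("power_verdict", class(out))
  out
}

#' Powered-flight comparison table
#'
#' Wide report with one row per (specimen, model, mass): power available
#' (\code{Pwr}) and minimum power required at each configured body drag
#' coefficient (columns \code{Min_Cd<value>}).
#'
#' @param tbl A \code{specimen_table}.
#' @param models Wing models to evaluate (skipped per specimen when
#'   anchors/geometry are unavailable).
#' @param config An [aero_config()].
#' @return A tibble.
#' @export
power_table <- function(tbl, models = c("MFW", "BBW"),
                        config = aero_config()) {
  stopifnot(inherits(tbl, "specimen_table"))
  rows <- list()
  for (sp in tbl$rows) {
    for (mod in models) {
      pf <- tryCatch(build_wing_model(sp, mod, config), error = function(e) NULL)
      if (is.null(pf)) next
      for (m in sp$mass_hypotheses_kg) {
        row <- list(Taxon = sp$taxon, Specimen = sp$specimen_id, Model = mod,
                    `Mass (kg)` = m,
                    Pwr = power_available(m, sp$flight_muscle_fraction,
                                          config))
        for (cd in config$Cd_body_set) {
          row[[sprintf("Min_Cd%g", cd)]] <-
            min_power(m, pf, config, cd)$Pmin_W
        }
        rows[[length(rows) + 1]] <- tibble::as_tibble(row)
      }
    }
  }
  dplyr::bind_rows(rows)
}
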
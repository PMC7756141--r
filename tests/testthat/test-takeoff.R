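test_that("take-off speed follows stall scaling", {
  cfg <- aero_config()
  pf <- toy_planform(area = 0.06)
  pf4 <- wing_planform("MFW", pf$span_b_m, 4 * pf$area_S_m2)
  v1 <- takeoff_speed(0.3, pf, Cl = 1.5, cfg)
  expect_equal(takeoff_speed(0.3, pf4, Cl = 1.5, cfg), v1 / 2,
               tolerance = 1e-12)
  # V_to * sqrt(Cl) is invariant under Cl changes
  expect_equal(takeoff_speed(0.3, pf, 1.0, cfg) * sqrt(1.0),
               takeoff_speed(0.3, pf, 1.5, cfg) * sqrt(1.5),
               tolerance = 1e-12)
  # forced arithmetic: geometry chosen so 2mg/(rho S Cl) = 25
  m <- 1; Cl <- 2
  S <- 2 * m * 9.81 / (1.225 * Cl * 25)
  expect_equal(takeoff_speed(m, wing_planform("MFW", 1, S), Cl,
                             aero_config()), 5, tolerance = 1e-12)
})

test_that("sprint speed is allometric, linear in its coefficient", {
  sp <- toy_specimen()
  v1 <- sprint_speed(sp, aero_config(sprint_a = 11.9))
  v2 <- sprint_speed(sp, aero_config(sprint_a = 23.8))
  expect_equal(v2, 2 * v1, tolerance = 1e-12)
  long <- toy_specimen()
  long$segments_m$hindlimb_total <- 1.5 * sp$segments_m$hindlimb_total
  expect_gt(sprint_speed(long, aero_config()), v1)
  # hindlimb_total falls back to femur+tibia+metatarsus
  sp2 <- toy_specimen()
  sp2$segments_m$hindlimb_total <- NULL
  expect_equal(sprint_speed(sp2, aero_config()),
               aero_config()$sprint_a *
                 (0.06 + 0.072 + 0.033)^0.5, tolerance = 1e-12)
  sp3 <- specimen("t", "x", 0.3, segments_m = list(humerus = 0.1))
  expect_error(sprint_speed(sp3), "hindlimb")
})

test_that("sprint allometry parameters are recoverable from simulated data", {
  a <- 9.5; p <- 0.45; q <- 0.12
  withr::with_seed(21, {
    L <- runif(120, 0.05, 0.5)
    m <- exp(runif(120, log(0.02), log(2)))
    v <- a * L^p * m^q * exp(rnorm(120, 0, 0.03))
    fit <- lm(log(v) ~ log(L) + log(m))
    ci <- confint(fit)
  })
  expect_gt(log(a), ci[1, 1]); expect_lt(log(a), ci[1, 2])
  expect_gt(p, ci[2, 1]); expect_lt(p, ci[2, 2])
  expect_gt(q, ci[3, 1]); expect_lt(q, ci[3, 2])
})

test_that("without flapping and a slow sprint there is no take-off", {
  sp <- toy_specimen()
  cfg <- aero_config(freq_coeff_bird = 0, horizon_s = 5)
  pf <- toy_planform(area = 0.02)  # small wing: V_to above sprint speed
  expect_gt(takeoff_speed(0.3, pf, cfg$Cl_flap, cfg),
            sprint_speed(sp, cfg))
  fr <- flap_run_simulate(sp, pf, config = cfg, mass_kg = 0.3)
  expect_true(is.na(fr$t_takeoff_s))
  expect_true(all(fr$time_series$lift_fraction < 1))
})

test_that("time to take-off decreases with Cl, flap frequency and wing area", {
  sp <- toy_specimen()
  cfg <- aero_config()
  pf <- toy_planform(area = 0.05)
  t_at <- function(Cl = 1.6, coeff = cfg$freq_coeff_bird, area = 0.05) {
    c2 <- aero_config(freq_coeff_bird = coeff)
    flap_run_simulate(sp, toy_planform(area = area), Cl = Cl,
                      config = c2, mass_kg = 0.3)$t_takeoff_s
  }
  base <- t_at()
  expect_false(is.na(base))
  hi_cl <- t_at(Cl = 2.2)
  expect_lte(hi_cl, base)
  lo_f <- t_at(coeff = 0.7 * cfg$freq_coeff_bird)
  expect_gte(lo_f, base)
  big_S <- t_at(area = 0.07)
  expect_lte(big_S, base)
})

test_that("flap-run integration converges under step halving", {
  sp <- toy_specimen()
  cfg <- aero_config()
  pf <- toy_planform(area = 0.05)
  t1 <- flap_run_simulate(sp, pf, Cl = 1.6, config = cfg, mass_kg = 0.3,
                          dt = 0.01)$t_takeoff_s
  t2 <- flap_run_simulate(sp, pf, Cl = 1.6, config = cfg, mass_kg = 0.3,
                          dt = 0.005)$t_takeoff_s
  expect_false(is.na(t1)); expect_false(is.na(t2))
  expect_lt(abs(t1 - t2) / t2, 0.02)
})

test_that("bat wingbeat frequency is below bird frequency", {
  pf <- toy_planform()
  f_bird <- wingbeat_frequency(0.3, pf, model = "bird")
  f_bat <- wingbeat_frequency(0.3, pf, model = "bat")
  expect_gt(f_bird, f_bat)
  expect_gt(f_bat, 0)
  # allometric form: frequency falls with span at fixed mass and area
  pf_long <- wing_planform("MFW", 1.4, pf$area_S_m2)
  expect_lt(wingbeat_frequency(0.3, pf_long), f_bird)
})

test_that("leaping cannot launch with zero leap coefficient", {
  sp <- toy_specimen()
  pf <- toy_planform()
  cfg <- aero_config(leap_coeff = 1e-12)
  r <- leap_takeoff(sp, pf, cfg, mass_kg = 0.3)
  expect_false(r$achieves_takeoff)
  expect_lt(r$launch_velocity_m_s, 1e-5)
})

test_that("a sufficiently large wing makes a leap launch succeed", {
  sp <- toy_specimen()
  # enormous lifting area drives V_to below the leap launch speed
  pf <- wing_planform("MFW", 6, 8)
  r <- leap_takeoff(sp, pf, aero_config(), mass_kg = 0.05)
  expect_lt(r$V_takeoff_m_s, r$launch_velocity_m_s)
  expect_true(r$achieves_takeoff)
  # flapping assistance only ever raises the effective airspeed
  r2 <- leap_takeoff(sp, toy_planform(), aero_config(),
                     with_flapping = TRUE, mass_kg = 0.3)
  r3 <- leap_takeoff(sp, toy_planform(), aero_config(),
                     with_flapping = FALSE, mass_kg = 0.3)
  expect_gte(r2$effective_airspeed_m_s, r3$effective_airspeed_m_s)
})

test_that("WAIR lift fraction is zero without flapping and level is monotone", {
  sp <- toy_specimen()
  pf <- toy_planform()
  cfg0 <- aero_config(freq_coeff_bird = 0)
  r0 <- wair_capability(sp, pf, config = cfg0, mass_kg = 0.3,
                        speed_m_s = 0)
  expect_equal(r0$lift_fraction_of_weight, 0)
  expect_identical(r0$level, "none")
  # increasing Cl raises the lift fraction and never lowers the level
  fracs <- vapply(c(0.5, 1, 1.5, 2, 3), function(cl)
    wair_capability(sp, pf, Cl = cl, config = aero_config(),
                    mass_kg = 0.3)$lift_fraction_of_weight, numeric(1))
  expect_true(all(diff(fracs) > 0))
  lv <- vapply(c(0.5, 1, 1.5, 2, 3), function(cl)
    wair_capability(sp, pf, Cl = cl, config = aero_config(),
                    mass_kg = 0.3)$level, character(1))
  ord <- match(lv, c("none", "I", "II"))
  expect_true(all(diff(ord) >= 0))
  # lift fraction is continuous (small) in speed around the reference
  f1 <- wair_capability(sp, pf, config = aero_config(), mass_kg = 0.3,
                        speed_m_s = 1.5)$lift_fraction_of_weight
  f2 <- wair_capability(sp, pf, config = aero_config(), mass_kg = 0.3,
                        speed_m_s = 1.51)$lift_fraction_of_weight
  expect_lt(abs(f2 - f1), 0.01)
})

test_that("the take-off report sweeps permutations and stays consistent", {
  tbl <- specimen_table(list(toy_specimen("A", 0.3)))
  rep <- takeoff_table(tbl, models = "MFW")
  expect_true(all(rep$ratio_takeoff_sprint ==
                    rep$V_takeoff_m_s / rep$V_sprint_m_s))
  expect_true(all(rep$V_takeoff_m_s > 0))
  # Cl sweep includes the configured set and the flap-run default
  expect_setequal(unique(rep$Cl), c(1.0, 1.5, 2.0))
})
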
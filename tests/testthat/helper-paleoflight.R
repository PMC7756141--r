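# shared fixtures built in code

# a fully-specified artificial specimen whose planform templates resolve
toy_specimen <- function(id = "TOY-1", masses = 0.3, muscle = 0.10,
                         scale = 1) {
  specimen(
    taxon = "toy", specimen_id = id, mass_hypotheses_kg = masses,
    flight_muscle_fraction = muscle,
    segments_m = list(
      humerus = 0.08 * scale, ulna = 0.09 * scale, radius = 0.085 * scale,
      styliform = 0.11 * scale,
      metacarpal_III = 0.024 * scale, phalanges_III = 0.04 * scale,
      metacarpal_IV = 0.027 * scale, phalanges_IV = 0.11 * scale,
      dpc_length = 0.016 * scale,
      femur = 0.06 * scale, tibia = 0.072 * scale,
      metatarsus = 0.033 * scale,
      hindlimb_total = 0.165 * scale, glenoid_height = 0.17 * scale))
}

toy_planform <- function(span = 0.7, area = 0.06, model = "MFW") {
  wing_planform(model, span, area)
}

# dense-grid oracle for the minimum of f over [lo, hi]
grid_min <- function(f, lo = 0.1, hi = 60, dv = 0.001) {
  V <- seq(lo, hi, by = dv)
  y <- f(V)
  i <- which.min(y)
  list(V = V[i], value = y[i])
}

# random convex polygon (vertices in angular order) for shoelace properties
random_convex_polygon <- function(n = 8) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(n, 0.5, 1.5)
  cbind(r * cos(th), r * sin(th))
}

# reference burst-power calibration pairs: body mass (kg) vs whole-animal
# burst power output (W) at a flight-muscle fraction of 0.10; these are
# the anchors behind the default muscle_power_coeff/exp allometry
burst_power_pairs <- function() {
  data.frame(
    mass_kg = c(0.18, 0.2, 0.23, 0.24, 0.31, 0.38, 0.45, 0.5, 0.7, 0.95),
    power_W = c(3.01, 3.26, 3.61, 3.73, 4.51, 5.24, 5.94, 6.42, 8.23, 10.32))
}
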
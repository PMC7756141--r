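# paleoflight

Aerodynamic feasibility analysis for small fossil vertebrates with
membranous wings — in particular the scansoriopterygid theropods *Yi qi*
and *Ambopteryx*, whose skin patagium stretched over elongate fingers and a
rod-like styliform wrist element has been proposed as a lifting surface.
The package is aimed at vertebrate palaeontologists and biomechanists who
want to screen a reconstructed animal for powered flight, terrestrial
take-off and gliding, and at methods developers who need a tested, fully
scriptable reference pipeline for such screens.

## What it computes

Given a specimen record (body-mass hypotheses, skeletal segment lengths,
optionally explicit wing span/area per wing model), the pipeline evaluates:

1. **Wing planforms** for four reconstruction hypotheses — maniraptoran
   forewing-only (MFW), bat-like fore+hindwing (BBW), pterosaur-like (PTW)
   and frog-like interdigital webbing (FRW) — either passed through from
   measured geometry or built from a documented segment-anchored polygon
   template (shoelace area, doubled, plus a central body strip).
2. **Wing loading** W/S = mg/S in N·m⁻², classified against the inclusive
   flight ceiling of 245 N·m⁻² and the extant-glider envelope 9–143 N·m⁻².
3. **Powered flight**: the U-shaped mechanical power curve
   P(V) = P_ind + P_par + P_pro with
   P_ind = k(mg)²/(2ρV·S_d), S_d = πb²/4,
   P_par = ½ρV³S_bC_db, and a speed-independent profile term
   (C_pro/Ra)·P_am; its minimum (V_mp, P_min) per drag coefficient is
   compared with burst muscle power available
   P_avail = f·m·s(m), s(m) = 107.22·m^(−0.26) W per kg muscle.
4. **Terrestrial take-off**: stall-limited minimum flight speed
   V_to = √(2mg/(ρSC_l)) against allometric sprint speed; ballistic
   leaping; a time-stepped flap-assisted running simulation (lift on the
   resultant of run and flap speed, stroke-plane-resolved thrust); and
   wing-assisted incline running (WAIR) lift fractions with level
   thresholds.
5. **Gliding**: glide polar under the shallow-glide approximation, best
   glide speed, sink rate, glide ratio, minimum sink, and the
   drag-independent stall-limited banked-turn radius
   r = 2n(m/S)/(ρC_l,max·tanφ) at a 24° bank.

A synthetic-specimen generator draws comparative glider and powered-flyer
populations (log-uniform mass, uniform wing loading and aspect ratio, exact
geometry back-derivation) for testing and morphospace context.

**Important caveat:** the built-in fixtures carry
`geometry_source = "placeholder"` — their segment lengths honour the
published anatomical ratios (styliform fraction, forelimb/femur = 4.65,
deltopectoral-crest and phalangeal indices) but are not primary
measurements, so absolute wing areas and everything downstream of them are
order-of-magnitude reconstructions, not published values. Supply real
measurements via `builtin_fixtures(override_path = ...)` or
`load_specimens()`.

## Worked example

```r
library(paleoflight)

fx  <- builtin_fixtures()
yi  <- get_specimen(fx, "STM 31-2")
cfg <- aero_config()

pf <- build_wing_model(yi, "MFW", cfg)
pf
#> <wing_planform> MFW: b = 0.699 m, S = 0.0666 m^2, Ra = 7.33

wing_loading(0.38, pf)$wing_loading_N_m2
#> [1] 55.9383

power_available(0.38, 0.10, cfg)
#> [1] 5.239019
min_power(0.38, pf, cfg, Cd_body = 0.4)$Pmin_W
#> [1] 5.852353

best_glide(0.38, pf, cfg, Cd_body = 0.4)
#> <glide_solution> best glide 10.25 m/s (sink 0.93 m/s, ratio 11.04);
#>   min sink 0.81 m/s at 7.79 m/s; turn radius 15.26 m at 24 deg bank
```

Reading this: under the template MFW reconstruction at the lightest mass
hypothesis, *Yi*'s wing loading (≈56 N·m⁻²) sits inside the glider
envelope, but the burst muscle power available (5.24 W) falls short of the
minimum mechanical power required at a realistic body drag coefficient of
0.4 (5.85 W) — powered flight fails the budget while gliding remains
possible, at a fast, steep glide. `flight_report(fx)` runs every stage over
every (specimen, wing model, mass) permutation and writes tidy CSVs plus a
per-specimen JSON verdict.

A thin command-line wrapper lives at `inst/cli/paleoflight.R`:

```sh
Rscript inst/cli/paleoflight.R glide --model MFW,BBW --out glide.csv
Rscript inst/cli/paleoflight.R synth --kind glider --n 500 --seed 7 --out pop.csv
```

## Package layout

- `R/` — specimen model and IO, wing-geometry templates, power curve,
  take-off dynamics, glide solver, synthetic populations, reports.
- `tests/testthat/` — unit, property and end-to-end suites (fixtures are
  generated in code).
- `vignettes/flight-feasibility.Rmd` — the methods vignette: model
  assumptions, parameter defaults and their provenance, numerical choices,
  limitations.
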
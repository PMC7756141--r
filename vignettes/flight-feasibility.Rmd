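---
title: "Flight feasibility screening for membrane-winged fossils: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flight feasibility screening for membrane-winged fossils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoflight)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the defaults and why they were chosen, the
numerical machinery, and what the synthetic-data tests do and do not
establish about real animals.

## The screening problem

Scansoriopterygid theropods such as *Yi qi* and *Ambopteryx* preserve a
membranous patagium supported by hypertrophied fingers and a styliform
wrist element — a wing architecture unlike the feathered forewings of
paravians. Whether such a wing could support powered flight, assisted
ground take-off, or only gliding is a quantitative question that can be
screened with classical flight mechanics, provided one is explicit about
reconstruction uncertainty. The package therefore treats every input as a
*permutation axis*: several body-mass hypotheses per specimen, four wing
planform models, several drag and lift coefficients, and two wingbeat
frequency models.

## Wing planforms

Four reconstruction hypotheses are supported: **MFW** (membrane behind the
arm and fingers only), **BBW** (membrane continued to the ankle, bat-like),
**PTW** (membrane to the ankle with a shallower root, pterosaur-like) and
**FRW** (webbing between the fingers only, flying-frog-like). When a
specimen carries measured span and area for a model they are passed
through untouched. Otherwise a documented polygon template is used, with
the extended arm as leading edge, the styliform element swept posteriorly
from the wrist (default 60° from the spanwise axis), and model-specific
root-trailing anchors. The half-wing polygon area comes from the shoelace
formula, is doubled, and a central body strip (body width × mean chord,
body width defaulting to 0.15 of the half-span) is added for all models
except FRW. By construction the templates order the areas
FRW < MFW ≤ PTW ≤ BBW, matching the anatomical expectation that
hindlimb-attached membranes enlarge the lifting surface while interdigital
webbing alone shrinks it drastically.

The templates are deliberately decoupled from the engine: every anchor
angle and fraction is an `aero_config()` entry, and explicit geometry
always wins, so measured values can be injected per specimen
(`builtin_fixtures(override_path = ...)`) without touching any code. The
built-in fixture skeletons are **placeholders** constructed to honour the
published dimensionless ratios (styliform fraction 0.42/0.32 of
humerus+ulna+styliform, forelimb 4.65 femur lengths, deltopectoral-crest
fractions, phalangeal indices 1.7/4.35, crural indices 1.17/1.25); their
absolute lengths, and hence absolute wing areas, are plausible but not
measured, and every output row carries the `geometry_source` flag to say
so.

Two definitions of "forelimb length" circulate for the forelimb/femur
ratio; both are computable (`anatomical_ratios(include_manus = )`). The
default excludes the manus because the 4.65 figure is conventionally
quoted alongside the humerus+ulna+styliform definition of the styliform
fraction.

## Wing loading thresholds

`wing_loading()` classifies W/S = mg/S against two inclusive bounds: 245
N·m⁻² as the ceiling for any flight, and [9, 143] N·m⁻² as the extant
glider envelope. Both bounds are applied inclusively — a value of exactly
245 passes the flight screen, 143 is inside the envelope — because the
thresholds are order-of-magnitude screens, not sharp physical constants; a
fossil outlier near 157 N·m⁻² falls outside the envelope by this
definition.

## The powered-flight budget

Mechanical power required is the standard three-term decomposition

$$P(V) = \underbrace{\frac{k (mg)^2}{2 \rho V S_d}}_{\text{induced}}
       + \underbrace{\tfrac12 \rho V^3 S_b C_{d,b}}_{\text{parasite}}
       + \underbrace{\frac{C_{pro}}{Ra} P_{am}}_{\text{profile}}$$

with wing disc area $S_d = \pi b^2/4$, induced-power factor $k = 1.2$,
body frontal area $S_b = 0.00813\,m^{0.666}$ m² (the standard allometry of
the bird flight-mechanics literature), and a profile term taken as
speed-independent: the constant $C_{pro} = 8.4$ divided by aspect ratio,
times the absolute minimum $P_{am}$ of the induced+parasite sum. All
constants are `aero_config()` fields. Air density defaults to sea-level
1.225 kg·m⁻³ and is configurable for palaeo-atmosphere sensitivity runs.

Power available is $P_{avail} = f\,m\,s(m)$ with muscle fraction $f$
(default 0.10, with 0.08 as the conservative alternative for
non-paravian pennaraptorans) and mass-specific burst power
$s(m) = 107.22\, m^{-0.2598}$ W per kg muscle. These two numbers are a
log-log least-squares calibration against reference whole-animal burst
power outputs for flyers spanning 0.18–0.95 kg at $f = 0.10$; the test
suite re-runs that fit as an oracle and requires the packaged defaults to
reproduce its coefficients, and every calibration pair to be predicted
within 1%. Burst-specialist muscle performance is almost certainly an
overestimate for a transitional flyer, which biases the screen *towards*
feasibility — a deliberate, conservative-in-the-other-direction choice.

The specific-lift screen (`specific_lift_check()`) asks whether the muscle
can produce body weight in lift: capable iff capacity ≥ g/f N per kg
muscle. The default capacity declines with mass,
$84\,m^{-0.2598}$ N/kg — the same allometric exponent as burst power —
so that heavier mass hypotheses of the same animal can fail where lighter
ones pass. The coefficient is provisional (it places the pass/fail
boundary between 0.45 and 0.7 kg at $f = 0.10$) and is an explicit
argument precisely so users can substitute their preferred value.

## Terrestrial take-off

*Running:* the stall-limited minimum flight speed
$V_{to} = \sqrt{2mg/(\rho S C_l)}$ is compared with an allometric sprint
ceiling $v = a L^p m^q$ (defaults $a = 11.9$, $p = 0.5$, $q = 0$: a
Froude-number-16 bound on hip height taken as 0.9 of hindlimb length — a
standard ceiling for bipedal running, configurable for other allometries;
the test suite demonstrates parameter recovery of $(a, p, q)$ from
simulated speed data).

*Leaping:* ballistic launch at $c_{leap}\sqrt{g h_{hip}}$ with
$c_{leap} = 1.41$, i.e. a vertical jump to roughly hip height — generous
for a small theropod. One flap's airspeed can be added as a resultant.

*Flap-running:* a forward-Euler integration (Δt = 0.01 s, horizon 20 s) of
a run with flapping wings. The wing sees the resultant
$V_r = \sqrt{V^2 + V_f^2}$ of ground speed and mean flap speed
$V_f = 2\Phi f \cdot \tfrac23 b/2$ (flap amplitude Φ defaults to π/3, a
restricted non-paravian stroke; frequency from the allometry
$f = C\,m^{3/8} g^{1/2} b^{-23/24} S^{-1/3} \rho^{-3/8}$ with $C = 1.08$
for the avian model and 0.80 for the bat model, since membrane flyers of
equal size beat their wings slower). The aerodynamic force
$\tfrac12 \rho S C_l V_r^2$ counts fully as weight support; its forward
thrust component is resolved through the stroke plane (60° from
horizontal) and weighted by the flapping share $V_f/V_r$ of the resultant,
so a non-flapping outstretched wing generates lift but no propulsion. Leg
drive contributes a peak 9.81 m·s⁻² decaying linearly to zero at the
sprint ceiling, active only while the wing supports less than body weight.
Take-off is declared when lift first reaches body weight. The default
lift coefficient while flapping is 2.0, with 1.5 and 1.0 as the standard
sensitivity levels.

*WAIR:* wing-assisted incline running is screened as the flapping lift
fraction of body weight at a low reference running speed (1.5 m·s⁻¹,
juvenile-chukar-like). Level I requires 6% of body weight, level II 50%;
both thresholds are provisional config entries — the published WAIR
literature does not fix them sharply — and the classification is
guaranteed monotone in the lift fraction.

## Gliding

Under the shallow-glide approximation (lift ≈ weight, good for glide
ratios well above 1; the error grows as the ratio approaches 1 and the
package makes no correction there), sink speed is $V D(V)/(mg)$ with
induced, body and wing-profile drag; the wing profile drag coefficient is
`profile_glide_scale × C_pro/Ra` (default scale 0.012, giving values near
the conventional 0.014 at aspect ratios around 7). Best glide maximises
$V/V_s$ (equivalently minimises drag), minimum sink minimises $V_s$; both
are unimodal on the search bracket and the solver enforces
$V_{minsink} < V_{bestglide}$.

The banked-turn radius uses the stall-limited form
$r = 2 n (m/S) / (\rho C_{l,max} \tan\phi)$ at a 24° bank with load factor
$n = 1/\cos\phi$ (toggleable to $n = 1$). This formulation was chosen over
a drag-balanced turning solution because it is independent of every drag
coefficient — the structurally observed behaviour of published turning
radii, which repeat identically across drag permutations — and depends
only on wing loading, $C_{l,max}$ (default 1.5) and the bank angle.

## Synthetic populations

`make_glider_population()` draws mass log-uniformly on 0.01–3 kg (extant
gliders top out between 2.5 and 3 kg), wing loading uniformly on 9–143
N·m⁻², aspect ratio uniformly on 1.5–4.5 and muscle fraction on
0.08–0.10, then *derives* the geometry ($S = mg/WL$, $b = \sqrt{Ra\,S}$)
so the drawn loading is recoverable exactly from the stored wing — the
recovery identity the acceptance suite checks. Skeletal segments are
back-filled from fixed proportions of the half-span with lognormal noise
(CV 5%) purely so the specimens flow through every pipeline stage; only
(m, S, b) matter downstream. The powered-flyer generator shifts the
defaults to 30–245 N·m⁻² and aspect ratios 4–9. Each generator call runs
on its own RNG stream seeded explicitly, leaving the caller's stream
untouched.

What passing these tests shows: the pipeline's algebra, classification
logic and optimisers are correct on airframes spanning the realistic
envelope. What it does not show: that any real species has these wing
loadings or proportions — the generator emulates envelope statistics, not
species values, and no curated extant-glider compilation ships with the
package.

## Numerical choices

- 1-D minimisation (power curve, glide polar) is bounded Brent search
  (`stats::optimize`) on 0.1–100 m·s⁻¹ at relative tolerance 1e-6,
  preceded by a 1000-point coarse-grid scan that raises a diagnostic
  error if the sampled curve is not unimodal. The test suite pins the
  optimiser to a ΔV = 0.001 m·s⁻¹ dense-grid oracle within 0.1% on
  random airframes.
- With the profile term off, $V_{mp}$ has the closed form
  $(A/3B)^{1/4}$ from the quartic stationarity of $A/V + BV^3$; the
  optimiser must match it to 1e-4 relative.
- The flap-run integrator is plain forward Euler — simple and auditable —
  with a convergence requirement that halving Δt moves the take-off time
  by under 2%.
- Quartiles in morphospace summaries use linear interpolation
  (`stats::quantile` type 7).
- Thresholds (245, [9,143], WAIR levels) are applied inclusively, and
  ties in WAIR level classification resolve upward at exact threshold
  values.

Problem sizes in the shipped tests were chosen to keep the default suite
fast while exercising the envelope: 50 random airframes per optimiser
check, populations of 100–2000 for the synthetic-identity and
distributional checks, and a 10⁴-draw population for the quantile
tolerance test.

## Known limitations

- No wing cross-section, camber, membrane tension or aeroelasticity: the
  wings are rigid planforms with prescribed coefficients. Maximum-lift
  and efficiency assumptions carried over from living membrane flyers are
  liberal for an animal that may have lacked active membrane control.
- The profile-power treatment (constant/Ra, speed-independent) is the
  coarsest of the standard options; it is adequate for minimum-power
  comparisons but not for high-speed ends of the curve.
- Non-equilibrium (short-duration) gliding and 3-D launch kinematics are
  out of scope; the glide solver is strictly equilibrium.
- Fixture geometry is placeholder-flagged reconstruction, not
  measurement; absolute fixture outputs are illustrative until real
  segment lengths and planform measurements are supplied through the
  override mechanism.
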
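---
title: "Methods: modeling biological propellant production on Mars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling biological propellant production on Mars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioisru)
```

This vignette records the modeling assumptions, parameter choices,
calibrations and numerical decisions behind `bioisru`, in the order the
flowsheet runs. It is the authoritative account of *why* the package
computes what it computes; the function reference documents *what*.

## Time base and scenario surface

All "per day" rates in the model are interpreted per sol (1 sol = 24.66 h),
so that totals over the 500-sol mission are self-consistent: a 6.64 g/m²/day
productivity over 500 sols with a ~51 t biomass demand implies a constant
harvest of ~0.103 t per sol. A `scenario_config` carries every tunable
parameter — cultivation mode, areal productivity, digestion yield and
residence, fermentation yield and productivity, target and mission length,
materials, nutrient excess (default 20%), and the Mars/Earth gravity ratio
(0.38). Validation is fail-fast: yields must lie in their physical ranges
(fermentation yield is capped at the constraint-based theoretical maximum of
0.538 g/g), and unknown config-file keys are errors.

The sweep generator (`generate_sweep()`) is the package's synthetic-input
surface: it emulates the optimization grids of the study — productivity
5–15 g/m²/day, digestion yield 0.3–0.6 g/g, fermentation yield up to
0.51 g/g — either as explicit grids or as seeded uniform draws. A fixed seed
reproduces the identical sequence, and the generator restores the caller's
RNG state. It deliberately does *not* model measurement noise or correlated
parameter uncertainty: each emitted scenario is an exact design point, so a
passing sweep says nothing about the robustness of the conclusions to joint
parameter error.

## Propellant thermochemistry

`combustion()` balances CxHyOz + (x + y/4 − z/2) O2 → x CO2 + (y/2) H2O
exactly; element conservation is asserted property-style in the tests. The
specific impulse is the kinetic-energy upper bound: every joule of the net
heat of combustion becomes exhaust kinetic energy. Two conventions matter
and are deliberate:

* **Heating-value basis.** The shipped table holds higher heating values
  (liquid product water) at 298 K, and the vaporization of the product
  water (40.7 kJ/mol each) is subtracted explicitly in the Isp and LHV
  expressions. This combination reproduces the reference values (~459 s for
  methane, ~420 s for 2,3-BDO) that anchor the mission sizing.
* **Exhaust mass.** `m_ex` is the *mass of exhaust produced per mole of
  fuel* (fuel plus consumed O2, kg/mol), not the mean molar mass of the
  exhaust mixture. Only this reading is dimensionally consistent with the
  printed specific impulses.

No chamber, nozzle, expansion-ratio or dissociation physics is modeled;
the Isp values are comparative upper bounds, which is why
`propellant_for_mission(..., conservative = TRUE)` exposes a 383 s buffer
value for sizing. RP-1 is approximated as n-dodecane in the comparison
table.

## Light-limited growth and its calibration

Areal productivity follows the light-limited balance

$$P = F\left(\alpha E_k \gamma
\ln\!\frac{E_k + E_0}{E_k + E_0 e^{-kD}}\ \frac{t_1}{D}
- R_0 C_c \gamma t_2\right)$$

evaluated exactly as written. The unit convention is: photon fluxes in
mol photons/m²/h, light path D in cm and attenuation k in 1/cm, areal
chlorophyll C~c~ in g/m², respiration R~0~ in mol C/(g chl·h), γ = 22.23 g
biomass per mol C (the mass of the biomass elemental formula per carbon),
photoperiod t~1~ = 12.33 h of a 24.66 h sol. Shared physiology (α = 0.061,
R~0~ = 0.002, E~0~ = 43% of a 2000 µmol/m²/s Earth reference, chlorophyll at
1.5% of biomass) is mode-independent; the two cultivation modes differ only
in geometry and concentration: suspended culture in 4.5 cm bags at 1 g/L
(k = 1.5 cm⁻¹), biofilm in a 0.3 mm film at 7.5 g/m² areal biomass.

Two parameters cannot be taken from literature under this equation's
scaling and are calibrated once, then frozen:

1. **E~k~** (light-saturation flux) is solved so the suspended parameter
   set yields exactly 6.54 g/m²/sol. The solution,
   E~k~ = 0.6730 mol/m²/h ≈ 187 µmol/m²/s, is squarely in the physiological
   range for *A. platensis*, which is the main reason this one-dimensional
   calibration is credible.
2. **k (biofilm)** has no independent value under the printed equation's
   1/D scaling (a literature attenuation coefficient for a dense film,
   combined with the 0.3 mm path, would predict productivities two orders
   of magnitude off). It is therefore back-solved from the biofilm anchor
   of 6.64 g/m²/sol with the shared E~k~ held fixed, giving an effective
   0.404 cm⁻¹. This is an effective, not a mechanistic, parameter.

`calibrate_growth_parameters()` reproduces both numbers from scratch, and
the regression tests lock the two anchors to 1 × 10⁻⁶. The optically thin
limit (ln term → kD·E₀/(E~k~+E₀)) is verified at kD = 10⁻⁶, where the
linearization error (which scales as kD/2 · E~k~/(E~k~+E₀)) is below 10⁻⁶.
The model excludes diel and seasonal light cycles, dust storms, and
CO2-limited growth; it answers "what does the light budget allow", not
"what will a particular season deliver".

## Farm sizing, nutrients, cultivation utilities

Land area is demand/(productivity × mission); illuminated surface is
F = 1.84 times land. Water is 41.47 L/m² of land (suspended bag inventory)
or 2.18 L/m² of substrate (biofilm). Power is mixing (52 W/m³ scaled by
gravity ratio) plus harvest pumping (0.058 kWh/m³) for suspended, and
0.038 W/m² pumping for biofilm.

Nutrient stoichiometry uses 0.029 mol N and 0.002 mol P *per mole of
biomass carbon* — the per-formula-unit elemental composition
(N 0.129, P 0.007 per 4.5 C) divided through by carbon. Reading these
ratios per formula unit instead would understate the diammonium phosphate
demand by ~20%; the per-carbon reading closes the N and P balances against
the reference masses (0.75 t DAP, 1.20 t NH3 for 52.4 t biomass at 20%
excess). DAP is taken as real diammonium phosphate, (NH4)2HPO4,
132.06 g/mol. Trace-element salts are dosed per litre of cultivation water
at the published medium recipe; because suspended culture holds ~10× the
water, this term is materially larger there (~1.4 t vs ~0.13 t), which is
the main reason the computed biofilm/suspended payload ratio (~0.82) sits
at the edge of the reported ~0.85.

Cultivation payload: 0.3 mm substrate (LDPE bags over the illuminated
surface for suspended; cotton or LDPE sheet over the substrate area for
biofilm — cotton at the 1.55 t/m³ fibre density, which reproduces both the
~82% substrate share of cultivation mass and the substrate-dominated total),
a PVC frame equivalent to the 78 t/ha pilot-scale steel structure scaled by
gravity (biofilm reactors at 11% of the suspended frame), and the
nutrients. The 0.3 mm thickness is used for both materials; a 10× thicker
bag would contradict the observed payload split.

## Preprocessing and fermentation

The cross-flow concentrator (suspended mode only) conserves biomass,
removes permeate water to reach the 20 g/L digester feed, and draws
5 kWh/m³ of feed processed. Its flux-consistent membrane area (permeate
flow / 40 L/m²/h ≈ 100 m² at reference scale) disagrees with the
design-basis constant of 155.61 m²; the payload deliberately uses the
larger constant and the discrepancy is flagged in the function
documentation. Biofilm harvest arrives at 20 g/L and bypasses the unit.

Digestion yield is piecewise-linear through (24 h, 0.30 g/g) and
(48 h, 0.45 g/g), clamped outside — a declared interpolation, not data.
The digester works at feed-flow × residence volume, 1.5 kW/m³ mixing
(Mars-reduced impeller duty), a 20% excess-volume steel vessel (2.5
height/radius, 5 mm wall by default — payload only), and 3 g/L of enzymes
replaced every 10 sols for the whole mission. The excess volume does not
contribute to mixing power; including it is possible but worsens agreement
with the reference power totals.

The fermenter consumes all fed glucose at consumption rate
productivity/yield (2.71 g/L/h at the state of the art). The residence
time deserves a note: deriving it from the full 9 g/L feed glucose gives
~199 min, while the process design basis is 72 min — consistent with an
effective consumable-glucose concentration of 3.25 g/L. The 72 min value
is the default (`basis = "design"`) because the downstream design numbers
(fermenter O2 demand ~12 t over the mission at 0.12 mol O2/L/h, the
~3.6 L/min aqueous stream) depend on it; `basis = "from_feed"` exposes the
literal derivation. This is the single largest internal tension in the
design basis and both readings are implemented.

## Separation train

The recovery train is: broth + (recycled + makeup) butanol → liquid–liquid
extraction at 25 °C → organic phase → pervaporation to the 95% 2,3-BDO
product, permeate returned as solvent; aqueous phase → reverse osmosis →
water back to the fermenter.

**Activity model.** NRTL with fixed dimensionless τ at 25 °C. The original
flowsheet's regressed parameters were never published, so the pair
parameters here are set by two bounded calibrations: (i) the
water–butanol pair gives an aqueous butanol saturation near 0.02 wt%, so
the raffinate solvent loss lands at the ~0.01% order of the design basis
— note this is far below butanol's real solubility in water (~7 wt%), i.e.
the model butanol is deliberately more hydrophobic than reality; (ii) the
water–BDO pair gives γ∞(BDO in water) ≈ 650, large enough that a single
equilibrium stage at the default solvent-to-feed ratio of 0.13 recovers
>90% of the product, reproducing the train's implicit near-complete
recovery. A real single-stage butanol extraction of a hydrophilic diol
would recover far less; treat the LLE block as a calibrated surrogate for
a multi-stage extractor, not as predictive ternary thermodynamics. The
flash itself is rigorous for the model: isoactivity is converged by
successive substitution through Rachford–Rice to an activity mismatch
below 10⁻¹², and per-species mass conservation is exact by construction.
Degenerate feeds (no solvent, sub-saturation compositions) return an
explicit no-split result.

**Pervaporation.** Solution-diffusion fluxes J_i = Q_i·x_i·γ_i·P_i^sat
(permeate under vacuum), integrated along the membrane area as a plug-flow
retentate with `deSolve::lsoda` (rtol 10⁻⁹). The butanol permeance is
calibrated so the converged train's organic feed reaches exactly 95%
product purity at 0.5 m²; water and BDO permeances are fixed ratios (0.5
and 0.003) of it. Purity is monotone in area; a feed exhausted before the
full area is flagged and capped. Electrical duty is the permeate latent
heat with 90% condenser heat integration — without that integration the
circulating solvent's latent load (~4 kW) would dominate and contradict
the process power totals; the heat-recovery fraction is an explicit
`membrane_spec` argument.

**Recycle convergence.** The tear stream is the pervaporation permeate,
initialized at zero recycle and iterated with damping 0.7 to a relative
residual of 10⁻⁸ (both exposed). A pure solvent loop has an indeterminate
circulating inventory, so the design specifies the solvent-to-feed mass
ratio and *computes* the butanol makeup as the converged loss rate
(raffinate plus product carry-over, ~0.05–0.07 kg/h at reference scale,
the same order as the 0.001 L/min design makeup). Butanol carried into the
product is not removed — it is itself a serviceable fuel — and purity is
reported as the 2,3-BDO mass fraction. The water-recycle membrane is sized
flux-consistently (flow / 25 L/m²/h ≈ 8.7 m² at reference scale) rather
than from the design basis' inconsistent 13.1 m² payload figure.

## Balances and comparisons

`aggregate_process()` sizes everything backwards from the target:
10 t / 0.432 / 0.45 = 51.44 t of biomass at the state of the art (the
reference documents print 52.4 t; the 2% difference is not derivable from
the printed yields and the chain value is used). The oxygen ledger credits
one O2 per carbon fixed (gross ≈ 1.44 t O2 per t biomass), debits the
fermenter (0.12 mol/L/h × working volume × mission) and the launch LOX
(target × stoichiometric O/P ratio). Report totals are exact sums of the
unit metrics; the DRA 5.0 comparison constants (7.5 t, 26.08 kW, 22.98 t
O2) are fixed inputs, never recomputed, and comparison ratios are derived
at access time. Materials swaps re-run the flowsheet and assert that flows
and power are unchanged. Resupply counts only sub-mission-lifetime
consumables: the biofilm substrate (1–2 year lifetime) and the digestion
enzymes; nutrients and solvent are assumed recovered.

Storage tanks (16 m³ product, 28 m³ LOX) are 6 mm HDPE regardless of the
vessel-material scenario. Vessel wall thickness (5 mm default) affects only
payload and moves the totals by roughly ±1 t at mission scale — the payload
criteria are quoted with that sensitivity in mind.

## Constraint-based yields

The FBA module is self-contained: a BiGG-JSON reader, a minimal SBML/FBC
fallback, pathway patches audited for elemental balance (exchanges exempt),
simulated deletions as zeroed bounds, and a dense two-phase simplex with
Bland's anti-cycling rule operating on shifted non-negative variables with
slack columns for upper bounds. Fixed fluxes (deletions, pinned exchanges)
are substituted out before the solve; the steady-state residual of every
solution is checked. The solver is written for the package's scale — toy
and mid-sized networks in tests; genome-scale models load, but a dense
tableau solve on thousands of reactions is slow and is not exercised in the
default suite, which instead uses the shipped synthetic network
(`inst/extdata/toy_model_synthetic.json`) whose optimum is derived by hand
in the tests (cofactor closure gives product flux 15 at 10 substrate
uptake, and 20/3 when the byproduct route is deleted).

Exchange constraints follow the reference protocol: glucose fixed at
−10, O2 fixed at −15 (equality by default; "fixed" is read literally, with
`o2_constraint = "bound"` available since a ≤ reading is also defensible).
The engineered pathway stoichiometries are reconstructed from the standard
pathway literature — α-acetolactate → acetoin → 2,3-BDO;
3-hydroxybutyryl-CoA → 3-hydroxybutanal → 1,3-BDO; D-lactate → lactoyl-CoA
→ lactaldehyde → 1,2-PDO with the methylglyoxal synthase deletion — since
the original supplementary reaction lists were not available; every added
reaction is elementally balanced against BiGG formulas.

## Problem sizes and determinism

The default test suite runs the full flowsheet (including the converged
separation train) a handful of times and property loops with a few hundred
iterations; everything is deterministic except the seeded sweep generator,
whose draws are reproducible by contract. The acceptance script recomputes
the specific impulse, the rocket-equation masses and the suspended-process
power total from scratch at the 10 t / 500 sol design basis.

## Known limitations

* The growth equation is used as printed; its biofilm attenuation
  coefficient is an effective calibrated value, and the model cannot
  extrapolate biofilm geometry changes mechanistically.
* The LLE thermodynamics are calibrated to the train's anchors, not
  regressed to ternary data; compositions far from the operating point
  (e.g. solvent-rich feeds) should not be trusted quantitatively.
* Temperature is fixed at 25 °C everywhere; no thermal-control energy is
  modeled.
* No dynamic start-up, dust-storm downtime, or seasonal light variation;
  the 10 t target's margin over the 8.4 t rocket-equation requirement is
  the only buffer.
* Water harvesting energetics (1–2 kW/t) are outside the power totals, as
  in the reference design basis.
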
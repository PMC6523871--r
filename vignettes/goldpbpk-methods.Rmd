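---
title: "Methods: a whole-body PBPK model for gold nanoparticle biodistribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a whole-body PBPK model for gold nanoparticle biodistribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goldpbpk)
```

## The model

`goldpbpk` implements a whole-body physiologically-based pharmacokinetic
(PBPK) model for inorganic nanoparticles, built in the tradition of
large-molecule (therapeutic protein) PBPK platforms rather than the
partition-coefficient models used for small molecules. Fifteen organs
(heart, kidneys, muscle, skin, brain, adipose, gonads, liver, stomach,
spleen, pancreas, small intestine, large intestine, bone, lungs) are
compartments connected by plasma and lymph flows. Each organ is divided
into four sub-compartments: organ plasma, vascular endothelium,
interstitial space and macrophages; the liver carries an additional
hepatocyte space. The lungs sit in series with total cardiac plasma
output; the five portal organs (stomach, spleen, pancreas, small and large
intestine) drain their venous outflow through the liver.

Particles move between spaces by five processes:

1. **Extravasation** across the capillary wall, described by the two-pore
   formalism (below).
2. **Transcytosis**: pinocytosis from organ plasma into the endothelium at
   rate `CLup` (0.05 mL/h per mL endothelial cells) and exocytosis to the
   interstitial side at `CLrec` (equal by fluid balance). The direction is
   plasma to interstitium only; the reverse route is not modelled.
3. **Phagocytosis** from the interstitial space into resident macrophages,
   saturable in the intracellular concentration `CiM`:
   `Pup_i = Pup * ViM * KM / (KM + CiM)` with half-saturation
   `KM = 5000 ug/mL`. Macrophages release particles back by exocytosis at
   `CLrec`. In the liver, Kupffer cells line the sinusoids, so a fraction
   `FupM = 0.5` of liver phagocytic uptake is drawn directly from organ
   plasma (the remainder from the interstitium) and a fraction
   `FrecM = 0.5` of exocytosis returns to plasma. A circulating phagocyte
   pool (1% of blood volume) exchanges with venous and arterial plasma
   under the same saturable law.
4. **Lymph recirculation**: interstitial fluid drains to a lymph node
   compartment at the organ lymph flow, reflected by the interstitial
   matrix with coefficient `sigma_IS`; the node empties into venous plasma
   at the total lymph flow (thoracic duct).
5. **Hepatobiliary elimination**: hepatocytes (75% of liver cellular
   volume) take up particles from the liver interstitium by pinocytosis at
   `CLup` and excrete them into bile at the first-order rate `KBile`. For
   particles above 10 nm hydrodynamic diameter this is the only
   elimination route; renal clearance is switched off
   (`renal_clearance_switch()`).

Intraperitoneal (IP) administration is a bolus into a depot. A fraction
`F` of the dose is absorbable (the complement stays sequestered in the
peritoneal space, matching the observation that part of an IP dose remains
there on dissection); the depot drains at the first-order rate `KAbs`,
90% into the portal organs' interstitial spaces in proportion to organ
volume, 10% directly into the lymph node. We implement `F` as the
*absorbed* fraction (estimated 0.76) because the observed day-1 liver
content (about a third of the dose) cannot be reached if only 24% of the
dose were available; the literal complementary convention is available via
`ip_literal_complement = TRUE`.

## Two-pore extravasation

Transcapillary exchange uses the classical two-pore (Rippe–Haraldsson)
construction. For a solute of radius `r_s` in a cylindrical pore of radius
`r_p`, with `a = r_s / r_p`:

* partition coefficient `Phi = (1 - a)^2` (0 for `a >= 1`),
* Renkin diffusive hindrance `Phi (1 - 2.104 a + 2.09 a^3 - 0.95 a^5)`,
  floored at zero,
* reflection coefficient `sigma = 1 - Phi (2 - Phi)(1 - a^2 / 3)`,
  clamped to [0, 1].

Fluid filtration (equal to the organ lymph flow `L` at steady state)
splits between the pore classes with a fraction `alpha_large = 0.05` of
hydraulic conductance in large pores, plus an isogravimetric circular flux
`J_iso` (large-pore filtration balanced by small-pore reabsorption),
parameterised as a fraction of `L` (default 0.5):
`J_large = alpha_large L + J_iso`, `J_small = (1 - alpha_large) L - J_iso`.
The solute flux through each pathway is the Patlak expression

```
Pe   = J (1 - sigma) / PS
flux = J (1 - sigma) (C_plasma - C_interstitial e^-Pe) / (1 - e^-Pe)
```

evaluated with `expm1` and an exponent cap at 700 for numerical
robustness (at that magnitude the pathway is purely convective and the cap
has no modelling effect). The permeability-surface area product anchors
pore geometry to organ physiology: the wall's hydraulic conductance is the
organ lymph flow divided by a net filtration pressure (default 1 mmHg),
each pore class takes its hydraulic share, Poiseuille flow converts the
share into an area-over-path `A0/dx = 8 eta Lp / r_p^2`, and
`PS = (A0/dx) * D_free * hindrance` with `D_free` from Stokes–Einstein at
37 °C in plasma of viscosity 1.2 mPa s.

Default pore radii are 4.5 nm (small) and 25 nm (large) — standard
two-pore literature values. For the study particles (hydrodynamic radii
9.81 and 12.5 nm) the small-pore pathway is therefore *exactly* closed
(`Phi = 0`, `sigma = 1`, `PS = 0`): all extravasation runs through large
pores. Every pore constant is exposed through `pore_system()`, so
alternative values can be dropped in without code change. These defaults
are reconstructions: the two-pore parameterisation is taken from the
protein-PBPK literature the model family descends from, and results that
depend on them inherit that uncertainty.

## Physiology tables

Organ volumes, plasma flows and composition fractions for a 28 g mouse
are packaged explicitly (assembled from the open rodent-physiology
literature used by platform PBPK models) rather than referenced to an
external database, so every downstream number is reproducible from the
shipped table alone. Lymph flow is 0.2% of organ plasma flow (of total
hepatic inflow for the liver); the lymph node volume is 0.113 mL at 28 g.
The rat table is the same canonical per-gram table at 280 g. Scaling to
other body weights is linear in volumes and flows — the simplest
defensible contract given that the model family uses single reference
weights; no allometric exponents are applied. Organ endothelial volume is
derived from vascular surface area as `FiE = ke * FiV * de` with
`ke = 950 cm^2/mL` and `de = 3e-5 cm`, treated as species-independent.

Macrophage volume is a fraction of organ cellular volume: 10% in liver
(Kupffer plus stellate cells), 30% in spleen white pulp, and a
prominent/low classification elsewhere (4%: lungs, kidneys, bone, small
and large intestine; 2%: the rest) informed by macrophage-specific RNA
expression. The per-organ table is packaged and overridable via a
physiology file (`read_physiology_file()`).

## Parameters

| Parameter | Meaning | Unit | Default | Origin |
|---|---|---|---|---|
| `Pup` | max. phagocytosis rate | mL/h/mL macrophage | 0.995 | optimized |
| `KM` | half-saturation in cells | ug/mL | 5000 | fixed |
| `CLup` | pinocytosis rate | mL/h/mL cells | 0.05 | fixed |
| `CLrec` | exocytosis rate | mL/h/mL cells | 0.05 | fixed |
| `KBile` | biliary excretion | 1/h | 0.0128 | optimized |
| `sigma_IS` | lymph reflection | – | 0.64 | optimized |
| `F` | IP absorbable fraction | – | 0.76 | optimized |
| `KAbs` | IP absorption rate | 1/h | 0.1 | chosen |
| `FupM`, `FrecM` | liver plasma-side fractions | – | 0.5 | fixed |

`KAbs` is not reported anywhere; 0.1 h⁻¹ (absorption half-life about 7 h)
is consistent with the substantial liver content observed on day 1 and is
config-exposed and fittable.

## Numerical choices

The 68-state system is integrated with `deSolve::lsoda` at relative
tolerance 1e-8 (1e-10 in the conservation tests) and absolute tolerance
1e-10 of the dose. The right-hand side exists twice: a readable R
reference implementation and a compiled C version registered with deSolve;
the two are cross-checked against each other in the test suite and the C
version is used by default (a 56-day mouse simulation takes ~50 ms).
Concentrations in zero-volume spaces are defined as zero. States are
checked non-negative at output times; integration failure surfaces the
solver diagnostic and the offending compartment.

Mass balance — the sum of all compartments, sinks and depots minus the
administered dose — is tracked for every simulation and stays at the
1e-12 level, far inside the 1e-6 relative requirement asserted in the
tests over an IV/IP × mouse/rat × dose (0.01, 0.7, 10 mg/kg) matrix.

## Fitting, identifiability, evaluation

The four drug-specific parameters (`Pup`, `KBile`, `sigma_IS`, `F`) are
estimated from liver and spleen group means by minimising the sum of
squared log10 residuals — chosen for scale balance between the two organs
whose amounts differ by an order of magnitude; the bounds are the
literature range 0.075–40 for `Pup` and natural physical ranges for the
rest. The optimizer is a temperature-based simulated annealing search
(`stats::optim`, method `"SANN"`) run in a bounded logistic transform
space — log10 scale for the rate constants `Pup` and `KBile`, which span
decades — followed by a Nelder–Mead polish with one restart. A short
dispersed-start screen seeds the annealer. Everything is reproducible
from a single integer seed.

`identifiability_check()` mirrors the pre-fit diagnostic of the original
workflow: finite-difference sensitivities of the log-predictions at the
observation design, pairwise correlations of the sensitivity vectors, and
flags for near-zero sensitivity or |correlation| > 0.95. On the default
design all four parameters pass.

Model evaluation uses the absolute average fold error,
`AAFE = 10^(mean |log10(pred/obs)|)`; zero observations are excluded
rather than floored, since the log is undefined and the evaluation is
restricted to organs with non-zero measurements.

Mouse-to-rat extrapolation swaps only the physiology (`rat`, 280 g) while
keeping every drug parameter and process unchanged; the two packaged rat
evaluation scenarios (0.01 mg Au/kg IV, 20 nm citrate core; 0.7 mg Au/kg
IV, 16 nm citrate core) carry a 46 nm hydrodynamic diameter, the median
evaluation-set hydrodynamic radius of 23 nm. No observed rat values are
packaged — the literature organ data exist only as published figures — so
the rat pipeline is exercised for mass conservation and monotone hepatic
washout, not for a packaged AAFE.

## The synthetic-data generator

`generate_synthetic_observations()` emulates the source study design:
sacrifice groups at days 1, 7, 14, 28 and 56; six measured organs (liver,
spleen, lungs, stomach, kidneys, heart); group sizes of 5–8 animals.
Between-animal variability is lognormal and multiplicative with a 40%
coefficient of variation — the study reports its variability only
qualitatively ("wide"), so the CV is a documented, configurable stand-in
— and the draw is mean-preserving so that group means converge to the
model prediction. What the generator does *not* emulate: measurement
error structure (detection/quantification limits are off by default,
available as a left-censoring threshold), organ-to-organ correlation
within an animal, and fluid loss during dissection. Passing the recovery
tests therefore shows that the estimation machinery is sound under the
stated noise model, not that real biodistribution data are this
well-behaved.

Parameter recovery, as exercised in the test suite: on noise-free
synthetic liver+spleen means generated at the optimized values the fit
recovers all four parameters within 10% (in practice to numerical
precision); under 40% CV noise with n = 6, individual-seed estimates of
`Pup` and `KBile` scatter widely (the data genuinely carry limited
information about them at this noise level) while the median estimate
across 20 seeds stays within 50% of the truth for every parameter — the
sense in which we read the stochastic recovery band.

## Problem sizes used in the checks

The packaged checks use the study's own scales: 56-day horizons, 337-point
output grids (29–57 points in the repeated conservation and recovery
loops), 20 fitting replicates in the noisy-recovery experiment with an
annealing budget of ~100 evaluations plus a 250-iteration polish per fit.
These sizes were chosen to characterise the estimator at the design's
actual dimensions while keeping each experiment self-contained.

## Known limitations

* The organ tables are literature reconstructions, not the exact values
  used to calibrate the original model; absolute organ predictions carry
  this uncertainty (the headline liver reproduction is asserted as an
  upper bound on AAFE partly for this reason).
* The two-pore formalism is unvalidated for particles much larger than
  10 nm radius; convection/diffusion for this class may be overestimated.
* Particle size distributions are not modelled (median radius only), nor
  are surface-chemistry or biocorona effects; the two study formulations
  are treated as one entity.
* Transcytosis is one-directional (plasma → endothelium → interstitium);
  hepatocyte uptake draws from the liver interstitium (the space of
  Disse side); dissected-organ comparisons include residual vascular
  plasma in the organ total. Each is a documented choice where the
  source description is silent, switchable where it matters.
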
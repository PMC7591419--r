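---
title: "Bioheat simulation and volumetric validation of renal cryoablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bioheat simulation and volumetric validation of renal cryoablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoplan)
```

## Scope

`cryoplan` simulates percutaneous cryoablation of renal tumors with up to
nine cryoprobes on a regular voxel grid, predicts the ablated volume through
a lethal-isotherm cell-death model, and quantifies how well a simulated
ablation zone Σ matches a reference zone S segmented from follow-up imaging.
The package is aimed at desk-scale planning and validation studies: all
inputs are binary NIfTI masks, a plain-text needle plan, and a YAML
configuration; everything else (phantoms included) is generated in code.

## The bioheat model

Temperature in perfused tissue follows a Pennes-type bioheat equation

$$C_{\mathrm{eff}}(T)\,\frac{\partial T}{\partial t}
  = \nabla\!\cdot\!\big(k_{\mathrm{eff}}(T)\,\nabla T\big)
  + (1 - D)\,\omega\,\rho_b c_b\,(T_b - T) + Q,$$

with volumetric apparent heat capacity $C_{\mathrm{eff}}$, effective
conductivity $k_{\mathrm{eff}}$, perfusion coefficient $\omega$ (1/s), blood
density and specific heat $\rho_b$, $c_b$, body temperature $T_b$, and the
local dead-cell fraction $D \in [0,1]$. Three modelling commitments matter:

* **Perfusion norming.** Dead tissue is no longer perfused, so the Pennes
  source is attenuated by $(1-D)$. In addition the source is clamped to zero
  wherever $T$ is at or below the solidus: no blood flows through ice. $D$
  enters linearly — the simplest form consistent with "perfusion of the
  surviving fraction".
* **Phase change.** Freezing releases latent heat $L$ over a mushy interval
  $[T_s, T_l]$ (defaults $-8$ to $-1$ °C, configurable). $C_{\mathrm{eff}}$
  is the apparent heat capacity: $\rho c_u$ above $T_l$, $\rho c_f$ below
  $T_s$, and $\rho\,(c_{\mathrm{mix}} + L/(T_l - T_s))$ in between, with
  $c_{\mathrm{mix}}$ interpolating linearly. $k_{\mathrm{eff}}$ interpolates
  between $k_u$ and $k_f$ the same way.
* **Probes as Dirichlet cylinders.** Each needle's active tip (a cylinder of
  length 15 mm for IceSeed, 25 mm for IceRod, radius 0.735 mm; all
  configurable) is held at a fixed temperature: during freezing at
  $T_b + p\,(T_{\mathrm{freeze}} - T_b)$ for power fraction $p \in (0,1]$
  (default $T_{\mathrm{freeze}} = -140$ °C), during active thaw at
  $T_{\mathrm{thaw}} = +20$ °C, and released during passive thaw. A linear
  Dirichlet scaling is the simplest monotone reading of "percentage of the
  maximum freezing power"; no flux-based generator model is attempted.
  Because several needles share one temperature field, multi-needle synergy
  emerges from the physics rather than from a union of single-needle ice
  balls.

Default kidney-like constants (density 1050 kg/m³, $c_u$ 3600 / $c_f$ 1800
J/(kg K), $k_u$ 0.52 / $k_f$ 2.0 W/(m K), $L$ 250 kJ/kg, $\omega$ 0.004 1/s)
are working defaults for soft, well-perfused tissue, not measured renal
values; they live in `inst/extdata/default_config.yaml` and never in code.
Treatment protocols default to the clinical pattern of two cycles of 10 min
freezing, 2 min passive and 1 min active thawing.

## Numerics

The solver is an explicit forward-Euler, 7-point finite-difference scheme on
the voxel grid, with arithmetic-mean face conductivities and insulated
(zero-flux) outer boundaries; the domain should therefore be chosen large
against the expected ice ball. The time step is taken automatically as 0.9
of the conservative stability bound
$C_{\min} / \big(2 k_{\max} (dx^{-2}+dy^{-2}+dz^{-2})\big)$ evaluated with
the worst-case material coefficients, and every step re-checks the bound for
the current fields, refusing to advance otherwise.

The update itself is performed in **conservative enthalpy form**: the
volumetric enthalpy $H$ (whose temperature derivative is
$C_{\mathrm{eff}}$) is advanced by the discrete flux divergence and sources,
then inverted back to temperature through the exact piecewise relation
(linear in the pure phases, a quadratic root across the mushy zone). This is
numerically equivalent to integrating the equation above but has two
decisive properties: total energy is conserved to machine precision under
insulated boundaries, and a voxel that crosses the whole mushy interval
within one step still absorbs the full latent heat. A literal
$C_{\mathrm{eff}}(T)\,\Delta T$ update loses roughly $10^{-3}$ of the total
enthalpy at each front crossing, which accumulates into a visibly biased
freezing front.

Needle rasterization floors the cylinder radius at the in-plane
half-diagonal of a voxel, so a thin 17 G probe whose axis runs between voxel
centers still receives support on coarse grids. Where probes overlap, the
coldest prescription wins.

Two behaviors of the model are worth knowing when interpreting monotonicity
checks. During uninterrupted freezing the frozen-voxel count grows
monotonically. At the restart of freezing after a thaw phase, however, the
outer ice front can keep retreating for tens of seconds — the thaw leaves a
warm annulus around the probe while perfusion keeps heating the margin — so
the global frozen count transiently dips before growing again. This is
physics of the stated model, not a solver artifact, and the package's
monotonicity tests therefore assert strict growth on uninterrupted freezing
phases.

Grid convergence of the conduction/phase-change core is verified by halving
the spacing from 2 mm to 1 mm in a perfusion-free single-needle scenario
with a 3 mm probe (ice-ball volume changes by about 3%). Perfusion is
excluded there deliberately: its all-or-nothing cutoff at the solidus is a
first-order-in-spacing term with a large constant, and with the default
$\omega$ the 2 mm grid is simply outside the asymptotic regime (differences
of order 10%). Production runs at 1 mm are recommended; 2 mm is adequate
for qualitative protocol comparisons.

## Cell death and ablation zones

Cryogenic cell death is modelled by a simple empirical lethal isotherm: a
voxel whose *minimum temperature over the whole thermal history* has reached
$T_{\mathrm{lethal}}$ (default $-20$ °C, configurable) is dead ($D = 1$),
otherwise alive ($D = 0$). Committing death on the historical minimum, not
the final instant, reflects that cryo-injury is irreversible once inflicted.
The dead field is stored as a real-valued fraction for forward compatibility
with graded kinetics (Arrhenius-type models are deliberately out of scope),
but the isotherm model only ever produces 0 or 1. The clinically quoted
lethal range spans roughly $-20$ to $-40$ °C; since the simulated zone
shrinks monotonically as the isotherm is lowered, sensitivity analysis over
this knob is a one-parameter sweep. The simulated ablation zone Σ is the
$D \ge 1$ region; the ice ball is the $T_{\min} \le 0$ °C region, and Σ is
always contained in it.

## Validation metrics

For masks $S$ (reference) and $\Sigma$ (simulated) on a common grid:

* DSC $= 2|S \cap \Sigma| / (|S| + |\Sigma|)$ — symmetric agreement;
* target overlap TO $= |S \cap \Sigma| / |S|$ — low values flag
  *underestimation* (validation reports sometimes call this
  "sensitivity"; identical formula);
* PPV $= |S \cap \Sigma| / |\Sigma|$ — low values flag *overestimation*;
* AAE — the absolute average surface error in mm, implemented as the
  symmetric mean surface distance: boundary voxels are extracted by
  6-connectivity face adjacency, voxel centers form the surface point sets,
  and nearest-neighbour distances are averaged over both directions
  weighted by point counts. The one-line verbal definition ("distance
  between the surfaces of S and Σ") does not fix a direction; the symmetric
  form is chosen because it names both surfaces and is the convention in
  segmentation validation.

DSC is algebraically the harmonic mean of TO and PPV, which the test suite
asserts to $10^{-12}$ on randomly constructed mask pairs. Metrics are rated
on the ordinal scale excellent ($\ge 0.8$), good ($[0.7, 0.8)$), adequate
($[0.6, 0.7)$), inadequate ($[0.5, 0.6)$), poor ($< 0.5$). The literal
upper bin reads "$1 >$ value $\ge 0.8$"; a perfect 1.0 is nevertheless rated
excellent, since perfect overlap cannot sensibly be unrated. Stored metric
values are never rounded; display rounding (volumes and TO/PPV to 2
decimals, DSC conventionally 1–2) happens only in print methods.

`metrics_from_volumes()` supports volume-level checks when only printed
volumes are available; the surface error is then flagged `NA` rather than
approximated.

## Phantoms: what they emulate and what they do not

The phantom module makes every other module testable without clinical data:

* `make_ellipsoid_mask()` voxelizes axis-aligned ellipsoids (voxel centers
  against the ellipsoid inequality); at spacings of a tenth of the semi-axis
  the volume error stays within about 3%.
* `make_overlap_pair()` constructs two masks hitting prescribed volumes
  *and* overlap each to within one voxel, by growing a central overlap core
  and two disjoint lateral appendages in a deterministic nearest-first scan
  order; the seed only jitters the appendage centers. Exactness to one voxel
  is guaranteed by construction, which is why volume-level worked examples
  can be reproduced from voxel counts rather than from real segmentations.
* `make_case_fixture()` writes a full synthetic case (kidney and tumor
  ellipsoids, a 2–4 needle fan through the tumor centroid, configuration)
  with tumor diameter capped at 4.5 cm, the inclusion scale of the clinical
  population this mirrors.

These phantoms reproduce grid geometry, volumetry and overlap topology; they
do **not** emulate anatomical shape, image intensities, registration error,
needle deflection, or inter-patient variability of perfusion. A passing
suite therefore demonstrates correctness of the simulator and metrics, not
clinical accuracy of predicted ablation zones — the published experience
with models of this family is that simulated zones *overestimate* the real
ablation zone, and the erosion-based tests reproduce exactly that signature
(TO $= 1$, PPV $< 1$) rather than claim calibration.

## Degenerate inputs and tie-breaks

Empty masks are rejected wherever a ratio would be undefined (both masks for
DSC, $S$ for TO, $\Sigma$ for PPV, either for AAE). Sub-voxel ellipsoids may
rasterize to empty masks without error. A zero-cycle protocol is valid and
returns body-temperature tissue with no dead cells, while a structurally
invalid protocol errors. Needle directions are normalized on construction
and validated to unit norm on file ingest ($10^{-6}$ tolerance); plans are
limited to 1–9 needles. The minimal enclosing sphere uses Welzl's
move-to-front algorithm on boundary voxel centers with an exhaustive
$\le 4$-point base case, so ties (cocircular support sets) resolve to the
same sphere regardless of point order.

## Problem sizes used in the shipped checks

The automated checks run, on one CPU in a few minutes: volume-level metric
reproductions on $96^3$–$128^3$ voxel grids at 1 mm; stepper-vs-oracle
equivalence on $8^3$; the spherical-probe analytic benchmark on $64^3$ at
1 mm (probe radius 4 mm, outer shell pinned to the analytic far field,
1500 s of relaxation); concentric-sphere surface-error calibration at
0.5 mm; grid convergence 2 mm vs 1 mm on a 48 mm domain; and the
monotonicity suite (duration doubling, needle addition, in-phase ice-ball
growth) at 2 mm. These sizes were chosen as the smallest at which each
property is in its asymptotic regime.

## Known limitations

* Tissue is homogeneous; no histology-dependent perfusion, no large-vessel
  heat sinks, no metabolic heat.
* The probe model ignores the generator's internal physics; power fractions
  scale a surface temperature, not a refrigerant flux.
* Explicit time stepping only; very fine grids pay a quadratic time-step
  penalty (an implicit solver is out of scope by design).
* Binary cell death; no freeze-rate or repetition-count kinetics, although
  the two-cycle protocol is simulated thermally.
* No image registration, DICOM handling, or segmentation: masks are assumed
  co-registered on a shared grid, and the package refuses bundles whose
  geometries disagree beyond $10^{-6}$ mm.
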
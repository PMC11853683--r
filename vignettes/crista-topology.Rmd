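---
title: "Modeling how inner-membrane topology modulates mitochondrial ATP output"
author: "cristaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling how inner-membrane topology modulates mitochondrial ATP output}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cristaflux)
```

## The problem

In working heart muscle, most ATP comes from mitochondria whose inner
membrane (IM) is densely folded into cristae. ATP synthase flux is set by
matrix ADP, which is supplied by the adenine nucleotide translocase (ANT)
from the ADP available *inside* cristae — and that, in turn, depends on
diffusion of cytosolic ADP through narrow crista junctions (CJs) into the
intracristal space (ICS). Dense IM packing therefore carries a "diffusion
penalty": standing ADP gradients form inside cristae at steady state and
depress ATP output. `cristaflux` is a virtual mitochondrion for
quantifying how the number, position and width of CJs, crista length, and
crista branching modulate that penalty.

## The reduced metabolic model

Three reactions drive the solute fields, in the package's canonical units
(um, ms, mM, mV; 1 mM = 602,214 molecules/um^3; flux densities per um^2 of
membrane):

**ANT** (electrogenic 1:1 ADP_in/ATP_out exchange, on every membrane
element):

$$J_{ANT} = V_{ANT}\,
\frac{1 - \dfrac{[ATP^{4-}]_e [ADP^{3-}]_m}{[ADP^{3-}]_e [ATP^{4-}]_m}
  e^{-F\psi_m/RT}}
{\left(1 + \dfrac{[ATP^{4-}]_e}{[ADP^{3-}]_e} e^{-f_P F\psi_m/RT}\right)
 \left(1 + \dfrac{[ADP^{3-}]_m}{[ATP^{4-}]_m}\right)}$$

with the ionic species fixed fractions of the totals. $\psi_m$ is held at
172 mV and $f_P = 0.5$; $RT/F \approx 26.7$ mV at the default 310 K (the
model does not prescribe a temperature; 310 K is the physiological
choice).

**ATP synthase** (driven by the matrix pool, uniform over the whole IM):

$$J_{AS} = V_{AS}\,
\frac{\frac{ADP_m}{K_{ADP}}\frac{Pi_m}{K_{Pi}} - \frac{ATP_m}{K_{ATP}}}
{\left(1+\frac{ADP_m}{K_{ADP}}\right)\left(1+\frac{Pi_m}{K_{Pi}}\right)
 + \frac{ATP_m}{K_{ATP}}}\;
\frac{\psi_m^8}{K_{V}^8 + \psi_m^8}\;\left(1 - e^{-Ca_m/K_{Ca}}\right)$$

The denominator grouping shown is the default; a flat-sum variant is
available via `kinetic_params(as_denominator = "flat")` because the
grouping is ambiguous in some transcriptions of this rate-law family.

**Surrogate kinase** (mass action, everywhere in the external solute
domain), standing in for adenylate/creatine-kinase cycling:
$V_{SK} = k_f\,ATP_e - k_r\,ADP_e\,Pi_e$, with the printed rates
$k_f = 0.009\ \mathrm{ms}^{-1}$ and $k_r = 1\ \mathrm{mM^{-1}ms^{-1}}$
(the latter interpreted with bimolecular units, the only dimensionally
consistent reading). By default $Pi_e$ is set per condition to
$k_f\,ATP_{cyt}/(k_r\,ADP_{cyt})$, which places the kinase exactly at
equilibrium at the boundary composition — the "tuned near equilibrium,
sensitive to local ADP" behavior — and, importantly, preserves the
workload dependence of intracristal depletion (deeper at low cytosolic
ADP) at every sweep point. A fixed $Pi_e$ is configurable; values below
~2 mM turn the kinase into a net ADP source at low workload (cristae fill
up), and larger fixed values invert the workload dependence, which is why
the equilibrium convention is the default.

Matrix ADP/ATP form a single well-mixed pool with conserved adenine total
(resting 0.72 + 0.44 = 1.16 mM): the reported steady state is a scalar
matrix composition plus one flux-vs-matrix-ADP relationship, which a
spatially resolved matrix would only perturb at second order. Cytosolic
ADP (0.0185–0.074 mM, the low-to-moderate workload sweep) and ATP
(4.0 mM) are Dirichlet data on the outer boundary.

## Geometry and discretization

Models are cell-centered finite-volume grids (default spacing 2 nm in
2-D — at least 10 cells across a 20-nm lumen — and 5 nm in 3-D, a
tractable compromise for boxes of ~10^4–10^5 cells). The external solute
domain is the crista lumens plus a 20-nm boundary layer standing in for
the OM gap/cytosol between the IM boundary (IBM) and the Dirichlet cells.
Membrane faces are faces between an external cell and a matrix cell; CJs
are open apertures (absent wall segments), not explicit channel objects.
The surface ledger classifies each face as crista membrane or IBM and
satisfies `S_IM = S_IBM + S_CRIS` exactly.

Three builders cover the study geometries:

* `build_uniform_2d()`: parallel cristae 20 nm wide, spaced 20 nm apart,
  with CJs at one end, both ends, or none. The array is strictly periodic
  across its width, so the standard condition grid runs a one-crista unit
  cell (`domain_w = 0.04`), which reproduces the infinite array at a
  fraction of the cost; the full-width array (19 cristae across 0.76 um)
  builds identically for visualization and cross-checks.
* `build_variable_2d()`: a trunk with CJs at both ends plus two side
  branches (lengths `L/3`, `L/4`) drawn perpendicular to the trunk, each
  running from its own CJ on the side IBM to an opening in the trunk
  wall; attachment heights 0.40 L and 0.60 L put the junctions in the
  depleted mid-trunk region. The boundary layer surrounds this model on
  all four sides.
* `build_lamellar_3d()`: a lamellar crista (150 nm wide, 20 nm lumen)
  attached to an IBM patch through no CJ, a 20-nm tubular CJ, a 150-nm
  slit CJ, or `n` equally spaced narrow CJs. The simulated box holds the
  crista, a thin matrix collar and the boundary-layer slab; IBM area
  beyond the simulated patch is carried as an analytic term operating at
  boundary-layer composition (it would sit within 20 nm of the Dirichlet
  data, where the fields are flat to <1%). That term is sized so
  S_CRIS/S_IBM follows a linear schedule from 1.0 at L = 0.15 um to 1.8
  at L = 0.9 um — the documented range for models of this class; the
  exact box proportions behind that range are not published, and the flux
  decomposition removes most of the residual dependence on them.

## Solving to steady state

The discrete steady equations per external cell couple diffusion, the
kinase, and membrane sources (ANT consumes lumen ADP and produces lumen
ATP; flux densities convert to volumetric rates through face area / cell
volume). Because ANT exchange and the kinase are strict 1:1
conversions, the ADP+ATP sum field obeys pure diffusion with uniform
Dirichlet data whenever the two diffusivities are equal, so the system
reduces *exactly* to a single-species problem; `cristaflux` solves that
by damped Newton iteration with an analytic ANT Jacobian, and closes the
matrix pool by a monotone scalar root-find on the flux balance
(total ANT uptake = total synthase flux) under adenine conservation. A
coupled two-species sparse-Newton path handles unequal diffusivities.
Either way the solver reports the residuals of the full, unreduced
two-species equations (typically ~1e-10 relative) plus the matrix-balance
residual, so correctness does not rest on the reduction. A pseudo-time
integrator was considered and rejected: the kinase rate (~2/ms) forces
sub-millisecond stable steps over ~100 ms of pseudo-time, which is
orders of magnitude more linear algebra for the same fixed point.

Detached (no-CJ) lumens have no Dirichlet connection, and 1:1 exchange
plus the kinase conserve their adenine total, leaving the steady state
underdetermined by one constant per compartment. The package closes it by
fixing each detached lumen's adenine total to the cytosolic total
(equivalently: lumens start at cytosolic composition before sealing).

Numerical conventions: concentrations are clamped to a 1e-12 mM floor
inside Newton steps; the matrix root-find brackets the open interval of
the adenine total; profiles are sampled on the two central lumen columns
and averaged; depletion integrals use the trapezoid rule with flat
extension over the end half-cells.

## Calibration of unprinted constants

The rate-law family's maximum velocities, binding constants, phosphate,
calcium and diffusivities are not printed with the model; `calibrate()`
fixes a chosen subset against three documented behavioral anchors:

1. the no-crista model at the top of the workload sweep sustains
   ~100 molecules ATP/ms/um^2 (consistent with experimental maxima for
   cardiomyocyte mitochondria, e.g. 1.3 mM ATP/s per liter of cells ~
   70 molecules/ms/um^2 via `convert_cell_rate_to_area_flux()`);
2. steady matrix ADP across the standard 18-condition grid spans
   ~0.18–0.37 mM;
3. the fitted gradient steepness `k` spans ~1–3.7 /um.

The bundled `params-calibrated-2025.yaml` is the frozen result (weighted
least-squares on the relative anchor errors, Nelder-Mead on log scales,
evaluated on the corner conditions at 4-nm resolution), with ionic
fractions 0.45 (ADP3-) and 0.05 (matrix ATP4-) from standard
physiological speciation, and the external ATP4- fraction calibrated —
it sets the translocase saturation scale
$ATP_e\,e^{-f_P F\psi/RT}\,f_{ATP^{4-}}/f_{ADP^{3-}}$, which must fall
inside the cytosolic ADP sweep to reproduce the workload dependence of
gradient steepness.

**A structural limitation, documented deliberately.** At steady state,
total ANT uptake equals CJ diffusive influx plus net kinase production,
and deep inside a long crista the local balance is
$c\,J_{ANT}(A) = k_f ATP_e - k_r Pi_e A$ with
$c = (2/w)/602214$ for a lumen of width $w$. With the printed kinase
rates and 4 mM ATP, the regeneration term (~0.036 mM/ms) is of the same
order as the anchored translocase's volumetric capacity (~0.02 mM/ms), so
intracristal ADP cannot fall much below roughly half its mouth value at
low workload: the kinase feeds an ADP/ATP cycle that both floors the
depletion and keeps deep ANT flux high. Consequently this model family
reproduces the *direction and ordering* of every topology effect
(depletion grows with length, shrinks with workload and with a second CJ;
flux ordering detached < one narrow CJ < one wide CJ < two CJs; the Rule
of 2), but compresses the extreme magnitudes: maximal area-based
depletions calibrate to ~25–40% rather than ~66%, fitted steepness tops
out near ~2.5 /um rather than 3.7, and worst-case diffusion penalties
to a few percent rather than 13–23%. Pushing any single magnitude to its
published extreme (large fixed $Pi_e$, or negligible $k_f$) breaks a
qualitative property the package treats as non-negotiable — the workload
direction of depletion, the near-parabolic profiles, or the substantial
flux of detached cristae (which *requires* kinase cycling). The
calibration therefore optimizes the three anchors above and accepts the
compressed extremes; the acceptance suite reports the corresponding
checks honestly rather than retuning toward them.

## The analysis layer

* `adp_profile()` / `depletion()` / `fit_quadratic()`: midline ICS
  profiles, area-based depletion `1 - AUC/(ADP0 L)`, and the quadratic
  gradient law `ADP(x) = ADP0 - a x (L - x)` with steepness
  `k = a L / ADP0` (for one-CJ cristae, fit the `mirror_profile()`).
* `rule_of_two_check()`: a one-CJ crista of length L against the first
  half of a two-CJ crista of length 2L.
* `diffusion_penalty()`, `decompose_flux()` / `recompose_flux()` (the
  surface-ledger split of model flux into IBM and crista contributions),
  `ibm_correction()`, `speed_zone()` (fast >= 0.9, moderate [0.75, 0.9),
  slow < 0.75; boundaries closed below, an explicit convention).
* `build_flux_curves()`: 3-D solves for detached / one-narrow / one-wide
  classes over a length grid (default 0.15/0.45/0.9 um plus the
  half-lengths), crista-contribution fluxes relative to the no-crista
  maximum, monotone `monoH.FC` interpolants, flat-clamped extrapolation;
  two-CJ (trans) classes synthesized by the Rule of 2 (one-CJ curve at
  L/2).
* `census_score()`: whole-mitochondrion J/J_MAX as the segment-length
  weighted average of per-crista curve values; cristae connected at both
  ends are scored on the Rule-of-2 transformed curve; one-end cristae on
  the one-CJ curve at full length; detached cristae on the no-CJ curve.
  Branch segments sharing a trunk enter through summed segment lengths
  (the `seg_length_total_um` column when present).

## The synthetic census generator

`generate_census()` emulates the morphometric structure of a reference
cardiomyocyte mitochondrion's 16 lamellar cristae: lengths rising
linearly with index across 0.41–1.46 um (Gaussian noise, s.d. 0.05 um,
clamped), branching Bernoulli with probability 5/7 above 0.8 um and 2/9
below, CJs per segment from a truncated normal (mean 2.2, s.d. 0.6,
clamped at 1, rounded half-up), CJ diameters 17 +/- 5 nm, spanning
cristae (length >= 0.55 um) connected at both ends with probability
11/12, and a configured CJ surface density (~220 /um^2) carried as
metadata. It reproduces aggregate statistics, not row-level identities;
the bundled `census_observed_synthetic.csv` is a hand-constructed
observed-like table (mean length 0.86 um, seven branched cristae, four
non-spanning) and is labelled synthetic because the underlying per-crista
measurements are not published as a table. What passing generator tests
show is distributional fidelity (moments, trends, reproducibility); they
cannot show fidelity to any individual mitochondrion.

## Problem sizes and runtimes

The standard grids run comfortably on one core: the 18-condition 2-D grid
at 2-nm resolution takes a few seconds; the 3-D flux-curve set at 5-nm
resolution a few minutes (the largest box, L = 0.9 um, has ~2.3e4
external cells); the variable-topology model about a minute. The test
suite uses 4-nm 2-D grids and short cristae for mechanics, reserving
production resolutions for the acceptance checks.

## Known limitations

* The compressed extreme magnitudes discussed under calibration.
* No proton/pH field, no time-varying membrane potential, no calcium
  dynamics, no electrodiffusion, no transient physiology.
* The matrix is a single pool (a diffusive matrix would add resistance in
  series and deepen penalties slightly).
* 3-D models cover the lamellar class only; fenestrated microstructure
  and tubular cristae are out of scope.
* Real tomogram meshes are not imported; the census path starts from
  per-crista tables.
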
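---
title: "A micro-multiphysics agent-based model of bone defect regeneration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A micro-multiphysics agent-based model of bone defect regeneration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`callusim` simulates the healing of a stabilised femoral osteotomy at
micro-CT resolution by coupling three sub-models on one voxel lattice
(10.5 µm isotropic): a voxel hexahedral micro-finite-element (micro-FE)
model of the mechanics, an implicit finite-difference reaction–diffusion–
decay (RDD) model of cytokines and oxygen, and a single-cell agent-based
model of the bone, immune, and vascular cell populations. This vignette
explains the model, its assumptions, the parameters that matter, and what
the synthetic phantom experiments can and cannot show.

## The coupled model

### Mechanics

Every voxel is one 8-node trilinear hexahedral element. Mineral density
(mg HA/cm³) maps to an isotropic Young's modulus by linear interpolation
between 4 GPa at 395 mg HA/cm³ and 14 GPa at 720 mg HA/cm³; tissue below
395 mg HA/cm³ is soft (3 MPa). Poisson's ratio is 0.3 everywhere. The
system is solved matrix-free with Jacobi-preconditioned conjugate
gradients; within a coupled run the previous solution warm-starts the next
solve and a solve is skipped entirely whenever no voxel has changed its
modulus.

Two load cases drive the biology:

* **Apparent stiffness** `k_c`: 1% uniaxial compression of the construct,
  distal face fixed axially, in-plane motion free up to rigid-body pins.
  `k_c` = reaction force / applied displacement. We read "simple uniaxial
  compression" as axially constrained but transversely free faces; the
  alternative (fully clamped faces) adds a confinement artefact that breaks
  the E·A/L closed form the implementation is verified against.
* **Ambulatory loading**: combined compression and bending through the
  external fixator. The proximal-face axial displacement varies linearly
  across the section towards the fixator plane,
  u_z(x) = −u₀(1 + β(x−x_f)/d), with the fixator a distance d = 2 mm to
  one side. The linear solution is rescaled so the total axial reaction
  equals the habitual peak force F_w = 10.5 N, and the callus carries the
  share k_c/(k_c + k_f) of it, with the fixator stiffness
  k_f = 23.8 N/mm.

The stimuli are strain-energy density (SED, MPa) for embedded osteocytes
and effective strain EFF = √(2·SED/E) for cells in soft tissue. Both are
smoothed with a truncated Gaussian (σ = 1.0 voxel, support 0.8, read as a
truncation radius of ⌈support/σ⌉ = 1 voxel — the convention is not uniquely
defined, so both parameters are exposed in `[mechanics]`). The kernel is
renormalised at the domain faces so constant fields are invariant. EFF is
computed per element and filtered independently of SED. The osteogenic
threshold is 0.008 (MPa for SED, strain for EFF), the osteolytic window is
SED < 0.015 MPa.

### Transport and signalling

Seven species diffuse and decay: VEGF, RANKL, OPG, sclerostin (Scl),
TGF-β, the RANKL–OPG complex, and oxygen. Each 30-minute step solves
backward-time centred-space (BTCS, unconditionally stable)
∂c/∂t = ∇·(D∇c) − λc with harmonic-mean face conductances, Dirichlet
proximal/distal faces at each species' background value, and reflective
lateral faces. All cytokines share one soft-tissue diffusivity and are
100× less diffusive in mineralised tissue; oxygen diffuses equally in
both. The six cytokines share one system matrix, which only changes when a
voxel crosses the mineralisation threshold, so the engine keeps a sparse
Cholesky factor and reduces each step to a backsolve; oxygen keeps a
preconditioned-CG path because vessel voxels are additional Dirichlet
sources at the normoxic set-point (0.065 mol/m³) and that set grows
continuously. The two paths agree to solver tolerance and are
cross-checked in the test suite.

Cellular oxygen consumption is continuous: occupied voxels carry a
first-order sink (nominal rate 0.02 mol/m³/s at normoxia, tapering linearly
with concentration) applied inside the implicit oxygen step, so diffusion
and consumption balance simultaneously and the steady profiles have the
classic ~150 µm supply length around vessels and boundaries. A cell is
"oxygen-sufficient" when its local concentration exceeds the hypoxia
threshold (0.01 mol/m³, ~15% of the normoxic set-point); with continuous
consumption the per-iteration-consumption criterion reduces to exactly such
a fixed concentration threshold.

Receptor–ligand binding (RANK–RANKL, VEGFR–VEGF, TGFBR1–TGF-β,
LRP5/6–Scl) follows linear mass action per cell,
dB/dt = k_on·c·(N−B) − k_off·B, integrated exactly over the step with the
local concentration frozen; bound ligand is removed from the cell's voxel
so free + bound mass is conserved, and uptake is limited to the ligand the
voxel actually holds. Free OPG and RANKL combine irreversibly into the
complex. Defaults: K_D = 10⁻⁶ mol/m³ (≈1 nM), k_off = 2.8·10⁻⁴ s⁻¹,
N = 1000 sites per receptor type. The site count matters more than it
looks: receptor pools act as a distributed ligand sink, and the
sustainable mean occupancy is roughly
production / (k_off · pool · n_cells). The production rates below were
chosen so that RANK occupancy exceeds the 50% differentiation gate near
unloaded cortex within days, while remaining well below it where bone is
mechanically loaded.

### Cells

One agent per voxel. Mineralised voxels (≥395 mg HA/cm³) host only
(pre-)osteocytes; soft voxels host SSPC, HSC, immune (M2) cells,
osteoblasts (OBL), osteoclasts (OCL), lining cells and endothelial cells.
On the 20-minute cell clock (24 updates per 8-hour FE interval, RDD steps
interleaved after every 1.5 cell updates on a fixed schedule table):

* **Migration**: one face step (10.5 µm) per update at step probability 1
  gives the 31.5 µm/h target speed. Occupied soft destinations are swapped
  with, except OBL↔OCL (refused — it would shuttle formation onto fresh
  resorption sites) and anchored residents. OCL drift up the RANKL field
  and OBL towards higher EFF with probability 0.5, else walk randomly; the
  directed variants take the best admissible neighbour.
* **Differentiation** (one transition per cell and step, gated by the
  oxygen-sufficiency flag): SSPC→OBL under oxygen +
  osteogenic strain + TGFBR1 engagement (>50%); SSPC/OBL lining bone at
  sub-threshold EFF become lining cells; lining→OBL above threshold unless
  sclerostin occupies LRP5/6 (>50%); HSC→OCL with oxygen and RANK > 50%;
  immune→OCL on RANK > 50% even in hypoxia; OBL caught by the
  mineralisation front embed as pre-osteocytes with probability 0.0519
  (calibrated so embedded density converges to 44 800 cells/mm³), are
  otherwise displaced to a free soft neighbour, and mature to osteocytes
  after 240 h.
* **Population**: SSPC and HSC divide (0.02 h⁻¹) when oxygen-sufficient
  and mechanically stimulated, into a free soft neighbour; SSPC, HSC, OBL,
  immune cells (0.008 h⁻¹) and OCL (0.01 h⁻¹) undergo spontaneous
  apoptosis; osteocytes and lining cells do not.
* **Production** (linear in the stimulus, clamped at zero): osteocytes
  read SED — RANKL and Scl fall to zero at the 0.015 MPa window edge, OPG
  rises; OBL/lining cells read EFF the same way at one tenth the osteocyte
  rates; VEGF = v_max·(1 − oxygen fulfilment) for SSPC, OBL, OCL,
  pre-osteocytes, lining and immune cells; immune cells make TGF-β at a
  constant rate.
* **Formation**: OBL above the EFF threshold deposit 5 mg HA/cm³ of
  osteoid into their own voxel and one face neighbour chosen by a softmax
  (sharpness β = 5) over neighbour EFF; vessel voxels and voxels at the
  720 cap are excluded. Osteoid mineralises at 30 mg HA/cm³/day, and a
  latent TGF-β fraction is banked in the mineral.
* **Resorption**: only face-adjacent OCL clusters of ≥3 with mean RANK
  occupancy >50% resorb, with probability 0.1 per cluster and update, one
  adjacent mineralised voxel inside the osteolytic window (SED < 0.015),
  polarised towards minimal ‖∇SED‖ by the same softmax. Mineral and
  osteoid are removed together, banked TGF-β returns to the field, and an
  embedded osteocyte in the voxel dies.

### Vasculature

Endothelial tip cells extend by one voxel per update (probability 0.5)
when local VEGF exceeds the sprout-maintenance threshold, choosing between
the VEGF gradient (p = 0.5), the previous direction (0.3) and a random
admissible step (0.2). The vacated voxel remains vessel (a stalk agent
anchors it). Stalks above the branching threshold bifurcate at rate
10⁻³ per update; a tip touching a foreign segment anastomoses, which
counts as a loop only when the two segments were already connected
(union–find over segments). Growth is not mechanosensitive. Vessel voxels
are oxygen sources and never carry osteoid: deposition excludes them, and a
tip invading an osteoid-bearing voxel clears the unmineralised matrix.

## Initial conditions

The phantom (`build_phantom()`) rasterises two hollow-cylinder cortical
fragments at 720 mg HA/cm³ separated by a transverse gap, with a 52.5-µm
periosteal shell. The defect-centre mask dilated by 210 µm defines the
haematoma; VEGF and oxygen start 5× above background inside it. The RDD
runs 48 iterations (one day) before any cell is placed. Seeding: SSPC on
50% of free periosteal voxels and 10% of the haematoma; immune cells on
10% of the haematoma; HSC on 5% of the marrow; lining cells on 20% of the
bone surfaces; osteocytes in mineralised tissue at the 44 800 /mm³ target;
exactly 200 endothelial tip cells on the periosteal and endosteal
fragment surfaces. No OBL or OCL exist at day 0 and all receptors start
unbound. The periosteal/haematoma/marrow seeding fractions are package
defaults (the quantitative seeding table behind the original protocol is
not public); all are exposed in `[seeding]`.

## Desk-scale phantom and load scaling

The default phantom is deliberately small — cortex outer radius 63 µm,
gap 210 µm, domain 24×24×50 voxels — so that a full 35-day coupled run
(105 FE solves, 11 760 implicit RDD steps, ~250 000 agent updates)
completes in minutes on one CPU. A real murine data set is ~12 million
elements; the phantom is a geometric scale model, and two quantities must
be scaled with it to keep the biology in the physiological regime:

* **Transmitted load.** At 10.5 N a cross-section 100× smaller than the
  murine femur would see ~100× the tissue stress, pinning every voxel
  above all thresholds. The engine therefore transmits
  F_w · (Ct.Ar / Ct.Ar_ref) · k_c/(k_c+k_f), with Ct.Ar the phantom's
  post-operative cortical area and Ct.Ar_ref = 0.92 mm² the murine
  reference: equal habitual stress rather than equal force. For a
  full-scale image the ratio is ≈1 and the 10.5 N applies unchanged.
* **Oxygen and VEGF scales.** The ~150 µm oxygen supply length that
  physiological consumption produces is comparable to the phantom's gap, so
  the avascular defect centre turns hypoxic within the first day and drives
  the VEGF → angiogenesis → oxygen-gated osteogenesis sequence, while the
  fragment surfaces (which carry the seeded tip cells, themselves oxygen
  sources) stay normoxic. VEGF signalling is production-driven: a small
  background (10⁻⁸ mol/m³), a sprout-maintenance threshold just above it,
  and a hypoxic production ceiling large enough that the chemotactic
  gradient survives the receptor sink of the dense cell population.

Both choices are stated here as the package's scaling policy, not tuning
knobs, and are exposed in the configuration.

## Numerical choices

* FE: relative residual 10⁻⁶ for standalone solves, 10⁻⁴ inside the
  coupled loop (the stimuli only enter through thresholds); matrix-free
  Jacobi-PCG; element matrices by 2×2×2 Gauss quadrature.
* RDD: CG to 10⁻⁶ with a diagonal incomplete-Cholesky preconditioner;
  cached sparse Cholesky for the shared cytokine matrix. One implicit step
  agrees with a dense solve to 10⁻¹² on a 5³ lattice and converges first
  order in dt to the matrix exponential.
* Reaction: exact exponential relaxation per step, uptake clamped to the
  locally available ligand; occupancy cannot leave [0, 1].
* Ties and polarisation draws use the Gumbel-argmax form of the softmax;
  flat score fields reduce to uniform choice.
* All randomness flows from one master seed through named per-module
  streams (init, agents, vessels), so runs are bit-reproducible and
  module-level tests are independently repeatable; checkpoints store the
  stream states, and a restored run continues bit-identically.
* Degenerate inputs: zero-stiffness meshes, unconstrained solves, empty
  dilation masks, gap-free lattices and over-dense seeding requests all
  raise errors rather than propagate.

## Morphometry

The evaluation layer mirrors standard time-lapsed micro-CT practice:
multidensity bone volumes at 395:25:720 mg HA/cm³ in the four automatic
VOIs (defect centre/periphery spanning the gap, fragment centre/periphery,
normalised DC/DC, DP/DC, FC/FC, FP/FC); the BV645/BV395 mineralisation
ratio; formation/quiescence/resorption voxel sets between consecutive
time points with BFR/BRR in %/day; cortical metrics (slice-wise Ct.Ar and
Ma.Ar, distance-transform ridge Ct.Th, closed-pore Ct.Po, cortical
threshold 720); gap width by rays cast from the least-squares longitudinal
axis every 2°, a direction's width being the number of bone-free axial
positions × 10.5 µm, with the median reported; connected (≥2-voxel,
26-neighbourhood) vascular volume; and RMSE of BV/TV series per VOI and
threshold averaged over time points.

## What the phantom experiments show — and what they cannot

With the default configuration a 0.21 mm gap bridges well inside 35
simulated days: the haematoma turns hypoxic, VEGF rises, vessels cross the
gap, SSPC differentiate and the osteoid front mineralises until the
ray-traced gap median reaches zero and the apparent stiffness rises toward
a plateau; doubling the gap at identical parameters and loading yields
less periosteal bone and a softer construct — the qualitative non-union
ordering. These phantom runs exercise every coupling in the pipeline, but
they are not a validation against animal data: the geometry is idealised
and scaled, the seeding densities and production coefficients are package
defaults rather than fitted values, and quantities that depend on absolute
scale (stiffness in N/mm, absolute bone volumes, vessel counts) should
only be compared within a study, not to in vivo measurements. The model
also excludes, by design, chondrocytes and endochondral repair,
intracortical vasculature, interstitial flow, and nonlinear tissue
mechanics.

## Known limitations

* The exact interleaving of RDD sub-steps and cell updates within the 8-h
  macro-step is a reconstruction (fixed schedule table, RDD after every
  1.5 cell updates); the ordering is part of the engine contract and
  asserted in tests.
* The bending displacement profile is a single-parameter linearisation of
  fixator mechanics; d and β are configurable.
* Receptor kinetics use one shared K_D and site count per receptor type;
  the per-type values behind the original protocol are not public.
* Lining cells are seeded at a package-default surface fraction; the
  paper-level protocol seeds them with SSPC but does not quantify the
  split.
* Anastomosis joins segments at first face contact; vessel diameters,
  maturation and perfusion are out of scope.
```
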
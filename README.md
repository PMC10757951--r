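# callusim

`callusim` is an R package that simulates bone regeneration in a stabilised
femoral osteotomy at micro-CT resolution. It couples three sub-models on a
single lattice of 10.5 µm voxels:

* **micro-FE mechanics** — every voxel is an 8-node hexahedral element;
  mineral density (mg HA/cm³) maps linearly to Young's modulus
  (395 → 4 GPa, 720 → 14 GPa, soft tissue 3 MPa, ν = 0.3). Ambulatory
  loading through an external fixator (peak force F_w = 10.5 N, fixator
  stiffness k_f = 23.8 N/mm, callus load share k_c/(k_c + k_f)) yields the
  stimuli: strain-energy density (SED) for osteocytes and effective strain
  EFF = √(2·SED/E) for soft-tissue cells, both Gaussian-regularised
  (σ = 1 voxel). Osteogenesis above SED/EFF = 0.008, resorption inside
  SED < 0.015 MPa.
* **reaction–diffusion–decay** — an implicit (BTCS) finite-difference
  solver moves VEGF, RANKL, OPG, sclerostin, TGF-β, the RANKL–OPG complex
  and oxygen (mineralised tissue is 100× less diffusive for cytokines),
  with receptor–ligand mass-action binding on every cell and continuous
  cellular oxygen consumption.
* **cell agents** — one cell per voxel: skeletal and hematopoietic
  progenitors, immune cells, osteoblasts, osteoclasts, lining cells,
  (pre-)osteocytes and endothelial tip/stalk cells, with mechano- and
  cytokine-regulated migration (31.5 µm/h), proliferation, apoptosis,
  differentiation, strain-polarised osteoid deposition (mineralising at
  30 mg HA/cm³/day), cluster-gated resorption (≥3 osteoclasts, RANK > 50%)
  and VEGF-driven sprouting angiogenesis.

A synthetic femur-osteotomy phantom generator, an in silico gap-size study
driver, and a time-lapsed morphometry layer (multidensity BV/TV, BFR/BRR,
cortical metrics, ray-traced gap width, vascular volume, RMSE scoring)
complete the pipeline. The methods vignette
(`vignettes/bone-regeneration-model.Rmd`) documents the model, its
assumptions and the desk-scaling policy in detail.

## Worked example

```r
library(callusim)

cfg <- sim_config()                      # all model parameters, seed 1
sim <- run_simulation(cfg)               # 35 simulated days, ~3 min
summary(sim)
#>   day   bvtv_dc gap_median_mm         k_c
#> 1   0 0.0000000          0.21          NA
#> 2   7 0.0000000          0.21   0.4854491
#> 3  14 0.7263393          0.00 107.2355270
#> 4  21 0.7294643          0.00 203.9899267
#> 5  28 0.7294643          0.00 235.5755509
#> 6  35 0.7294643          0.00 235.5755509
```

Reading the table: the phantom's 0.21 mm osteotomy gap (`gap_median_mm`,
measured by ray tracing from the femoral axis) is fully bridged by day 14;
the bone volume fraction of the defect centre (`bvtv_dc`) rises from zero
to ~0.73; and the construct's apparent stiffness `k_c` climbs from
0.49 N/mm (open gap, load carried by soft tissue) to a ~236 N/mm plateau as
the mineralised callus consolidates. Doubling the gap at identical
parameters leaves it unbridged after five weeks with a ~130× softer
construct and less periosteal bone — the critical-gap-size behaviour:

```r
wide <- run_simulation(sim_config(phantom = list(gap_width = 420)))
tail(summary(wide), 1)
#>   day   bvtv_dc gap_median_mm      k_c
#> 6  35 0.4495536         0.084 1.750971
```

Per-snapshot morphometry (`sim$morphometry`), agent tables
(`sim$snapshots[[i]]$cells`), the per-step population/event ledger
(`sim$timeline`) and checkpointing (`save_snapshot()` /
`restore_snapshot()`, bit-identical continuation) give access to every
layer; `gap_size_study()` translates the distal fragment in 0.15 mm steps
to reproduce the full gap-size sweep.

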
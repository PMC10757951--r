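# Simulation configuration: every tunable of the coupled model, grouped by
# sub-model, with the calibrated defaults. Units are stated per field.
# Configs round-trip through YAML files whose top-level sections mirror the
# groups below ([phantom], [seeding], [mechanics], [species], [cells],
# [production], [vessels], [engine]).

#' Default simulation configuration
#'
#' Builds the full parameter set of the coupled model. Any field can be
#' overridden via named nested lists, e.g.
#' `sim_config(engine = list(duration_days = 7))`.
#'
#' Groups and core defaults:
#' \describe{
#'   \item{mechanics}{density-to-modulus map (395 -> 4 GPa, 720 -> 14 GPa,
#'     soft tissue 3 MPa, Poisson 0.3), osteogenic/osteolytic thresholds
#'     (SED 0.008 / 0.015 MPa, EFF 0.008 / 0.015), peak ambulatory force
#'     10.5 N, fixator stiffness 23.8 N/mm, Gaussian regularisation
#'     (sigma 1.0 voxel, support 0.8), solver tolerance.}
#'   \item{species}{shared cytokine diffusivity in soft tissue, the 100x
#'     mineral diffusivity penalty, decay constants, oxygen parameters
#'     (normoxic set-point 0.065 mol/m^3), receptor-ligand kinetics.}
#'   \item{cells}{update interval 20 min, migration step probability (one
#'     10.5-um step per update = 31.5 um/h), proliferation/apoptosis rates,
#'     embedding probability calibrated to 44'800 osteocytes/mm^3,
#'     polarisation sharpness.}
#'   \item{engine}{micro-FE interval 8 h (24 cell updates, 16 RDD steps of
#'     30 min), duration 35 days, master seed.}
#' }
#'
#' @param ... Named nested lists overriding groups of defaults.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    phantom = list(
      outer_radius = 63, inner_radius = 31.5,
      frag_len_proximal = 126, frag_len_distal = 126,
      gap_width = 210, periosteum = 52.5, haematoma_dilation = 210,
      margin_xy = 10.5, margin_z = 31.5, voxel_size = 10.5
    ),
    seeding = list(
      sspc_periosteum = 0.50,   # fraction of free periosteal voxels
      sspc_haematoma = 0.10,    # fraction of free haematoma voxels
      immune_haematoma = 0.10,
      hsc_marrow = 0.10,
      lining_surface = 0.20,    # fraction of free endosteal+periosteal surface
      ocy_density = 44800,      # cells/mm^3 of mineralised tissue
      n_tips = 200,
      o2_background = 0.065,    # mol/m^3 (normoxic)
      haematoma_factor = 5,     # VEGF and O2 multiplier inside haematoma
      vegf_background = 1e-8,   # mol/m^3
      prerun_iterations = 48    # RDD iterations (1 day) before cell seeding
    ),
    mechanics = list(
      E_low = 4000, E_high = 14000, E_soft = 3,   # MPa
      rho_low = 395, rho_high = 720,              # mg HA/cm^3
      nu = 0.3,
      sed_for = 0.008, eff_for = 0.008,           # osteogenic thresholds
      sed_res = 0.015, eff_res = 0.015,           # osteolytic thresholds
      F_w = 10.5,                                 # N, peak ambulatory force
      k_f = 23.8,                                 # N/mm, fixator stiffness
      fixator_offset = 2000,                      # um, distance d to fixator
      reference_ct_ar = 0.92,                     # mm^2, in vivo cortical area
      bending_beta = 1,
      sigma = 1.0, support = 0.8,                 # Gaussian regularisation
      compression = 0.01,                         # stiffness protocol strain
      tol = 1e-6, run_tol = 1e-4, maxit = 20000
    ),
    species = list(
      D_soft = 100,         # um^2/s, shared by all cytokines in soft tissue
      mineral_ratio = 100,  # soft/mineral diffusivity ratio for cytokines
      decay = 1e-4,         # 1/s, cytokine decay
      D_o2 = 2000,          # um^2/s, oxygen (equal in soft tissue and bone)
      o2_decay = 0,
      dt_rdd = 1800,        # s (30 min)
      kon = 280,            # m^3/(mol s), receptor on-rate
      koff = 2.8e-4,        # 1/s, receptor off-rate (KD = 1e-6 mol/m^3)
      k_complex = 280,      # m^3/(mol s), OPG + RANKL -> RANKL-OPG
      binding_sites = 1e3,  # per cell and receptor type
      rdd_tol = 1e-6, rdd_maxit = 2000
    ),
    cells = list(
      dt_cells = 1200,          # s (20 min)
      p_move = 1.0,             # step probability: 31.5 um/h at 1.0
      p_bias = 0.5,             # directed-migration probability (OBL, OCL)
      proliferation = 0.02,     # 1/h, SSPC and HSC
      apoptosis = 0.008,        # 1/h, SSPC/HSC/OBL/Immune
      apoptosis_ocl = 0.01,     # 1/h
      p_embed = 44800 * (10.5e-3)^3, # OBL->preOCY at mineralisation front
      maturation_h = 240,       # preOCY -> OCY, hours
      receptor_threshold = 0.5, # RANK / TGFBR1 / LRP5-6 gating occupancy
      o2_consumption = 0.02,    # mol/m^3/s per cell at normoxia
      o2_threshold = 0.01,      # mol/m^3, hypoxia threshold for sufficiency
      osteoid_increment = 5,    # mg HA/cm^3 per deposition event
      p_resorb = 0.1,           # resorption event probability per cluster step
      polar_beta = 5            # polarisation softmax sharpness
    ),
    production = list(
      # mol/m^3/s at zero signal (rates clamp at >= 0)
      ocy_rankl = 2e-7, ocy_scl = 1e-7, ocy_opg = 1e-7,
      obl_rankl = 1e-8, obl_opg = 1e-8,   # also lining cells
      vegf_max = 1e-6,                    # hypoxia-driven, all listed types
      immune_tgfb = 1e-7,
      tgfb_bank = 1e-8,   # latent TGF-beta stored per mg HA/cm^3 mineralised
      sed_cap = 10        # linear laws capped at cap x threshold signal
    ),
    vessels = list(
      p_grad = 0.5, p_persist = 0.3, p_rand = 0.2,
      sprout_threshold = 1.2e-8, # mol/m^3 VEGF to keep a tip growing
      branch_threshold = 1e-7,  # mol/m^3 VEGF for bifurcation
      branch_rate = 1e-4,       # per stalk voxel per cell update
      p_tip_move = 0.5
    ),
    engine = list(
      dt_fe = 28800,       # s (8 h) between micro-FE solves
      duration_days = 35,
      snapshot_days = 7,   # weekly snapshots
      seed = 1,
      gap_step = 150       # um, fragment translation step of the gap study
    )
  )
  over <- list(...)
  for (grp in names(over)) {
    if (!grp %in% names(cfg)) stop("unknown config group: ", grp)
    bad <- setdiff(names(over[[grp]]), names(cfg[[grp]]))
    if (length(bad)) stop("unknown config field(s) in ", grp, ": ", paste(bad, collapse = ", "))
    cfg[[grp]] <- utils::modifyList(cfg[[grp]], over[[grp]])
  }
  validate_config(structure(cfg, class = "sim_config"))
}

validate_config <- function(cfg) {
  m <- cfg$mechanics
  stopifnot(
    m$F_w > 0, m$k_f > 0, m$E_low <= m$E_high, m$nu > 0, m$nu < 0.5,
    cfg$species$dt_rdd > 0, cfg$cells$dt_cells > 0, cfg$engine$dt_fe > 0
  )
  n_cells <- cfg$engine$dt_fe / cfg$cells$dt_cells
  n_rdd <- cfg$engine$dt_fe / cfg$species$dt_rdd
  if (abs(n_cells - round(n_cells)) > 1e-9 || abs(n_rdd - round(n_rdd)) > 1e-9) {
    stop("dt_fe must be an integer multiple of dt_cells and dt_rdd")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (grp in names(x)) {
    v <- unlist(x[[grp]])
    cat("  [", grp, "] ", paste(names(v), v, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read / write a configuration file
#'
#' Configurations are stored as YAML with one top-level section per group.
#'
#' @param path File path.
#' @return For `read_config`, a validated `sim_config`.
#' @export
read_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A `sim_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
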
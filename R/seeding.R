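# Post-operative initial conditions: cell seeding, initial fields, and the
# one-day RDD pre-run.
#
# SSPC are seeded densely in the periosteum and sparsely in the haematoma
# (the defect-centre mask dilated by 210 um); immune (M2) cells in the
# haematoma; HSC in the endosteal cavity; lining cells on the bone surfaces;
# osteocytes in mineralised tissue at the calibration target density; 200
# endothelial tip cells on the periosteal and endosteal surfaces of both
# fragments. No osteoblasts or osteoclasts exist at day 0. VEGF and oxygen
# start 5x higher inside the haematoma than background; all receptors are
# unbound. The RDD runs 48 iterations (one day) before cells are placed, to
# wash out initialisation artifacts.

#' Seeding plan
#'
#' @param config A [sim_config()]; the `seeding` group provides defaults.
#' @param ... Overrides for individual fields.
#' @return An object of class `seeding_plan`.
#' @export
seeding_plan <- function(config = sim_config(), ...) {
  plan <- utils::modifyList(config$seeding, list(...))
  stopifnot(plan$n_tips >= 0, plan$o2_background > 0, plan$haematoma_factor > 0)
  structure(plan, class = "seeding_plan")
}

sample_mask <- function(mask, frac, occ) {
  free <- which(mask & occ == 0L)
  n <- round(frac * length(free))
  if (n == 0) return(integer(0))
  if (n > length(free)) stop("requested seeding density exceeds free voxels")
  sample(free, n)
}

#' Initialise the model state on a lattice
#'
#' Builds the haematoma and anatomical masks, sets the initial cytokine and
#' oxygen fields, executes the one-day RDD pre-run, then seeds all agents.
#' With a fixed seed the result is bit-identical across runs.
#'
#' @param lattice A post-operative [sim_lattice()] (e.g. from
#'   [build_phantom()]).
#' @param plan A [seeding_plan()].
#' @param config A [sim_config()].
#' @param streams RNG streams from the engine; created from
#'   `config$engine$seed` when `NULL`.
#' @return List: `lattice` (occupancy filled), `cells`, `state`
#'   (a [cytokine_state()] after the pre-run), `net` (vessel network),
#'   `vois`, `haematoma` mask.
#' @export
initialise_model <- function(lattice, plan = seeding_plan(config),
                             config = sim_config(), streams = NULL) {
  if (is.null(streams)) streams <- make_streams(config$engine$seed)
  dims <- lattice$dims
  TY <- CELL_TYPES

  vois <- make_vois(lattice)
  haem <- make_haematoma(vois$DC,
    radius = config$phantom$haematoma_dilation,
    voxel_size = lattice$voxel_size
  )
  shells <- surface_shells(lattice, config$phantom$periosteum)

  # initial fields, then the one-day pre-run (48 implicit iterations)
  state <- cytokine_state(lattice, config)
  soft_haem <- haem & lattice$mineral < MINERAL_THRESHOLD
  state$conc$O2[soft_haem] <- plan$o2_background * plan$haematoma_factor
  state$conc$VEGF[soft_haem] <- plan$vegf_background * plan$haematoma_factor
  for (it in seq_len(plan$prerun_iterations)) {
    for (sp in state$species$name) {
      state <- step_diffusion_decay(state, sp)
    }
  }

  cells <- new_cell_table()
  occ <- lattice$occupancy
  soft <- lattice$mineral < MINERAL_THRESHOLD

  with_stream(streams, "init", {
    place <- function(cells, type, vox) {
      occ[vox] <<- 1L # reserve; rebuilt below
      add_cells(cells, type, vox, dims)
    }
    cells <- place(cells, TY[["SSPC"]],
      sample_mask(shells$periosteum & soft, plan$sspc_periosteum, occ))
    cells <- place(cells, TY[["SSPC"]],
      sample_mask(soft_haem, plan$sspc_haematoma, occ))
    cells <- place(cells, TY[["Immune"]],
      sample_mask(soft_haem, plan$immune_haematoma, occ))
    cells <- place(cells, TY[["HSC"]],
      sample_mask(shells$marrow & soft, plan$hsc_marrow, occ))
    surface <- (shells$periosteum | shells$endosteum) & soft
    cells <- place(cells, TY[["Lining"]],
      sample_mask(surface, plan$lining_surface, occ))
    # osteocytes at the calibration target density in mineralised tissue
    p_ocy <- plan$ocy_density * (lattice$voxel_size * 1e-3)^3
    mine <- which(!soft & occ == 0L)
    ocy <- mine[runif(length(mine)) < p_ocy]
    cells <- place(cells, TY[["OCY"]], ocy)
    # endothelial tip cells: periosteal + endosteal surfaces of the fragments
    tip_pool <- which(surface & occ == 0L)
    if (length(tip_pool) < plan$n_tips) stop("not enough free surface voxels for tip cells")
    tips <- sample(tip_pool, plan$n_tips)
    cells <- place(cells, TY[["EndothelialTip"]], tips)
    NULL
  })

  lattice$occupancy <- rebuild_occupancy(cells, dims)
  net <- vessel_network(dims)
  sv <- seed_vessels(net, lattice, cell_voxels(
    cells[cells$type == TY[["EndothelialTip"]], ], dims))
  net <- sv$net
  lattice <- sv$lattice
  # tips carry their segment id
  cells$segment[cells$type == TY[["EndothelialTip"]]] <-
    net$segment[cell_voxels(cells[cells$type == TY[["EndothelialTip"]], ], dims)]

  list(
    lattice = lattice, cells = cells, state = state, net = net,
    vois = vois, haematoma = haem
  )
}
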
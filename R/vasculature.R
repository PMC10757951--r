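# Lattice angiogenesis: endothelial tip cells extend through soft tissue by
# a three-way choice between VEGF chemotaxis, persistence, and a random
# step; stalks are laid behind the tips; new tips arise by bifurcation at
# existing stalks; tips touching a foreign segment anastomose and close a
# loop. Vessel growth is not mechanosensitive. Vessel voxels are held at the
# normoxic oxygen set-point during RDD steps, and never receive osteoid.

#' Create an empty vessel network
#'
#' @return An object of class `vessel_network`: `segment` (per-voxel segment
#'   id, 0 = no vessel), `parent` (per-voxel 1-based parent voxel index,
#'   0 = seed), `anastomoses` (two-column matrix of joined voxel pairs) and
#'   `loops` (loop count).
#' @param dims Lattice dimensions.
#' @export
vessel_network <- function(dims) {
  structure(
    list(
      segment = array(0L, dims),
      parent = array(0L, dims),
      anastomoses = matrix(integer(0), 0, 2),
      loops = 0L,
      next_segment = 1L,
      seg_parent = integer(0)
    ),
    class = "vessel_network"
  )
}

# register seed voxels (initial tip positions) as vessel voxels
seed_vessels <- function(net, lattice, vox) {
  ids <- seq.int(net$next_segment, length.out = length(vox))
  net$segment[vox] <- ids
  net$next_segment <- net$next_segment + length(vox)
  net$seg_parent[ids] <- ids
  lattice$vessel[vox] <- TRUE
  list(net = net, lattice = lattice)
}

# union-find over segment ids: an anastomosis between segments already in
# the same component closes a loop; otherwise it merges two trees
seg_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# direction vectors matching face_neighbours() column order
DIR_OFFSETS <- rbind(
  c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
  c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L)
)

#' Extend vessel tips
#'
#' Every tip whose local VEGF is above the sprout-maintenance threshold
#' attempts one face step (with the configured move probability) chosen by a
#' three-way draw: up the VEGF gradient (best admissible neighbour), along
#' its previous direction, or uniformly at random. Admissible voxels are
#' unoccupied soft tissue without vessel. The vacated voxel stays vessel
#' (stalk); a stalk agent is left behind. A tip landing next to a foreign
#' segment anastomoses: it converts to a stalk and the loop count grows.
#'
#' @param cells Agent table.
#' @param lattice A [sim_lattice()].
#' @param net A [vessel_network()].
#' @param vegf VEGF concentration field.
#' @param config A [sim_config()].
#' @return List `cells`, `lattice`, `net`, `n_moved`, `n_anastomosed`.
#' @export
extend_tips <- function(cells, lattice, net, vegf, config = sim_config()) {
  vs <- config$vessels
  TY <- CELL_TYPES
  dims <- lattice$dims
  tips <- which(cells$type == TY[["EndothelialTip"]])
  n_moved <- 0L
  n_ana <- 0L
  if (length(tips) == 0) {
    return(list(cells = cells, lattice = lattice, net = net,
                n_moved = 0L, n_anastomosed = 0L))
  }
  u_gate <- runif(length(tips))
  u_mode <- runif(length(tips))
  u_pick <- runif(length(tips))
  new_stalks <- integer(0)
  stalk_seg <- integer(0)

  for (k in seq_along(tips)) {
    i <- tips[k]
    if (u_gate[k] >= vs$p_tip_move) next
    vi <- vox_index(cells$x[i], cells$y[i], cells$z[i], dims)
    if (vegf[vi] < vs$sprout_threshold) next
    nb <- face_neighbours(vi, dims)[1, ]
    ok <- nb > 0L
    ok[ok] <- lattice$mineral[nb[ok]] < MINERAL_THRESHOLD &
      !lattice$vessel[nb[ok]] & lattice$occupancy[nb[ok]] == 0L
    if (!any(ok)) next # dormant

    mode <- if (u_mode[k] < vs$p_grad) {
      "grad"
    } else if (u_mode[k] < vs$p_grad + vs$p_persist) "persist" else "rand"
    dest <- NA_integer_
    dirn <- NA_integer_
    if (mode == "grad") {
      cand <- which(ok)
      dirn <- cand[which.max(vegf[nb[cand]])]
      dest <- nb[dirn]
    } else if (mode == "persist") {
      d <- cells$dir[i]
      if (!is.na(d) && ok[d]) {
        dest <- nb[d]
        dirn <- d
      } # else dormant this step
    } else {
      cand <- which(ok)
      dirn <- cand[ceiling(u_pick[k] * length(cand))]
      dest <- nb[dirn]
    }
    if (is.na(dest)) next

    seg <- net$segment[vi]
    # move: old voxel becomes a stalk, new voxel becomes the tip;
    # invading vasculature clears any unmineralised osteoid there
    lattice$occupancy[vi] <- 0L
    lattice$occupancy[dest] <- i
    lattice$vessel[dest] <- TRUE
    lattice$osteoid[dest] <- 0
    net$segment[dest] <- seg
    net$parent[dest] <- vi
    co <- index_vox(dest, dims)
    cells$x[i] <- co[1]; cells$y[i] <- co[2]; cells$z[i] <- co[3]
    cells$dir[i] <- dirn
    new_stalks <- c(new_stalks, vi)
    stalk_seg <- c(stalk_seg, seg)
    n_moved <- n_moved + 1L

    # anastomosis with a face-adjacent foreign segment
    nb2 <- face_neighbours(dest, dims)[1, ]
    nb2 <- nb2[nb2 > 0L]
    foreign <- nb2[lattice$vessel[nb2] & net$segment[nb2] != seg &
      net$segment[nb2] > 0L]
    if (length(foreign)) {
      net$anastomoses <- rbind(net$anastomoses, c(dest, foreign[1]))
      ra <- seg_find(net$seg_parent, seg)
      rb <- seg_find(net$seg_parent, net$segment[foreign[1]])
      if (ra == rb) {
        net$loops <- net$loops + 1L # same component: a genuine loop
      } else {
        net$seg_parent[ra] <- rb
      }
      cells$type[i] <- TY[["EndothelialStalk"]]
      n_ana <- n_ana + 1L
    }
  }
  if (length(new_stalks)) {
    cells <- add_cells(cells, CELL_TYPES[["EndothelialStalk"]], new_stalks,
      dims,
      segment = stalk_seg
    )
    lattice$occupancy <- rebuild_occupancy(cells, dims)
  }
  list(cells = cells, lattice = lattice, net = net,
       n_moved = n_moved, n_anastomosed = n_ana)
}

#' Vessel bifurcation
#'
#' Stalk voxels with VEGF above the branching threshold and a free
#' soft-tissue neighbour spawn a new tip there with the configured branching
#' rate. The branch inherits its parent's segment id.
#'
#' @inheritParams extend_tips
#' @param dt_steps Number of cell updates this call covers (rate scaling).
#' @return List `cells`, `lattice`, `net`, `n_branched`.
#' @export
branch_vessels <- function(cells, lattice, net, vegf, config = sim_config(),
                           dt_steps = 1) {
  vs <- config$vessels
  TY <- CELL_TYPES
  dims <- lattice$dims
  rate <- vs$branch_rate * dt_steps
  n_br <- 0L
  if (rate > 0) {
    stalks <- which(cells$type == TY[["EndothelialStalk"]])
    if (length(stalks)) {
      vi <- vox_index(cells$x[stalks], cells$y[stalks], cells$z[stalks], dims)
      hot <- vegf[vi] >= vs$branch_threshold
      fire <- which(hot & runif(length(stalks)) < rate)
      for (k in fire) {
        vi_k <- vi[k]
        nb <- face_neighbours(vi_k, dims)[1, ]
        nb <- nb[nb > 0L]
        free <- nb[lattice$mineral[nb] < MINERAL_THRESHOLD &
          !lattice$vessel[nb] & lattice$occupancy[nb] == 0L]
        if (length(free) == 0) next
        dest <- free[sample.int(length(free), 1L)]
        seg <- net$segment[vi_k]
        lattice$vessel[dest] <- TRUE
        lattice$osteoid[dest] <- 0
        net$segment[dest] <- seg
        net$parent[dest] <- vi_k
        cells <- add_cells(cells, TY[["EndothelialTip"]], dest, dims,
          segment = seg
        )
        n_br <- n_br + 1L
      }
      if (n_br > 0) lattice$occupancy <- rebuild_occupancy(cells, dims)
    }
  }
  list(cells = cells, lattice = lattice, net = net, n_branched = n_br)
}

#' Vessel voxels as oxygen sources
#'
#' @param lattice A [sim_lattice()].
#' @param o2_setpoint Oxygen concentration imposed at vessel voxels
#'   (mol/m^3).
#' @return `list(idx, val)` suitable for `extra_dirichlet` in
#'   [step_diffusion_decay()].
#' @export
oxygen_sources <- function(lattice, o2_setpoint = sim_config()$seeding$o2_background) {
  idx <- which(lattice$vessel)
  list(idx = idx, val = o2_setpoint)
}

#' Vessel segment graph
#'
#' Builds the network graph (nodes = vessel voxels, edges = parent links
#' plus anastomoses) for connectivity audits and loop counting.
#'
#' @param net A [vessel_network()].
#' @return An igraph graph whose vertex names are voxel linear indices.
#' @export
vessel_graph <- function(net) {
  vox <- which(net$segment > 0L)
  par <- net$parent[vox]
  edges <- cbind(vox[par > 0L], par[par > 0L])
  edges <- rbind(edges, net$anastomoses)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(vox))
  )
  g
}

#' Vascular volume within a VOI
#'
#' Counts connected vessel voxels (26-connectivity components, singleton
#' voxels excluded) inside the mask and converts to a volume and a volume
#' fraction.
#'
#' @param lattice A [sim_lattice()].
#' @param voi Logical mask (defaults to the whole domain).
#' @return List `vv_um3` (vascular volume, um^3), `vv_tv` (fraction of the
#'   VOI volume), `n_voxels`.
#' @export
vascular_volume <- function(lattice, voi = NULL) {
  dims <- lattice$dims
  if (is.null(voi)) voi <- array(TRUE, dims)
  lab <- label_components_cpp(as.logical(lattice$vessel), as.integer(dims), 26L)
  if (attr(lab, "n_components") > 0) {
    sizes <- tabulate(lab[lab > 0L])
    connected <- array(lab > 0L & sizes[pmax(lab, 1L)] >= 2L, dims)
  } else {
    connected <- array(FALSE, dims)
  }
  n <- sum(connected & voi)
  vv <- n * lattice$voxel_size^3
  list(vv_um3 = vv, vv_tv = n / max(sum(voi), 1), n_voxels = n)
}
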
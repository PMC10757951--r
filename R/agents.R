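# Cell agents and their behaviours.
#
# Each agent occupies one voxel (at most one agent per voxel). Soft-tissue
# voxels (< 395 mg HA/cm^3) may host SSPC, HSC, immune (M2) cells, OBL, OCL,
# lining cells and vascular endothelial cells; mineralised voxels only
# pre-osteocytes and osteocytes. Behaviours run on the 20-min cell clock:
# random-walk migration with swap (one 10.5-um face step per update gives
# the 31.5 um/h target speed), proliferation and spontaneous apoptosis,
# the oxygen/strain/receptor-gated differentiation map, mechanically
# regulated cytokine production, strain-polarised osteoid deposition, and
# cluster-gated resorption.

#' Create an empty agent table
#'
#' @return A zero-row data frame with the agent schema: `id`, `type`
#'   (see [cell_type_codes()]), 0-based voxel coordinates `x`, `y`, `z`,
#'   receptor occupancy fractions (`occ_rank`, `occ_vegfr`, `occ_tgfbr`,
#'   `occ_lrp`), `age_h`, `embed_h` (hours since osteoblast embedding),
#'   `dir` (previous direction, tips), `segment` (vessel segment id) and
#'   the oxygen-sufficiency flag `o2_ok`.
#' @export
new_cell_table <- function() {
  data.frame(
    id = integer(0), type = integer(0),
    x = integer(0), y = integer(0), z = integer(0),
    occ_rank = numeric(0), occ_vegfr = numeric(0),
    occ_tgfbr = numeric(0), occ_lrp = numeric(0),
    age_h = numeric(0), embed_h = numeric(0),
    dir = integer(0), segment = integer(0), o2_ok = logical(0)
  )
}

add_cells <- function(cells, type, vox, dims, segment = NA_integer_,
                      dir = NA_integer_) {
  if (length(vox) == 0) return(cells)
  co <- index_vox(vox, dims)
  id0 <- if (nrow(cells)) max(cells$id) else 0L
  new <- data.frame(
    id = id0 + seq_along(vox), type = as.integer(type),
    x = co[, 1], y = co[, 2], z = co[, 3],
    occ_rank = 0, occ_vegfr = 0, occ_tgfbr = 0, occ_lrp = 0,
    age_h = 0, embed_h = NA_real_,
    dir = as.integer(dir), segment = as.integer(segment), o2_ok = TRUE
  )
  rbind(cells, new)
}

# occupancy array consistent with the table's row order
rebuild_occupancy <- function(cells, dims) {
  occ <- array(0L, dims)
  if (nrow(cells)) {
    occ[vox_index(cells$x, cells$y, cells$z, dims)] <- seq_len(nrow(cells))
  }
  occ
}

cell_voxels <- function(cells, dims) vox_index(cells$x, cells$y, cells$z, dims)

#' Migration sweep
#'
#' One face-adjacent random-walk step for every mobile agent (SSPC, HSC,
#' immune, OBL, OCL, lining), restricted to soft tissue. Occupied targets are
#' swapped with — except OBL/OCL pairs (refused, to avoid a formation/
#' resorption loop) and anchored residents. With probability `p_bias`, OCL
#' step towards the neighbour richest in RANKL and OBL towards the highest
#' effective strain. Visit order is reshuffled every sweep.
#'
#' @param cells Agent table.
#' @param lattice A [sim_lattice()] (its occupancy is rewritten).
#' @param rankl,eff 3D signal fields used for the directed biases.
#' @param config A [sim_config()].
#' @return List `cells`, `lattice`, and `nmoved`.
#' @export
migrate_cells <- function(cells, lattice, rankl, eff, config = sim_config()) {
  n <- nrow(cells)
  if (n == 0) return(list(cells = cells, lattice = lattice, nmoved = 0L))
  dims <- lattice$dims
  res <- migrate_cpp(
    cbind(cells$x, cells$y, cells$z), cells$type,
    as.integer(lattice$occupancy),
    as.numeric(lattice$mineral), as.numeric(rankl), as.numeric(eff),
    as.integer(dims), MINERAL_THRESHOLD,
    sample.int(n) - 1L, runif(n), runif(n), runif(n),
    rep_len(config$cells$p_move, n), config$cells$p_bias
  )
  cells$x <- res$pos[, 1]; cells$y <- res$pos[, 2]; cells$z <- res$pos[, 3]
  occ <- res$occ
  dim(occ) <- dims
  lattice$occupancy <- occ
  list(cells = cells, lattice = lattice, nmoved = res$nmoved)
}

#' Detect osteoclast clusters
#'
#' Resorption-competent clusters are connected components of OCL under face
#' adjacency with three or more members.
#'
#' @param cells Agent table.
#' @param dims Lattice dimensions.
#' @param min_size Minimum component size (default 3).
#' @return List of integer vectors of agent row indices, one per cluster.
#' @export
detect_clusters <- function(cells, dims, min_size = 3L) {
  rows <- which(cells$type == CELL_TYPES[["OCL"]])
  if (length(rows) < min_size) return(list())
  mask <- array(FALSE, dims)
  vi <- vox_index(cells$x[rows], cells$y[rows], cells$z[rows], dims)
  mask[vi] <- TRUE
  lab <- label_components_cpp(as.logical(mask), as.integer(dims), 6L)
  labs <- lab[vi]
  keep <- as.integer(names(which(table(labs) >= min_size)))
  lapply(keep, function(k) rows[labs == k])
}

#' Differentiation map
#'
#' Applies the transition table once (at most one transition per cell):
#' embedding of osteoblasts caught by the mineralisation front
#' (own voxel >= 395 mg HA/cm^3: with the calibrated embedding probability
#' they become pre-osteocytes, otherwise they are pushed to a free soft
#' neighbour or die); pre-osteocyte maturation after the maturation time;
#' SSPC -> OBL (oxygen-sufficient, osteogenic strain, TGFBR1 engaged);
#' SSPC/OBL lining mineral at sub-threshold strain -> lining cell;
#' lining -> OBL (strain above threshold, LRP5/6 below the sclerostin
#' inhibition threshold, oxygen-sufficient); HSC -> OCL (oxygen-sufficient,
#' RANK occupancy > 50%); immune -> OCL (RANK occupancy > 50%, no oxygen
#' requirement).
#'
#' @param cells Agent table.
#' @param lattice A [sim_lattice()].
#' @param sed,eff Regularised stimulus fields.
#' @param config A [sim_config()].
#' @return List `cells`, `lattice`, and a named vector `flows` of transition
#'   counts (including `embed_died`).
#' @export
differentiate_cells <- function(cells, lattice, sed, eff,
                                config = sim_config()) {
  cc <- config$cells
  m <- config$mechanics
  dims <- lattice$dims
  TY <- CELL_TYPES
  flows <- c(
    sspc_obl = 0L, to_lining = 0L, lining_obl = 0L, hsc_ocl = 0L,
    imm_ocl = 0L, obl_preocy = 0L, preocy_ocy = 0L, embed_died = 0L
  )
  if (nrow(cells) == 0) {
    return(list(cells = cells, lattice = lattice, flows = flows))
  }
  vi <- cell_voxels(cells, dims)
  mineral_here <- lattice$mineral[vi] >= MINERAL_THRESHOLD
  changed <- logical(nrow(cells))
  dead <- logical(nrow(cells))

  # --- mineralisation front: soft-type agents caught in mineralised voxels
  trapped <- which(cells$type <= TY[["Lining"]] & mineral_here)
  if (length(trapped)) {
    u <- runif(length(trapped))
    for (k in seq_along(trapped)) {
      i <- trapped[k]
      if (cells$type[i] == TY[["OBL"]] && u[k] < cc$p_embed) {
        cells$type[i] <- TY[["preOCY"]]
        cells$embed_h[i] <- 0
        flows["obl_preocy"] <- flows["obl_preocy"] + 1L
      } else {
        nb <- face_neighbours(vi[i], dims)
        nb <- nb[nb > 0L]
        free <- nb[lattice$mineral[nb] < MINERAL_THRESHOLD &
          lattice$occupancy[nb] == 0L]
        if (length(free)) {
          dest <- free[sample.int(length(free), 1L)]
          lattice$occupancy[vi[i]] <- 0L
          lattice$occupancy[dest] <- i
          co <- index_vox(dest, dims)
          cells$x[i] <- co[1]; cells$y[i] <- co[2]; cells$z[i] <- co[3]
          vi[i] <- dest
        } else {
          dead[i] <- TRUE
          flows["embed_died"] <- flows["embed_died"] + 1L
        }
      }
      changed[i] <- TRUE
    }
  }

  sed_at <- sed[vi]
  eff_at <- eff[vi]
  osteogenic <- sed_at > m$sed_for | eff_at > m$eff_for
  thr <- cc$receptor_threshold

  # pre-osteocyte maturation
  idx <- which(!changed & cells$type == TY[["preOCY"]] &
    !is.na(cells$embed_h) & cells$embed_h >= cc$maturation_h)
  if (length(idx)) {
    cells$type[idx] <- TY[["OCY"]]
    changed[idx] <- TRUE
    flows["preocy_ocy"] <- flows["preocy_ocy"] + length(idx)
  }

  # SSPC -> OBL
  idx <- which(!changed & cells$type == TY[["SSPC"]] & cells$o2_ok &
    osteogenic & cells$occ_tgfbr > thr)
  if (length(idx)) {
    cells$type[idx] <- TY[["OBL"]]
    changed[idx] <- TRUE
    flows["sspc_obl"] <- flows["sspc_obl"] + length(idx)
  }

  # SSPC / OBL lining mineral at low strain -> lining cell
  cand <- which(!changed & !dead &
    cells$type %in% TY[c("SSPC", "OBL")] & eff_at <= m$eff_for)
  if (length(cand)) {
    nb <- face_neighbours(vi[cand], dims)
    near_bone <- rowSums(
      matrix(nb > 0L & lattice$mineral[pmax(nb, 1L)] >= MINERAL_THRESHOLD,
        nrow = length(cand)
      )
    ) > 0
    idx <- cand[near_bone]
    if (length(idx)) {
      cells$type[idx] <- TY[["Lining"]]
      changed[idx] <- TRUE
      flows["to_lining"] <- flows["to_lining"] + length(idx)
    }
  }

  # lining -> OBL unless inhibited by sclerostin (LRP5/6 engagement)
  idx <- which(!changed & cells$type == TY[["Lining"]] & cells$o2_ok &
    eff_at > m$eff_for & cells$occ_lrp < thr)
  if (length(idx)) {
    cells$type[idx] <- TY[["OBL"]]
    changed[idx] <- TRUE
    flows["lining_obl"] <- flows["lining_obl"] + length(idx)
  }

  # HSC -> OCL (oxygen-sufficient); immune -> OCL (even hypoxic)
  idx <- which(!changed & cells$type == TY[["HSC"]] & cells$o2_ok &
    cells$occ_rank > thr)
  if (length(idx)) {
    cells$type[idx] <- TY[["OCL"]]
    changed[idx] <- TRUE
    flows["hsc_ocl"] <- flows["hsc_ocl"] + length(idx)
  }
  idx <- which(!changed & cells$type == TY[["Immune"]] & cells$occ_rank > thr)
  if (length(idx)) {
    cells$type[idx] <- TY[["OCL"]]
    changed[idx] <- TRUE
    flows["imm_ocl"] <- flows["imm_ocl"] + length(idx)
  }

  if (any(dead)) {
    cells <- cells[!dead, , drop = FALSE]
    lattice$occupancy <- rebuild_occupancy(cells, dims)
  }
  list(cells = cells, lattice = lattice, flows = flows)
}

#' Proliferation and apoptosis
#'
#' SSPC and HSC divide when oxygen-sufficient and in an osteogenic mechanical
#' environment, placing the daughter in a random free soft neighbour voxel
#' (no free neighbour, no division). SSPC, HSC, OCL, OBL and immune cells
#' undergo spontaneous apoptosis; (pre-)osteocytes and lining cells do not.
#'
#' @param cells Agent table.
#' @param lattice A [sim_lattice()].
#' @param sed,eff Stimulus fields.
#' @param config A [sim_config()].
#' @param dt_h Time step in hours (default one cell update).
#' @return List `cells`, `lattice`, `births`, `deaths`.
#' @export
proliferate_or_die <- function(cells, lattice, sed, eff,
                               config = sim_config(),
                               dt_h = config$cells$dt_cells / 3600) {
  TY <- CELL_TYPES
  cc <- config$cells
  m <- config$mechanics
  dims <- lattice$dims
  if (nrow(cells) == 0) {
    return(list(cells = cells, lattice = lattice, births = 0L, deaths = 0L))
  }
  vi <- cell_voxels(cells, dims)

  # apoptosis
  p_apo <- rep(0, nrow(cells))
  p_apo[cells$type %in% TY[c("SSPC", "HSC", "OBL", "Immune")]] <-
    cc$apoptosis * dt_h
  p_apo[cells$type == TY[["OCL"]]] <- cc$apoptosis_ocl * dt_h
  die <- runif(nrow(cells)) < p_apo
  deaths <- sum(die)

  # division (parents drawn before removal so the uniform draws are stable)
  sed_at <- sed[vi]
  eff_at <- eff[vi]
  can_divide <- cells$type %in% TY[c("SSPC", "HSC")] & cells$o2_ok & !die &
    (sed_at > m$sed_for | eff_at > m$eff_for)
  dividing <- which(can_divide & runif(nrow(cells)) < cc$proliferation * dt_h)

  births <- 0L
  newvox <- integer(0)
  newtype <- integer(0)
  if (length(dividing)) {
    occ <- lattice$occupancy
    for (i in dividing) {
      nb <- face_neighbours(vi[i], dims)
      nb <- nb[nb > 0L]
      free <- nb[lattice$mineral[nb] < MINERAL_THRESHOLD & occ[nb] == 0L &
        !lattice$vessel[nb]]
      if (length(free)) {
        dest <- free[sample.int(length(free), 1L)]
        occ[dest] <- -1L # reserve
        newvox <- c(newvox, dest)
        newtype <- c(newtype, cells$type[i])
        births <- births + 1L
      }
    }
  }

  if (deaths > 0) cells <- cells[!die, , drop = FALSE]
  if (births > 0) cells <- add_cells(cells, newtype, newvox, dims)
  lattice$occupancy <- rebuild_occupancy(cells, dims)
  list(cells = cells, lattice = lattice, births = births, deaths = deaths)
}

#' Cytokine production rates
#'
#' Linear laws in the perceived mechanical signal: (pre-)osteocytes read the
#' local SED — RANKL and sclerostin fall with SED, OPG rises; osteoblasts and
#' lining cells read the local EFF for OPG (rising) and RANKL (falling).
#' VEGF production is hypoxia-driven for SSPC, OBL, OCL, pre-osteocytes,
#' lining and immune cells: v_max (1 - oxygen fulfilment), zero at full
#' saturation. Immune cells produce TGF-beta at a constant rate. All rates
#' clamp at zero.
#'
#' @param cells Agent table.
#' @param sed_at,eff_at,o2_at Per-cell local signal/oxygen values.
#' @param config A [sim_config()].
#' @return Matrix (rows = cells) with columns VEGF, RANKL, OPG, Scl, TGFb
#'   in mol/m^3/s.
#' @export
produce_cytokines <- function(cells, sed_at, eff_at, o2_at,
                              config = sim_config()) {
  TY <- CELL_TYPES
  pr <- config$production
  m <- config$mechanics
  n <- nrow(cells)
  rates <- matrix(0, n, 5, dimnames = list(NULL, c("VEGF", "RANKL", "OPG", "Scl", "TGFb")))
  if (n == 0) return(rates)
  cap <- pr$sed_cap

  ocy <- cells$type %in% TY[c("preOCY", "OCY")]
  if (any(ocy)) {
    s <- sed_at[ocy] / m$sed_res
    rates[ocy, "RANKL"] <- pr$ocy_rankl * pmax(1 - s, 0)
    rates[ocy, "Scl"] <- pr$ocy_scl * pmax(1 - s, 0)
    rates[ocy, "OPG"] <- pr$ocy_opg * pmin(s, cap)
  }
  surf <- cells$type %in% TY[c("OBL", "Lining")]
  if (any(surf)) {
    e <- eff_at[surf] / m$eff_res
    rates[surf, "OPG"] <- pr$obl_opg * pmin(e, cap)
    rates[surf, "RANKL"] <- pr$obl_rankl * pmax(1 - e, 0)
  }
  vegf_types <- TY[c("SSPC", "OBL", "OCL", "preOCY", "Lining", "Immune")]
  vg <- cells$type %in% vegf_types
  fulfil <- pmin(o2_at / config$seeding$o2_background, 1)
  rates[vg, "VEGF"] <- pr$vegf_max * (1 - fulfil[vg])
  imm <- cells$type == TY[["Immune"]]
  rates[imm, "TGFb"] <- pr$immune_tgfb
  rates
}

#' Osteoid deposition with strain polarisation
#'
#' Osteoblasts above the osteogenic strain threshold deposit osteoid into
#' their own voxel and into one face neighbour selected by a softmax over the
#' neighbours' effective strain (sharpness `polar_beta`); vessel voxels and
#' voxels at the density cap never receive osteoid.
#'
#' @param cells Agent table.
#' @param lattice A [sim_lattice()].
#' @param eff Regularised effective-strain field.
#' @param config A [sim_config()].
#' @return List `lattice` and `n_deposits` (number of depositing OBL).
#' @export
deposit_osteoid <- function(cells, lattice, eff, config = sim_config()) {
  TY <- CELL_TYPES
  cc <- config$cells
  m <- config$mechanics
  dims <- lattice$dims
  obl <- which(cells$type == TY[["OBL"]])
  if (length(obl) == 0) return(list(lattice = lattice, n_deposits = 0L))
  vi <- vox_index(cells$x[obl], cells$y[obl], cells$z[obl], dims)
  active <- eff[vi] > m$eff_for
  obl <- obl[active]
  vi <- vi[active]
  if (length(obl) == 0) return(list(lattice = lattice, n_deposits = 0L))

  inc <- cc$osteoid_increment
  total <- lattice$mineral + lattice$osteoid
  room <- total < MINERAL_MAX & !lattice$vessel
  # own voxel
  ownok <- which(room[vi])
  if (length(ownok)) {
    add <- tabulate(vi[ownok], nbins = prod(dims))
    lattice$osteoid <- lattice$osteoid + inc * array(add, dims)
  }
  # polarisation-selected neighbour (weight ~ exp(beta * EFF / EFF_FOR))
  nb <- face_neighbours(vi, dims)
  valid <- nb > 0L
  nb1 <- pmax(nb, 1L)
  valid <- valid & array(room[nb1], dim(nb)) &
    array(lattice$mineral[nb1] < MINERAL_THRESHOLD, dim(nb))
  score <- array(eff[nb1] / m$eff_for, dim(nb))
  score[!valid] <- NA
  pick <- softmax_pick(score, cc$polar_beta)
  sel <- !is.na(pick)
  if (any(sel)) {
    dest <- nb[cbind(which(sel), pick[sel])]
    add <- tabulate(dest, nbins = prod(dims))
    lattice$osteoid <- lattice$osteoid + inc * array(add, dims)
  }
  list(lattice = lattice, n_deposits = length(obl))
}

#' Cluster-gated resorption
#'
#' Each osteoclast cluster (>= 3 face-adjacent OCL) with mean RANK occupancy
#' above 50% resorbs, with the configured event probability, one adjacent
#' mineralised voxel inside the osteolytic window (local SED < SED_RES). The
#' target is polarised towards minimal SED-gradient magnitude (softmax on
#' the negative normalised gradient). Mineral and osteoid are removed
#' together, the voxel's latent TGF-beta store is released to the field, and
#' an embedded (pre-)osteocyte in the voxel dies.
#'
#' @param cells Agent table.
#' @param lattice A [sim_lattice()].
#' @param sed Regularised SED field (MPa).
#' @param state A [cytokine_state()].
#' @param config A [sim_config()].
#' @return List `cells`, `lattice`, `state`, `n_resorbed`, `ocy_killed`.
#' @export
resorb <- function(cells, lattice, sed, state, config = sim_config()) {
  cc <- config$cells
  m <- config$mechanics
  dims <- lattice$dims
  clusters <- detect_clusters(cells, dims)
  n_res <- 0L
  ocy_killed <- 0L
  if (length(clusters)) {
    gm <- sed_gradient_magnitude(sed)
    gscale <- stats::median(gm[gm > 0])
    if (!is.finite(gscale) || gscale <= 0) gscale <- 1 # flat field: unbiased

    killed <- integer(0)
    for (cl in clusters) {
      if (mean(cells$occ_rank[cl]) <= cc$receptor_threshold) next
      if (runif(1) >= cc$p_resorb) next
      vi <- vox_index(cells$x[cl], cells$y[cl], cells$z[cl], dims)
      nb <- unique(as.vector(face_neighbours(vi, dims)))
      nb <- nb[nb > 0L]
      nb <- nb[lattice$mineral[nb] >= MINERAL_THRESHOLD & sed[nb] < m$sed_res]
      if (length(nb) == 0) next
      pick <- softmax_pick(matrix(-gm[nb] / gscale, nrow = 1), cc$polar_beta)
      target <- nb[pick]
      lattice$mineral[target] <- 0
      lattice$osteoid[target] <- 0
      rel <- release_tgfb(target, lattice, state)
      lattice <- rel$lattice
      state <- rel$state
      occ <- lattice$occupancy[target]
      if (occ > 0L) {
        killed <- c(killed, occ)
        ocy_killed <- ocy_killed + 1L
      }
      n_res <- n_res + 1L
    }
    if (length(killed)) {
      cells <- cells[-killed, , drop = FALSE]
      lattice$occupancy <- rebuild_occupancy(cells, dims)
    }
  }
  list(
    cells = cells, lattice = lattice, state = state,
    n_resorbed = n_res, ocy_killed = ocy_killed
  )
}

# central-difference gradient magnitude of a 3D field (voxel units)
sed_gradient_magnitude <- function(a) {
  d <- dim(a)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[2:(d[1] - 1), , ] <- (a[3:d[1], , ] - a[1:(d[1] - 2), , ]) / 2
  gy[, 2:(d[2] - 1), ] <- (a[, 3:d[2], ] - a[, 1:(d[2] - 2), ]) / 2
  gz[, , 2:(d[3] - 1)] <- (a[, , 3:d[3]] - a[, , 1:(d[3] - 2)]) / 2
  sqrt(gx^2 + gy^2 + gz^2)
}
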
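# Cytokine and oxygen transport: implicit (BTCS) diffusion-decay on the
# voxel grid plus the reaction step (receptor-ligand binding on cells and
# OPG + RANKL complexation) and per-cell secretion/consumption.
#
# Species: VEGF, RANKL, OPG, Scl (sclerostin), TGFb, the RANKL-OPG complex,
# and O2. All cytokines share one soft-tissue diffusivity and are two orders
# of magnitude less diffusive in mineralised tissue; oxygen diffuses equally
# in both. Concentrations are mol/m^3. Boundaries: Dirichlet on the
# proximal/distal z-faces (held at each species' background value),
# zero-flux on the four lateral faces. Vessel voxels act as additional
# Dirichlet oxygen sources at the normoxic set-point.

SPECIES <- c("VEGF", "RANKL", "OPG", "Scl", "TGFb", "RANKL_OPG", "O2")

#' Species parameter table
#'
#' @param config A [sim_config()].
#' @return Data frame with one row per species: soft/mineral diffusivity
#'   (um^2/s), decay constant (1/s) and Dirichlet boundary value (mol/m^3).
#' @export
species_table <- function(config = sim_config()) {
  sp <- config$species
  cyto_D <- sp$D_soft
  data.frame(
    name = SPECIES,
    D_soft = c(rep(cyto_D, 6), sp$D_o2),
    D_mineral = c(rep(cyto_D / sp$mineral_ratio, 6), sp$D_o2),
    decay = c(rep(sp$decay, 6), sp$o2_decay),
    boundary_prox = c(
      config$seeding$vegf_background, 0, 0, 0, 0, 0,
      config$seeding$o2_background
    ),
    boundary_dist = c(
      config$seeding$vegf_background, 0, 0, 0, 0, 0,
      config$seeding$o2_background
    ),
    stringsAsFactors = FALSE
  )
}

#' Create the cytokine/oxygen field state
#'
#' Initialises all concentration fields to their background values.
#'
#' @param lattice A [sim_lattice()].
#' @param config A [sim_config()].
#' @return An object of class `cytokine_state`: per-species concentration
#'   arrays (`conc`), diffusivity maps (`D`, shared between cytokines),
#'   and the species table.
#' @export
cytokine_state <- function(lattice, config = sim_config()) {
  tab <- species_table(config)
  dims <- lattice$dims
  conc <- lapply(seq_len(nrow(tab)), function(i) array(tab$boundary_prox[i], dims))
  names(conc) <- tab$name
  st <- structure(
    list(
      conc = conc, species = tab, dims = dims,
      voxel_size = lattice$voxel_size,
      dt = config$species$dt_rdd,
      D = NULL
    ),
    class = "cytokine_state"
  )
  update_diffusivity(st, lattice$mineral)
}

#' Update per-voxel diffusivities from the mineral field
#'
#' Voxels at or above the mineralisation threshold take the mineral
#' diffusivity (1/100 of soft tissue for cytokines, unchanged for oxygen).
#'
#' @param state A [cytokine_state()].
#' @param mineral Mineral density array (mg HA/cm^3).
#' @return The updated state.
#' @export
update_diffusivity <- function(state, mineral) {
  mineralised <- mineral >= MINERAL_THRESHOLD
  tab <- state$species
  cyto <- which(tab$name != "O2")[1]
  Dc <- array(tab$D_soft[cyto], state$dims)
  Dc[mineralised] <- tab$D_mineral[cyto]
  o2 <- which(tab$name == "O2")
  Do <- array(tab$D_soft[o2], state$dims)
  Do[mineralised] <- tab$D_mineral[o2]
  state$D <- list(cytokine = Dc, O2 = Do)
  state
}

#' One implicit diffusion-decay step for one species
#'
#' Backward-time centred-space step of dc/dt = div(D grad c) - lambda c,
#' unconditionally stable for any dt. Dirichlet voxels (the two z-face slabs
#' plus any extra sources such as vessels for O2) are held fixed.
#'
#' @param state A [cytokine_state()].
#' @param species Species name (see [species_table()]).
#' @param dt Time step in seconds (default the configured RDD step).
#' @param extra_dirichlet Optional list(idx, val) of additional fixed voxels
#'   (1-based linear indices).
#' @param extra_sink Optional per-voxel first-order loss rate (1/s) added to
#'   the species' decay constant — used for continuous cellular oxygen
#'   consumption, which the implicit step balances against diffusion.
#' @param boundary `"dirichlet"` (proximal/distal faces held at the species'
#'   background value; the lateral faces are always zero-flux) or `"closed"`
#'   (all faces reflective, e.g. for conservation checks).
#' @param tol,maxit CG controls.
#' @return The updated state.
#' @export
step_diffusion_decay <- function(state, species, dt = state$dt,
                                 extra_dirichlet = NULL, extra_sink = NULL,
                                 boundary = c("dirichlet", "closed"),
                                 tol = 1e-8, maxit = 2000) {
  if (dt <= 0) stop("dt must be positive")
  boundary <- match.arg(boundary)
  i <- match(species, state$species$name)
  if (is.na(i)) stop("unknown species: ", species)
  dims <- state$dims
  h <- state$voxel_size # um; D is um^2/s
  D <- if (species == "O2") state$D$O2 else state$D$cytokine
  nxy <- prod(dims[1:2])
  if (boundary == "dirichlet") {
    fixed <- c(seq_len(nxy), (prod(dims) - nxy) + seq_len(nxy)) # z-face slabs
    vals <- c(
      rep(state$species$boundary_prox[i], nxy),
      rep(state$species$boundary_dist[i], nxy)
    )
  } else {
    fixed <- integer(0)
    vals <- numeric(0)
  }
  if (!is.null(extra_dirichlet) && length(extra_dirichlet$idx)) {
    keep <- !(extra_dirichlet$idx %in% fixed)
    fixed <- c(fixed, extra_dirichlet$idx[keep])
    vals <- c(vals, rep_len(extra_dirichlet$val, length(extra_dirichlet$idx))[keep])
  }
  lam <- state$species$decay[i]
  lam <- if (is.null(extra_sink)) lam else lam + as.numeric(extra_sink)
  res <- btcs_cg_cpp(
    as.numeric(state$conc[[species]]), as.numeric(D), as.integer(dims),
    h, dt, lam,
    as.integer(fixed - 1L), as.numeric(vals), tol, as.integer(maxit)
  )
  if (!res$converged) {
    stop(sprintf(
      "RDD linear solve for %s did not converge (relres %.3g)",
      species, res$relres
    ))
  }
  state$conc[[species]] <- array(pmax(res$c, 0), dims)
  state
}

# --- cached direct solver for the shared cytokine matrix --------------------
# The BTCS system matrix for the six cytokines is identical (shared
# diffusivity map, decay and step) and changes only when a voxel crosses the
# mineralisation threshold. A cached sparse Cholesky factor then turns each
# implicit step into a backsolve. Oxygen keeps the CG path because its
# Dirichlet set (vessel sources) changes continuously.

#' Build a factored BTCS solver for the cytokine species
#'
#' @param state A [cytokine_state()].
#' @param dt Time step (s).
#' @return A list with the Cholesky factor, the Dirichlet bookkeeping, and a
#'   fingerprint of the diffusivity map it was built for.
#' @export
btcs_factor <- function(state, dt = state$dt) {
  dims <- state$dims
  n <- prod(dims)
  h <- state$voxel_size
  D <- as.numeric(state$D$cytokine)
  i0 <- which(state$species$name != "O2")[1]
  lambda <- state$species$decay[i0]
  nxy <- prod(dims[1:2])
  fixed <- c(seq_len(nxy), (n - nxy) + seq_len(nxy))
  isfix <- logical(n)
  isfix[fixed] <- TRUE

  co <- index_vox(seq_len(n), dims)
  offs <- rbind(
    c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
    c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L)
  )
  ii <- jj <- xx <- vector("list", 6)
  bi <- bj <- bx <- vector("list", 6)
  diag_add <- numeric(n)
  for (d in 1:6) {
    x <- co[, 1] + offs[d, 1]; y <- co[, 2] + offs[d, 2]; z <- co[, 3] + offs[d, 3]
    ok <- x >= 0L & x < dims[1] & y >= 0L & y < dims[2] & z >= 0L & z < dims[3]
    i <- which(ok)
    j <- vox_index(x[ok], y[ok], z[ok], dims)
    w <- ifelse(D[i] + D[j] > 0, 2 * D[i] * D[j] / (D[i] + D[j]), 0) / h^2
    diag_add[i] <- diag_add[i] + w
    keep <- !isfix[i] & !isfix[j]
    ii[[d]] <- i[keep]; jj[[d]] <- j[keep]; xx[[d]] <- -w[keep]
    bd <- !isfix[i] & isfix[j] # coupling of free voxels to Dirichlet values
    bi[[d]] <- i[bd]; bj[[d]] <- j[bd]; bx[[d]] <- w[bd]
  }
  dg <- 1 / dt + lambda + diag_add
  dg[isfix] <- 1
  A <- Matrix::sparseMatrix(
    i = c(unlist(ii), seq_len(n)), j = c(unlist(jj), seq_len(n)),
    x = c(unlist(xx), dg), dims = c(n, n)
  )
  B <- Matrix::sparseMatrix(
    i = unlist(bi), j = unlist(bj), x = unlist(bx), dims = c(n, n)
  )
  list(
    ch = Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, super = TRUE),
    B = B, fixed = fixed, isfix = isfix, dt = dt, lambda = lambda,
    fingerprint = D
  )
}

#' One implicit cytokine step via the cached factor
#'
#' Numerically equivalent to [step_diffusion_decay()] for non-oxygen species
#' (to solver tolerance); used by the engine for speed.
#'
#' @param state A [cytokine_state()].
#' @param species Cytokine name (not `"O2"`).
#' @param fact A factor from [btcs_factor()].
#' @return The updated state.
#' @export
step_diffusion_decay_factored <- function(state, species, fact) {
  i <- match(species, state$species$name)
  if (is.na(i) || species == "O2") stop("factored path is for cytokines only")
  dims <- state$dims
  vals <- numeric(prod(dims))
  nxy <- prod(dims[1:2])
  vals[seq_len(nxy)] <- state$species$boundary_prox[i]
  vals[(prod(dims) - nxy) + seq_len(nxy)] <- state$species$boundary_dist[i]
  b <- as.numeric(state$conc[[species]]) / fact$dt
  b <- b + as.numeric(fact$B %*% vals)
  b[fact$fixed] <- vals[fact$fixed]
  x <- as.numeric(Matrix::solve(fact$ch, b, system = "A"))
  state$conc[[species]] <- array(pmax(x, 0), dims)
  state
}

# receptor -> ligand pairing used by the binding step
RECEPTOR_LIGANDS <- c(
  rank = "RANKL", vegfr = "VEGF", tgfbr = "TGFb", lrp = "Scl"
)

# concentration equivalent (mol/m^3) of one molecule in one voxel
site_concentration <- function(voxel_size_um) {
  1 / (6.02214076e23 * (voxel_size_um * 1e-6)^3)
}

#' Reaction step: receptor-ligand binding and RANKL-OPG complexation
#'
#' Linear mass-action kinetics per cell receptor,
#' dB/dt = kon c (N - B) - koff B, integrated exactly over dt with the local
#' concentration frozen; the bound ligand is removed from (or returned to)
#' the cell's voxel so that free + bound mass is conserved. Free OPG and
#' RANKL additionally combine into the RANKL-OPG complex.
#'
#' @param state A [cytokine_state()].
#' @param cells An agent table (see [initialise_model()]).
#' @param dt Time step (s).
#' @param config A [sim_config()].
#' @return List with the updated `state` and `cells`.
#' @export
react <- function(state, cells, dt = state$dt, config = sim_config()) {
  sp <- config$species
  sconc <- site_concentration(state$voxel_size)
  pool <- sp$binding_sites * sconc # full receptor pool, mol/m^3 equivalent
  kd <- sp$koff / sp$kon
  if (nrow(cells) > 0) {
    vi <- vox_index(cells$x, cells$y, cells$z, state$dims)
    for (r in names(RECEPTOR_LIGANDS)) {
      lig <- RECEPTOR_LIGANDS[[r]]
      col <- paste0("occ_", r)
      c_loc <- state$conc[[lig]][vi]
      b <- cells[[col]]
      beq <- c_loc / (c_loc + kd)
      rate <- sp$kon * c_loc + sp$koff
      bnew <- beq + (b - beq) * exp(-rate * dt)
      dB <- bnew - b
      dc <- -dB * pool
      # ligand depletion: uptake is limited to the ligand the voxel holds
      short <- which(c_loc + dc < 0)
      if (length(short)) {
        scale <- c_loc[short] / (-dc[short])
        dB[short] <- dB[short] * scale
        dc[short] <- -c_loc[short]
        bnew <- b + dB
      }
      if (any(bnew < -1e-12) || any(bnew > 1 + 1e-12)) {
        warning("receptor occupancy left [0,1]; clamping (sub-step too large)")
      }
      cells[[col]] <- pmin(pmax(bnew, 0), 1)
      conc <- state$conc[[lig]]
      conc[vi] <- conc[vi] + dc
      state$conc[[lig]] <- conc
    }
  }
  # ligand-ligand: OPG + RANKL -> RANKL-OPG
  R <- state$conc$RANKL
  O <- state$conc$OPG
  dx <- pmin(sp$k_complex * R * O * dt, R, O)
  state$conc$RANKL <- R - dx
  state$conc$OPG <- O - dx
  state$conc$RANKL_OPG <- state$conc$RANKL_OPG + dx
  list(state = state, cells = cells)
}

#' Secretion and oxygen sufficiency
#'
#' Adds each cell's cytokine production (from [produce_cytokines()]) to its
#' voxel and refreshes the per-cell oxygen-sufficiency flag. Oxygen
#' consumption itself is continuous — a first-order sink at occupied voxels
#' applied inside the implicit transport step (see [o2_sink_map()]) — so a
#' cell is oxygen-sufficient when its local steady concentration stays above
#' the hypoxia threshold.
#'
#' @param state A [cytokine_state()].
#' @param cells Agent table.
#' @param rates Production matrix from [produce_cytokines()] (mol/m^3/s),
#'   rows matching `cells`.
#' @param dt Time step (s).
#' @param config A [sim_config()].
#' @return List with updated `state` and `cells`.
#' @export
secrete_and_consume <- function(state, cells, rates, dt = state$dt,
                                config = sim_config()) {
  if (nrow(cells) == 0) {
    return(list(state = state, cells = cells))
  }
  vi <- vox_index(cells$x, cells$y, cells$z, state$dims)
  for (spn in colnames(rates)) {
    r <- rates[, spn]
    nz <- which(r > 0)
    if (length(nz)) {
      conc <- state$conc[[spn]]
      conc[vi[nz]] <- conc[vi[nz]] + r[nz] * dt
      state$conc[[spn]] <- conc
    }
  }
  cells$o2_ok <- state$conc$O2[vi] > config$cells$o2_threshold
  list(state = state, cells = cells)
}

#' Cellular oxygen sink map
#'
#' First-order consumption rate per voxel (1/s): occupied voxels consume at
#' `o2_consumption / o2_background` times the local concentration, i.e. the
#' nominal rate at normoxia, tapering linearly as oxygen falls. Vessel
#' voxels are sources, never sinks.
#'
#' @param lattice A [sim_lattice()].
#' @param config A [sim_config()].
#' @return 3D array of sink rates (1/s).
#' @export
o2_sink_map <- function(lattice, config = sim_config()) {
  rate <- config$cells$o2_consumption / config$seeding$o2_background
  sink <- array(0, lattice$dims)
  sink[lattice$occupancy > 0L & !lattice$vessel] <- rate
  sink
}

#' @export
print.cytokine_state <- function(x, ...) {
  cat("<cytokine_state> ", paste(x$dims, collapse = " x "),
      " voxels, dt = ", x$dt, " s\n", sep = "")
  for (n in names(x$conc)) {
    cat(sprintf("  %-10s mean %.3g mol/m^3 (max %.3g)\n", n,
                mean(x$conc[[n]]), max(x$conc[[n]])))
  }
  invisible(x)
}
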
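# Voxel hexahedral micro-finite-element mechanics.
#
# The mineral density image is mapped element-wise to an isotropic Young's
# modulus and meshed one trilinear 8-node hexahedron per voxel. Two loading
# protocols are provided: the apparent-stiffness protocol (1% uniaxial
# compression) and ambulatory loading through an external fixator (combined
# compression/bending, linearly rescaled to the 10.5 N peak force, with the
# callus/fixator load share k_c/(k_c + k_f)). The mechanical stimuli are the
# strain-energy density (SED, for osteocytes in mineralised tissue) and the
# effective strain EFF = sqrt(2 SED / E) (for cells in soft tissue), both
# Gaussian-regularised. Internally: lengths mm, moduli MPa, forces N.

#' Mineral density to Young's modulus
#'
#' Piecewise-linear material map: soft tissue below 395 mg HA/cm^3 at
#' 3.0 MPa; linear interpolation from (395, 4 GPa) to (720, 14 GPa);
#' extrapolation above 720 is capped at the cortical modulus.
#'
#' @param density Numeric vector/array of mineral density, mg HA/cm^3.
#' @param mechanics Mechanics config group (see [sim_config()]).
#' @return Young's modulus in MPa, same shape as `density`.
#' @export
density_to_modulus <- function(density, mechanics = sim_config()$mechanics) {
  if (any(density < 0)) stop("negative mineral density")
  m <- mechanics
  slope <- (m$E_high - m$E_low) / (m$rho_high - m$rho_low)
  E <- ifelse(density < m$rho_low, m$E_soft,
    pmin(m$E_low + slope * (density - m$rho_low), m$E_high)
  )
  if (is.array(density)) dim(E) <- dim(density)
  E
}

# --- element matrices --------------------------------------------------------

# unit-modulus isotropic elasticity matrix (engineering shear convention)
elasticity_matrix <- function(nu) {
  lam <- nu / ((1 + nu) * (1 - 2 * nu))
  mu <- 1 / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  C
}

# trilinear shape-function derivatives on the unit cube at (x,y,z)
hex_dN <- function(p) {
  off <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
  )
  dN <- matrix(0, 8, 3)
  for (a in 1:8) {
    s <- ifelse(off[a, ] == 1, 1, -1)
    f <- ifelse(off[a, ] == 1, p, 1 - p)
    dN[a, 1] <- s[1] * f[2] * f[3]
    dN[a, 2] <- f[1] * s[2] * f[3]
    dN[a, 3] <- f[1] * f[2] * s[3]
  }
  dN
}

hex_B <- function(p) {
  dN <- hex_dN(p)
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    i <- 3 * (a - 1)
    B[1, i + 1] <- dN[a, 1]
    B[2, i + 2] <- dN[a, 2]
    B[3, i + 3] <- dN[a, 3]
    B[4, i + 1] <- dN[a, 2]; B[4, i + 2] <- dN[a, 1]
    B[5, i + 2] <- dN[a, 3]; B[5, i + 3] <- dN[a, 2]
    B[6, i + 1] <- dN[a, 3]; B[6, i + 3] <- dN[a, 1]
  }
  B
}

# 24x24 unit-modulus element stiffness for a cube of edge h (2x2x2 Gauss)
hex_stiffness <- function(nu, h) {
  C <- elasticity_matrix(nu)
  gp <- 0.5 + c(-1, 1) / (2 * sqrt(3))
  Ke <- matrix(0, 24, 24)
  for (x in gp) for (y in gp) for (z in gp) {
    B <- hex_B(c(x, y, z))
    Ke <- Ke + t(B) %*% C %*% B / 8
  }
  Ke * h # B ~ 1/h, dV ~ h^3
}

# --- node/dof helpers (0-based dofs, matching the C++ kernels) --------------

node_grid_dims <- function(dims) dims + 1L

# 0-based dof indices of a component (1=x,2=y,3=z) for nodes on a z-plane
plane_dofs <- function(dims, zplane, comp) {
  nd <- node_grid_dims(dims)
  nodes <- as.vector(outer(
    seq_len(nd[1]) - 1L,
    (seq_len(nd[2]) - 1L) * nd[1],
    "+"
  )) + nd[1] * nd[2] * zplane
  3L * nodes + (comp - 1L)
}

node_coords_plane <- function(dims, h) {
  nd <- node_grid_dims(dims)
  list(
    x = rep(seq_len(nd[1]) - 1L, nd[2]) * h,
    y = rep(seq_len(nd[2]) - 1L, each = nd[1]) * h
  )
}

# linear-ramp initial guess: interpolates the prescribed top-face axial
# displacements linearly down to the fixed bottom face (the exact solution
# for a homogeneous column, and a good start elsewhere)
ramp_guess <- function(dims, top_vals) {
  nd <- node_grid_dims(dims)
  u <- numeric(3 * prod(nd))
  nxy <- nd[1] * nd[2]
  for (iz in seq_len(nd[3]) - 1L) {
    nodes <- nxy * iz + seq_len(nxy) - 1L
    u[3L * nodes + 3L] <- top_vals * (iz / (nd[3] - 1L))
  }
  u
}

# minimal in-plane rigid-body pins (two corner nodes)
rigid_pins <- function(dims) {
  nd <- node_grid_dims(dims)
  n0 <- 0L # node (0,0,0)
  n1 <- nd[1] - 1L # node (nx,0,0)
  list(idx = c(3L * n0, 3L * n0 + 1L, 3L * n1 + 1L), val = c(0, 0, 0))
}

# --- solver ------------------------------------------------------------------

#' Solve the voxel FE system under Dirichlet boundary conditions
#'
#' Low-level entry point: assembles nothing — a matrix-free Jacobi-PCG
#' operates on the element stiffness scaled per voxel by the modulus field.
#'
#' @param lattice A [sim_lattice()].
#' @param fixed_dofs 0-based constrained dof indices
#'   (dof = 3 * node + component, node = ix + (nx+1)(iy + (ny+1) iz)).
#' @param fixed_vals Prescribed displacements (mm) for `fixed_dofs`.
#' @param modulus Optional modulus field (MPa) overriding the density map.
#' @param tol Relative residual tolerance (default 1e-6).
#' @param maxit Maximum CG iterations.
#' @param warm_start Optional displacement vector to start from.
#' @param mechanics Mechanics config group.
#' @return List with displacement vector `u` (mm), `iters`, `relres`.
#' @export
fe_solve <- function(lattice, fixed_dofs, fixed_vals, modulus = NULL,
                     tol = NULL, maxit = NULL, warm_start = NULL,
                     mechanics = sim_config()$mechanics) {
  dims <- lattice$dims
  if (prod(dims) == 0) stop("empty lattice")
  E <- if (is.null(modulus)) {
    density_to_modulus(lattice$mineral, mechanics)
  } else {
    modulus
  }
  if (max(E) <= 0) stop("zero-stiffness mesh: no material to solve")
  if (length(fixed_dofs) == 0) stop("fully unconstrained system is singular")
  h <- lattice$voxel_size / 1000 # mm
  Ke <- hex_stiffness(mechanics$nu, h)
  tol <- if (is.null(tol)) mechanics$tol else tol
  maxit <- if (is.null(maxit)) mechanics$maxit else maxit
  if (is.null(warm_start)) warm_start <- numeric(0)
  res <- fe_pcg_cpp(
    as.numeric(E), as.integer(dims), Ke,
    as.integer(fixed_dofs), as.numeric(fixed_vals),
    as.numeric(warm_start), tol, as.integer(maxit)
  )
  if (!res$converged) {
    stop(sprintf(
      "FE solver did not converge: relative residual %.3g after %d iterations",
      res$relres, res$iters
    ))
  }
  res$E <- E
  res$Ke <- Ke
  res
}

# total z-reaction (N) over the nodes of a z-plane
reaction_force_z <- function(u, E, dims, Ke, zplane) {
  f <- fe_apply_cpp(u, as.numeric(E), as.integer(dims), Ke)
  sum(f[plane_dofs(dims, zplane, 3L) + 1L])
}

#' Apparent stiffness of the osteotomy construct
#'
#' Applies the stiffness protocol — uniaxial compression by 1% of the
#' longitudinal length, distal face fixed axially, in-plane motion free up to
#' rigid-body pins — and reports reaction force / applied displacement.
#'
#' @inheritParams fe_solve
#' @param config A [sim_config()].
#' @param warm_start Optional displacement vector from a previous call.
#' @return List: `k_c` (N/mm), `u`, `reaction` (N), `iters`.
#' @export
apparent_stiffness <- function(lattice, config = sim_config(), modulus = NULL,
                               tol = NULL, warm_start = NULL) {
  m <- config$mechanics
  dims <- lattice$dims
  h <- lattice$voxel_size / 1000
  L <- dims[3] * h
  delta <- m$compression * L
  pins <- rigid_pins(dims)
  bot <- plane_dofs(dims, 0L, 3L)
  top <- plane_dofs(dims, dims[3], 3L)
  fixed <- c(bot, top, pins$idx)
  vals <- c(rep(0, length(bot)), rep(-delta, length(top)), pins$val)
  if (is.null(warm_start)) {
    warm_start <- ramp_guess(dims, rep(-delta, length(top)))
  }
  sol <- fe_solve(lattice, fixed, vals,
    modulus = modulus, tol = tol,
    warm_start = warm_start, mechanics = m
  )
  Fz <- reaction_force_z(sol$u, sol$E, dims, sol$Ke, dims[3])
  list(k_c = abs(Fz) / delta, u = sol$u, reaction = Fz, iters = sol$iters)
}

#' Ambulatory loading through the external fixator
#'
#' Combined compression and bending: the proximal-face axial displacement
#' varies linearly across the section towards the fixator plane,
#' u_z(x) = -u0 (1 + beta (x - x_f) / d). The linear solution is rescaled so
#' the total axial reaction equals the peak ambulatory force (10.5 N), and
#' the callus/fixator load share k_c / (k_c + k_f) is applied to the
#' transmitted load before the stimulus fields are evaluated.
#'
#' @inheritParams apparent_stiffness
#' @param k_c Apparent stiffness (N/mm); computed on the fly if missing.
#' @param force_scale Multiplier on the peak force. The engine passes the
#'   ratio of the specimen's post-operative cortical area to the reference
#'   murine cortical area, so a geometrically scaled phantom is loaded at
#'   matched tissue-level stress; for a full-scale image the factor is ~1.
#' @return An object of class `mech_state`: modulus field `E` (MPa),
#'   displacement `u` (mm, at transmitted load), `sed` (MPa) and `eff`
#'   (dimensionless) regularised element fields, `k_c`, `load_share`,
#'   `reaction` (N, = F_w), `iters`.
#' @export
ambulatory_load <- function(lattice, config = sim_config(), k_c = NULL,
                            modulus = NULL, tol = NULL, warm_start = NULL,
                            force_scale = 1) {
  m <- config$mechanics
  dims <- lattice$dims
  h <- lattice$voxel_size / 1000
  L <- dims[3] * h
  if (is.null(k_c)) {
    k_c <- apparent_stiffness(lattice, config, modulus = modulus, tol = tol)$k_c
  }
  if (k_c + m$k_f <= 0) stop("k_c + k_f must be positive")

  u0 <- m$compression * L
  xf <- dims[1] * h / 2 - m$fixator_offset / 1000 # fixator plane (mm)
  nc <- node_coords_plane(dims, h)
  prof <- -u0 * (1 + m$bending_beta * (nc$x - xf) / (m$fixator_offset / 1000))
  pins <- rigid_pins(dims)
  bot <- plane_dofs(dims, 0L, 3L)
  top <- plane_dofs(dims, dims[3], 3L)
  fixed <- c(bot, top, pins$idx)
  vals <- c(rep(0, length(bot)), prof, pins$val)
  if (is.null(warm_start)) warm_start <- ramp_guess(dims, prof)
  sol <- fe_solve(lattice, fixed, vals,
    modulus = modulus, tol = tol,
    warm_start = warm_start, mechanics = m
  )
  Fz <- reaction_force_z(sol$u, sol$E, dims, sol$Ke, dims[3])
  if (Fz == 0) stop("zero reaction force under ambulatory protocol")
  scale_fw <- m$F_w * force_scale / abs(Fz) # rescale to the peak force
  share <- k_c / (k_c + m$k_f) # callus share of the transmitted load
  u_eff <- sol$u * scale_fw * share
  state <- structure(
    list(
      E = sol$E, u = u_eff, k_c = k_c, load_share = share,
      reaction = m$F_w * force_scale, iters = sol$iters, dims = dims,
      voxel_size = lattice$voxel_size, Ke = sol$Ke,
      u_solver = sol$u
    ),
    class = "mech_state"
  )
  sig <- compute_signals(state, config)
  state$sed <- sig$sed
  state$eff <- sig$eff
  state
}

#' Mechanical stimulus fields (SED and EFF)
#'
#' Per-element strain-energy density from the centroid strain tensor and the
#' effective strain EFF = sqrt(2 SED / E); both fields are smoothed with the
#' truncated Gaussian (sigma in voxels, truncation radius
#' ceiling(support/sigma)).
#'
#' @param state A `mech_state` (or list with `u`, `E`, `dims`, `voxel_size`).
#' @param config A [sim_config()].
#' @return List of 3D arrays `sed` (MPa) and `eff`.
#' @export
compute_signals <- function(state, config = sim_config()) {
  m <- config$mechanics
  dims <- state$dims
  h <- state$voxel_size / 1000
  B0 <- hex_B(c(0.5, 0.5, 0.5))
  C0 <- elasticity_matrix(m$nu)
  raw <- fe_sed_cpp(state$u, as.numeric(state$E), as.integer(dims), B0, C0, h)
  sed <- array(pmax(raw$sed, 0), dims)
  eff <- sqrt(2 * sed / array(state$E, dims))
  list(
    sed = gaussian_filter3(sed, m$sigma, m$support),
    eff = gaussian_filter3(eff, m$sigma, m$support)
  )
}

#' @export
print.mech_state <- function(x, ...) {
  cat("<mech_state> ", paste(x$dims, collapse = " x "), " elements\n", sep = "")
  cat(sprintf(
    "  k_c = %.4g N/mm | load share = %.3f | reaction = %.3g N | CG iters = %d\n",
    x$k_c, x$load_share, x$reaction, x$iters
  ))
  if (!is.null(x$sed)) {
    cat(sprintf(
      "  SED [MPa]: median %.3g, max %.3g | EFF: median %.3g, max %.3g\n",
      median(x$sed), max(x$sed), median(x$eff), max(x$eff)
    ))
  }
  invisible(x)
}
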
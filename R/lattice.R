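# Simulation lattice and synthetic femur-osteotomy phantoms.
#
# The lattice is the shared spatial state of all sub-models: a regular grid of
# 10.5-um isotropic voxels (z = longitudinal, proximal -> distal, 0-based
# voxel indices, voxel centres at (i + 1/2) * voxel_size) carrying mineral
# density (mg HA/cm^3), unmineralised osteoid (same units), a latent TGF-beta
# store, single-cell occupancy, and a vessel flag.

#' Create a simulation lattice
#'
#' @param dims Integer vector (nx, ny, nz) of voxel counts; z is the
#'   longitudinal (proximal to distal) axis.
#' @param voxel_size Isotropic voxel size in micrometres (default 10.5).
#' @param mineral Optional 3D array of mineral density, mg HA/cm^3.
#' @return An object of class `sim_lattice` with fields `mineral`, `osteoid`,
#'   `tgfb_store`, `occupancy` (0 = empty), and `vessel`.
#' @export
sim_lattice <- function(dims, voxel_size = 10.5, mineral = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1), voxel_size > 0)
  if (is.null(mineral)) mineral <- array(0, dims)
  stopifnot(all(dim(mineral) == dims))
  if (any(mineral < 0) || any(mineral > MINERAL_MAX)) {
    stop("mineral density must lie in [0, ", MINERAL_MAX, "] mg HA/cm^3")
  }
  structure(
    list(
      dims = dims,
      voxel_size = voxel_size, # um
      mineral = mineral,
      osteoid = array(0, dims),
      tgfb_store = array(0, dims),
      occupancy = array(0L, dims),
      vessel = array(FALSE, dims)
    ),
    class = "sim_lattice"
  )
}

#' @export
print.sim_lattice <- function(x, ...) {
  bv <- sum(x$mineral >= MINERAL_THRESHOLD)
  cat("<sim_lattice> ", paste(x$dims, collapse = " x "),
      " voxels @ ", x$voxel_size, " um\n", sep = "")
  cat("  mineralised voxels: ", bv,
      sprintf(" (%.1f%%)", 100 * bv / prod(x$dims)), "\n", sep = "")
  cat("  osteoid-bearing voxels: ", sum(x$osteoid > 0),
      " | vessel voxels: ", sum(x$vessel),
      " | occupied voxels: ", sum(x$occupancy > 0L), "\n", sep = "")
  invisible(x)
}

#' Phantom specification for a femur osteotomy
#'
#' Geometric parameters (all in micrometres) of the synthetic phantom that
#' stands in for a post-operative micro-CT scan: two hollow-cylinder cortical
#' fragments at cortical density separated by a transverse gap, surrounded by
#' a periosteal margin.
#'
#' @param outer_radius,inner_radius Cortex outer/inner radius (um).
#' @param frag_len_proximal,frag_len_distal Fragment lengths along z (um).
#' @param gap_width Transverse osteotomy gap width (um); must be positive.
#' @param periosteum Periosteal layer thickness (um, default 52.5 = 5 voxels).
#' @param haematoma_dilation Dilation radius of the defect-centre mask that
#'   defines the initial haematoma (um, default 210).
#' @param margin_xy,margin_z Free margin around the phantom (um).
#' @param voxel_size Voxel size (um).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_radius = 63, inner_radius = 31.5,
                         frag_len_proximal = 126, frag_len_distal = 126,
                         gap_width = 210, periosteum = 52.5,
                         haematoma_dilation = 210,
                         margin_xy = 10.5, margin_z = 31.5,
                         voxel_size = 10.5) {
  if (gap_width <= 0) stop("gap_width must be positive")
  if (inner_radius >= outer_radius) stop("inner_radius must be < outer_radius")
  if (periosteum <= 0 || (periosteum / voxel_size) %% 1 > 1e-9) {
    stop("periosteum thickness must be a positive voxel multiple")
  }
  structure(
    list(
      outer_radius = outer_radius, inner_radius = inner_radius,
      frag_len_proximal = frag_len_proximal, frag_len_distal = frag_len_distal,
      gap_width = gap_width, periosteum = periosteum,
      haematoma_dilation = haematoma_dilation,
      margin_xy = margin_xy, margin_z = margin_z, voxel_size = voxel_size
    ),
    class = "phantom_spec"
  )
}

# voxel-centre coordinates (um) along one axis
vox_centres <- function(n, h) (seq_len(n) - 0.5) * h

#' Build a synthetic femur-osteotomy phantom
#'
#' Deterministically rasterises the phantom described by a [phantom_spec()]:
#' hollow-cylinder cortical fragments at cortical density (720 mg HA/cm^3)
#' separated by a transverse bone-free gap; marrow and gap at density 0.
#'
#' @param spec A [phantom_spec()].
#' @return A [sim_lattice()] with attribute `"phantom_spec"` attached.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$voxel_size
  r_shell <- spec$outer_radius + spec$periosteum + spec$margin_xy
  nxy <- as.integer(ceiling(2 * r_shell / h))
  gap_vox <- as.integer(round(spec$gap_width / h))
  if (gap_vox < 1) stop("gap narrower than one voxel")
  nz <- as.integer(
    round((spec$frag_len_proximal + spec$frag_len_distal) / h) + gap_vox +
      2L * as.integer(ceiling(spec$margin_z / h))
  )
  if (nz > 4000 || nxy > 2000) {
    stop("gap or fragments wider than the supported simulation domain")
  }
  dims <- c(nxy, nxy, nz)

  cx <- nxy * h / 2
  xs <- vox_centres(nxy, h) - cx
  r2 <- outer(xs^2, xs^2, "+") # nxy x nxy matrix of squared radii
  annulus <- r2 > spec$inner_radius^2 & r2 <= spec$outer_radius^2

  mz <- ceiling(spec$margin_z / h)
  npz <- round(spec$frag_len_proximal / h)
  ndz <- round(spec$frag_len_distal / h)
  z_prox <- seq.int(mz + 1, mz + npz)
  z_dist <- seq.int(mz + npz + gap_vox + 1, mz + npz + gap_vox + ndz)
  if (max(z_dist) > nz) stop("fragments + gap exceed domain length")

  mineral <- array(0, dims)
  for (z in c(z_prox, z_dist)) {
    sl <- mineral[, , z]
    sl[annulus] <- MINERAL_MAX
    mineral[, , z] <- sl
  }

  lat <- sim_lattice(dims, voxel_size = h, mineral = mineral)
  attr(lat, "phantom_spec") <- spec
  attr(lat, "gap_z") <- c(min = mz + npz + 1L, max = mz + npz + gap_vox)
  lat
}

# least-squares longitudinal axis of the mineralised structure:
# per-slice bone centroids fitted linearly in z. Returns a function of
# z (1-based slice) giving the (x, y) axis position in voxel-centre um.
longitudinal_axis <- function(lattice) {
  dims <- lattice$dims
  h <- lattice$voxel_size
  bone <- lattice$mineral >= MINERAL_THRESHOLD
  per_slice <- apply(bone, 3, sum)
  zs <- which(per_slice > 0)
  if (length(zs) == 0) stop("no mineralised tissue: cannot fit an axis")
  xs <- vox_centres(dims[1], h)
  ys <- vox_centres(dims[2], h)
  cx <- vapply(zs, function(z) {
    m <- bone[, , z]
    sum(xs * rowSums(m)) / sum(m)
  }, numeric(1))
  cy <- vapply(zs, function(z) {
    m <- bone[, , z]
    sum(ys * colSums(m)) / sum(m)
  }, numeric(1))
  if (length(zs) > 1) {
    fx <- stats::lm.fit(cbind(1, zs), cx)$coefficients
    fy <- stats::lm.fit(cbind(1, zs), cy)$coefficients
  } else {
    fx <- c(cx, 0); fy <- c(cy, 0)
  }
  function(z) cbind(fx[1] + fx[2] * z, fy[1] + fy[2] * z)
}

# squared radial distance of every voxel centre from the longitudinal axis
radial_distance2 <- function(lattice, axis = longitudinal_axis(lattice)) {
  dims <- lattice$dims
  h <- lattice$voxel_size
  xs <- vox_centres(dims[1], h)
  ys <- vox_centres(dims[2], h)
  out <- array(0, dims)
  for (z in seq_len(dims[3])) {
    a <- axis(z)
    out[, , z] <- outer((xs - a[1])^2, (ys - a[2])^2, "+")
  }
  out
}

#' Volumes of interest for time-lapsed evaluation
#'
#' Derives the four standard evaluation masks from a post-operative geometry:
#' the defect centre (DC) and defect periphery (DP) span the osteotomy gap
#' (bone-free slab between the fragments), split at the cortical footprint
#' radius; the fragment centre (FC, cortices plus medullary cavities) and
#' fragment periphery (FP, periosteal to the old cortices) split the fragment
#' slabs the same way. Masks are reproducible from the geometry alone.
#'
#' @param lattice A post-operative [sim_lattice()] whose gap is void of bone.
#' @return A list of logical arrays `DC`, `DP`, `FC`, `FP`, and `TOT`
#'   (their union), with the gap slice range as attribute `"gap_z"`.
#' @export
make_vois <- function(lattice) {
  dims <- lattice$dims
  bone <- lattice$mineral >= MINERAL_THRESHOLD
  per_slice <- apply(bone, 3, sum)
  zb <- which(per_slice > 0)
  if (length(zb) == 0) stop("no mineralised tissue in lattice")
  gap <- which(per_slice == 0)
  gap <- gap[gap > min(zb) & gap < max(zb)]
  if (length(gap) == 0) stop("no identifiable osteotomy gap")

  axis <- longitudinal_axis(lattice)
  r2 <- radial_distance2(lattice, axis)
  bone_r2 <- r2[bone]
  r_out2 <- max(bone_r2) # cortical footprint radius (squared)

  zmask <- function(zs) {
    m <- array(FALSE, dims)
    m[, , zs] <- TRUE
    m
  }
  frag <- zmask(seq.int(min(zb), max(zb)))
  frag[, , gap] <- FALSE
  gapm <- zmask(gap)
  inside <- r2 <= r_out2

  vois <- list(
    DC = gapm & inside,
    DP = gapm & !inside,
    FC = frag & inside,
    FP = frag & !inside
  )
  vois$TOT <- vois$DC | vois$DP | vois$FC | vois$FP
  attr(vois, "gap_z") <- range(gap)
  vois
}

#' Haematoma mask by morphological dilation
#'
#' Dilates the defect-centre mask by a Euclidean ball, reproducing the
#' initial haematoma region (default radius 210 um = 20 voxels).
#'
#' @param defect_centre Logical 3D mask (nonempty).
#' @param radius Dilation radius in micrometres.
#' @param voxel_size Voxel size in micrometres.
#' @return Logical mask, a superset of the input.
#' @export
make_haematoma <- function(defect_centre, radius = 210, voxel_size = 10.5) {
  if (!any(defect_centre)) stop("defect_centre mask is empty")
  if (radius < 0) stop("radius must be non-negative")
  if (radius == 0) return(defect_centre)
  dims <- dim(defect_centre)
  # EDT of the complement gives, for every outside voxel, the distance to the mask
  d <- edt_cpp(!defect_centre, as.integer(dims))
  dim(d) <- dims
  defect_centre | (d <= radius / voxel_size)
}

# --- anatomical masks used by seeding ---------------------------------------

# periosteum: outward shell of the cortical surface (thickness_um thick);
# endosteum: 1-voxel inward shell (marrow voxels face-adjacent to cortex)
surface_shells <- function(lattice, periosteum_um = 52.5) {
  dims <- lattice$dims
  bone <- lattice$mineral >= MINERAL_THRESHOLD
  d_out <- edt_cpp(!bone, as.integer(dims)) # distance of soft voxels to bone
  dim(d_out) <- dims
  nvox <- periosteum_um / lattice$voxel_size
  shell <- !bone & d_out <= nvox & d_out > 0

  r2 <- radial_distance2(lattice)
  bone_r2 <- r2[bone]
  r_mid2 <- mean(range(bone_r2)) # between inner and outer cortical radius
  periosteum <- shell & r2 > r_mid2
  endosteum <- !bone & d_out <= 1 & d_out > 0 & r2 <= r_mid2
  marrow <- !bone & r2 <= min(bone_r2)
  # restrict marrow/endosteum to the fragment slabs
  per_slice <- apply(bone, 3, sum)
  zb <- which(per_slice > 0)
  slab <- array(FALSE, dims)
  slab[, , zb] <- TRUE
  list(
    periosteum = periosteum & slab,
    endosteum = endosteum & slab,
    marrow = marrow & slab,
    cortex = bone
  )
}
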
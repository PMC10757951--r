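# Time-lapsed bone morphometry: multidensity bone volumes, the
# formation/quiescence/resorption decomposition with BFR/BRR, cortical
# metrics, ray-traced gap width, and RMSE scoring of predicted against
# reference BV/TV series. The analysis mirrors standard micro-CT practice:
# BV counts voxels above a tissue-mineral-density threshold; the
# multidensity thresholds run from 395 to 720 mg HA/cm^3 in steps of 25.

MULTIDENSITY_THRESHOLDS <- seq(395, 720, by = 25)

#' Multidensity bone volume per VOI
#'
#' BV = voxel count above threshold x voxel volume, for each of the 14
#' multidensity thresholds and each VOI. BV/TV normalises to the central
#' VOI of each compartment (DC for DC/DP, FC for FC/FP, following the
#' DC/DC, DP/DC, FC/FC, FP/FC convention).
#'
#' @param lattice A [sim_lattice()] (or density array with attribute
#'   `voxel_size`).
#' @param vois VOI masks from [make_vois()].
#' @param thresholds Density thresholds, mg HA/cm^3.
#' @return Data frame: `voi`, `threshold`, `bv_um3`, `bv_tv`.
#' @export
bv_multithreshold <- function(lattice, vois,
                              thresholds = MULTIDENSITY_THRESHOLDS) {
  need <- c("DC", "DP", "FC", "FP")
  if (!all(need %in% names(vois))) {
    stop("missing VOI mask(s): ", paste(setdiff(need, names(vois)), collapse = ", "))
  }
  vol <- lattice$voxel_size^3
  denom <- c(DC = sum(vois$DC), DP = sum(vois$DC), FC = sum(vois$FC), FP = sum(vois$FC))
  out <- expand.grid(
    voi = need, threshold = thresholds,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  mineral <- lattice$mineral
  counts <- mapply(function(v, thr) sum(mineral[vois[[v]]] >= thr), out$voi, out$threshold)
  out$bv_um3 <- counts * vol
  out$bv_tv <- counts / denom[out$voi]
  out
}

#' Mineralisation ratio BV645/BV395
#'
#' Ratio of highly mineralised (>= 645 mg HA/cm^3) to total mineralised
#' (>= 395) volume within a mask.
#'
#' @param lattice A [sim_lattice()].
#' @param mask Logical mask (default whole domain).
#' @return Scalar in `[0, 1]` (0 when no mineralised tissue).
#' @export
mineralisation_ratio <- function(lattice, mask = NULL) {
  m <- lattice$mineral
  if (!is.null(mask)) m <- m[mask]
  b395 <- sum(m >= 395)
  if (b395 == 0) return(0)
  sum(m >= 645) / b395
}

#' Formation/quiescence/resorption between two time points
#'
#' Voxel-wise difference of two thresholded images: F = newly above
#' threshold, R = lost, Q = persistent. BFR and BRR are expressed as percent
#' of the baseline bone volume per day.
#'
#' @param lattice_t,lattice_t1 Lattices at consecutive time points (same
#'   grid).
#' @param dt_days Time between the images (default 7).
#' @param threshold Binary threshold (default 395 mg HA/cm^3).
#' @param mask Optional VOI restriction.
#' @return List: logical masks `F`, `Q`, `R`, and `bfr`, `brr` (%/day).
#' @export
fqr <- function(lattice_t, lattice_t1, dt_days = 7, threshold = 395,
                mask = NULL) {
  if (!all(lattice_t$dims == lattice_t1$dims)) stop("image grids differ")
  b0 <- lattice_t$mineral >= threshold
  b1 <- lattice_t1$mineral >= threshold
  if (!is.null(mask)) {
    b0 <- b0 & mask
    b1 <- b1 & mask
  }
  f <- b1 & !b0
  r <- b0 & !b1
  q <- b0 & b1
  base <- sum(b0)
  list(
    F = f, Q = q, R = r,
    bfr = if (base > 0) 100 * sum(f) / base / dt_days else 0,
    brr = if (base > 0) 100 * sum(r) / base / dt_days else 0
  )
}

#' Cortical morphometry across the defect region
#'
#' Slice-wise cortical bone area (Ct.Ar) and medullary area (Ma.Ar) averaged
#' over the region, cortical thickness (Ct.Th) by the distance-transform
#' (sphere-fitting ridge) method, and intracortical porosity (Ct.Po) as the
#' closed-pore fraction of the cortical compartment. The cortical compartment
#' is thresholded at the cortical density (720 mg HA/cm^3 by default).
#'
#' @param lattice A [sim_lattice()].
#' @param zrange Slice range (1-based, inclusive) to evaluate; default all
#'   slices containing bone.
#' @param threshold Cortical density threshold.
#' @return List `ct_ar_mm2`, `ma_ar_mm2`, `ct_th_mm`, `ct_po`, and
#'   `bridged` (FALSE when any evaluated slice has no cortex, in which case
#'   the metrics are `NA`).
#' @export
cortical_metrics <- function(lattice, zrange = NULL, threshold = 720) {
  dims <- lattice$dims
  h_mm <- lattice$voxel_size / 1000
  bone <- lattice$mineral >= threshold
  if (is.null(zrange)) {
    zb <- which(apply(bone, 3, sum) > 0)
    if (length(zb) == 0) {
      return(list(ct_ar_mm2 = NA, ma_ar_mm2 = NA, ct_th_mm = NA, ct_po = NA, bridged = FALSE))
    }
    zrange <- range(zb)
  }
  zs <- seq.int(zrange[1], zrange[2])
  if (any(apply(bone[, , zs, drop = FALSE], 3, sum) == 0)) {
    return(list(ct_ar_mm2 = NA, ma_ar_mm2 = NA, ct_th_mm = NA, ct_po = NA, bridged = FALSE))
  }

  ct_ar <- ma_ar <- numeric(length(zs))
  for (j in seq_along(zs)) {
    sl <- bone[, , zs[j]]
    ct_ar[j] <- sum(sl) * h_mm^2
    # enclosed non-bone regions: 2D components not touching the slice edge
    lab <- label_components_2d(!sl)
    edge_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    enc <- lab > 0 & !(lab %in% edge_labels)
    if (any(enc)) {
      sizes <- tabulate(lab[enc])
      ma_ar[j] <- max(sizes) * h_mm^2 # medullary cavity = largest enclosed void
    }
  }

  sub <- bone[, , zs, drop = FALSE]
  d <- edt_cpp(as.logical(sub), as.integer(dim(sub)))
  dim(d) <- dim(sub)
  # ridge voxels: local maxima of the distance map inside the structure
  ridge <- sub & d >= max_filter3(d)
  ct_th <- if (any(ridge)) 2 * mean(d[ridge]) * h_mm else NA_real_

  # closed pores: background components (6-conn) not reaching the subvolume
  # boundary
  labp <- label_components_cpp(as.logical(!sub), as.integer(dim(sub)), 6L)
  dim(labp) <- dim(sub)
  border <- unique(c(
    labp[1, , ], labp[dim(sub)[1], , ], labp[, 1, ], labp[, dim(sub)[2], ],
    labp[, , 1], labp[, , dim(sub)[3]]
  ))
  pores <- labp > 0 & !(labp %in% border)
  ct_po <- sum(pores) / (sum(sub) + sum(pores))

  list(
    ct_ar_mm2 = mean(ct_ar), ma_ar_mm2 = mean(ma_ar),
    ct_th_mm = ct_th, ct_po = ct_po, bridged = TRUE
  )
}

# 2D connected components (4-connectivity) via the 3D labeller
label_components_2d <- function(mask2d) {
  d <- dim(mask2d)
  lab <- label_components_cpp(as.logical(mask2d), as.integer(c(d, 1L)), 6L)
  matrix(lab, d[1], d[2])
}

# 6-neighbour maximum filter (used for distance-ridge extraction)
max_filter3 <- function(a) {
  d <- dim(a)
  out <- a
  sh <- function(a, ax, by) {
    o <- array(-Inf, d)
    idx_src <- seq_len(d[ax])
    idx_dst <- idx_src + by
    keep <- idx_dst >= 1 & idx_dst <= d[ax]
    if (ax == 1) o[idx_dst[keep], , ] <- a[idx_src[keep], , ]
    if (ax == 2) o[, idx_dst[keep], ] <- a[, idx_src[keep], ]
    if (ax == 3) o[, , idx_dst[keep]] <- a[, , idx_src[keep]]
    o
  }
  for (ax in 1:3) for (by in c(-1, 1)) out <- pmax(out, sh(a, ax, by))
  out
}

#' Ray-traced osteotomy gap width
#'
#' Casts rays perpendicular to the least-squares longitudinal axis. For each
#' angular direction, the gap width is the number of axial positions whose
#' radial ray meets no bone, multiplied by the voxel height; the median over
#' all directions is reported.
#'
#' @param lattice A [sim_lattice()].
#' @param angle_step Angular sampling in degrees (default 2).
#' @param threshold Bone threshold, mg HA/cm^3.
#' @return List: `median_mm`, `widths_mm` (per direction), `angles_deg`.
#' @export
gap_width <- function(lattice, angle_step = 2, threshold = 395) {
  dims <- lattice$dims
  h <- lattice$voxel_size
  bone <- lattice$mineral >= threshold
  per_slice <- apply(bone, 3, sum)
  zb <- which(per_slice > 0)
  if (length(zb) == 0) stop("no bone: longitudinal axis undefined")
  zs <- seq.int(min(zb), max(zb))

  axis <- longitudinal_axis(lattice)
  angles <- seq(0, 360 - angle_step, by = angle_step)
  rmax <- max(dims[1], dims[2]) * h / 2
  rsteps <- seq(h / 2, rmax, by = h / 2)

  widths <- numeric(length(angles))
  bone_free <- matrix(FALSE, length(angles), length(zs))
  for (j in seq_along(zs)) {
    z <- zs[j]
    a <- axis(z)
    sl <- bone[, , z]
    for (i in seq_along(angles)) {
      th <- angles[i] * pi / 180
      px <- a[1] + cos(th) * rsteps
      py <- a[2] + sin(th) * rsteps
      ix <- ceiling(px / h)
      iy <- ceiling(py / h)
      keep <- ix >= 1 & ix <= dims[1] & iy >= 1 & iy <= dims[2]
      bone_free[i, j] <- !any(sl[cbind(ix[keep], iy[keep])])
    }
  }
  widths <- rowSums(bone_free) * h / 1000 # mm
  list(
    median_mm = stats::median(widths), widths_mm = widths,
    angles_deg = angles
  )
}

#' RMSE score of a predicted BV/TV series against a reference
#'
#' Root-mean-square error of the BV/TV differences, evaluated independently
#' per VOI and per density threshold, averaged across time points.
#'
#' @param insilico,reference Data frames with columns `voi`, `threshold`,
#'   `time`, `bv_tv` covering matched time points.
#' @return Data frame `voi`, `threshold`, `rmse`.
#' @export
rmse_score <- function(insilico, reference) {
  key <- function(d) paste(d$voi, d$threshold, d$time)
  if (nrow(insilico) != nrow(reference)) {
    stop("series length mismatch: ", nrow(insilico), " vs ", nrow(reference))
  }
  reference <- reference[match(key(insilico), key(reference)), ]
  if (any(is.na(reference$bv_tv))) stop("unmatched voi/threshold/time rows")
  d2 <- (insilico$bv_tv - reference$bv_tv)^2
  agg <- stats::aggregate(
    d2,
    by = list(voi = insilico$voi, threshold = insilico$threshold),
    FUN = function(v) sqrt(mean(v))
  )
  names(agg)[3] <- "rmse"
  agg
}
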
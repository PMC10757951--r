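# Osteoid-to-mineral conversion and the latent TGF-beta pool.
#
# Osteoid (deposited by osteoblasts, tracked in the same density units as
# mineral) converts to mineral at a fixed rate of 30 mg HA/cm^3 per day,
# capped at the cortical density of 720 mg HA/cm^3 — the time delay between
# matrix deposition and mineralisation. A fraction of the newly mineralised
# matrix banks latent TGF-beta, which is released into the local field when
# the voxel is resorbed.

#' Mineralise osteoid
#'
#' @param lattice A [sim_lattice()].
#' @param dt_days Time step in days.
#' @param rate Mineralisation rate, mg HA/cm^3 per day (default 30).
#' @param tgfb_bank Latent TGF-beta banked per unit of mineral formed
#'   (mol/m^3 per mg HA/cm^3).
#' @return The updated lattice.
#' @export
mineralise <- function(lattice, dt_days, rate = 30,
                       tgfb_bank = sim_config()$production$tgfb_bank) {
  if (dt_days <= 0) stop("dt_days must be positive")
  room <- pmax(MINERAL_MAX - lattice$mineral, 0)
  transfer <- pmin(lattice$osteoid, rate * dt_days, room)
  lattice$mineral <- lattice$mineral + transfer
  lattice$osteoid <- lattice$osteoid - transfer
  lattice$tgfb_store <- lattice$tgfb_store + tgfb_bank * transfer
  lattice
}

#' Release stored TGF-beta on resorption
#'
#' Adds a resorbed voxel's latent TGF-beta store to the local concentration
#' field and zeroes the store.
#'
#' @param voxel 1-based linear voxel index (or vector thereof).
#' @param lattice A [sim_lattice()].
#' @param state A [cytokine_state()].
#' @return List with updated `lattice` and `state`.
#' @export
release_tgfb <- function(voxel, lattice, state) {
  s <- lattice$tgfb_store[voxel]
  conc <- state$conc$TGFb
  conc[voxel] <- conc[voxel] + s
  state$conc$TGFb <- conc
  lattice$tgfb_store[voxel] <- 0
  list(lattice = lattice, state = state)
}
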
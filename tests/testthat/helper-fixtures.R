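# Shared fixtures: a small osteotomy phantom and convenience builders.
# Everything is generated in code; no stored data.

default_cfg <- sim_config()

small_phantom <- function(gap = 210) {
  build_phantom(phantom_spec(gap_width = gap))
}

# homogeneous bar lattice at a given density
bar_lattice <- function(dims = c(6, 6, 12), density = 720) {
  sim_lattice(dims, mineral = array(density, dims))
}

# a lattice with agents of given types at given 0-based voxel coordinates
lattice_with_cells <- function(dims, types, coords) {
  lat <- sim_lattice(dims)
  cells <- new_cell_table()
  vox <- callusim:::vox_index(coords[, 1], coords[, 2], coords[, 3], dims)
  cells <- callusim:::add_cells(cells, types, vox, dims)
  lat$occupancy <- callusim:::rebuild_occupancy(cells, dims)
  list(lattice = lat, cells = cells)
}

# uniform stimulus fields
uniform_field <- function(dims, value) array(value, dims)

# one short coupled run (8 simulated hours on the default phantom), computed
# on first use and shared by every test that only inspects its state
shared_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seeding = list(prerun_iterations = 2))
      cache <<- run_simulation(cfg, duration_days = 1 / 3)
    }
    cache
  }
})

expect_occupancy_consistent <- function(cells, lattice) {
  dims <- lattice$dims
  vi <- callusim:::vox_index(cells$x, cells$y, cells$z, dims)
  expect_false(any(duplicated(vi)))
  occ <- lattice$occupancy
  expect_equal(sort(which(occ > 0L)), sort(vi))
  expect_equal(occ[vi], seq_len(nrow(cells)))
}
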
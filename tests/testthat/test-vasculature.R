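# Lattice angiogenesis: tip extension, branching, anastomosis, oxygen
# sourcing, vascular volume, connectivity audits.

TY <- cell_type_codes()

# build a state with tips at given coordinates and a VEGF field
vessel_setup <- function(dims, tip_coords, vegf) {
  lc <- lattice_with_cells(dims, rep(TY[["EndothelialTip"]], nrow(tip_coords)), tip_coords)
  net <- vessel_network(dims)
  vox <- callusim:::cell_voxels(lc$cells, dims)
  sv <- callusim:::seed_vessels(net, lc$lattice, vox)
  lc$cells$segment <- sv$net$segment[vox]
  list(cells = lc$cells, lattice = sv$lattice, net = sv$net, vegf = vegf)
}

test_that("tips climb a VEGF gradient deterministically when p_grad = 1", {
  cfg <- sim_config(vessels = list(p_grad = 1, p_persist = 0, p_rand = 0, p_tip_move = 1))
  dims <- c(5L, 5L, 20L)
  vegf <- array(rep(seq(1e-6, 2e-5, length.out = 20), each = 25), dims)
  vs <- vessel_setup(dims, cbind(2L, 2L, 1L), vegf)
  for (i in 1:15) {
    out <- extend_tips(vs$cells, vs$lattice, vs$net, vs$vegf, cfg)
    vs$cells <- out$cells; vs$lattice <- out$lattice; vs$net <- out$net
  }
  tip <- vs$cells[vs$cells$type == TY[["EndothelialTip"]], ]
  expect_equal(tip$z, 16L) # strictly up-gradient path
  expect_equal(sum(vs$lattice$vessel), 16)

  # below the sprout threshold nothing grows
  vs2 <- vessel_setup(dims, cbind(2L, 2L, 1L), array(1e-8, dims))
  out2 <- extend_tips(vs2$cells, vs2$lattice, vs2$net, vs2$vegf, cfg)
  expect_equal(out2$n_moved, 0L)
})

test_that("the default mix drifts up-gradient (biased-walk oracle)", {
  cfg <- sim_config(vessels = list(p_tip_move = 1))
  dims <- c(9L, 9L, 40L)
  vegf <- array(rep(seq(1e-6, 5e-5, length.out = 40), each = 81), dims)
  n_tips <- 30
  set.seed(13)
  coords <- cbind(
    sample(2:6, n_tips, TRUE), sample(2:6, n_tips, TRUE),
    rep(10L, n_tips)
  )
  coords <- coords[!duplicated(coords), , drop = FALSE]
  vs <- vessel_setup(dims, coords, vegf)
  z0 <- vs$cells$z
  for (i in 1:25) {
    out <- extend_tips(vs$cells, vs$lattice, vs$net, vs$vegf, cfg)
    vs$cells <- out$cells; vs$lattice <- out$lattice; vs$net <- out$net
  }
  tips <- vs$cells$type == TY[["EndothelialTip"]]
  dz <- vs$cells$z[tips] - z0[seq_len(sum(tips))]
  # sign test: essentially all surviving tips should have moved distally
  expect_gt(mean(dz > 0), 0.8)
  expect_gt(mean(dz), 2)
})

test_that("branching bookkeeping: rates, graph degree, Poisson count", {
  dims <- c(5L, 5L, 20L)
  vegf <- array(rep(seq(1e-6, 2e-5, length.out = 20), each = 25), dims)
  grow <- function(cfg, steps = 12) {
    vs <- vessel_setup(dims, cbind(2L, 2L, 1L), vegf)
    set.seed(14)
    for (i in seq_len(steps)) {
      out <- extend_tips(vs$cells, vs$lattice, vs$net, vs$vegf, cfg)
      br <- branch_vessels(out$cells, out$lattice, out$net, vs$vegf, cfg)
      vs$cells <- br$cells; vs$lattice <- br$lattice; vs$net <- br$net
    }
    vs
  }
  # branching rate zero: the tip count never increases
  cfg0 <- sim_config(vessels = list(
    p_grad = 1, p_persist = 0, p_rand = 0, p_tip_move = 1, branch_rate = 0
  ))
  vs0 <- grow(cfg0)
  expect_equal(sum(vs0$cells$type == TY[["EndothelialTip"]]), 1)

  # forced single bifurcation: the graph gains a degree-3 node
  cfg1 <- sim_config(vessels = list(
    p_grad = 1, p_persist = 0, p_rand = 0, p_tip_move = 1,
    branch_rate = 1, branch_threshold = 0
  ))
  vs1 <- grow(cfg1, steps = 3)
  g <- vessel_graph(vs1$net)
  expect_gte(max(igraph::degree(g)), 3)

  # expected branch count ~ Poisson(rate * stalk-steps)
  rate <- 0.05
  cfgp <- sim_config(vessels = list(
    p_grad = 1, p_persist = 0, p_rand = 0, p_tip_move = 1,
    branch_rate = rate, branch_threshold = 0
  ))
  set.seed(15)
  n_br <- 0
  exposure <- 0
  for (rep in 1:10) {
    vs <- vessel_setup(dims, cbind(2L, 2L, 1L), vegf)
    for (i in 1:10) {
      out <- extend_tips(vs$cells, vs$lattice, vs$net, vs$vegf, cfgp)
      exposure <- exposure + sum(out$cells$type == TY[["EndothelialStalk"]])
      br <- branch_vessels(out$cells, out$lattice, out$net, vs$vegf, cfgp)
      n_br <- n_br + br$n_branched
      vs$cells <- br$cells; vs$lattice <- br$lattice; vs$net <- br$net
    }
  }
  lambda <- rate * exposure
  expect_lt(abs(n_br - lambda), 4 * sqrt(lambda))
})

test_that("anastomosis joins segments and counts loops", {
  cfg <- sim_config(vessels = list(p_grad = 1, p_persist = 0, p_rand = 0, p_tip_move = 1))
  dims <- c(9L, 5L, 9L)
  # two tips growing head-on along a shared gradient ridge
  vegf <- array(0, dims)
  vegf[, 3, ] <- 2e-5
  vegf[5, 3, 5] <- 5e-5 # both climb towards the centre
  for (z in 1:9) vegf[, 3, z] <- 2e-5 + 1e-6 * (4 - abs(z - 5))
  vs <- vessel_setup(dims, rbind(c(4L, 2L, 1L), c(4L, 2L, 7L)), vegf)
  loops0 <- vs$net$loops
  for (i in 1:8) {
    out <- extend_tips(vs$cells, vs$lattice, vs$net, vs$vegf, cfg)
    vs$cells <- out$cells; vs$lattice <- out$lattice; vs$net <- out$net
  }
  g <- vessel_graph(vs$net)
  expect_equal(igraph::components(g)$no, 1) # single connected component
  expect_gte(vs$net$loops, loops0) # contact may close a loop

  # isolated straight growth never changes the loop count
  vegf2 <- array(rep(seq(1e-6, 2e-5, length.out = 9), each = 45), dims)
  vs2 <- vessel_setup(dims, cbind(2L, 2L, 1L), vegf2)
  for (i in 1:6) {
    out <- extend_tips(vs2$cells, vs2$lattice, vs2$net, vs2$vegf, cfg)
    vs2$cells <- out$cells; vs2$lattice <- out$lattice; vs2$net <- out$net
  }
  expect_equal(vs2$net$loops, 0L)

  # ring closure on a constructed two-segment path increments the loop count
  expect_equal(igraph::components(vessel_graph(vs$net))$no, 1)
  if (vs$net$loops > 0) {
    # cycle count in the graph matches the recorded anastomoses
    expect_equal(
      igraph::ecount(g) - igraph::vcount(g) + igraph::components(g)$no,
      vs$net$loops
    )
  }
})

test_that("vessels source oxygen; more vessels, more oxygen", {
  cfg <- sim_config()
  lat <- sim_lattice(c(7, 7, 15))
  expect_equal(length(oxygen_sources(lat)$idx), 0) # no vessels, empty mask

  # single vessel line in a hypoxic slab: O2 falls with distance
  lat$vessel[4, 4, ] <- TRUE
  st <- cytokine_state(lat, cfg)
  st$conc$O2[] <- 0
  src <- oxygen_sources(lat, 0.065)
  for (i in 1:200) {
    st <- step_diffusion_decay(st, "O2", dt = 1e4, extra_dirichlet = src, boundary = "closed")
  }
  mid <- st$conc$O2[, , 8]
  d <- abs(seq_len(7) - 4)
  prof <- tapply(as.vector(mid), outer(d, d, pmax), mean)
  expect_true(all(diff(prof) <= 1e-9)) # monotone decrease with distance

  # doubling vessel density never lowers the mean steady-state O2
  lat2 <- lat
  lat2$vessel[2, 2, ] <- TRUE
  st2 <- cytokine_state(lat2, cfg)
  st2$conc$O2[] <- 0
  src2 <- oxygen_sources(lat2, 0.065)
  for (i in 1:200) {
    st2 <- step_diffusion_decay(st2, "O2", dt = 1e4, extra_dirichlet = src2, boundary = "closed")
  }
  expect_gte(mean(st2$conc$O2), mean(st$conc$O2))
})

test_that("vascular volume counts connected vessel voxels only", {
  lat <- sim_lattice(c(10, 10, 10))
  expect_equal(vascular_volume(lat)$vv_um3, 0) # empty network
  lat$vessel[2, 2, 1:10] <- TRUE # a 10-voxel line... plus scattered singletons
  lat$vessel[8, 8, 2] <- TRUE
  lat$vessel[5, 9, 7] <- TRUE
  vv <- vascular_volume(lat)
  expect_equal(vv$n_voxels, 10) # singletons excluded
  expect_equal(vv$vv_um3, 10 * 10.5^3)
  # 100 connected vessel voxels -> exact volume
  lat3 <- sim_lattice(c(10, 10, 10))
  lat3$vessel[, , 1] <- TRUE # 100-voxel plate
  expect_equal(vascular_volume(lat3)$vv_um3, 100 * 10.5^3)
})

test_that("every vessel voxel stays reachable from a seed (graph audit)", {
  sim <- shared_run()
  st <- sim$final_state
  net <- st$net
  vox <- which(net$segment > 0)
  seeds <- vox[net$parent[vox] == 0L]
  g <- vessel_graph(net)
  comp <- igraph::components(g)
  seed_comps <- comp$membership[as.character(seeds)]
  expect_true(all(comp$membership %in% seed_comps))
  # vessel flags and the network agree
  expect_setequal(which(st$lattice$vessel), vox)
  # no osteoid in vessel voxels
  expect_equal(sum(st$lattice$osteoid[st$lattice$vessel]), 0)
})
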
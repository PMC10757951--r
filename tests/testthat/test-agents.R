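# Agent behaviours: migration, differentiation map, population dynamics,
# production laws, deposition/resorption polarisation, cluster detection.

TY <- cell_type_codes()

test_that("free random walk at move-probability 1 gives 31.5 um/h", {
  cfg <- sim_config()
  dims <- c(21L, 21L, 21L)
  lc <- lattice_with_cells(dims, TY[["SSPC"]], cbind(10L, 10L, 10L))
  cells <- lc$cells
  lat <- lc$lattice
  set.seed(1)
  steps <- 60
  path <- 0
  for (i in seq_len(steps)) {
    old <- c(cells$x, cells$y, cells$z)
    out <- migrate_cells(cells, lat, uniform_field(dims, 0), uniform_field(dims, 0), cfg)
    cells <- out$cells
    lat <- out$lattice
    path <- path + sum(abs(c(cells$x, cells$y, cells$z) - old)) * 10.5
  }
  hours <- steps * cfg$cells$dt_cells / 3600
  expect_equal(path / hours, 31.5, tolerance = 1e-9) # one 10.5-um step per 20 min
})

test_that("swap rules: OBL cannot displace OCL; mineral blocks movement", {
  cfg <- sim_config(cells = list(p_bias = 0))
  dims <- c(5L, 3L, 3L)
  lc <- lattice_with_cells(dims, c(TY[["OBL"]], TY[["OCL"]]),
    rbind(c(1L, 1L, 1L), c(2L, 1L, 1L)))
  # wall off everything except the OCL voxel so the OBL can only move right
  lat <- lc$lattice
  lat$mineral[] <- 720
  lat$mineral[2, 2, 2] <- 0 # OBL voxel
  lat$mineral[3, 2, 2] <- 0 # OCL voxel
  set.seed(2)
  for (i in 1:20) {
    out <- migrate_cells(lc$cells, lat, uniform_field(dims, 0), uniform_field(dims, 0), cfg)
    expect_equal(out$cells$x, c(1L, 2L)) # both unmoved
    expect_equal(out$nmoved, 0L)
  }

  # fully mineral-surrounded agent never moves
  lc2 <- lattice_with_cells(c(3L, 3L, 3L), TY[["SSPC"]], cbind(1L, 1L, 1L))
  lat2 <- lc2$lattice
  lat2$mineral[] <- 720
  lat2$mineral[2, 2, 2] <- 0
  out2 <- migrate_cells(lc2$cells, lat2, uniform_field(c(3L, 3L, 3L), 0),
    uniform_field(c(3L, 3L, 3L), 0), cfg)
  expect_equal(out2$nmoved, 0L)
})

test_that("occupancy stays unique through crowded migration sweeps", {
  cfg <- sim_config()
  dims <- c(8L, 8L, 8L)
  set.seed(3)
  vox <- sample(prod(dims), 200)
  co <- callusim:::index_vox(vox, dims)
  lc <- lattice_with_cells(dims, sample(1:6, 200, replace = TRUE), co)
  cells <- lc$cells
  lat <- lc$lattice
  for (i in 1:30) {
    out <- migrate_cells(cells, lat, uniform_field(dims, 0), uniform_field(dims, 0), cfg)
    cells <- out$cells
    lat <- out$lattice
  }
  expect_occupancy_consistent(cells, lat)
})

test_that("differentiation map follows the oxygen/strain/receptor gates", {
  cfg <- sim_config()
  dims <- c(5L, 5L, 5L)
  build <- function(type, occ = list(), o2 = TRUE) {
    lc <- lattice_with_cells(dims, type, cbind(2L, 2L, 2L))
    for (n in names(occ)) lc$cells[[n]] <- occ[[n]]
    lc$cells$o2_ok <- o2
    lc
  }
  run1 <- function(lc, eff = 0, sed = 0) {
    differentiate_cells(lc$cells, lc$lattice,
      uniform_field(dims, sed), uniform_field(dims, eff), cfg)
  }

  # SSPC -> OBL under oxygen + strain + TGFBR1 engagement
  lc <- build(TY[["SSPC"]], list(occ_tgfbr = 0.6))
  expect_equal(run1(lc, eff = 0.01)$cells$type, TY[["OBL"]])
  # below the osteogenic threshold: no transition
  expect_equal(run1(lc, eff = 0.005)$cells$type, TY[["SSPC"]])
  # hypoxic SSPC never differentiates
  lc <- build(TY[["SSPC"]], list(occ_tgfbr = 0.6), o2 = FALSE)
  expect_equal(run1(lc, eff = 0.01)$cells$type, TY[["SSPC"]])

  # immune -> OCL on RANK engagement even when hypoxic
  lc <- build(TY[["Immune"]], list(occ_rank = 0.6), o2 = FALSE)
  expect_equal(run1(lc)$cells$type, TY[["OCL"]])
  # HSC needs oxygen for the same transition
  lc <- build(TY[["HSC"]], list(occ_rank = 0.6), o2 = FALSE)
  expect_equal(run1(lc)$cells$type, TY[["HSC"]])
  lc <- build(TY[["HSC"]], list(occ_rank = 0.6))
  expect_equal(run1(lc)$cells$type, TY[["OCL"]])

  # sclerostin inhibition: lining cell with engaged LRP5/6 stays lining
  lc <- build(TY[["Lining"]], list(occ_lrp = 0.7))
  expect_equal(run1(lc, eff = 0.01)$cells$type, TY[["Lining"]])
  lc <- build(TY[["Lining"]], list(occ_lrp = 0.1))
  expect_equal(run1(lc, eff = 0.01)$cells$type, TY[["OBL"]])

  # SSPC lining mineral at low strain becomes a lining cell
  lc <- build(TY[["SSPC"]])
  lc$lattice$mineral[4, 3, 3] <- 720 # face-adjacent bone
  expect_equal(run1(lc, eff = 0.005)$cells$type, TY[["Lining"]])
})

test_that("population dynamics: division gates, protected osteocytes, decay law", {
  cfg <- sim_config()
  dims <- c(3L, 3L, 3L)
  # SSPC boxed in by occupied neighbours cannot divide
  all_vox <- callusim:::index_vox(seq_len(27), c(3L, 3L, 3L))
  lc <- lattice_with_cells(dims, rep(TY[["SSPC"]], 27), all_vox)
  set.seed(4)
  out <- proliferate_or_die(lc$cells, lc$lattice,
    uniform_field(dims, 0.02), uniform_field(dims, 0.02),
    cfg, dt_h = 1e-9) # no apoptosis in a vanishing interval
  expect_equal(out$births, 0L)

  # OCY neither divide nor die spontaneously
  lc2 <- lattice_with_cells(dims, rep(TY[["OCY"]], 5), all_vox[1:5, ])
  out2 <- proliferate_or_die(lc2$cells, lc2$lattice,
    uniform_field(dims, 1), uniform_field(dims, 1), cfg, dt_h = 1e6)
  expect_equal(nrow(out2$cells), 5)
  expect_equal(out2$births, 0L)

  # isolated OBL cohort decays exponentially (analytic oracle)
  dims3 <- c(40L, 40L, 2L)
  n0 <- 1200
  vox <- sample(prod(dims3), n0)
  lc3 <- lattice_with_cells(dims3, rep(TY[["OBL"]], n0), callusim:::index_vox(vox, dims3))
  cells <- lc3$cells
  lat <- lc3$lattice
  hours <- 40
  for (i in seq_len(hours)) {
    out <- proliferate_or_die(cells, lat, uniform_field(dims3, 0),
      uniform_field(dims3, 0), cfg, dt_h = 1)
    cells <- out$cells
    lat <- out$lattice
  }
  p_surv <- exp(-cfg$cells$apoptosis * hours)
  expect_lt(
    abs(nrow(cells) - n0 * p_surv),
    4 * sqrt(n0 * p_surv * (1 - p_surv)) + 4 # CLT band (+slack for discreteness)
  )
})

test_that("cytokine production laws respond to SED, EFF and oxygen", {
  cfg <- sim_config()
  cells <- lattice_with_cells(c(3L, 3L, 3L),
    c(TY[["OCY"]], TY[["SSPC"]], TY[["Immune"]]),
    rbind(c(0L, 0L, 0L), c(1L, 1L, 1L), c(2L, 2L, 2L)))$cells

  # OCY at SED = 0: maximal RANKL rate; monotone non-increasing with SED
  sweep <- seq(0, 0.03, by = 0.003)
  rankl <- vapply(sweep, function(s) {
    produce_cytokines(cells, rep(s, 3), rep(0, 3), rep(0.065, 3), cfg)[1, "RANKL"]
  }, numeric(1))
  expect_equal(rankl[1], cfg$production$ocy_rankl)
  expect_true(all(diff(rankl) <= 1e-15))
  expect_equal(rankl[length(rankl)], 0) # clamped at zero beyond SED_RES

  # fully oxygen-saturated cells produce no VEGF; hypoxic cells do
  r <- produce_cytokines(cells, rep(0, 3), rep(0, 3), rep(0.065, 3), cfg)
  expect_equal(unname(r[2, "VEGF"]), 0)
  r2 <- produce_cytokines(cells, rep(0, 3), rep(0, 3), rep(0, 3), cfg)
  expect_equal(unname(r2[2, "VEGF"]), cfg$production$vegf_max)
  # immune TGF-beta is constant
  expect_equal(unname(r[3, "TGFb"]), cfg$production$immune_tgfb)
})

test_that("osteoid deposition is gated, vessel-safe, and unbiased when flat", {
  cfg <- sim_config()
  dims <- c(5L, 5L, 5L)
  lc <- lattice_with_cells(dims, TY[["OBL"]], cbind(2L, 2L, 2L))

  # below threshold: nothing deposited
  out <- deposit_osteoid(lc$cells, lc$lattice, uniform_field(dims, 0.005), cfg)
  expect_equal(sum(out$lattice$osteoid), 0)

  # all neighbours vessel: deposition only in the OBL's own voxel
  lat <- lc$lattice
  nb <- callusim:::face_neighbours(callusim:::vox_index(2L, 2L, 2L, dims), dims)
  lat$vessel[nb[nb > 0]] <- TRUE
  set.seed(6)
  out2 <- deposit_osteoid(lc$cells, lat, uniform_field(dims, 0.02), cfg)
  expect_equal(sum(out2$lattice$osteoid > 0), 1)
  expect_equal(out2$lattice$osteoid[2 + 1, 2 + 1, 2 + 1], cfg$cells$osteoid_increment)

  # uniform EFF: neighbour selection uniform within a multinomial band
  set.seed(7)
  counts <- integer(6)
  n_draw <- 6000
  for (i in seq_len(n_draw)) {
    out3 <- deposit_osteoid(lc$cells, lc$lattice, uniform_field(dims, 0.02), cfg)
    got <- which(out3$lattice$osteoid[nb] > 0)
    counts[got] <- counts[got] + 1L
  }
  expect_equal(sum(counts), n_draw)
  p <- counts / n_draw
  expect_true(all(abs(p - 1 / 6) < 4 * sqrt((1 / 6) * (5 / 6) / n_draw)))
})

test_that("resorption needs a cluster, RANK engagement and the SED window", {
  cfg <- sim_config(cells = list(p_resorb = 1))
  dims <- c(6L, 6L, 6L)
  mk <- function(n_ocl, occ) {
    co <- cbind(1L + seq_len(n_ocl), 2L, 2L)
    lc <- lattice_with_cells(dims, rep(TY[["OCL"]], n_ocl), co)
    lc$cells$occ_rank <- occ
    lc$lattice$mineral[4, 4, 3] <- 720 # adjacent mineral target
    lc$lattice$mineral[4, 3, 4] <- 700
    lc
  }
  sed <- uniform_field(dims, 0.001) # osteolytic window

  out <- resorb(mk(2, 0.9)$cells, mk(2, 0.9)$lattice, sed, cytokine_state(mk(2, 0.9)$lattice), cfg)
  expect_equal(out$n_resorbed, 0L) # pairs never resorb

  lc3 <- mk(3, 0.6)
  set.seed(8)
  out3 <- resorb(lc3$cells, lc3$lattice, sed, cytokine_state(lc3$lattice), cfg)
  expect_equal(out3$n_resorbed, 1L) # exactly one voxel per event
  expect_equal(sum(out3$lattice$mineral > 0), 1)

  lc4 <- mk(3, 0.4)
  out4 <- resorb(lc4$cells, lc4$lattice, sed, cytokine_state(lc4$lattice), cfg)
  expect_equal(out4$n_resorbed, 0L) # RANK gate

  lc5 <- mk(3, 0.9)
  out5 <- resorb(lc5$cells, lc5$lattice, uniform_field(dims, 0.05),
    cytokine_state(lc5$lattice), cfg)
  expect_equal(out5$n_resorbed, 0L) # outside the osteolytic window
})

test_that("cluster detection equals a brute-force component search", {
  dims <- c(12L, 12L, 4L)
  # L-shaped triple
  lcL <- lattice_with_cells(dims, rep(TY[["OCL"]], 3),
    rbind(c(1L, 1L, 1L), c(2L, 1L, 1L), c(2L, 2L, 1L)))
  expect_equal(lengths(detect_clusters(lcL$cells, dims)), 3L)
  # two isolated OCL: nothing
  lc0 <- lattice_with_cells(dims, rep(TY[["OCL"]], 2),
    rbind(c(1L, 1L, 1L), c(5L, 5L, 1L)))
  expect_equal(length(detect_clusters(lc0$cells, dims)), 0L)
  # random sprinkle vs igraph component oracle
  set.seed(10)
  vox <- sample(prod(dims), 60)
  co <- callusim:::index_vox(vox, dims)
  lc <- lattice_with_cells(dims, rep(TY[["OCL"]], 60), co)
  got <- detect_clusters(lc$cells, dims)
  adj <- which(as.matrix(dist(co, method = "manhattan")) == 1, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(cbind(adj[, 1], adj[, 2]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, 60 - igraph::vcount(g)))
  comp <- igraph::components(g)
  expect_setequal(
    lengths(got),
    unname(comp$csize[comp$csize >= 3])
  )
})

test_that("embedding calibration reaches the osteocyte target density", {
  cfg <- sim_config()
  dims <- c(40L, 40L, 6L)
  n <- prod(dims)
  # mineralising slab: osteoid-loaded voxels each holding an osteoblast
  slab <- which(callusim:::index_vox(seq_len(n), dims)[, 3] %in% 1:3)
  lc <- lattice_with_cells(dims, rep(TY[["OBL"]], length(slab)),
    callusim:::index_vox(slab, dims))
  lat <- lc$lattice
  lat$osteoid[slab] <- 400
  cells <- lc$cells
  set.seed(12)
  for (day in 1:14) {
    lat <- mineralise(lat, 1)
    out <- differentiate_cells(cells, lat, uniform_field(dims, 0),
      uniform_field(dims, 0), cfg)
    cells <- out$cells
    lat <- out$lattice
  }
  n_min <- sum(lat$mineral >= 395)
  expect_equal(n_min, length(slab))
  dens <- sum(cells$type %in% TY[c("preOCY", "OCY")]) / (n_min * (10.5e-3)^3)
  expect_lt(abs(dens - 44800) / 44800, 0.10)
})

test_that("behaviour steps keep the tissue-compatibility invariant", {
  sim <- shared_run()
  cells <- sim$final_state$cells
  lat <- sim$final_state$lattice
  vi <- callusim:::cell_voxels(cells, lat$dims)
  mineralised <- lat$mineral[vi] >= 395
  embedded <- cells$type %in% TY[c("preOCY", "OCY")]
  expect_true(all(mineralised == embedded))
  expect_occupancy_consistent(cells, lat)
})
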
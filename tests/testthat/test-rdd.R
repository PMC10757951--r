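# Implicit diffusion-decay: conservation, closed forms, stability, dense
# oracles; receptor-ligand kinetics; secretion and oxygen accounting.

test_that("closed domain conserves mass; decay follows the exponential", {
  cfg <- sim_config()
  lat <- sim_lattice(c(8, 8, 12))
  st <- cytokine_state(lat, cfg)
  set.seed(7)
  st$conc$RANKL <- array(runif(prod(lat$dims)), lat$dims)
  st$species$decay[] <- 0
  m0 <- sum(st$conc$RANKL)
  for (i in 1:10) st <- step_diffusion_decay(st, "RANKL", boundary = "closed", tol = 1e-13)
  expect_lt(abs(sum(st$conc$RANKL) - m0) / m0, 1e-10)

  # uniform field, D = 0: c(t) = c0 exp(-lambda t) within 1% for dt << 1/lambda
  st2 <- cytokine_state(lat, cfg)
  st2$conc$Scl[] <- 2
  st2$D$cytokine[] <- 0
  lam <- st2$species$decay[st2$species$name == "Scl"]
  dt <- 600
  for (i in 1:5) st2 <- step_diffusion_decay(st2, "Scl", dt = dt, boundary = "closed")
  expect_lt(abs(mean(st2$conc$Scl) - 2 * exp(-lam * 5 * dt)) / (2 * exp(-lam * 5 * dt)), 0.01)
})

test_that("Dirichlet steady state is the linear Laplace profile", {
  cfg <- sim_config()
  lat <- sim_lattice(c(6, 6, 15))
  st <- cytokine_state(lat, cfg)
  st$species$decay[] <- 0
  st$species$boundary_prox[1] <- 1
  st$species$boundary_dist[1] <- 0
  for (i in 1:200) st <- step_diffusion_decay(st, "VEGF", dt = 1e5)
  prof <- apply(st$conc$VEGF, 3, mean)
  # linear between the two Dirichlet slabs
  zref <- seq_along(prof)
  expected <- approx(c(1, 15), c(1, 0), xout = zref)$y
  expect_lt(max(abs(prof - expected)), 1e-3)
})

test_that("diffusivity map follows the mineral field", {
  cfg <- sim_config()
  lat <- sim_lattice(c(4, 4, 4))
  st <- cytokine_state(lat, cfg)
  expect_true(all(st$D$cytokine == cfg$species$D_soft)) # all-soft phantom
  mineral <- lat$mineral
  mineral[2, 2, 2] <- 500
  st <- update_diffusivity(st, mineral)
  expect_equal(
    st$D$cytokine[1, 1, 1] / st$D$cytokine[2, 2, 2], 100 # two orders less diffusive
  )
  expect_equal(st$D$O2[1, 1, 1] / st$D$O2[2, 2, 2], 1) # oxygen unchanged
})

test_that("BTCS equals a dense oracle and converges first order to expm", {
  skip_if_not_installed("Matrix")
  dims <- c(5L, 5L, 5L)
  n <- prod(dims)
  set.seed(11)
  D <- runif(n, 50, 150)
  c0 <- runif(n)
  h <- 10.5
  lam <- 1e-4
  hm <- function(a, b) 2 * a * b / (a + b)
  A <- matrix(0, n, n)
  co <- callusim:::index_vox(1:n, dims)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (i in 1:n) {
    A[i, i] <- lam
    for (d in 1:6) {
      x <- co[i, 1] + offs[d, 1]; y <- co[i, 2] + offs[d, 2]; z <- co[i, 3] + offs[d, 3]
      if (x >= 0 && x < 5 && y >= 0 && y < 5 && z >= 0 && z < 5) {
        j <- callusim:::vox_index(x, y, z, dims)
        w <- hm(D[i], D[j]) / h^2
        A[i, i] <- A[i, i] + w
        A[i, j] <- A[i, j] - w
      }
    }
  }
  # one implicit step == dense linear solve of (I/dt + A) c = c0/dt
  dt <- 1800
  res <- callusim:::btcs_cg_cpp(
    c0, D, dims, h, dt, lam, integer(0), numeric(0), 1e-12, 5000
  )
  dense <- solve(diag(n) / dt + A, c0 / dt)
  expect_lt(max(abs(res$c - dense)), 1e-6)

  # first-order convergence to the matrix exponential over one hour
  expm_ref <- as.matrix(Matrix::expm(-A * 3600)) %*% c0
  err <- sapply(c(1800, 900, 450), function(dt) {
    cc <- c0
    for (k in seq_len(3600 / dt)) {
      cc <- callusim:::btcs_cg_cpp(cc, D, dims, h, dt, lam, integer(0), numeric(0), 1e-12, 5000)$c
    }
    max(abs(cc - expm_ref))
  })
  expect_lt(err[2] / err[1], 0.65) # halving dt roughly halves the error
  expect_lt(err[3] / err[2], 0.65)
})

test_that("BTCS is stable far beyond the explicit CFL limit", {
  cfg <- sim_config()
  lat <- sim_lattice(c(8, 8, 8))
  st <- cytokine_state(lat, cfg)
  st$conc$VEGF[4, 4, 4] <- 1e3
  dt_cfl <- 10.5^2 / (6 * cfg$species$D_soft)
  for (i in 1:20) st <- step_diffusion_decay(st, "VEGF", dt = 100 * dt_cfl, boundary = "closed")
  expect_true(all(is.finite(st$conc$VEGF)))
  expect_lt(max(st$conc$VEGF), 1e3) # diffusion only flattens the spike
})

test_that("factored cytokine path matches the CG path", {
  cfg <- sim_config()
  lat <- small_phantom()
  st <- cytokine_state(lat, cfg)
  set.seed(3)
  st$conc$RANKL <- array(runif(prod(lat$dims), 0, 1e-5), lat$dims)
  fact <- btcs_factor(st)
  a <- step_diffusion_decay(st, "RANKL", tol = 1e-12, maxit = 5000)
  b <- step_diffusion_decay_factored(st, "RANKL", fact)
  expect_lt(max(abs(a$conc$RANKL - b$conc$RANKL)), 1e-12)
})

test_that("receptor kinetics: off-rate decay, bath equilibrium, conservation", {
  cfg <- sim_config()
  dims <- c(3L, 3L, 3L)
  lc <- lattice_with_cells(dims, cell_type_codes()[["SSPC"]], cbind(1L, 1L, 1L))
  st <- cytokine_state(lc$lattice, cfg)

  # zero ligand: occupancy decays at k_off
  cells <- lc$cells
  cells$occ_rank <- 0.8
  st$conc$RANKL[] <- 0
  dt <- 600
  out <- react(st, cells, dt, cfg)
  expect_equal(out$cells$occ_rank, 0.8 * exp(-cfg$species$koff * dt), tolerance = 1e-10)

  # constant bath: equilibrium occupancy c / (c + koff/kon) within 1%
  kd <- cfg$species$koff / cfg$species$kon
  bath <- 2 * kd
  cells$occ_rank <- 0
  for (i in 1:400) {
    st$conc$RANKL[] <- bath # replenished bath
    out <- react(st, cells, 600, cfg)
    cells <- out$cells
    st <- out$state
  }
  expect_lt(abs(cells$occ_rank - bath / (bath + kd)) / (bath / (bath + kd)), 0.01)

  # closed domain: free + cell-bound + complexed RANKL is conserved
  set.seed(5)
  st2 <- cytokine_state(lc$lattice, cfg)
  st2$conc$RANKL <- array(runif(27, 0, 1e-5), dims)
  st2$conc$OPG <- array(runif(27, 0, 1e-5), dims)
  cells2 <- lc$cells
  pool <- cfg$species$binding_sites * callusim:::site_concentration(10.5)
  total <- function(st, cells) {
    sum(st$conc$RANKL) + sum(st$conc$RANKL_OPG) + sum(cells$occ_rank) * pool
  }
  t0 <- total(st2, cells2)
  for (i in 1:100) {
    out <- react(st2, cells2, 600, cfg)
    st2 <- out$state
    cells2 <- out$cells
  }
  expect_lt(abs(total(st2, cells2) - t0) / t0, 1e-8)
})

test_that("secretion adds mass exactly; oxygen flag follows consumption", {
  cfg <- sim_config()
  dims <- c(4L, 4L, 4L)
  lc <- lattice_with_cells(dims, rep(cell_type_codes()[["Immune"]], 2),
    rbind(c(1L, 1L, 1L), c(2L, 2L, 2L)))
  st <- cytokine_state(lc$lattice, cfg)

  # no cells: state unchanged
  empty <- secrete_and_consume(st, new_cell_table(),
    matrix(0, 0, 5, dimnames = list(NULL, c("VEGF", "RANKL", "OPG", "Scl", "TGFb"))),
    600, cfg)
  expect_identical(empty$state$conc, st$conc)

  rates <- produce_cytokines(lc$cells, c(0, 0), c(0, 0), c(0.065, 0.065), cfg)
  m0 <- sum(st$conc$TGFb)
  out <- secrete_and_consume(st, lc$cells, rates, 600, cfg)
  expect_equal(sum(out$state$conc$TGFb) - m0, sum(rates[, "TGFb"]) * 600, tolerance = 1e-12)

  # the sufficiency flag follows the hypoxia threshold
  vi <- callusim:::cell_voxels(lc$cells, dims)
  st$conc$O2[] <- 0
  st$conc$O2[vi[1]] <- cfg$cells$o2_threshold / 2 # below: starved
  st$conc$O2[vi[2]] <- cfg$cells$o2_threshold * 2 # above: sufficient
  out2 <- secrete_and_consume(st, lc$cells, rates * 0, 600, cfg)
  expect_false(out2$cells$o2_ok[1])
  expect_true(out2$cells$o2_ok[2])
})

test_that("continuous consumption carves a hypoxic core away from sources", {
  cfg <- sim_config()
  dims <- c(5L, 5L, 41L)
  # cells throughout; oxygen only from the two z-faces
  vox <- which(callusim:::index_vox(seq_len(prod(dims)), dims)[, 3] %in% 2:38)
  lc <- lattice_with_cells(dims, rep(cell_type_codes()[["SSPC"]], length(vox)),
    callusim:::index_vox(vox, dims))
  st <- cytokine_state(lc$lattice, cfg)
  sink <- o2_sink_map(lc$lattice, cfg)
  for (i in 1:50) st <- step_diffusion_decay(st, "O2", extra_sink = sink)
  prof <- apply(st$conc$O2, 3, mean)
  expect_gt(prof[1], cfg$cells$o2_threshold) # supplied face stays normoxic
  expect_lt(min(prof), cfg$cells$o2_threshold) # core goes hypoxic
  # profile decreases towards the centre from both faces
  expect_true(all(diff(prof[1:21]) <= 1e-9))
})

test_that("combined stepping with random sources preserves non-negativity", {
  cfg <- sim_config()
  lat <- sim_lattice(c(6, 6, 6))
  lc <- lattice_with_cells(
    c(6L, 6L, 6L), rep(cell_type_codes()[["Immune"]], 5),
    cbind(1:5, 1:5, 1:5)
  )
  st <- cytokine_state(lc$lattice, cfg)
  cells <- lc$cells
  set.seed(9)
  for (i in 1:150) {
    sp <- sample(c("VEGF", "RANKL", "OPG", "TGFb"), 1)
    st$conc[[sp]][sample(216, 5)] <- runif(5, 0, 1e-5)
    st <- step_diffusion_decay(st, sp)
    out <- react(st, cells, 600, cfg)
    st <- out$state
    cells <- out$cells
    expect_true(all(vapply(st$conc, function(a) all(a >= 0), logical(1))))
    expect_true(all(cells$occ_rank >= 0 & cells$occ_rank <= 1))
  }
})
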
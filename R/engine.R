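# The coupling scheduler. One macro-step covers 8 h: the micro-FE solve
# refreshes the mechanical signals, then 24 cell updates (20 min each)
# interleave with 16 implicit RDD steps (30 min each) on a fixed schedule
# table (an RDD block after every 1.5 cell updates, rounded to the fixed
# slots), and osteoid mineralises once per macro-step. Vessel growth runs on
# the cell clock. All randomness is drawn from named per-module streams
# spawned from the master seed, so a run is bit-reproducible.

# cell-update slots (1..24) after which an RDD block runs; 16 slots per 8 h
rdd_schedule <- function(n_cells = 24L, n_rdd = 16L) {
  unique(ceiling(seq_len(n_rdd) * n_cells / n_rdd))
}

#' Run the coupled simulation
#'
#' @param config A [sim_config()].
#' @param lattice Initial geometry; built from `config$phantom` when `NULL`.
#' @param init Optional state to continue from (a snapshot restored via
#'   [restore_snapshot()] or the `final_state` of a previous run).
#' @param duration_days Simulated duration; defaults to the config value.
#'   `0` returns the initial snapshot only.
#' @param progress Print a line per macro-step.
#' @return An object of class `bone_sim`: weekly `snapshots`, a `timeline`
#'   data frame (per macro-step apparent stiffness, populations, event
#'   counts, mass ledger), `morphometry` per snapshot, the `final_state`,
#'   `vois`, and the `config`.
#' @export
run_simulation <- function(config = sim_config(), lattice = NULL, init = NULL,
                           duration_days = config$engine$duration_days,
                           progress = FALSE) {
  eng <- config$engine
  dt_fe <- eng$dt_fe
  n_cell_steps <- as.integer(round(dt_fe / config$cells$dt_cells))
  n_rdd_steps <- as.integer(round(dt_fe / config$species$dt_rdd))
  sched <- rdd_schedule(n_cell_steps, n_rdd_steps)
  dt_cells_h <- config$cells$dt_cells / 3600

  if (is.null(init)) {
    if (is.null(lattice)) lattice <- build_phantom(do.call(phantom_spec, config$phantom))
    streams <- make_streams(eng$seed)
    ini <- initialise_model(lattice, seeding_plan(config), config, streams)
    # habitual load transmitted at matched tissue stress: scale the peak
    # force by the specimen's cortical area relative to the in vivo femur
    bone0 <- ini$lattice$mineral >= MINERAL_THRESHOLD
    slices <- which(apply(bone0, 3, sum) > 0)
    ct_ar0 <- mean(apply(bone0[, , slices, drop = FALSE], 3, sum)) *
      (ini$lattice$voxel_size / 1000)^2
    st <- list(
      lattice = ini$lattice, cells = ini$cells, state = ini$state,
      net = ini$net, vois = ini$vois, streams = streams, day = 0,
      load_scale = ct_ar0 / config$mechanics$reference_ct_ar,
      fe = list(E = NULL, ap = NULL, mech = NULL)
    )
  } else {
    st <- init
    if (!is.null(st$stream_states)) {
      st$streams <- restore_streams(st$stream_states)
      st$stream_states <- NULL
    }
  }

  n_macro <- as.integer(round(duration_days * 86400 / dt_fe))
  snap_every <- max(1L, as.integer(round(eng$snapshot_days * 86400 / dt_fe)))
  snapshots <- list()
  morpho <- list()
  timeline <- list()

  take_snapshot <- function(st, mech) {
    st$rddf <- NULL # cached factor: rebuilt on demand, never serialised
    list(
      time_days = st$day, lattice = st$lattice, cells = st$cells,
      state = st$state, net = st$net, vois = st$vois,
      k_c = if (is.null(mech)) NA_real_ else mech$k_c,
      stream_states = stream_states(st$streams),
      version = 1L
    )
  }

  snapshots[[1]] <- take_snapshot(st, NULL)
  morpho[[1]] <- bv_multithreshold(st$lattice, st$vois)

  macro0 <- as.integer(round(st$day * 86400 / dt_fe))
  for (macro in seq_len(n_macro)) {
    # (i) mechanics — re-solved only when the modulus field changed
    E_now <- density_to_modulus(st$lattice$mineral, config$mechanics)
    if (is.null(st$fe$E) || !identical(E_now, st$fe$E)) {
      kc_warm <- if (is.null(st$fe$ap)) NULL else st$fe$ap$u
      ap <- apparent_stiffness(st$lattice, config,
        modulus = E_now,
        tol = config$mechanics$run_tol, warm_start = kc_warm
      )
      amb_warm <- if (is.null(st$fe$mech)) NULL else st$fe$mech$u_solver
      mech <- ambulatory_load(st$lattice, config,
        k_c = ap$k_c, modulus = E_now,
        tol = config$mechanics$run_tol, warm_start = amb_warm,
        force_scale = if (is.null(st$load_scale)) 1 else st$load_scale
      )
      st$fe <- list(E = E_now, ap = ap, mech = mech)
    }
    ap <- st$fe$ap
    mech <- st$fe$mech
    sed <- mech$sed
    eff <- mech$eff

    ledger <- c(
      births = 0L, deaths = 0L, resorbed = 0L, deposits = 0L,
      tip_moves = 0L, branches = 0L, anastomoses = 0L
    )
    flows_total <- NULL

    for (k in seq_len(n_cell_steps)) {
      # (iii) vasculature on the cell clock
      st <- local({
        s <- st
        with_stream(s$streams, "vessels", {
          ext <- extend_tips(s$cells, s$lattice, s$net, s$state$conc$VEGF, config)
          br <- branch_vessels(ext$cells, ext$lattice, ext$net,
            s$state$conc$VEGF, config)
          s$cells <- br$cells; s$lattice <- br$lattice; s$net <- br$net
          ledger["tip_moves"] <<- ledger["tip_moves"] + ext$n_moved
          ledger["anastomoses"] <<- ledger["anastomoses"] + ext$n_anastomosed
          ledger["branches"] <<- ledger["branches"] + br$n_branched
        })
        s
      })

      # (iv) cell behaviour
      st <- local({
        s <- st
        with_stream(s$streams, "agents", {
          mg <- migrate_cells(s$cells, s$lattice, s$state$conc$RANKL, eff, config)
          s$cells <- mg$cells; s$lattice <- mg$lattice
          df <- differentiate_cells(s$cells, s$lattice, sed, eff, config)
          s$cells <- df$cells; s$lattice <- df$lattice
          flows_total <<- if (is.null(flows_total)) df$flows else flows_total + df$flows
          pd <- proliferate_or_die(s$cells, s$lattice, sed, eff, config, dt_cells_h)
          s$cells <- pd$cells; s$lattice <- pd$lattice
          ledger["births"] <<- ledger["births"] + pd$births
          ledger["deaths"] <<- ledger["deaths"] + pd$deaths
          dp <- deposit_osteoid(s$cells, s$lattice, eff, config)
          s$lattice <- dp$lattice
          ledger["deposits"] <<- ledger["deposits"] + dp$n_deposits
          rs <- resorb(s$cells, s$lattice, sed, s$state, config)
          s$cells <- rs$cells; s$lattice <- rs$lattice; s$state <- rs$state
          ledger["resorbed"] <<- ledger["resorbed"] + rs$n_resorbed
          ledger["deaths"] <<- ledger["deaths"] + rs$ocy_killed
        })
        s$cells$age_h <- s$cells$age_h + dt_cells_h
        emb <- !is.na(s$cells$embed_h)
        s$cells$embed_h[emb] <- s$cells$embed_h[emb] + dt_cells_h
        s
      })

      # (ii) reaction-diffusion-decay on its own clock
      if (k %in% sched) {
        if (is.null(st$rddf) ||
          !identical(st$rddf$fingerprint, as.numeric(st$state$D$cytokine))) {
          st$rddf <- btcs_factor(st$state)
        }
        o2src <- oxygen_sources(st$lattice, config$seeding$o2_background)
        o2sink <- o2_sink_map(st$lattice, config)
        for (sp in st$state$species$name) {
          if (sp == "O2") {
            st$state <- step_diffusion_decay(st$state, sp,
              extra_dirichlet = o2src, extra_sink = o2sink,
              tol = config$species$rdd_tol, maxit = config$species$rdd_maxit
            )
          } else {
            st$state <- step_diffusion_decay_factored(st$state, sp, st$rddf)
          }
        }
        rc <- react(st$state, st$cells, st$state$dt, config)
        st$state <- rc$state
        st$cells <- rc$cells
        vi <- cell_voxels(st$cells, st$lattice$dims)
        rates <- produce_cytokines(st$cells, sed[vi], eff[vi],
          st$state$conc$O2[vi], config)
        sc <- secrete_and_consume(st$state, st$cells, rates, st$state$dt, config)
        st$state <- sc$state
        st$cells <- sc$cells
      }
    }

    # (v) mineralisation, then refresh diffusivities for the next macro-step
    st$lattice <- mineralise(st$lattice, dt_fe / 86400,
      tgfb_bank = config$production$tgfb_bank
    )
    st$state <- update_diffusivity(st$state, st$lattice$mineral)
    st$day <- st$day + dt_fe / 86400

    counts <- tabulate(st$cells$type, nbins = length(CELL_TYPES))
    names(counts) <- names(CELL_TYPES)
    timeline[[macro]] <- c(
      list(day = st$day, k_c = ap$k_c, fe_iters = mech$iters),
      as.list(counts), as.list(ledger),
      as.list(if (is.null(flows_total)) integer(0) else flows_total),
      list(
        bone_mass = sum(st$lattice$mineral),
        osteoid_mass = sum(st$lattice$osteoid)
      )
    )
    if (progress) {
      message(sprintf(
        "day %5.2f | k_c %8.3g N/mm | cells %6d | bone %10.0f",
        st$day, ap$k_c, nrow(st$cells), sum(st$lattice$mineral)
      ))
    }
    if ((macro0 + macro) %% snap_every == 0L) {
      snapshots[[length(snapshots) + 1]] <- take_snapshot(st, mech)
      morpho[[length(morpho) + 1]] <- bv_multithreshold(st$lattice, st$vois)
    }
  }

  timeline <- if (length(timeline)) {
    do.call(rbind, lapply(timeline, function(r) as.data.frame(r)))
  } else {
    data.frame()
  }
  structure(
    list(
      snapshots = snapshots, timeline = timeline, morphometry = morpho,
      final_state = st, vois = st$vois, config = config
    ),
    class = "bone_sim"
  )
}

#' @export
print.bone_sim <- function(x, ...) {
  days <- vapply(x$snapshots, `[[`, numeric(1), "time_days")
  cat("<bone_sim> ", length(x$snapshots), " snapshots (day ",
    paste(range(days), collapse = " to "), ")\n",
    sep = ""
  )
  if (nrow(x$timeline)) {
    last <- x$timeline[nrow(x$timeline), ]
    cat(sprintf(
      "  final: k_c = %.4g N/mm, %d agents, bone mass %.0f\n",
      last$k_c, sum(unlist(last[names(CELL_TYPES)])), last$bone_mass
    ))
  }
  invisible(x)
}

#' @export
summary.bone_sim <- function(object, ...) {
  days <- vapply(object$snapshots, `[[`, numeric(1), "time_days")
  bvtv <- vapply(object$morphometry, function(m) {
    m$bv_tv[m$threshold == MINERAL_THRESHOLD & m$voi == "DC"]
  }, numeric(1))
  gw <- vapply(object$snapshots, function(s) {
    gap_width(s$lattice)$median_mm
  }, numeric(1))
  out <- data.frame(day = days, bvtv_dc = bvtv, gap_median_mm = gw)
  k <- vapply(object$snapshots, `[[`, numeric(1), "k_c")
  out$k_c <- k
  class(out) <- c("summary.bone_sim", class(out))
  out
}

#' @export
plot.bone_sim <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  tl <- x$timeline
  if (nrow(tl)) {
    plot(tl$day, tl$k_c,
      type = "l", xlab = "day", ylab = "apparent stiffness [N/mm]",
      main = "construct stiffness"
    )
    types <- c("SSPC", "OBL", "OCY", "OCL")
    cols <- c("grey40", "orange3", "steelblue4", "firebrick")
    matplot(tl$day, as.matrix(tl[, types]),
      type = "l", lty = 1, col = cols,
      xlab = "day", ylab = "cells", main = "populations"
    )
    legend("topleft", types, col = cols, lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Save / restore a snapshot
#'
#' Snapshots are fully self-contained (lattice, agents, fields, vessel
#' network, RNG stream states) so a restored run continues bit-identically.
#'
#' @param snapshot A snapshot from a [run_simulation()] result (or its
#'   `final_state`).
#' @param path File path.
#' @return `restore_snapshot` returns the state list, ready for the `init`
#'   argument of [run_simulation()].
#' @export
save_snapshot <- function(snapshot, path) {
  snapshot$rddf <- NULL
  if (!is.null(snapshot$streams)) {
    snapshot$stream_states <- stream_states(snapshot$streams)
    snapshot$streams <- NULL
  }
  snapshot$version <- 1L
  saveRDS(snapshot, path)
  invisible(path)
}

#' @rdname save_snapshot
#' @export
restore_snapshot <- function(path) {
  snap <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt or unreadable snapshot file: ", conditionMessage(e))
  })
  if (is.null(snap$version) || snap$version != 1L) {
    stop("snapshot version mismatch")
  }
  snap
}

#' In silico gap-size study
#'
#' Rigidly translates the distal cortical fragment along z in the given
#' offsets (multiples of the configured 0.15 mm step by default), producing
#' one geometry per offset; optionally runs the full simulation on each.
#'
#' @param lattice Base post-operative lattice.
#' @param offsets_um Numeric vector of z-translations (um; positive widens
#'   the gap). Rounded to whole voxels.
#' @param config A [sim_config()].
#' @param run Run the coupled simulation on each geometry (else geometries
#'   only).
#' @param ... Passed to [run_simulation()].
#' @return List with `geometries` (lattices) and, when `run = TRUE`, `runs`.
#' @export
gap_size_study <- function(lattice, offsets_um, config = sim_config(),
                           run = FALSE, ...) {
  dims <- lattice$dims
  bone <- lattice$mineral >= MINERAL_THRESHOLD
  per_slice <- apply(bone, 3, sum)
  zb <- which(per_slice > 0)
  gap <- which(per_slice == 0)
  gap <- gap[gap > min(zb) & gap < max(zb)]
  if (length(gap) == 0) stop("no identifiable gap to manipulate")
  z_dist0 <- (max(gap) + 1L):dims[3] # distal block incl. margin

  geoms <- lapply(offsets_um, function(off) {
    k <- as.integer(round(off / lattice$voxel_size))
    new <- lattice
    blk <- lattice$mineral[, , z_dist0, drop = FALSE]
    new$mineral[, , z_dist0] <- 0
    zt <- z_dist0 + k
    keep <- zt >= 1L & zt <= dims[3]
    if (k < 0 && (min(zt) <= max(setdiff(zb, z_dist0)))) {
      stop("fragments overlap after translation by ", off, " um")
    }
    new$mineral[, , zt[keep]] <- blk[, , keep, drop = FALSE]
    attr(new, "offset_um") <- off
    new
  })

  out <- list(geometries = geoms, offsets_um = offsets_um)
  if (run) {
    out$runs <- lapply(geoms, function(g) run_simulation(config, lattice = g, ...))
  }
  out
}
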
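# Shared internal helpers: named RNG streams, lattice indexing, the Gaussian
# signal filter, and a vectorised Gumbel-softmax sampler used by the
# polarisation rules.

# --- named RNG streams -------------------------------------------------------
# One master seed spawns independent named streams (init, agents, vessels, ...)
# so each module's stochastic behaviour is reproducible in isolation. A stream
# is the saved state of R's generator; with_stream() swaps it in, evaluates,
# and swaps it back out.

make_streams <- function(seed, names = c("init", "agents", "vessels", "misc")) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  subseeds <- sample.int(.Machine$integer.max - 1L, length(names))
  states <- new.env(parent = emptyenv())
  for (i in seq_along(names)) {
    set.seed(subseeds[i])
    assign(names[i], get(".Random.seed", globalenv()), envir = states)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  states
}

with_stream <- function(streams, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  res <- force(expr)
  assign(name, get(".Random.seed", globalenv()), envir = streams)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  res
}

stream_states <- function(streams) {
  nm <- ls(streams)
  stats::setNames(lapply(nm, function(n) get(n, envir = streams)), nm)
}

restore_streams <- function(states) {
  env <- new.env(parent = emptyenv())
  for (n in names(states)) assign(n, states[[n]], envir = env)
  env
}

# --- lattice indexing --------------------------------------------------------

# 0-based voxel coordinates -> 1-based linear index into a dims[1:3] array
vox_index <- function(x, y, z, dims) {
  1L + x + dims[1] * (y + dims[2] * z)
}

index_vox <- function(i, dims) {
  i0 <- i - 1L
  cbind(
    x = i0 %% dims[1],
    y = (i0 %/% dims[1]) %% dims[2],
    z = i0 %/% (dims[1] * dims[2])
  )
}

# linear indices of the 6 face neighbours; 0 marks out-of-domain
face_neighbours <- function(i, dims) {
  co <- index_vox(i, dims)
  offs <- rbind(
    c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
    c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L)
  )
  out <- matrix(0L, length(i), 6)
  for (d in 1:6) {
    x <- co[, 1] + offs[d, 1]; y <- co[, 2] + offs[d, 2]; z <- co[, 3] + offs[d, 3]
    ok <- x >= 0L & x < dims[1] & y >= 0L & y < dims[2] & z >= 0L & z < dims[3]
    idx <- vox_index(x, y, z, dims)
    idx[!ok] <- 0L
    out[, d] <- idx
  }
  out
}

# --- Gaussian signal regularisation -----------------------------------------

# Separable truncated-Gaussian smoothing of a 3D field, the regularisation
# applied to SED/EFF to mitigate partial-volume effects. `sigma` is in voxels;
# `support` is the truncation parameter: the kernel is cut at
# radius ceiling(support/sigma) voxels (default sigma 1.0, support 0.8 ->
# radius 1, a 3-tap kernel per axis). At the domain faces the kernel is
# renormalised over its in-domain taps, so constant fields are invariant
# under smoothing; fields vanishing within the kernel radius of the faces
# keep their total mass exactly.
gaussian_filter3 <- function(a, sigma = 1.0, support = 0.8) {
  r <- max(1L, as.integer(ceiling(support / sigma)))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  d <- dim(a)
  conv_axis <- function(a, axis) {
    out <- array(0, d)
    for (j in -r:r) {
      w <- k[j + r + 1]
      src <- pmin(pmax(seq_len(d[axis]) + j, 1L), .Machine$integer.max)
      keep <- src >= 1L & src <= d[axis]
      dst <- seq_len(d[axis])[keep]
      src <- src[keep]
      if (axis == 1) out[dst, , ] <- out[dst, , ] + w * a[src, , ]
      else if (axis == 2) out[, dst, ] <- out[, dst, ] + w * a[, src, ]
      else out[, , dst] <- out[, , dst] + w * a[, , src]
    }
    out
  }
  out <- conv_axis(conv_axis(conv_axis(a, 1), 2), 3)
  norm <- conv_axis(conv_axis(conv_axis(array(1, d), 1), 2), 3)
  out / norm
}

# --- Gumbel-softmax choice ---------------------------------------------------

# Vectorised sample from softmax(beta * score) rows via the Gumbel-argmax
# trick; score is an n x k matrix, NA marks inadmissible options. Returns the
# chosen column (NA when a row has no admissible option). Consumes n*k
# uniforms from the current RNG stream.
softmax_pick <- function(score, beta) {
  n <- nrow(score); k <- ncol(score)
  if (n == 0) return(integer(0))
  g <- -log(-log(matrix(runif(n * k), n, k)))
  val <- beta * score + g
  val[is.na(score)] <- -Inf
  pick <- max.col(val, ties.method = "first")
  pick[!is.finite(val[cbind(seq_len(n), pick)])] <- NA_integer_
  pick
}
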
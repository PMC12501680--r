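# Internal helpers: b0 detection, seeded evaluation, 3D morphology.

# b0 = diffusion weighting below 50 s/mm^2; vendor files sometimes store
# small nonzero values for the unweighted volume.
isB0 <- function(bvals) bvals < 50

# Evaluate expr under a temporary RNG seed, restoring the caller's state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed for a (stream, counter) pair, kept inside 32-bit
# signed range so parallel / reordered execution reproduces the same draws.
subSeed <- function(seed, stream, counter) {
  as.integer((as.numeric(seed) * 48271 + stream * 69621 + counter * 16807) %%
               2147483562) + 1L
}

# Shift a 3D logical array by one voxel along an axis, padding with FALSE.
shiftLogical3 <- function(a, axis, by) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- lapply(d, seq_len)
  if (by == 1L) {
    src[[axis]] <- seq_len(d[axis] - 1L)
    dst[[axis]] <- 2:d[axis]
  } else {
    src[[axis]] <- 2:d[axis]
    dst[[axis]] <- seq_len(d[axis] - 1L)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

shiftNumeric3 <- function(a, axis, by) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- lapply(d, seq_len)
  if (by == 1L) {
    src[[axis]] <- seq_len(d[axis] - 1L)
    dst[[axis]] <- 2:d[axis]
  } else {
    src[[axis]] <- 2:d[axis]
    dst[[axis]] <- seq_len(d[axis] - 1L)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 6-connected flood fill from a set of seed voxels, restricted to `domain`.
# Vectorized label-free propagation: grow the frontier by one voxel per
# iteration along each axis until it stops changing.
floodFill3 <- function(seeds, domain) {
  cur <- seeds & domain
  repeat {
    grown <- cur
    for (axis in 1:3) {
      grown <- grown | shiftLogical3(cur, axis, 1L) |
        shiftLogical3(cur, axis, -1L)
    }
    grown <- grown & domain
    if (sum(grown) == sum(cur)) return(cur)
    cur <- grown
  }
}

# Largest 6-connected component of a 3D logical array.
largestComponent3 <- function(mask) {
  remaining <- mask
  best <- NULL
  bestSize <- 0L
  total <- sum(remaining)
  while (any(remaining)) {
    seedIdx <- which(remaining)[1]
    seed <- array(FALSE, dim(mask))
    seed[seedIdx] <- TRUE
    comp <- floodFill3(seed, remaining)
    sz <- sum(comp)
    if (sz > bestSize) {
      best <- comp
      bestSize <- sz
    }
    remaining <- remaining & !comp
    # once the biggest found exceeds everything left, stop early
    if (bestSize >= sum(remaining)) break
  }
  best
}

# Fill interior holes: background voxels not 6-connected to the array border
# become foreground.
fillHoles3 <- function(mask) {
  d <- dim(mask)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  outside <- floodFill3(border, !mask)
  mask | (!mask & !outside)
}

# Circularly shift a matrix by integer amounts (dev/test fixture helper,
# also used by the ghost model for the half-FOV copy).
circShift2 <- function(m, s) {
  n <- dim(m)
  i <- ((seq_len(n[1]) - 1L - s[1]) %% n[1]) + 1L
  j <- ((seq_len(n[2]) - 1L - s[2]) %% n[2]) + 1L
  m[i, j, drop = FALSE]
}
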
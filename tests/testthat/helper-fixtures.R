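# Shared fixtures and independent oracles for the test suite.

# --- independent oracles -----------------------------------------------

# Textbook Pearson coefficient, no shortcuts.
pearsonOracle <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  sum((a - am) * (b - bm)) / sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# Brute-force correlation matrix: explicit double loop over column pairs.
corrOracle <- function(x) {
  nd <- ncol(x)
  C <- diag(nd)
  for (i in seq_len(nd)) {
    for (j in seq_len(nd)) {
      if (i != j) C[i, j] <- pearsonOracle(x[, i], x[, j])
    }
  }
  C
}

# Brute-force end-to-end DIM: pairwise Pearson loop + dense symmetric
# eigendecomposition, entirely separate from the package's
# standardize/crossprod path.
dimOracle <- function(x) {
  C <- corrOracle(x)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  1 - max(ev) / sum(ev)
}

# Independent eigen route via SVD of the standardized matrix: the singular
# values squared are the eigenvalues of C.
dimSvdOracle <- function(x) {
  xc <- sweep(x, 2, colMeans(x), "-")
  xs <- sweep(xc, 2, sqrt(colSums(xc^2)), "/")
  ev <- svd(xs, nu = 0, nv = 0)$d^2
  1 - max(ev) / sum(ev)
}

# Exactly equicorrelated correlation matrix.
equicorrMatrix <- function(nd, r) {
  C <- matrix(r, nd, nd)
  diag(C) <- 1
  C
}

# --- fixture builders --------------------------------------------------

# Random voxel matrix with correlated columns (shared signal + noise).
randomVoxelMatrix <- function(nv, nd, seed, rho = 0.9) {
  set.seed(seed)
  shared <- rnorm(nv)
  x <- sqrt(rho) * matrix(shared, nv, nd) +
    sqrt(1 - rho) * matrix(rnorm(nv * nd), nv, nd)
  x <- x * 10 + 100  # arbitrary intensity scale/offset
  new("VoxelMatrix", values = x, directionIds = seq_len(nd))
}

# Small HardiDataset straight from arrays.
makeDataset <- function(data, bvals = NULL, bvecs = NULL) {
  nv <- dim(data)[4]
  if (is.null(bvals)) bvals <- c(0, rep(1000, nv - 1))
  if (is.null(bvecs)) {
    bvecs <- cbind(c(0, 0, 0), hemisphereDirections(nv - 1))[, seq_len(nv)]
    if (bvals[1] != 0) bvecs <- hemisphereDirections(nv)
  }
  new("HardiDataset", data = data, affine = diag(4),
      bvals = bvals, bvecs = bvecs, volumeLabels = seq_len(nv))
}

# Standard small phantom configs; sphere radius 9 on a 32x32x22 grid spans
# more than half the phase-encode matrix, so ghosts fold onto the phantom.
smallConfig <- function(nDirections = 8L, ...) {
  simulationConfig(gridShape = c(32L, 32L, 22L), sphereRadius = 9,
                   nDirections = nDirections, ...)
}

# Circularly shift every slice of selected volumes of a dataset (integer
# shift injection for registration tests).
injectCircShift <- function(dataset, volumes, s) {
  data <- imgData(dataset)
  for (v in volumes) {
    for (z in seq_len(dim(data)[3])) {
      m <- data[, , z, v]
      n <- dim(m)
      i <- ((seq_len(n[1]) - 1L - s[1]) %% n[1]) + 1L
      j <- ((seq_len(n[2]) - 1L - s[2]) %% n[2]) + 1L
      data[, , z, v] <- m[i, j]
    }
  }
  makeDataset(data, bvals = bValues(dataset), bvecs = bVectors(dataset))
}

# Subpixel shift injection via a Fourier phase ramp, per slice.
injectPhaseRamp <- function(dataset, volumes, d) {
  data <- imgData(dataset)
  n <- dim(data)[1:2]
  k1 <- c(0:(n[1] %/% 2 - 1), -((n[1] - n[1] %/% 2):1))
  k2 <- c(0:(n[2] %/% 2 - 1), -((n[2] - n[2] %/% 2):1))
  ramp <- exp(-2i * pi * (outer(k1, rep(1, n[2])) * d[1] / n[1] +
                          outer(rep(1, n[1]), k2) * d[2] / n[2]))
  for (v in volumes) {
    for (z in seq_len(dim(data)[3])) {
      data[, , z, v] <- Re(fft(fft(data[, , z, v]) * ramp, inverse = TRUE)) /
        prod(n)
    }
  }
  makeDataset(data, bvals = bValues(dataset), bvecs = bVectors(dataset))
}

# Circularly shift a slice along its second (phase-encode) axis.
circShiftSlice <- function(m, s) {
  n <- ncol(m)
  j <- ((seq_len(n) - 1L - s) %% n) + 1L
  m[, j]
}

# Analytic voxel count of the partial-volume sphere profile at a threshold
# of half the base intensity (voxels with >= half coverage).
sphereVoxelCount <- function(gridShape, radius) {
  cx <- (gridShape + 1) / 2
  dx2 <- (seq_len(gridShape[1]) - cx[1])^2
  dy2 <- (seq_len(gridShape[2]) - cx[2])^2
  dz2 <- (seq_len(gridShape[3]) - cx[3])^2
  dist <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  sum(pmin(pmax(radius + 0.5 - dist, 0), 1) > 0.5)
}
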
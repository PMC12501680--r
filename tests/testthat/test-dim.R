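test_that("column standardization matches the closed form and is affine invariant", {
  x <- new("VoxelMatrix", values = cbind(c(1, 2, 3), c(4, 7, 1)),
           directionIds = 1:2)
  s <- standardizeColumns(x)
  expect_equal(values(s)[, 1], c(-1, 0, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(colMeans(values(s)), c(0, 0), tolerance = 1e-12)
  expect_equal(colSums(values(s)^2), c(1, 1), tolerance = 1e-12)
  # positive affine transform of a column leaves its standardized form alone
  x2 <- new("VoxelMatrix", values = cbind(x@values[, 1] * 5 + 7,
                                          x@values[, 2]),
            directionIds = 1:2)
  expect_equal(values(standardizeColumns(x2)), values(s), tolerance = 1e-12)
  # constant column is a hard error naming the direction
  x3 <- new("VoxelMatrix", values = cbind(c(4, 4, 4), c(1, 2, 3)),
            directionIds = c(7L, 8L))
  expect_error(standardizeColumns(x3), "direction 7.*zero variance")
})

test_that("correlation matrix agrees with the brute-force pairwise oracle", {
  set.seed(42)
  x <- matrix(rnorm(1000 * 8), 1000, 8)
  vm <- new("VoxelMatrix", values = x, directionIds = 1:8)
  C <- values(correlationMatrix(vm))
  expect_lt(max(abs(C - corrOracle(x))), 1e-12)
  # identical columns -> all-ones matrix
  same <- new("VoxelMatrix", values = matrix(rep(rnorm(50), 3), 50, 3),
              directionIds = 1:3)
  expect_equal(values(correlationMatrix(same)), matrix(1, 3, 3))
  # exactly orthogonal centered columns -> identity
  orth <- new("VoxelMatrix", values = cbind(c(1, -1, 1, -1), c(1, 1, -1, -1)),
              directionIds = 1:2)
  expect_equal(values(correlationMatrix(orth)), diag(2), tolerance = 1e-14)
})

test_that("DIM closed forms: rank-one, 2x2, and equicorrelated spectra", {
  # identical DWIs: rank-one C, DIM = 0
  ones <- new("CorrelationMatrix", values = matrix(1, 8, 8),
              directionIds = 1:8)
  expect_lt(dimRaw(dimStatistic(ones)), 1e-12)
  # N_d = 2: eigenvalues 1 +/- r, DIM = (1 - r)/2
  r <- 0.9
  c2 <- new("CorrelationMatrix", values = equicorrMatrix(2, r),
            directionIds = 1:2)
  res2 <- dimStatistic(c2)
  expect_equal(dimRaw(res2), (1 - r) / 2, tolerance = 1e-12)
  expect_equal(dimPpm(res2), 5e4, tolerance = 1e-9)
  # general equicorrelated: DIM = (N_d - 1)(1 - r)/N_d
  for (nd in c(3, 16)) {
    for (r in c(0.2, 0.95)) {
      cm <- new("CorrelationMatrix", values = equicorrMatrix(nd, r),
                directionIds = seq_len(nd))
      expect_equal(dimRaw(dimStatistic(cm)), (nd - 1) * (1 - r) / nd,
                   tolerance = 1e-12)
    }
  }
})

test_that("eigen spectrum is descending, PSD and traces to N_d", {
  vm <- randomVoxelMatrix(500, 16, seed = 3L)
  res <- dimOfMatrix(vm)
  ev <- eigenSpectrum(res)
  expect_false(is.unsorted(rev(ev)))
  expect_gt(min(ev), -1e-10)
  expect_equal(sum(ev), 16, tolerance = 1e-8)
  # independent eigensolver route (SVD of standardized X)
  expect_equal(dimRaw(res), dimSvdOracle(values(vm)), tolerance = 1e-12)
})

test_that("end-to-end DIM matches the brute-force pipeline on seeded instances", {
  for (seed in 1:10) {
    set.seed(seed)
    nv <- sample(100:2000, 1)
    nd <- sample(3:24, 1)
    vm <- randomVoxelMatrix(nv, nd, seed = seed + 100L,
                            rho = runif(1, 0.3, 0.99))
    expect_equal(dimRaw(dimOfMatrix(vm)), dimOracle(values(vm)),
                 tolerance = 1e-10)
  }
})

test_that("DIM is invariant to voxel order, direction order and affine rescaling", {
  for (seed in 1:6) {
    vm <- randomVoxelMatrix(400, 12, seed = seed)
    ref <- dimRaw(dimOfMatrix(vm))
    set.seed(seed + 500L)
    x <- values(vm)
    perm <- new("VoxelMatrix", values = x[sample(nrow(x)), sample(ncol(x))],
                directionIds = directionIds(vm))
    expect_equal(dimRaw(dimOfMatrix(perm)), ref, tolerance = 1e-10)
    gains <- runif(ncol(x), 0.1, 10)
    offs <- rnorm(ncol(x), 0, 50)
    aff <- new("VoxelMatrix",
               values = sweep(sweep(x, 2, gains, "*"), 2, offs, "+"),
               directionIds = directionIds(vm))
    expect_equal(dimRaw(dimOfMatrix(aff)), ref, tolerance = 1e-10)
  }
})

test_that("DIM stays within [0, 1 - 1/N_d] and nears the ceiling for pure noise", {
  for (seed in 1:5) {
    set.seed(seed)
    nd <- sample(3:32, 1)
    vm <- randomVoxelMatrix(300, nd, seed = seed, rho = runif(1))
    raw <- dimRaw(dimOfMatrix(vm))
    expect_gte(raw, 0)
    expect_lte(raw, 1 - 1 / nd + 1e-12)
  }
  # i.i.d. Gaussian columns: C ~ identity, DIM close to its ceiling, the
  # gap bounded by the largest-eigenvalue edge (1 + sqrt(N_d/N_v))^2
  set.seed(99)
  nv <- 2e4; nd <- 16
  noise <- new("VoxelMatrix", values = matrix(rnorm(nv * nd), nv, nd),
               directionIds = seq_len(nd))
  raw <- dimRaw(dimOfMatrix(noise))
  edge <- (1 + sqrt(nd / nv))^2
  expect_gte(raw, 1 - edge / nd - 0.002)
  expect_lte(raw, 1 - 1 / nd)
})

test_that("dataset-level DIM handles policies, b0 exclusion and corruption", {
  cfg <- smallConfig(snr = Inf)
  clean <- generatePhantom(cfg)
  expect_lt(dimPpm(dimFromDataset(clean)), 1e-3)
  expect_lt(dimPpm(dimFromDataset(clean, subsetPolicy = "exclude_first")),
            1e-3)
  # a heavily ghost-corrupted first direction inflates all-direction DIM
  bad <- generatePhantom(smallConfig(snr = 100, corruptDirections = 1L,
                                     corruptAmplitude = 0.5, seed = 4L))
  m <- makePhantomMask(bad)
  dAll <- dimPpm(dimFromDataset(bad, mask = m, subsetPolicy = "all"))
  dExcl <- dimPpm(dimFromDataset(bad, mask = m,
                                 subsetPolicy = "exclude_first"))
  expect_lt(dExcl, dAll)
  # on an instability-free scan, first- vs last-exclusion are equivalent
  noisy <- generatePhantom(smallConfig(snr = 50, seed = 6L))
  mn <- makePhantomMask(noisy)
  dF <- dimPpm(dimFromDataset(noisy, mask = mn, subsetPolicy = "exclude_first"))
  dL <- dimPpm(dimFromDataset(noisy, mask = mn, subsetPolicy = "exclude_last"))
  expect_lt(abs(dF - dL) / dL, 0.10)
  # custom subsets and degenerate sizes
  dCustom <- dimFromDataset(noisy, mask = mn, subsetPolicy = "custom",
                            directions = c(2L, 4L, 6L))
  expect_equal(directionIds(dCustom), c(2L, 4L, 6L))
  expect_error(dimFromDataset(noisy, mask = mn, subsetPolicy = "custom",
                              directions = 2L), "fewer than 2")
  # b0 stays out unless asked for
  expect_equal(length(eigenSpectrum(dimFromDataset(noisy, mask = mn))), 8)
  expect_equal(length(eigenSpectrum(
    dimFromDataset(noisy, mask = mn, includeB0 = TRUE))), 9)
})
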
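test_that("noiseless zero-diffusivity phantoms have DWIs identical to b0", {
  ds <- generatePhantom(smallConfig(snr = Inf, diffusivity = 0))
  b0 <- imgData(ds)[, , , 1]
  for (v in 2:nVolumes(ds)) {
    expect_identical(imgData(ds)[, , , v], b0)
  }
})

test_that("noiseless attenuation follows exp(-b D) exactly", {
  cfg <- smallConfig(snr = Inf, diffusivity = 1e-5, bValue = 10000)
  ds <- generatePhantom(cfg)
  b0 <- imgData(ds)[, , , 1]
  inside <- b0 == 1000
  expect_true(any(inside))
  for (v in c(2, 5, 9)) {
    expect_equal(unique(imgData(ds)[, , , v][inside]), 1000 * exp(-0.1),
                 tolerance = 1e-12)
  }
})

test_that("configured SNR matches the empirical noise level", {
  cfg <- smallConfig(snr = 100, diffusivity = 0, seed = 12L)
  ds <- generatePhantom(cfg)
  b0 <- imgData(generatePhantom(smallConfig(snr = Inf, diffusivity = 0)))
  core <- b0[, , , 1] == 1000
  # per-voxel SD across directions, averaged over interior voxels
  stack <- apply(imgData(ds)[, , , 2:9], 4, function(v) v[core])
  sds <- apply(stack, 1, sd)
  expect_lt(abs(mean(sds) - 10) / 10, 0.1)
})

test_that("identical config and seed reproduce the dataset bitwise", {
  c1 <- smallConfig(snr = 50, seed = 21L, ghostAmplitudes = 0.01,
                    driftPerVolume = 1e-4)
  expect_identical(imgData(generatePhantom(c1)), imgData(generatePhantom(c1)))
  c2 <- smallConfig(snr = 50, seed = 22L, ghostAmplitudes = 0.01,
                    driftPerVolume = 1e-4)
  expect_false(identical(imgData(generatePhantom(c1)),
                         imgData(generatePhantom(c2))))
})

test_that("intensity drift compounds multiplicatively per volume", {
  cfg <- smallConfig(snr = Inf, diffusivity = 0, driftPerVolume = 0.01)
  ds <- generatePhantom(cfg)
  b0 <- imgData(ds)[, , , 1]
  inside <- b0 == 1000
  for (i in c(1, 4, 8)) {
    expect_equal(unique(imgData(ds)[, , , i + 1][inside]),
                 1000 * 1.01^i, tolerance = 1e-12)
  }
})

test_that("the half-FOV ghost adds a displaced copy of each slice", {
  amp <- rep(0, 8); amp[3] <- 0.1
  cfg <- smallConfig(snr = Inf, diffusivity = 0, ghostAmplitudes = amp)
  ds <- generatePhantom(cfg)
  clean <- imgData(ds)[, , , 2]   # unghosted direction
  ghosted <- imgData(ds)[, , , 4] # direction 3
  z <- 11
  expected <- clean[, , z] + 0.1 * circShiftSlice(clean[, , z], 16L)
  expect_equal(ghosted[, , z], expected, tolerance = 1e-12)
})

test_that("changing ghosts raise DIM more than a constant ghost", {
  hits <- 0L
  for (seed in 1:5) {
    alt <- generatePhantom(smallConfig(snr = 100, seed = seed,
                                       ghostAmplitudes = rep(c(0, 0.02), 4)))
    con <- generatePhantom(smallConfig(snr = 100, seed = seed,
                                       ghostAmplitudes = rep(0.02, 8)))
    m <- makePhantomMask(con)
    hits <- hits + (dimPpm(dimFromDataset(alt, mask = m)) >
                      dimPpm(dimFromDataset(con, mask = m)))
  }
  expect_equal(hits, 5L)
})

test_that("rician noise keeps signals nonnegative at matched scale", {
  cfg <- smallConfig(snr = 20, seed = 2L, noiseModel = "rician")
  ds <- generatePhantom(cfg)
  expect_true(all(imgData(ds) >= 0))
})

test_that("hemisphere directions are unit length, apex-first, upper-half", {
  v <- hemisphereDirections(64)
  expect_equal(sqrt(colSums(v^2)), rep(1, 64), tolerance = 1e-12)
  expect_equal(v[, 1], c(0, 0, 1))
  expect_true(all(v[3, ] >= 0))
  # crude uniformity: mean pairwise angle well away from clustering
  expect_gt(mean(v[3, ]), 0.3)
  expect_lt(mean(v[3, ]), 0.7)
})

test_that("study grid reproduces the expected orderings", {
  tab <- runSnrStudy(bValues = 10000, diffusivities = c(0, 1e-5),
                     snrs = c(100, 20), nDirections = 8L,
                     gridShape = c(32L, 32L, 22L), sphereRadius = 9,
                     seed = 5L)
  expect_equal(nrow(tab), 4L)
  expect_true(all(tab$dim_ppm >= 0))
  # lower SNR -> higher DIM at both D
  for (d in c(0, 1e-5)) {
    sub <- tab[tab$diffusivity == d, ]
    expect_gt(sub$dim_ppm[sub$snr == 20], sub$dim_ppm[sub$snr == 100])
  }
  # higher D -> attenuation -> higher noise-dominated DIM (paired noise)
  for (s in c(100, 20)) {
    sub <- tab[tab$snr == s, ]
    expect_gte(sub$dim_ppm[sub$diffusivity == 1e-5],
               sub$dim_ppm[sub$diffusivity == 0])
  }
})

test_that("noiseless single study cell sits at the numerical floor", {
  tab <- runSnrStudy(bValues = 1000, diffusivities = 0, snrs = Inf,
                     nDirections = 4L, gridShape = c(32L, 32L, 22L),
                     sphereRadius = 9, seed = 1L)
  expect_lt(tab$dim_ppm, 1e-3)
})
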
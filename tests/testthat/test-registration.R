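test_that("self-registration yields exactly zero shifts", {
  ds <- generatePhantom(smallConfig(snr = Inf))
  sh <- suppressWarnings(estimateShifts(ds))  # edge slices carry no phantom
  expect_true(all(shiftArray(sh) == 0))
  # and applying a zero field returns the input bitwise
  expect_identical(imgData(applyShifts(ds, sh)), imgData(ds))
})

test_that("integer circular shifts are recovered exactly", {
  ds <- generatePhantom(smallConfig(snr = Inf, nDirections = 3L))
  shifted <- injectCircShift(ds, volumes = 3L, s = c(2L, 0L))
  sh <- suppressWarnings(estimateShifts(shifted))
  midSlices <- 5:18  # slices where the phantom has support
  expect_equal(max(abs(shiftArray(sh)[3, midSlices, 1] - 2)), 0,
               tolerance = 1e-9)
  expect_equal(max(abs(shiftArray(sh)[3, midSlices, 2])), 0,
               tolerance = 1e-9)
})

test_that("half-voxel phase-ramp shifts are recovered within 0.1 voxel", {
  ds <- generatePhantom(smallConfig(snr = Inf, nDirections = 3L))
  shifted <- injectPhaseRamp(ds, volumes = 4L, d = c(0.5, 0))
  sh <- suppressWarnings(estimateShifts(shifted))
  midSlices <- 5:18
  expect_lt(max(abs(shiftArray(sh)[4, midSlices, 1] - 0.5)), 0.1)
  expect_lt(max(abs(shiftArray(sh)[4, midSlices, 2])), 0.1)
})

test_that("estimate-then-apply undoes an injected shift inside the phantom", {
  ds <- generatePhantom(smallConfig(snr = Inf, nDirections = 3L,
                                    diffusivity = 0))
  shifted <- injectCircShift(ds, volumes = c(2L, 3L, 4L), s = c(2L, 1L))
  reg <- applyShifts(shifted, suppressWarnings(estimateShifts(shifted)))
  m <- maskArray(makePhantomMask(ds))
  ref <- imgData(ds)[, , , 1]
  before <- after <- 0
  for (v in 2:4) {
    before <- max(before, max(abs((imgData(shifted)[, , , v] - ref))[m]))
    after <- max(after, max(abs((imgData(reg)[, , , v] - ref))[m]))
  }
  expect_gt(before, 100)          # injected misalignment is gross
  expect_lt(after, 1e-6)          # exact inversion for integer shifts
})

test_that("all-zero volumes and slices register to zero shift", {
  ds <- generatePhantom(smallConfig(snr = Inf, nDirections = 3L))
  data <- imgData(ds)
  data[, , , 4] <- 0
  dz <- makeDataset(data, bValues(ds), bVectors(ds))
  expect_warning(sh <- estimateShifts(dz), "all-zero slice")
  expect_true(all(shiftArray(sh)[4, , ] == 0))
  reg <- applyShifts(dz, sh)
  expect_true(all(imgData(reg)[, , , 4] == 0))
})

test_that("shift magnitudes are capped at maxShift", {
  ds <- generatePhantom(smallConfig(snr = Inf, nDirections = 3L))
  shifted <- injectCircShift(ds, volumes = 3L, s = c(8L, 0L))
  sh <- suppressWarnings(estimateShifts(shifted, maxShift = 5))
  expect_lte(max(abs(shiftArray(sh))), 5)
})

test_that("registration lowers DIM on drifting data, leaves aligned data alone", {
  # positional drift + noise: registered DIM below unregistered DIM
  lower <- 0L
  for (seed in 1:5) {
    ds <- generatePhantom(smallConfig(snr = 100, shiftPerVolume = 0.3,
                                      seed = seed))
    un <- dimPpm(dimFromDataset(ds, register = FALSE))
    rg <- suppressWarnings(dimPpm(dimFromDataset(ds, register = TRUE)))
    lower <- lower + (rg <= un)
  }
  expect_gte(lower, 4L)
  # already-aligned noiseless data: registration changes DIM by < 1 ppm
  clean <- generatePhantom(smallConfig(snr = Inf))
  d0 <- dimPpm(dimFromDataset(clean, register = FALSE))
  d1 <- suppressWarnings(dimPpm(dimFromDataset(clean, register = TRUE)))
  expect_lt(abs(d1 - d0), 1)
})

test_that("shift tables export one row per (volume, slice)", {
  ds <- generatePhantom(smallConfig(snr = Inf, nDirections = 2L))
  tab <- shiftTable(suppressWarnings(estimateShifts(ds)))
  expect_equal(nrow(tab), 3 * 22)
  expect_named(tab, c("volume", "slice", "dx", "dy"))
})
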
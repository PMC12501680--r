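# Slice-wise, translation-only registration of every volume to a reference
# volume, as applied before computing DIM. Estimation is 2D phase
# correlation (normalized cross-power spectrum) with matrix-multiply
# upsampled DFT refinement around the integer peak; resampling is bilinear
# with zero fill outside the field of view.

# fft-layout wavenumbers 0, 1, ..., -n/2, ..., -1
fftFreq <- function(n) {
  half <- floor(n / 2)
  c(0:(n - half - 1L), -(half:1))
}

# Estimate the (dx, dy) translating `ref` onto `mov` (mov ~ ref shifted by
# +d). Returns c(0, 0) when either slice carries no signal.
phaseCorrelate2 <- function(ref, mov, maxShift = 5, upsample = 20L) {
  if (all(ref == 0) || all(mov == 0)) return(c(0, 0))
  n <- dim(ref)
  R <- Conj(stats::fft(ref)) * stats::fft(mov)
  mag <- Mod(R)
  Rn <- R / pmax(mag, .Machine$double.eps * max(mag))
  cc <- Re(stats::fft(Rn, inverse = TRUE))
  k1 <- fftFreq(n[1])
  k2 <- fftFreq(n[2])
  # cap the integer search at maxShift to reject pathological matches
  ok1 <- abs(k1) <= maxShift
  ok2 <- abs(k2) <= maxShift
  ccw <- cc[ok1, ok2, drop = FALSE]
  pk <- which(ccw == max(ccw), arr.ind = TRUE)[1, ]
  d0 <- c(k1[ok1][pk[1]], k2[ok2][pk[2]])
  # subpixel refinement: evaluate the correlation surface on a 1/upsample
  # grid spanning +-1 voxel around the integer peak
  u1 <- d0[1] + seq(-1, 1, by = 1 / upsample)
  u2 <- d0[2] + seq(-1, 1, by = 1 / upsample)
  E1 <- exp(2i * pi * outer(u1, k1) / n[1])
  E2 <- exp(2i * pi * outer(u2, k2) / n[2])
  fine <- Re(E1 %*% Rn %*% t(E2))
  pkf <- which(fine == max(fine), arr.ind = TRUE)[1, ]
  d <- c(u1[pkf[1]], u2[pkf[2]])
  pmax(pmin(d, maxShift), -maxShift)
}

#' Estimate slice-wise in-plane shifts against a reference volume
#'
#' For every volume and every axial slice (third spatial axis),
#' estimates the in-plane translation (dx, dy) that best aligns the slice
#' with the corresponding slice of the reference volume, by phase
#' correlation with subpixel refinement. Shifts are capped at
#' \code{maxShift} voxels; all-zero reference slices yield (0, 0) with a
#' warning.
#'
#' @param dataset a \linkS4class{HardiDataset}.
#' @param referenceVolume index of the reference (default 1, the first EPI
#'   volume).
#' @param maxShift cap on |dx|, |dy| in voxels.
#' @param upsample subpixel refinement factor (shift resolution
#'   1/upsample voxel).
#' @return a \linkS4class{ShiftField}.
#' @export
estimateShifts <- function(dataset, referenceVolume = 1L, maxShift = 5,
                           upsample = 20L) {
  d <- dim(dataset@data)
  nvol <- d[4]
  nslice <- d[3]
  if (nvol < 2L) stop("need at least 2 volumes to register")
  if (referenceVolume < 1L || referenceVolume > nvol) {
    stop("referenceVolume out of range")
  }
  shifts <- array(0, c(nvol, nslice, 2L))
  zeroRef <- logical(nslice)
  for (z in seq_len(nslice)) {
    ref <- dataset@data[, , z, referenceVolume]
    if (all(ref == 0)) {
      zeroRef[z] <- TRUE
      next
    }
    for (v in seq_len(nvol)) {
      if (v == referenceVolume) next
      shifts[v, z, ] <- phaseCorrelate2(ref, dataset@data[, , z, v],
                                        maxShift = maxShift,
                                        upsample = upsample)
    }
  }
  if (any(zeroRef)) {
    warning(sprintf("reference volume has %d all-zero slice(s); their shifts are (0,0)",
                    sum(zeroRef)))
  }
  new("ShiftField", shifts = shifts,
      referenceVolume = as.integer(referenceVolume))
}

# Bilinear resampling of a 2D slice at (x + dx, y + dy); samples falling
# outside the slice are 0.
translateSlice <- function(slice, dx, dy) {
  n <- dim(slice)
  xs <- seq_len(n[1]) + dx
  ys <- seq_len(n[2]) + dy
  x0 <- floor(xs); fx <- xs - x0
  y0 <- floor(ys); fy <- ys - y0
  padded <- matrix(0, n[1] + 2L, n[2] + 2L)
  padded[2:(n[1] + 1L), 2:(n[2] + 1L)] <- slice
  # clamp into the padded frame; anything beyond one voxel outside is zero
  cl <- function(i, n) pmin(pmax(i, 0L), n + 1L)
  i0 <- cl(x0, n[1]) + 1L; i1 <- cl(x0 + 1L, n[1]) + 1L
  j0 <- cl(y0, n[2]) + 1L; j1 <- cl(y0 + 1L, n[2]) + 1L
  w00 <- outer(1 - fx, 1 - fy)
  w10 <- outer(fx, 1 - fy)
  w01 <- outer(1 - fx, fy)
  w11 <- outer(fx, fy)
  padded[i0, j0] * w00 + padded[i1, j0] * w10 +
    padded[i0, j1] * w01 + padded[i1, j1] * w11
}

#' Resample a dataset onto its reference by undoing estimated shifts
#'
#' Each slice of each non-reference volume is translated by the negated
#' estimated shift, with bilinear interpolation and zero fill outside the
#' field of view. Slices with an exactly zero shift - including the whole
#' reference volume - are returned bitwise unchanged.
#'
#' @param dataset a \linkS4class{HardiDataset}.
#' @param shifts a \linkS4class{ShiftField} from \code{\link{estimateShifts}}.
#' @return a registered \linkS4class{HardiDataset}.
#' @export
applyShifts <- function(dataset, shifts) {
  d <- dim(dataset@data)
  sd3 <- dim(shifts@shifts)
  if (sd3[1] != d[4] || sd3[2] != d[3]) {
    stop("ShiftField does not match the dataset's volume/slice counts")
  }
  out <- dataset@data
  for (v in seq_len(d[4])) {
    if (v == shifts@referenceVolume) next
    for (z in seq_len(d[3])) {
      dx <- shifts@shifts[v, z, 1]
      dy <- shifts@shifts[v, z, 2]
      if (dx == 0 && dy == 0) next
      out[, , z, v] <- translateSlice(dataset@data[, , z, v], dx, dy)
    }
  }
  new("HardiDataset", data = out, affine = dataset@affine,
      bvals = dataset@bvals, bvecs = dataset@bvecs,
      volumeLabels = dataset@volumeLabels)
}

#' Export a shift field as a tidy table
#'
#' @param shifts a \linkS4class{ShiftField}.
#' @return data.frame with columns volume, slice, dx, dy (1-based indices).
#' @export
shiftTable <- function(shifts) {
  d <- dim(shifts@shifts)
  data.frame(
    volume = rep(seq_len(d[1]), times = d[2]),
    slice = rep(seq_len(d[2]), each = d[1]),
    dx = as.vector(shifts@shifts[, , 1]),
    dy = as.vector(shifts@shifts[, , 2])
  )
}
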
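#' Apparent diffusivity from the central ROI
#'
#' Sanity-checks the phantom's diffusivity inside a cubic region of interest
#' (default 11 x 11 x 11 voxels) centered at the mask centroid: for each
#' non-b0 direction i, D_i = -(1/b) * ln(Sbar_i / Sbar_0), where Sbar_0 is
#' the mean b0 intensity over the ROI (multiple b0 volumes are averaged
#' first) and Sbar_i the mean intensity of direction i. For a silicone-oil
#' phantom the expected mean D is on the order of 1e-6 mm^2/s.
#'
#' The ratio is scale-invariant, so global intensity calibration does not
#' affect the estimate. The log amplifies noise at low SNR; the ROI mean
#' over ~1300 voxels keeps that in check.
#'
#' @param dataset a \linkS4class{HardiDataset} with at least one b0 volume.
#' @param mask a \linkS4class{PhantomMask}; built automatically when NULL.
#' @param roiEdge odd cube edge in voxels (default 11).
#' @return a \linkS4class{DiffusivityEstimate}.
#' @export
estimateDiffusivity <- function(dataset, mask = NULL, roiEdge = 11L) {
  roiEdge <- as.integer(roiEdge)
  if (roiEdge < 1L || roiEdge %% 2L == 0L) stop("roiEdge must be odd and >= 1")
  if (is.null(mask)) mask <- makePhantomMask(dataset)
  b0idx <- which(isB0(dataset@bvals))
  if (!length(b0idx)) stop("dataset has no b0 volume (b < 50 s/mm^2)")
  dwidx <- setdiff(seq_len(dim(dataset@data)[4]), b0idx)
  if (!length(dwidx)) stop("dataset has no diffusion-weighted volumes")
  bset <- unique(dataset@bvals[dwidx])
  if (length(bset) > 1L) {
    stop("multiple nonzero b-values present; estimate per shell instead")
  }
  b <- bset[1]

  idx <- which(mask@mask, arr.ind = TRUE)
  center <- as.integer(round(colMeans(idx)))
  half <- (roiEdge - 1L) %/% 2L
  rx <- (center[1] - half):(center[1] + half)
  ry <- (center[2] - half):(center[2] + half)
  rz <- (center[3] - half):(center[3] + half)
  d <- dim(dataset@data)
  if (min(rx, ry, rz) < 1L || max(rx) > d[1] || max(ry) > d[2] ||
      max(rz) > d[3] || !all(mask@mask[rx, ry, rz])) {
    stop("ROI escapes the phantom mask; use a smaller roiEdge")
  }

  s0 <- mean(vapply(b0idx, function(v) mean(dataset@data[rx, ry, rz, v]),
                    numeric(1)))
  si <- vapply(dwidx, function(v) mean(dataset@data[rx, ry, rz, v]),
               numeric(1))
  if (s0 <= 0 || any(si <= 0)) {
    stop("nonpositive ROI mean signal; log-ratio undefined")
  }
  di <- -log(si / s0) / b
  new("DiffusivityEstimate",
      perDirectionD = di, meanD = mean(di),
      roiCenter = center, roiEdge = roiEdge, bValue = b)
}

#' DiffusivityEstimate as a tidy table
#'
#' @param est a \linkS4class{DiffusivityEstimate}.
#' @return data.frame with columns direction, d_mm2_s.
#' @export
diffusivityTable <- function(est) {
  data.frame(direction = seq_along(est@perDirectionD),
             d_mm2_s = est@perDirectionD)
}
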
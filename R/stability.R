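#' DIM stability under random voxel removal
#'
#' Quantifies how robust the eigenratio statistic is to the size of the
#' volume of interest: for each removal fraction f, draws random subsets of
#' ceiling(f * N_v) voxel rows (uniform, without replacement, independently
#' re-drawn per resample), recomputes DIM on the remaining rows - with
#' columns re-standardized on the subsample, since their means and norms
#' change - and summarizes mean and SD across resamples.
#'
#' Each (fraction, resample) cell draws from its own deterministic seed
#' stream derived from \code{seed}, so the curve is bitwise reproducible
#' regardless of evaluation order.
#'
#' @param matrix a \linkS4class{VoxelMatrix} (full mask).
#' @param removalFractions fractions in [0, 0.99) of voxels to remove;
#'   defaults to the 1, 2, 3, 5, 10, 20 percent ladder.
#' @param nResamples random subsets per fraction (default 100).
#' @param seed integer RNG seed.
#' @return a \linkS4class{StabilityCurve}.
#' @export
voxelSubsamplingCurve <- function(matrix,
                                  removalFractions = c(0.01, 0.02, 0.03,
                                                       0.05, 0.10, 0.20),
                                  nResamples = 100L, seed = 1L) {
  stopifnot(nResamples >= 1L)
  if (any(removalFractions < 0 | removalFractions >= 0.99)) {
    stop("removal fractions must lie in [0, 0.99)")
  }
  nv <- nrow(matrix@values)
  means <- sds <- numeric(length(removalFractions))
  fullDim <- dimOfMatrix(matrix)@dimPpm
  for (fi in seq_along(removalFractions)) {
    f <- removalFractions[fi]
    nRemove <- ceiling(f * nv)
    if (nv - nRemove < 2L) {
      stop(sprintf("fraction %.2f leaves fewer than 2 voxels", f))
    }
    if (nRemove == 0L) {
      means[fi] <- fullDim
      sds[fi] <- 0
      next
    }
    dims <- vapply(seq_len(nResamples), function(ri) {
      drop <- withSeed(subSeed(seed, fi, ri),
                       sample.int(nv, nRemove, replace = FALSE))
      sub <- new("VoxelMatrix",
                 values = matrix@values[-drop, , drop = FALSE],
                 directionIds = matrix@directionIds)
      dimOfMatrix(sub)@dimPpm
    }, numeric(1))
    means[fi] <- mean(dims)
    sds[fi] <- if (nResamples > 1L) stats::sd(dims) else 0
  }
  new("StabilityCurve",
      removalFractions = removalFractions,
      meanDimPpm = means, sdDimPpm = sds,
      nResamples = as.integer(nResamples), seed = as.integer(seed))
}

#' StabilityCurve as a tidy table
#'
#' @param curve a \linkS4class{StabilityCurve}.
#' @return data.frame with columns fraction, mean_dim_ppm, sd_dim_ppm.
#' @export
stabilityTable <- function(curve) {
  data.frame(fraction = curve@removalFractions,
             mean_dim_ppm = curve@meanDimPpm,
             sd_dim_ppm = curve@sdDimPpm)
}
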
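#' Standardize the columns of a voxel matrix
#'
#' Centers every column with its own mean and rescales it to unit Euclidean
#' norm, so that the Gram product of the result is exactly the Pearson
#' correlation matrix with unit diagonal. (Dividing by the sample standard
#' deviation instead only changes a global factor of sqrt(N_v - 1), which
#' cancels in the eigenratio.)
#'
#' @param matrix a \linkS4class{VoxelMatrix}.
#' @return a \linkS4class{VoxelMatrix} with standardized columns.
#' @export
standardizeColumns <- function(matrix) {
  x <- matrix@values
  x <- sweep(x, 2L, colMeans(x), "-")
  nrm <- sqrt(colSums(x^2))
  zero <- nrm <= .Machine$double.eps * sqrt(nrow(x)) *
    apply(abs(matrix@values), 2L, max)
  zero <- zero | nrm == 0
  if (any(zero)) {
    stop(sprintf("direction %d has zero variance; cannot standardize",
                 matrix@directionIds[which(zero)[1]]))
  }
  x <- sweep(x, 2L, nrm, "/")
  new("VoxelMatrix", values = x, directionIds = matrix@directionIds)
}

#' Inter-direction Pearson correlation matrix
#'
#' Builds the N_d x N_d matrix C whose entry (i, j) is the Pearson
#' correlation between the masked voxel intensities of diffusion directions
#' i and j, via the Gram product of the standardized matrix. The result is
#' symmetrized and its diagonal pinned to 1 to absorb last-bit float
#' asymmetry.
#'
#' @param matrix a \linkS4class{VoxelMatrix} (standardized or not).
#' @return a \linkS4class{CorrelationMatrix}.
#' @export
correlationMatrix <- function(matrix) {
  xs <- standardizeColumns(matrix)
  c0 <- crossprod(xs@values)
  c0 <- (c0 + t(c0)) / 2
  diag(c0) <- 1
  c0[c0 > 1] <- 1
  c0[c0 < -1] <- -1
  new("CorrelationMatrix", values = c0, directionIds = matrix@directionIds)
}

#' The diffusion instability measure of a correlation matrix
#'
#' DIM = 1 - lambda_max / sum(lambda), where lambda are the eigenvalues of
#' the inter-direction correlation matrix C. If every DWI were a perfect
#' copy of the first, C would be rank one and DIM zero; for mutually
#' uncorrelated DWIs C approaches the identity and DIM its ceiling
#' 1 - 1/N_d. Reported in parts per million.
#'
#' The eigenvalue sum is taken as the trace N_d (exact for a unit-diagonal
#' matrix), and the spectrum comes from a symmetric eigendecomposition of C
#' - never from an SVD of the large voxel matrix, which serves only as an
#' independent cross-check in the test suite.
#'
#' @param corr a \linkS4class{CorrelationMatrix}.
#' @param nVoxels number of voxels behind the correlations (provenance).
#' @param subsetPolicy provenance string recorded in the result.
#' @param registered provenance flag recorded in the result.
#' @return a \linkS4class{DimResult}.
#' @export
dimStatistic <- function(corr, nVoxels = NA_integer_,
                         subsetPolicy = "custom", registered = FALSE) {
  ev <- eigen(corr@values, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  nd <- length(ev)
  raw <- 1 - ev[1] / nd
  raw <- max(raw, 0)
  new("DimResult",
      dimRaw = raw, dimPpm = raw * 1e6,
      eigenvalues = ev,
      nVoxels = as.integer(nVoxels),
      directionIds = corr@directionIds,
      subsetPolicy = subsetPolicy,
      registered = registered)
}

#' DIM of a voxel matrix
#'
#' Convenience composition: standardize, correlate, eigendecompose.
#'
#' @param matrix a \linkS4class{VoxelMatrix}.
#' @inheritParams dimStatistic
#' @return a \linkS4class{DimResult}.
#' @export
dimOfMatrix <- function(matrix, subsetPolicy = "custom", registered = FALSE) {
  dimStatistic(correlationMatrix(matrix),
               nVoxels = nrow(matrix@values),
               subsetPolicy = subsetPolicy, registered = registered)
}

# Resolve a direction-subset policy to volume indices. `candidates` are the
# volume indices remaining after the b0 split, in acquisition order.
resolveSubset <- function(candidates, subsetPolicy, directions = NULL) {
  sel <- switch(subsetPolicy,
    all = candidates,
    exclude_first = candidates[-1L],
    exclude_last = candidates[-length(candidates)],
    custom = {
      if (is.null(directions)) {
        stop("subsetPolicy 'custom' requires a directions vector")
      }
      if (any(!directions %in% candidates)) {
        stop("custom directions must be drawn from the available volumes")
      }
      as.integer(directions)
    },
    stop("unknown subsetPolicy: ", subsetPolicy)
  )
  if (length(sel) < 2L) {
    stop("fewer than 2 diffusion directions remain after subsetting")
  }
  sel
}

#' End-to-end DIM from a HARDI dataset
#'
#' Composes the full pipeline: optional slice-wise registration to the first
#' volume, voxel extraction under the mask, column standardization,
#' correlation matrix, and the eigenratio statistic. By default b0 volumes
#' are excluded from the correlation matrix (the instability of interest
#' lives among the diffusion-weighted volumes); \code{includeB0 = TRUE}
#' forces them in.
#'
#' @param dataset a \linkS4class{HardiDataset}.
#' @param mask a \linkS4class{PhantomMask}; built automatically from the
#'   dataset when NULL.
#' @param subsetPolicy one of \code{"all"}, \code{"exclude_first"},
#'   \code{"exclude_last"}, \code{"custom"}.
#' @param directions explicit volume indices for \code{subsetPolicy =
#'   "custom"}.
#' @param register apply slice-wise translation-only registration first.
#' @param includeB0 keep b0 volumes in the correlation matrix.
#' @param maxShift registration shift cap in voxels.
#' @return a \linkS4class{DimResult}.
#' @export
dimFromDataset <- function(dataset, mask = NULL, subsetPolicy = "all",
                           directions = NULL, register = FALSE,
                           includeB0 = FALSE, maxShift = 5) {
  if (register) {
    shifts <- estimateShifts(dataset, maxShift = maxShift)
    dataset <- applyShifts(dataset, shifts)
  }
  if (is.null(mask)) mask <- makePhantomMask(dataset)
  nvol <- dim(dataset@data)[4]
  candidates <- seq_len(nvol)
  if (!includeB0) {
    candidates <- candidates[!isB0(dataset@bvals)]
    if (length(candidates) < 2L) {
      stop("fewer than 2 non-b0 volumes in the dataset")
    }
  }
  sel <- resolveSubset(candidates, subsetPolicy, directions)
  vm <- extractVoxelMatrix(dataset, mask, sel)
  dimOfMatrix(vm, subsetPolicy = subsetPolicy, registered = register)
}
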
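#' Read a HARDI acquisition from NIfTI + FSL bval/bvec files
#'
#' Reads a 4D NIfTI-1 image together with its FSL-dialect gradient table
#' (\code{bval}: one whitespace-delimited row of N numbers; \code{bvec}:
#' three rows of N numbers) and returns a validated \linkS4class{HardiDataset}.
#' Volume order is preserved from file.
#'
#' @param imagePath path to a 4D NIfTI-1 file (.nii or .nii.gz).
#' @param bvalPath path to the bval text file.
#' @param bvecPath path to the bvec text file.
#' @return a \linkS4class{HardiDataset}.
#' @export
readHardi <- function(imagePath, bvalPath, bvecPath) {
  img <- RNifti::readNifti(imagePath)
  data <- unclass(as.array(img))
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) {
    stop("expected a 4D image, got ", length(dim(data)), " dimensions")
  }
  attributes(data) <- list(dim = dim(data))
  nvol <- dim(data)[4]
  bvals <- scan(bvalPath, quiet = TRUE)
  bvecRaw <- scan(bvecPath, quiet = TRUE)
  if (length(bvecRaw) %% 3L != 0L) {
    stop("bvec file must contain 3 rows of equal length")
  }
  bvecs <- matrix(bvecRaw, nrow = 3L, byrow = TRUE)
  if (length(bvals) != nvol) {
    stop(sprintf("%d b-values for %d volumes", length(bvals), nvol))
  }
  if (ncol(bvecs) != nvol) {
    stop(sprintf("%d b-vectors for %d volumes", ncol(bvecs), nvol))
  }
  if (!all(is.finite(data))) stop("image contains non-finite voxels")
  new("HardiDataset",
      data = data,
      affine = structure(RNifti::xform(img), class = NULL,
                         code = NULL, imagedim = NULL),
      bvals = bvals, bvecs = bvecs,
      volumeLabels = seq_len(nvol))
}

#' Write a HARDI dataset as NIfTI + FSL bval/bvec files
#'
#' Emits the same dialects \code{\link{readHardi}} consumes; a read of the
#' written files round-trips the data array bitwise (float64 storage) and
#' the gradient table to printed precision.
#'
#' @param dataset a \linkS4class{HardiDataset}.
#' @param imagePath output NIfTI path.
#' @param bvalPath output bval path.
#' @param bvecPath output bvec path.
#' @return invisibly, the three paths.
#' @export
writeHardi <- function(dataset, imagePath, bvalPath, bvecPath) {
  img <- RNifti::asNifti(dataset@data, datatype = "double")
  img <- RNifti::`qform<-`(img, structure(dataset@affine, code = 2L))
  RNifti::writeNifti(img, imagePath)
  writeLines(paste(format(dataset@bvals, trim = TRUE, digits = 15),
                   collapse = " "), bvalPath)
  writeLines(apply(dataset@bvecs, 1, function(r) {
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")
  }), bvecPath)
  invisible(c(imagePath, bvalPath, bvecPath))
}

#' Derive the phantom volume of interest from a reference volume
#'
#' Thresholds the reference volume (default: the first b0) at
#' \code{thresholdFraction} times the in-phantom mean intensity, keeps the
#' largest 6-connected 3D component, and fills interior holes. The
#' in-phantom mean is estimated in two passes - the mean of voxels brighter
#' than half the 99.9th intensity percentile - so that background noise
#' voxels (which are positive in magnitude images) cannot drag the
#' threshold down, and a stray hot voxel cannot push it up. The
#' construction is invariant to global positive intensity scaling.
#'
#' @param dataset a \linkS4class{HardiDataset}.
#' @param thresholdFraction fraction of the nonzero-mean intensity, in (0,1).
#' @param referenceVolume volume index; defaults to the first b0 volume
#'   (b-value < 50 s/mm^2), or volume 1 if none is marked.
#' @return a \linkS4class{PhantomMask}.
#' @export
makePhantomMask <- function(dataset, thresholdFraction = 0.5,
                            referenceVolume = NULL) {
  stopifnot(thresholdFraction > 0, thresholdFraction < 1)
  if (is.null(referenceVolume)) {
    b0 <- which(isB0(dataset@bvals))
    referenceVolume <- if (length(b0)) b0[1] else 1L
  }
  nvol <- dim(dataset@data)[4]
  if (referenceVolume < 1L || referenceVolume > nvol) {
    stop("referenceVolume out of range")
  }
  vol <- dataset@data[, , , referenceVolume]
  pos <- vol[vol > 0]
  if (!length(pos)) {
    stop("reference volume has no positive voxels; cannot build a mask")
  }
  bright <- pos[pos > 0.5 * stats::quantile(pos, 0.999)]
  thr <- thresholdFraction * mean(bright)
  raw <- vol > thr
  if (!any(raw)) {
    stop("empty mask after thresholding; try a lower thresholdFraction")
  }
  mask <- fillHoles3(largestComponent3(raw))
  new("PhantomMask", mask = mask, nVoxels = as.integer(sum(mask)))
}

#' Read / write a binary mask as NIfTI
#'
#' @param path NIfTI file holding a 3D binary image (nonzero = in mask).
#' @return a \linkS4class{PhantomMask}.
#' @export
readPhantomMask <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) dim(a) <- dim(a)[1:3]
  if (length(dim(a)) != 3L) stop("mask image must be 3D")
  m <- array(a != 0, dim(a))
  new("PhantomMask", mask = m, nVoxels = as.integer(sum(m)))
}

#' @rdname readPhantomMask
#' @param mask a \linkS4class{PhantomMask}.
#' @export
writePhantomMask <- function(mask, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask@mask),
                                           dim(mask@mask))), path)
  invisible(path)
}

#' Reshape masked voxels into the voxel-by-direction matrix
#'
#' Extracts the masked voxels of each requested volume into the columns of
#' an N_v x N_d matrix. Scan order is fixed: x varies fastest, then y, then
#' z (R's native array order), identical for every column, so results are
#' reproducible; DIM itself is invariant to any fixed row order.
#'
#' @param dataset a \linkS4class{HardiDataset}.
#' @param mask a \linkS4class{PhantomMask} on the same grid.
#' @param volumeSubset ordered volume indices (1-based) to use as columns;
#'   default all volumes.
#' @return a \linkS4class{VoxelMatrix}.
#' @export
extractVoxelMatrix <- function(dataset, mask,
                               volumeSubset = seq_len(dim(dataset@data)[4])) {
  d <- dim(dataset@data)
  if (!all(dim(mask@mask) == d[1:3])) {
    stop("mask grid does not match the dataset grid")
  }
  if (!length(volumeSubset)) stop("volumeSubset must be non-empty")
  if (anyDuplicated(volumeSubset)) stop("volumeSubset indices must be unique")
  if (any(volumeSubset < 1L | volumeSubset > d[4])) {
    stop("volumeSubset index out of range")
  }
  flat <- matrix(dataset@data, nrow = prod(d[1:3]), ncol = d[4])
  vals <- flat[as.vector(mask@mask), volumeSubset, drop = FALSE]
  new("VoxelMatrix", values = vals,
      directionIds = as.integer(volumeSubset))
}
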
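#' @import methods
NULL

#' HardiDataset: a 4D diffusion-weighted image series
#'
#' Container for a HARDI acquisition: the 4D intensity array (x, y, z, volume),
#' the voxel-to-world affine, and the FSL-style gradient table (b-values in
#' s/mm^2 and unit b-vectors; the zero vector marks b0 volumes).
#'
#' @slot data 4D numeric array, dimensions x, y, z, volume.
#' @slot affine 4x4 voxel-to-world transform.
#' @slot bvals numeric vector, one b-value per volume (s/mm^2).
#' @slot bvecs 3 x nVolumes matrix of diffusion-encoding unit vectors.
#' @slot volumeLabels integer ordinal index of each volume (0-based as stored
#'   on disk order; kept 1-based internally like all R indices).
#'
#' @exportClass HardiDataset
setClass("HardiDataset",
  representation(
    data = "array",
    affine = "matrix",
    bvals = "numeric",
    bvecs = "matrix",
    volumeLabels = "integer"
  )
)

setValidity("HardiDataset", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) {
    return("data must be a 4D array (x, y, z, volume)")
  }
  nv <- d[4]
  if (nv < 2L) return("dataset must contain at least 2 volumes")
  if (length(object@bvals) != nv) {
    return(sprintf("%d b-values for %d volumes", length(object@bvals), nv))
  }
  if (!all(dim(object@bvecs) == c(3L, nv))) {
    return(sprintf("bvecs must be 3 x %d, got %d x %d",
                   nv, nrow(object@bvecs), ncol(object@bvecs)))
  }
  if (length(object@volumeLabels) != nv) {
    return("volumeLabels length must equal the number of volumes")
  }
  if (!all(is.finite(object@data))) return("intensities must be finite")
  nrm <- sqrt(colSums(object@bvecs^2))
  bad <- nrm > 1e-6 & abs(nrm - 1) > 1e-3
  if (any(bad)) {
    return(sprintf("bvec %d has norm %.6f (nonzero b-vectors must be unit)",
                   which(bad)[1], nrm[which(bad)[1]]))
  }
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4x4")
  TRUE
})

#' PhantomMask: binary volume of interest over the phantom
#'
#' @slot mask 3D logical array on the dataset grid.
#' @slot nVoxels number of TRUE voxels (the paper-level N_v).
#'
#' @exportClass PhantomMask
setClass("PhantomMask",
  representation(mask = "array", nVoxels = "integer")
)

setValidity("PhantomMask", function(object) {
  if (length(dim(object@mask)) != 3L) return("mask must be a 3D array")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (object@nVoxels != sum(object@mask)) {
    return("nVoxels does not match the number of TRUE voxels")
  }
  if (object@nVoxels < 1L) return("mask must contain at least one voxel")
  TRUE
})

#' VoxelMatrix: masked voxels by diffusion direction
#'
#' The N_v x N_d matrix X whose column j holds the masked voxel intensities of
#' one diffusion-encoding volume, in a fixed scan order (x fastest, then y,
#' then z - R's native array order).
#'
#' @slot values numeric matrix, N_v rows (voxels) x N_d columns (directions).
#' @slot directionIds integer volume indices (1-based) behind each column.
#'
#' @exportClass VoxelMatrix
setClass("VoxelMatrix",
  representation(values = "matrix", directionIds = "integer")
)

setValidity("VoxelMatrix", function(object) {
  v <- object@values
  if (nrow(v) < 2L || ncol(v) < 2L) {
    return("VoxelMatrix needs at least 2 voxels and 2 directions")
  }
  if (!all(is.finite(v))) return("VoxelMatrix entries must be finite")
  if (length(object@directionIds) != ncol(v)) {
    return("directionIds length must equal the number of columns")
  }
  TRUE
})

#' CorrelationMatrix: inter-direction Pearson correlations
#'
#' The N_d x N_d symmetric matrix C whose entry (i, j) is the Pearson
#' correlation between the masked voxel intensities of directions i and j.
#'
#' @slot values symmetric numeric matrix with unit diagonal.
#' @slot directionIds integer volume indices behind each row/column.
#'
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
  representation(values = "matrix", directionIds = "integer")
)

setValidity("CorrelationMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("correlation matrix must be square")
  if (max(abs(v - t(v))) > 1e-12) return("correlation matrix must be symmetric")
  if (max(abs(diag(v) - 1)) > 1e-12) return("diagonal must be 1")
  if (any(v < -1 - 1e-12) || any(v > 1 + 1e-12)) {
    return("entries must lie in [-1, 1]")
  }
  if (length(object@directionIds) != ncol(v)) {
    return("directionIds length must equal matrix dimension")
  }
  TRUE
})

#' DimResult: the diffusion instability measure and its provenance
#'
#' @slot dimRaw dimensionless DIM in [0, 1 - 1/N_d].
#' @slot dimPpm dimRaw times 1e6.
#' @slot eigenvalues eigenvalue spectrum of C, sorted descending.
#' @slot nVoxels number of voxels N_v entering the correlation matrix.
#' @slot directionIds volume indices of the directions used.
#' @slot subsetPolicy one of "all", "exclude_first", "exclude_last", "custom".
#' @slot registered whether slice-wise registration was applied first.
#'
#' @exportClass DimResult
setClass("DimResult",
  representation(
    dimRaw = "numeric",
    dimPpm = "numeric",
    eigenvalues = "numeric",
    nVoxels = "integer",
    directionIds = "integer",
    subsetPolicy = "character",
    registered = "logical"
  )
)

setValidity("DimResult", function(object) {
  nd <- length(object@eigenvalues)
  if (nd < 2L) return("need at least 2 eigenvalues")
  if (object@dimPpm != object@dimRaw * 1e6) {
    return("dimPpm must equal dimRaw * 1e6")
  }
  if (object@dimRaw < -1e-12 || object@dimRaw > 1 - 1 / nd + 1e-12) {
    return(sprintf("dimRaw %.3g outside [0, 1 - 1/%d]", object@dimRaw, nd))
  }
  if (any(object@eigenvalues < -1e-10)) {
    return("eigenvalues must be nonnegative (within tolerance)")
  }
  if (is.unsorted(rev(object@eigenvalues))) {
    return("eigenvalues must be sorted descending")
  }
  if (abs(sum(object@eigenvalues) - nd) > 1e-8 * nd) {
    return("eigenvalues must sum to N_d (trace of C)")
  }
  TRUE
})

#' ShiftField: per-volume, per-slice in-plane translations
#'
#' @slot shifts numeric array nVolumes x nSlices x 2, (dx, dy) in voxels.
#' @slot referenceVolume index of the reference volume (its shifts are 0).
#'
#' @exportClass ShiftField
setClass("ShiftField",
  representation(shifts = "array", referenceVolume = "integer")
)

setValidity("ShiftField", function(object) {
  d <- dim(object@shifts)
  if (length(d) != 3L || d[3] != 2L) {
    return("shifts must be nVolumes x nSlices x 2")
  }
  if (!all(is.finite(object@shifts))) return("shifts must be finite")
  rv <- object@referenceVolume
  if (rv < 1L || rv > d[1]) return("referenceVolume out of range")
  if (any(object@shifts[rv, , ] != 0)) {
    return("reference volume shifts must be exactly zero")
  }
  TRUE
})

#' StabilityCurve: DIM as a function of random voxel removal
#'
#' @slot removalFractions fractions of masked voxels removed.
#' @slot meanDimPpm mean DIM (ppm) across resamples at each fraction.
#' @slot sdDimPpm standard deviation of DIM (ppm) across resamples.
#' @slot nResamples number of random resamples per fraction.
#' @slot seed RNG seed the curve was computed under.
#'
#' @exportClass StabilityCurve
setClass("StabilityCurve",
  representation(
    removalFractions = "numeric",
    meanDimPpm = "numeric",
    sdDimPpm = "numeric",
    nResamples = "integer",
    seed = "integer"
  )
)

setValidity("StabilityCurve", function(object) {
  n <- length(object@removalFractions)
  if (length(object@meanDimPpm) != n || length(object@sdDimPpm) != n) {
    return("curve arrays must share length")
  }
  if (any(object@sdDimPpm < 0)) return("sd must be nonnegative")
  TRUE
})

#' DiffusivityEstimate: apparent diffusivity from the central ROI
#'
#' @slot perDirectionD apparent diffusivity D_i (mm^2/s) per non-b0 direction.
#' @slot meanD arithmetic mean of perDirectionD.
#' @slot roiCenter voxel index triple of the ROI center (1-based).
#' @slot roiEdge ROI cube edge in voxels (odd).
#' @slot bValue the b-value used (s/mm^2).
#'
#' @exportClass DiffusivityEstimate
setClass("DiffusivityEstimate",
  representation(
    perDirectionD = "numeric",
    meanD = "numeric",
    roiCenter = "integer",
    roiEdge = "integer",
    bValue = "numeric"
  )
)

setValidity("DiffusivityEstimate", function(object) {
  if (object@roiEdge < 1L || object@roiEdge %% 2L == 0L) {
    return("roiEdge must be odd and >= 1")
  }
  if (!all(is.finite(object@perDirectionD))) {
    return("per-direction diffusivities must be finite")
  }
  if (abs(object@meanD - mean(object@perDirectionD)) >
      1e-12 * max(1, abs(object@meanD))) {
    return("meanD must be the arithmetic mean of perDirectionD")
  }
  TRUE
})

#' SimulationConfig: parameterization of the synthetic spherical phantom
#'
#' Describes a uniform spherical phantom (silicone-oil-like, near-zero
#' diffusivity) imaged as a HARDI series, with controllable noise, EPI
#' half-FOV ghosting, multiplicative intensity drift, in-plane positional
#' drift, and single-volume corruption.
#'
#' @slot gridShape voxel grid (x, y, z).
#' @slot sphereRadius sphere radius in voxels.
#' @slot baseIntensity in-phantom b0 intensity (arbitrary units).
#' @slot nDirections number of diffusion-encoding directions.
#' @slot bValue diffusion weighting (s/mm^2).
#' @slot diffusivity isotropic diffusivity D (mm^2/s).
#' @slot snr baseIntensity / noise SD; Inf means noiseless.
#' @slot ghostAmplitudes per-direction half-FOV ghost amplitude as a fraction
#'   of the local intensity (length nDirections).
#' @slot driftPerVolume fractional multiplicative intensity change per volume.
#' @slot shiftPerVolume in-plane (x) positional drift in voxels per volume.
#' @slot corruptDirections direction indices (1-based) given a heavy ghost.
#' @slot corruptAmplitude ghost amplitude applied to corrupt directions.
#' @slot noiseModel "gaussian" (default) or "rician".
#' @slot seed RNG seed for noise (b-vectors are seed-independent).
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    gridShape = "integer",
    sphereRadius = "numeric",
    baseIntensity = "numeric",
    nDirections = "integer",
    bValue = "numeric",
    diffusivity = "numeric",
    snr = "numeric",
    ghostAmplitudes = "numeric",
    driftPerVolume = "numeric",
    shiftPerVolume = "numeric",
    corruptDirections = "integer",
    corruptAmplitude = "numeric",
    noiseModel = "character",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 4L)) {
    return("gridShape must be three voxel counts >= 4")
  }
  if (object@sphereRadius <= 0 ||
      2 * object@sphereRadius + 2 > min(object@gridShape[1:2])) {
    return("sphere (diameter + margin) must fit inside the in-plane FOV")
  }
  if (object@nDirections < 2L) return("need at least 2 diffusion directions")
  if (object@snr <= 0) return("snr must be positive (Inf = noiseless)")
  if (length(object@ghostAmplitudes) != object@nDirections) {
    return("ghostAmplitudes must have one entry per direction")
  }
  if (any(object@ghostAmplitudes < 0)) return("ghost amplitudes must be >= 0")
  if (any(object@corruptDirections < 1L |
          object@corruptDirections > object@nDirections)) {
    return("corruptDirections out of range")
  }
  if (!object@noiseModel %in% c("gaussian", "rician")) {
    return("noiseModel must be 'gaussian' or 'rician'")
  }
  if (object@diffusivity < 0) return("diffusivity must be >= 0")
  TRUE
})
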
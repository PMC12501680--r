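#' @include AllClasses.R
NULL

#' Accessors for dimqa objects
#'
#' Small accessor generics so user code never reaches into slots.
#'
#' @param x a dimqa object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname accessors
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' @rdname accessors
#' @export
setGeneric("bVectors", function(x) standardGeneric("bVectors"))

#' @rdname accessors
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname accessors
#' @export
setGeneric("spatialDim", function(x) standardGeneric("spatialDim"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname accessors
#' @export
setGeneric("directionIds", function(x) standardGeneric("directionIds"))

#' @rdname accessors
#' @export
setGeneric("dimRaw", function(x) standardGeneric("dimRaw"))

#' @rdname accessors
#' @export
setGeneric("dimPpm", function(x) standardGeneric("dimPpm"))

#' @rdname accessors
#' @export
setGeneric("eigenSpectrum", function(x) standardGeneric("eigenSpectrum"))

#' @rdname accessors
#' @export
setGeneric("shiftArray", function(x) standardGeneric("shiftArray"))

#' @exportMethod imgData
setMethod("imgData", "HardiDataset", function(x) x@data)

#' @exportMethod bValues
setMethod("bValues", "HardiDataset", function(x) x@bvals)

#' @exportMethod bVectors
setMethod("bVectors", "HardiDataset", function(x) x@bvecs)

#' @exportMethod nVolumes
setMethod("nVolumes", "HardiDataset", function(x) dim(x@data)[4])

#' @exportMethod spatialDim
setMethod("spatialDim", "HardiDataset", function(x) dim(x@data)[1:3])

#' @exportMethod maskArray
setMethod("maskArray", "PhantomMask", function(x) x@mask)

#' @exportMethod nVoxels
setMethod("nVoxels", "PhantomMask", function(x) x@nVoxels)

#' @exportMethod nVoxels
setMethod("nVoxels", "DimResult", function(x) x@nVoxels)

#' @exportMethod values
setMethod("values", "VoxelMatrix", function(x) x@values)

#' @exportMethod values
setMethod("values", "CorrelationMatrix", function(x) x@values)

#' @exportMethod directionIds
setMethod("directionIds", "VoxelMatrix", function(x) x@directionIds)

#' @exportMethod directionIds
setMethod("directionIds", "CorrelationMatrix", function(x) x@directionIds)

#' @exportMethod directionIds
setMethod("directionIds", "DimResult", function(x) x@directionIds)

#' @exportMethod dimRaw
setMethod("dimRaw", "DimResult", function(x) x@dimRaw)

#' @exportMethod dimPpm
setMethod("dimPpm", "DimResult", function(x) x@dimPpm)

#' @exportMethod eigenSpectrum
setMethod("eigenSpectrum", "DimResult", function(x) x@eigenvalues)

#' @exportMethod shiftArray
setMethod("shiftArray", "ShiftField", function(x) x@shifts)

setMethod("show", "HardiDataset", function(object) {
  d <- dim(object@data)
  nb0 <- sum(isB0(object@bvals))
  cat(sprintf("HardiDataset: %d x %d x %d voxels, %d volumes (%d b0)\n",
              d[1], d[2], d[3], d[4], nb0))
  cat(sprintf("  b-values: %s s/mm^2\n",
              paste(unique(round(object@bvals)), collapse = ", ")))
})

setMethod("show", "PhantomMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("PhantomMask: %d voxels on a %d x %d x %d grid (N_v = %d)\n",
              object@nVoxels, d[1], d[2], d[3], object@nVoxels))
})

setMethod("show", "VoxelMatrix", function(object) {
  cat(sprintf("VoxelMatrix: N_v = %d voxels x N_d = %d directions\n",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "CorrelationMatrix", function(object) {
  v <- object@values
  off <- v[upper.tri(v)]
  cat(sprintf("CorrelationMatrix: %d x %d, off-diagonal range [%.6f, %.6f]\n",
              nrow(v), ncol(v), min(off), max(off)))
})

setMethod("show", "DimResult", function(object) {
  cat(sprintf("DimResult: DIM = %.2f ppm (raw %.3e)\n",
              object@dimPpm, object@dimRaw))
  cat(sprintf("  N_v = %d, N_d = %d, policy = %s, registered = %s\n",
              object@nVoxels, length(object@eigenvalues),
              object@subsetPolicy, object@registered))
  cat(sprintf("  lambda_max = %.4f, lambda_min = %.3e\n",
              object@eigenvalues[1],
              object@eigenvalues[length(object@eigenvalues)]))
})

setMethod("show", "ShiftField", function(object) {
  d <- dim(object@shifts)
  mx <- max(abs(object@shifts))
  cat(sprintf("ShiftField: %d volumes x %d slices, max |shift| = %.3f voxels\n",
              d[1], d[2], mx))
})

setMethod("show", "StabilityCurve", function(object) {
  cat(sprintf("StabilityCurve: %d fractions x %d resamples\n",
              length(object@removalFractions), object@nResamples))
  print(data.frame(fraction = object@removalFractions,
                   mean_dim_ppm = object@meanDimPpm,
                   sd_dim_ppm = object@sdDimPpm))
})

setMethod("show", "DiffusivityEstimate", function(object) {
  cat(sprintf(
    "DiffusivityEstimate: mean D = %.3e mm^2/s over %d directions (b = %g)\n",
    object@meanD, length(object@perDirectionD), object@bValue))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %s grid, radius %g, %d directions, b = %g, D = %g, SNR = %g\n",
    paste(object@gridShape, collapse = "x"), object@sphereRadius,
    object@nDirections, object@bValue, object@diffusivity, object@snr))
})
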
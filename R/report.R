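# Result serialization and the standard visual outputs: correlation-matrix
# heatmap, log-scaled DIM scatter, and tiled difference-image mosaics.

#' Serialize a DimResult to JSON and/or a CSV row
#'
#' JSON keys: dim_ppm, dim_raw, eigenvalues, n_voxels, n_directions,
#' direction_ids, subset_policy, registered. The CSV form is a single row
#' (without the spectrum) suitable for appending to a longitudinal QA log.
#'
#' @param result a \linkS4class{DimResult}.
#' @param jsonPath output JSON path, or NULL to skip.
#' @param csvPath output CSV path, or NULL to skip.
#' @return invisibly, the list form of the result.
#' @export
writeDimResult <- function(result, jsonPath = NULL, csvPath = NULL) {
  lst <- list(
    dim_ppm = result@dimPpm,
    dim_raw = result@dimRaw,
    eigenvalues = result@eigenvalues,
    n_voxels = result@nVoxels,
    n_directions = length(result@eigenvalues),
    direction_ids = result@directionIds,
    subset_policy = result@subsetPolicy,
    registered = result@registered
  )
  if (!is.null(jsonPath)) {
    jsonlite::write_json(lst, jsonPath, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csvPath)) {
    utils::write.csv(
      data.frame(dim_ppm = result@dimPpm, dim_raw = result@dimRaw,
                 n_voxels = result@nVoxels,
                 n_directions = length(result@eigenvalues),
                 subset_policy = result@subsetPolicy,
                 registered = result@registered),
      csvPath, row.names = FALSE)
  }
  invisible(lst)
}

#' Read a DimResult back from its JSON form
#'
#' @param jsonPath path written by \code{\link{writeDimResult}}.
#' @return a \linkS4class{DimResult}.
#' @export
readDimResult <- function(jsonPath) {
  lst <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  # recompute ppm from the raw value: decimal serialization need not
  # round-trip the x1e6 identity bit-exactly
  new("DimResult",
      dimRaw = lst$dim_raw, dimPpm = lst$dim_raw * 1e6,
      eigenvalues = as.numeric(lst$eigenvalues),
      nVoxels = as.integer(lst$n_voxels),
      directionIds = as.integer(lst$direction_ids),
      subsetPolicy = lst$subset_policy,
      registered = lst$registered)
}

#' Correlation-matrix heatmap
#'
#' Renders C with a fixed intensity window, by convention [0.95, 1] for
#' good data and [0.7, 1] for visibly unstable data; values below the
#' window floor are clipped into it so structure near 1 stays visible.
#'
#' @param corr a \linkS4class{CorrelationMatrix}.
#' @param window length-2 numeric display window (low, high).
#' @param main plot title.
#' @export
plotCorrelationMatrix <- function(corr, window = c(0.95, 1),
                                  main = "Inter-direction correlation") {
  stopifnot(length(window) == 2L, window[1] < window[2])
  v <- pmin(pmax(corr@values, window[1]), window[2])
  n <- ncol(v)
  pal <- grDevices::hcl.colors(128, "viridis")
  # flip rows so direction 1 sits top-left, matrix-style
  graphics::image(seq_len(n), seq_len(n), t(v[n:1, ]),
                  zlim = window, col = pal, axes = FALSE,
                  xlab = "direction", ylab = "direction", main = main,
                  useRaster = TRUE)
  at <- pretty(seq_len(n))
  at <- at[at >= 1 & at <= n]
  graphics::axis(1, at = at)
  graphics::axis(2, at = n + 1 - at, labels = at)
  graphics::box()
  invisible(NULL)
}

#' Log-scaled DIM scatter across datasets
#'
#' Natural-log-scaled scatter of DIM (ppm) grouped by a label, the standard
#' way to compare scanners, sequences, or sessions spanning orders of
#' magnitude.
#'
#' @param dimPpmValues numeric vector of DIM values in ppm.
#' @param labels grouping label per value; legend keeps first-appearance
#'   order.
#' @param main plot title.
#' @export
plotDimScatter <- function(dimPpmValues, labels = rep("data", length(dimPpmValues)),
                           main = "DIM per dataset (ln scale)") {
  stopifnot(length(dimPpmValues) >= 1,
            length(labels) == length(dimPpmValues),
            all(dimPpmValues > 0))
  labels <- factor(labels, levels = unique(labels))
  grp <- as.integer(labels)
  y <- log(dimPpmValues)
  pad <- max(0.2, 0.05 * diff(range(y)))
  graphics::plot(grp, y, xlim = c(0.5, nlevels(labels) + 0.5),
                 ylim = range(y) + c(-pad, pad),
                 xaxt = "n", pch = 19, col = grp,
                 xlab = "", ylab = "ln(DIM [ppm])", main = main)
  graphics::axis(1, at = seq_len(nlevels(labels)), labels = levels(labels),
                 las = 2)
  invisible(NULL)
}

#' Tiled difference-image mosaic between two directions
#'
#' Per-slice mosaic of volume_i - volume_j with a symmetric gray window
#' around zero; ghosting or motion between the two directions shows up as
#' structured residuals (a half-FOV ghost appears as a displaced copy of
#' the phantom rim).
#'
#' @param dataset a \linkS4class{HardiDataset}.
#' @param i,j distinct volume indices (1-based).
#' @param window symmetric window half-width; defaults to the 99th
#'   percentile of |difference|.
#' @return invisibly, the difference 3D array.
#' @export
diffImageMosaic <- function(dataset, i, j, window = NULL) {
  nvol <- dim(dataset@data)[4]
  if (i == j) stop("i and j must differ")
  if (min(i, j) < 1L || max(i, j) > nvol) stop("volume index out of range")
  d3 <- dataset@data[, , , i] - dataset@data[, , , j]
  if (is.null(window)) {
    window <- stats::quantile(abs(d3), 0.99)
    if (window == 0) window <- 1
  }
  nz <- dim(d3)[3]
  ncolTiles <- ceiling(sqrt(nz))
  nrowTiles <- ceiling(nz / ncolTiles)
  nx <- dim(d3)[1]; ny <- dim(d3)[2]
  mosaic <- matrix(0, nrowTiles * nx, ncolTiles * ny)
  for (z in seq_len(nz)) {
    r <- (z - 1) %/% ncolTiles
    cl <- (z - 1) %% ncolTiles
    mosaic[r * nx + seq_len(nx), cl * ny + seq_len(ny)] <- d3[, , z]
  }
  mosaic <- pmin(pmax(mosaic, -window), window)
  graphics::image(mosaic[, ncol(mosaic):1], zlim = c(-window, window),
                  col = grDevices::gray.colors(128), axes = FALSE,
                  main = sprintf("Difference: volume %d - volume %d", i, j),
                  useRaster = TRUE)
  invisible(d3)
}
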
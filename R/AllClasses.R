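#' @useDynLib pwlsfr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Fan-beam scan geometry
#'
#' Describes one fan-beam acquisition: a point source and a (curved
#' equiangular or flat equispaced) detector rotating on a circle around the
#' isocenter, with views uniformly spaced over \code{angularRange}.
#'
#' @slot nViews number of projection views.
#' @slot angularRange total angular range of the orbit, degrees, in (0, 360].
#' @slot nBins number of detector bins per view.
#' @slot sourceToDetector distance from the source to the detector, mm.
#' @slot centerToDetector distance from the rotation axis to the detector, mm.
#' @slot detectorExtent total detector length (arc length for a curved
#'   detector), mm.
#' @slot detectorShape \code{"curved"} (equiangular bins) or \code{"flat"}
#'   (equispaced bins).
#'
#' @details The source-to-isocenter distance is
#' \code{sourceToDetector - centerToDetector}. View angle 0 places the source
#' on the +x axis; angles increase counter-clockwise. Detector bins are
#' indexed from 0 with the central ray falling between the two middle bins.
#'
#' @seealso [makeGeometry()], [viewAngles()], [fanOffsets()]
#' @export
setClass("ScanGeometry",
  representation(
    nViews = "integer",
    angularRange = "numeric",
    nBins = "integer",
    sourceToDetector = "numeric",
    centerToDetector = "numeric",
    detectorExtent = "numeric",
    detectorShape = "character"
  )
)

setValidity("ScanGeometry", function(object) {
  msg <- character()
  if (length(object@nViews) != 1L || is.na(object@nViews) || object@nViews < 1L)
    msg <- c(msg, "nViews must be a single integer >= 1")
  if (length(object@nBins) != 1L || is.na(object@nBins) || object@nBins < 1L)
    msg <- c(msg, "nBins must be a single integer >= 1")
  if (!(object@angularRange > 0 && object@angularRange <= 360))
    msg <- c(msg, "angularRange must lie in (0, 360] degrees")
  for (s in c("sourceToDetector", "centerToDetector", "detectorExtent")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, paste(s, "must be a single positive number"))
  }
  if (length(msg) == 0 && object@sourceToDetector <= object@centerToDetector)
    msg <- c(msg, "sourceToDetector must exceed centerToDetector (source outside the object)")
  if (!object@detectorShape %in% c("curved", "flat"))
    msg <- c(msg, "detectorShape must be 'curved' or 'flat'")
  if (length(msg)) msg else TRUE
})

#' Reconstruction image grid
#'
#' A square-pixel grid of \code{nRows} x \code{nCols} pixels of side
#' \code{pixelSize} mm, centered on the rotation axis. Pixels are addressed
#' 0-based with pixel (0, 0) at the top-left; pixel (r, c) has its center at
#' x = xmin + (c + 0.5) h, y = ymax - (r + 0.5) h.
#'
#' @slot nRows,nCols grid dimensions (pixels).
#' @slot pixelSize pixel side length, mm.
#' @seealso [makeGrid()], [defaultGrid()]
#' @export
setClass("ImageGrid",
  representation(nRows = "integer", nCols = "integer", pixelSize = "numeric")
)

setValidity("ImageGrid", function(object) {
  msg <- character()
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "grid dimensions must be >= 1")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be positive")
  if (length(msg)) msg else TRUE
})

#' Attenuation image
#'
#' A 2-D map of linear attenuation coefficients (mm^-1) on an [ImageGrid].
#' Used for ground-truth phantoms, reconstructions, and intermediate
#' iterates; intermediate iterates may contain negative values (the
#' non-negativity clamp is applied only in the feature-refinement step).
#'
#' @slot grid the [ImageGrid] the values live on.
#' @slot values numeric matrix, nRows x nCols.
#' @export
setClass("AttenuationImage",
  representation(grid = "ImageGrid", values = "matrix")
)

setValidity("AttenuationImage", function(object) {
  msg <- character()
  if (nrow(object@values) != object@grid@nRows ||
      ncol(object@values) != object@grid@nCols)
    msg <- c(msg, "values dimensions must match the grid")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' Sinogram
#'
#' Line integrals of attenuation (dimensionless), one row per view and one
#' column per detector bin, tied to the [ScanGeometry] that produced them.
#'
#' @slot geometry the [ScanGeometry].
#' @slot values numeric matrix, nViews x nBins.
#' @export
setClass("Sinogram",
  representation(geometry = "ScanGeometry", values = "matrix")
)

setValidity("Sinogram", function(object) {
  msg <- character()
  if (nrow(object@values) != object@geometry@nViews ||
      ncol(object@values) != object@geometry@nBins)
    msg <- c(msg, "values must be nViews x nBins")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn ScanGeometry-class compact display
#' @param object a \code{ScanGeometry}
#' @export
setMethod("show", "ScanGeometry", function(object) {
  cat(sprintf(
    "ScanGeometry: %d views / %.4g deg, %d %s bins\n  source-detector %.4g mm, center-detector %.4g mm, extent %.4g mm\n",
    object@nViews, object@angularRange, object@nBins,
    object@detectorShape, object@sourceToDetector,
    object@centerToDetector, object@detectorExtent))
})

#' @describeIn ImageGrid-class compact display
#' @param object an \code{ImageGrid}
#' @export
setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid: %d x %d pixels, %.4g mm/pixel (FOV %.4g x %.4g mm)\n",
              object@nRows, object@nCols, object@pixelSize,
              object@nCols * object@pixelSize, object@nRows * object@pixelSize))
})

#' @describeIn AttenuationImage-class compact display
#' @param object an \code{AttenuationImage}
#' @export
setMethod("show", "AttenuationImage", function(object) {
  v <- object@values
  cat(sprintf("AttenuationImage: %d x %d, range [%.4g, %.4g] mm^-1\n",
              nrow(v), ncol(v), min(v), max(v)))
})

#' @describeIn Sinogram-class compact display
#' @param object a \code{Sinogram}
#' @export
setMethod("show", "Sinogram", function(object) {
  v <- object@values
  cat(sprintf("Sinogram: %d views x %d bins, range [%.4g, %.4g]\n",
              nrow(v), ncol(v), min(v), max(v)))
})
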
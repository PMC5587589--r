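#' Create a fan-beam scan geometry
#'
#' Builds a validated [ScanGeometry-class], either from one of the built-in
#' presets or from a complete set of explicit parameters. Presets:
#' \describe{
#'   \item{xcat_sparse}{sparse-view head protocol: 120 views over 360 degrees,
#'     672 bins, source-to-detector 1040 mm, center-to-detector 570 mm,
#'     curved detector. The detector extent is sized so that the fan
#'     inscribes a 200 mm-radius field of view.}
#'   \item{xcat_dense}{the densely sampled reference scan of the same
#'     system: 1160 views.}
#'   \item{micro_sparse}{small-animal protocol: 225 views over 360 degrees,
#'     4000 bins on a 50.12 mm curved detector arc, object-to-source 121 mm,
#'     object-to-detector 165 mm.}
#'   \item{micro_dense}{the same system with 450 views.}
#'   \item{micro_limited}{limited-angle variant: 291 views over 197.88
#'     degrees.}
#' }
#'
#' @param preset preset name, or \code{NULL} to use explicit parameters.
#' @param nViews,angularRange,nBins,sourceToDetector,centerToDetector,
#'   detectorExtent,detectorShape explicit geometry parameters; any of them
#'   overrides the preset value (useful for scaled-down experiments).
#'
#' @details View angles are uniformly spaced over \code{angularRange} with
#' spacing \code{angularRange / nViews}, starting at 0 (the end point is
#' excluded, so a 360-degree orbit has no duplicated view).
#'
#' @return a [ScanGeometry-class]
#' @examples
#' g <- makeGeometry("xcat_sparse")
#' viewAngles(g)[1:3]
#' @export
makeGeometry <- function(preset = NULL,
                         nViews = NULL, angularRange = NULL, nBins = NULL,
                         sourceToDetector = NULL, centerToDetector = NULL,
                         detectorExtent = NULL, detectorShape = NULL) {
  p <- list()
  if (!is.null(preset)) {
    presets <- list(
      xcat_sparse = list(nViews = 120L, angularRange = 360, nBins = 672L,
                         sourceToDetector = 1040, centerToDetector = 570,
                         detectorExtent = 2 * asin(200 / 470) * 1040,
                         detectorShape = "curved"),
      micro_sparse = list(nViews = 225L, angularRange = 360, nBins = 4000L,
                          sourceToDetector = 286, centerToDetector = 165,
                          detectorExtent = 50.12, detectorShape = "curved"),
      micro_limited = list(nViews = 291L, angularRange = 197.88, nBins = 4000L,
                           sourceToDetector = 286, centerToDetector = 165,
                           detectorExtent = 50.12, detectorShape = "curved")
    )
    presets$xcat_dense <- utils::modifyList(presets$xcat_sparse,
                                            list(nViews = 1160L))
    presets$micro_dense <- utils::modifyList(presets$micro_sparse,
                                             list(nViews = 450L))
    if (!preset %in% names(presets))
      stop("unknown geometry preset: '", preset, "'")
    p <- presets[[preset]]
  }
  override <- list(nViews = nViews, angularRange = angularRange, nBins = nBins,
                   sourceToDetector = sourceToDetector,
                   centerToDetector = centerToDetector,
                   detectorExtent = detectorExtent,
                   detectorShape = detectorShape)
  p <- utils::modifyList(p, Filter(Negate(is.null), override))
  need <- c("nViews", "angularRange", "nBins", "sourceToDetector",
            "centerToDetector", "detectorExtent", "detectorShape")
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("incomplete geometry: missing ", paste(missing, collapse = ", "))
  if (!is.finite(p$nViews) || p$nViews < 1)
    stop("nViews must be a positive count")
  if (!is.finite(p$nBins) || p$nBins < 1)
    stop("nBins must be a positive count")
  new("ScanGeometry",
      nViews = as.integer(p$nViews), angularRange = as.numeric(p$angularRange),
      nBins = as.integer(p$nBins),
      sourceToDetector = as.numeric(p$sourceToDetector),
      centerToDetector = as.numeric(p$centerToDetector),
      detectorExtent = as.numeric(p$detectorExtent),
      detectorShape = p$detectorShape)
}

#' Source-to-isocenter distance of a geometry, mm
#' @param geom a [ScanGeometry-class]
#' @export
sourceToCenter <- function(geom) geom@sourceToDetector - geom@centerToDetector

#' View angles of a scan, degrees
#'
#' Uniformly spaced over the angular range with spacing
#' \code{angularRange / nViews}, starting at 0.
#' @param geom a [ScanGeometry-class]
#' @return numeric vector of length \code{nViews}
#' @export
viewAngles <- function(geom) {
  seq(0, by = geom@angularRange / geom@nViews, length.out = geom@nViews)
}

#' Detector bin offsets
#'
#' For a curved detector, the fan angle gamma of each bin center (radians,
#' relative to the central ray); for a flat detector, the lateral offset s of
#' each bin center on the detector (mm). Bins are centered: the central ray
#' falls midway between the two middle bins.
#' @param geom a [ScanGeometry-class]
#' @return numeric vector of length \code{nBins}
#' @export
fanOffsets <- function(geom) {
  nb <- geom@nBins
  if (geom@detectorShape == "curved") {
    dg <- geom@detectorExtent / geom@sourceToDetector / nb
    (seq_len(nb) - 1 - (nb - 1) / 2) * dg
  } else {
    ds <- geom@detectorExtent / nb
    (seq_len(nb) - 1 - (nb - 1) / 2) * ds
  }
}

#' Radius of the field of view inscribed in the fan, mm
#' @param geom a [ScanGeometry-class]
#' @export
fovRadius <- function(geom) {
  dso <- sourceToCenter(geom)
  if (geom@detectorShape == "curved") {
    half <- geom@detectorExtent / geom@sourceToDetector / 2
  } else {
    half <- atan(geom@detectorExtent / 2 / geom@sourceToDetector)
  }
  dso * sin(half)
}

#' Create an image grid
#' @param nRows,nCols grid dimensions in pixels.
#' @param pixelSize pixel side, mm.
#' @return an [ImageGrid-class]
#' @export
makeGrid <- function(nRows, nCols = nRows, pixelSize) {
  new("ImageGrid", nRows = as.integer(nRows), nCols = as.integer(nCols),
      pixelSize = as.numeric(pixelSize))
}

#' Default reconstruction grid for a geometry
#'
#' A square n x n grid whose square field of view inscribes the fan beam
#' (pixel size \code{2 * fovRadius(geom) / n}). When \code{n} is omitted it
#' defaults to 512 for small-bore (micro) systems with a field of view under
#' 50 mm and 256 otherwise.
#' @param geom a [ScanGeometry-class]
#' @param n grid side, pixels.
#' @return an [ImageGrid-class]
#' @export
defaultGrid <- function(geom, n = NULL) {
  r <- fovRadius(geom)
  if (is.null(n)) n <- if (r < 50) 512L else 256L
  makeGrid(n, n, 2 * r / n)
}

#' Wrap a numeric matrix as an attenuation image
#' @param vals numeric matrix (or a single number recycled to the grid).
#' @param grid an [ImageGrid-class]
#' @return an [AttenuationImage-class]
#' @export
attenuationImage <- function(vals, grid) {
  if (length(vals) == 1L)
    vals <- matrix(vals, grid@nRows, grid@nCols)
  new("AttenuationImage", grid = grid, values = vals)
}

#' Wrap a numeric matrix as a sinogram
#' @param vals numeric matrix, nViews x nBins (or a single number recycled).
#' @param geom a [ScanGeometry-class]
#' @return a [Sinogram-class]
#' @export
sinogram <- function(vals, geom) {
  if (length(vals) == 1L)
    vals <- matrix(vals, geom@nViews, geom@nBins)
  new("Sinogram", geometry = geom, values = vals)
}

# One ray per (view, bin): source position and unit direction, in sinogram
# element order (views vary fastest, matching as.vector of a nViews x nBins
# matrix). Shared by the Siddon projector and the analytic ellipse sinogram
# so both integrate along identical rays.
rayTable <- function(geom) {
  beta <- viewAngles(geom) * pi / 180
  dso <- sourceToCenter(geom)
  nv <- geom@nViews
  nb <- geom@nBins
  sxv <- dso * cos(beta)
  syv <- dso * sin(beta)
  uxv <- -cos(beta)
  uyv <- -sin(beta)
  off <- fanOffsets(geom)
  if (geom@detectorShape == "curved") {
    g <- rep(off, each = nv)
    ux <- rep(uxv, nb); uy <- rep(uyv, nb)
    cg <- cos(g); sg <- sin(g)
    dx <- cg * ux - sg * uy
    dy <- sg * ux + cg * uy
  } else {
    sdd <- geom@sourceToDetector
    s <- rep(off, each = nv)
    ux <- rep(uxv, nb); uy <- rep(uyv, nb)
    wxv <- -uy; wyv <- ux
    px <- sdd * ux + s * wxv
    py <- sdd * uy + s * wyv
    nrm <- sqrt(px^2 + py^2)
    dx <- px / nrm; dy <- py / nrm
  }
  list(sx = rep(sxv, nb), sy = rep(syv, nb), dx = dx, dy = dy)
}

gridXmin <- function(grid) -grid@nCols * grid@pixelSize / 2
gridYmax <- function(grid) grid@nRows * grid@pixelSize / 2

#' Write / read a scan geometry as a plain-text config block
#'
#' One \code{key: value} pair per field (YAML), so geometries can be stored
#' alongside sinograms and reloaded exactly.
#' @param geom a [ScanGeometry-class]
#' @param path file path
#' @return \code{readGeometry} returns a [ScanGeometry-class]
#' @export
writeGeometry <- function(geom, path) {
  yaml::write_yaml(geometryToList(geom), path)
  invisible(path)
}

#' @rdname writeGeometry
#' @export
readGeometry <- function(path) {
  geometryFromList(yaml::read_yaml(path))
}

geometryToList <- function(geom) {
  list(nViews = geom@nViews, angularRange = geom@angularRange,
       nBins = geom@nBins, sourceToDetector = geom@sourceToDetector,
       centerToDetector = geom@centerToDetector,
       detectorExtent = geom@detectorExtent,
       detectorShape = geom@detectorShape)
}

geometryFromList <- function(x) {
  do.call(makeGeometry, c(list(preset = NULL), x))
}
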
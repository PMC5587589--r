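#' Fan-beam forward projection
#'
#' Computes the line integrals of an attenuation image along every ray of a
#' fan-beam scan: the linear operator G of the reconstruction problem. One
#' ray is traced per detector bin, with exact pixel intersection lengths
#' (Siddon weights), so each sinogram entry is \eqn{\sum_j l_{ij} \mu_j} with
#' \eqn{l_{ij}} the chord length (mm) of ray i inside pixel j.
#'
#' @param image an [AttenuationImage-class]
#' @param geom a [ScanGeometry-class]
#' @return a [Sinogram-class] containing \eqn{G\mu}
#' @seealso [backProject()] for the exact transpose
#' @export
setGeneric("forwardProject",
           function(image, geom) standardGeneric("forwardProject"))

#' @rdname forwardProject
#' @export
setMethod("forwardProject", signature("AttenuationImage", "ScanGeometry"),
  function(image, geom) {
    grid <- image@grid
    checkFieldOfView(grid, geom)
    rays <- rayTable(geom)
    v <- .cpp_forward_project(image@values, rays$sx, rays$sy, rays$dx, rays$dy,
                              gridXmin(grid), gridYmax(grid), grid@pixelSize)
    sinogram(matrix(v, geom@nViews, geom@nBins), geom)
  })

#' Fan-beam back projection (exact transpose of the forward projector)
#'
#' Applies \eqn{G^T} to a sinogram: every ray scatters its value into the
#' pixels it crosses with the same intersection-length weights used by
#' [forwardProject()], so the pair satisfies the adjoint identity
#' \eqn{\langle G x, y\rangle = \langle x, G^T y\rangle} to machine
#' precision. This is the unfiltered transpose used inside the iterative
#' update, not a filtered back-projection (see [fbpReconstruct()]).
#'
#' @param sino a [Sinogram-class]
#' @param geom a [ScanGeometry-class]; must match the sinogram's geometry
#' @param grid the target [ImageGrid-class]
#' @return an [AttenuationImage-class] containing \eqn{G^T y}
#' @export
setGeneric("backProject",
           function(sino, geom, grid) standardGeneric("backProject"))

#' @rdname backProject
#' @export
setMethod("backProject", signature("Sinogram", "ScanGeometry", "ImageGrid"),
  function(sino, geom, grid) {
    if (!identical(dim(sino@values), c(geom@nViews, geom@nBins)))
      stop("sinogram shape does not match the geometry")
    checkFieldOfView(grid, geom)
    rays <- rayTable(geom)
    img <- .cpp_back_project(as.vector(sino@values),
                             rays$sx, rays$sy, rays$dx, rays$dy,
                             gridXmin(grid), gridYmax(grid), grid@pixelSize,
                             grid@nRows, grid@nCols)
    attenuationImage(img, grid)
  })

# the source must stay outside the reconstruction grid
checkFieldOfView <- function(grid, geom) {
  half_diag <- sqrt((grid@nRows^2 + grid@nCols^2)) * grid@pixelSize / 2
  if (half_diag >= sourceToCenter(geom))
    stop("image grid extends beyond the source orbit; shrink the grid or ",
         "its pixel size")
  invisible(TRUE)
}
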
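#' Extract the numeric array from a container
#'
#' @param x an [AttenuationImage-class] or [Sinogram-class]
#' @return the underlying numeric matrix
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname values
#' @export
setMethod("values", "AttenuationImage", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "Sinogram", function(x) x@values)

#' Extract the scan geometry of a sinogram
#' @param x a [Sinogram-class]
#' @return the [ScanGeometry-class]
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname geometry
#' @export
setMethod("geometry", "Sinogram", function(x) x@geometry)

#' Extract the image grid of an attenuation image
#' @param x an [AttenuationImage-class]
#' @return the [ImageGrid-class]
#' @export
setGeneric("imageGrid", function(x) standardGeneric("imageGrid"))

#' @rdname imageGrid
#' @export
setMethod("imageGrid", "AttenuationImage", function(x) x@grid)
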
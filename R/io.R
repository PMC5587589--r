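#' Write / read a sinogram (with optional weights) as self-describing text
#'
#' Plain-text storage: a YAML header in \code{#}-comment lines carrying the
#' scan geometry, the simulation seed (if any) and layout, followed by the
#' sinogram values as tab-separated rows (one view per row) and, when
#' present, the per-ray variance map in the same layout. Round-trips
#' exactly at full double precision.
#'
#' @param sino a [Sinogram-class]
#' @param path output file
#' @param weights optional per-ray variance matrix
#' @param seed optional integer seed recorded in the metadata
#' @return \code{readSinogram} returns a list with \code{sinogram},
#'   \code{weights} (or NULL) and \code{seed} (or NULL)
#' @export
writeSinogram <- function(sino, path, weights = NULL, seed = NULL) {
  geom <- sino@geometry
  meta <- list(geometry = geometryToList(geom),
               seed = seed,
               hasWeights = !is.null(weights))
  hdr <- strsplit(yaml::as.yaml(meta), "\n")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", hdr), con)
  fmt <- function(m) apply(m, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = "\t"))
  writeLines(fmt(sino@values), con)
  if (!is.null(weights)) {
    if (!identical(dim(weights), dim(sino@values)))
      stop("weights shape must match the sinogram")
    writeLines(fmt(weights), con)
  }
  invisible(path)
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  meta <- yaml::yaml.load(paste(sub("^# ?", "", lines[is_hdr]),
                                collapse = "\n"))
  geom <- geometryFromList(meta$geometry)
  body <- lines[!is_hdr]
  nv <- geom@nViews
  expect <- nv * (1L + isTRUE(meta$hasWeights))
  if (length(body) != expect)
    stop("corrupt sinogram file: expected ", expect, " data rows, found ",
         length(body))
  parse <- function(rows) {
    do.call(rbind, lapply(rows, function(l)
      as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
  }
  vals <- parse(body[1:nv])
  w <- if (isTRUE(meta$hasWeights)) parse(body[(nv + 1):(2 * nv)]) else NULL
  list(sinogram = sinogram(vals, geom), weights = w, seed = meta$seed)
}

#' Write / read an attenuation image as 32-bit TIFF
#'
#' Values are affinely rescaled to [0, 1] and stored as 32-bit samples; the
#' offset/scale and the pixel size go into a small YAML sidecar
#' (\code{<path>.yaml}) so physical attenuation values and the grid
#' round-trip (quantization error below 1e-11 of the value range). Reading
#' falls back to raw sample values and pixel size 1 mm when the sidecar is
#' absent.
#' @param image an [AttenuationImage-class]
#' @param path output TIFF path
#' @return \code{readImageTiff} returns an [AttenuationImage-class]
#' @export
writeImageTiff <- function(image, path) {
  v <- image@values
  lo <- min(v)
  hi <- max(v)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((v - lo) / scale, path, bits.per.sample = 32L,
                  reduce = FALSE)
  yaml::write_yaml(list(pixelSize = image@grid@pixelSize,
                        offset = lo, scale = scale),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeImageTiff
#' @export
readImageTiff <- function(path) {
  v <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  ps <- meta$pixelSize %||% 1
  v <- v * (meta$scale %||% 1) + (meta$offset %||% 0)
  attenuationImage(v, makeGrid(nrow(v), ncol(v), ps))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a per-iteration history table as CSV
#' @param report an \code{EvaluationReport} from [reconstruct()]
#' @param path output CSV path
#' @export
writeHistory <- function(report, path) {
  utils::write.csv(report$history, path, row.names = FALSE)
  invisible(path)
}
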
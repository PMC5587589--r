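#' Ellipse phantom description
#'
#' An additive superposition of ellipses, each contributing a constant
#' attenuation increment inside its boundary. Used both to rasterize
#' ground-truth images and to compute exact analytic line integrals.
#'
#' @param cx,cy ellipse centers, mm.
#' @param a,b semi-axes along the (un-rotated) x and y directions, mm.
#' @param phi counter-clockwise rotation, degrees.
#' @param delta attenuation increment inside the ellipse, mm^-1 (may be
#'   negative for cavities; the composite must stay non-negative).
#' @return a data frame of class \code{EllipsePhantom}
#' @export
ellipsePhantom <- function(cx = numeric(), cy = numeric(), a = numeric(),
                           b = numeric(), phi = numeric(),
                           delta = numeric()) {
  ph <- data.frame(cx = cx, cy = cy, a = a, b = b, phi = phi, delta = delta)
  if (nrow(ph) && any(ph$a <= 0 | ph$b <= 0))
    stop("degenerate ellipse: semi-axes must be positive")
  class(ph) <- c("EllipsePhantom", "data.frame")
  ph
}

# built-in phantoms in normalized coordinates (unit = phantom scale, applied
# later); a Shepp-Logan-like head and an asymmetric object for limited-angle
# experiments
phantomPreset <- function(preset) {
  switch(preset,
    head = ellipsePhantom(
      cx    = c(0, 0,      0.22, -0.22, 0,    0,    0,     -0.08, 0,     0.06),
      cy    = c(0, -0.0184, 0,    0,    0.35, 0.1,  -0.1,  -0.605, -0.605, -0.605),
      a     = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
      b     = c(0.92, 0.874,  0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
      phi   = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0),
      delta = c(0.019, -0.0092, -0.002, -0.002, 0.0015,
                0.001, 0.001, 0.001, 0.001, 0.001)),
    asymmetric = ellipsePhantom(
      cx    = c(0.05, 0.05, -0.3, 0.3,  0.25, -0.2, 0.0),
      cy    = c(-0.08, -0.08, 0.25, 0.1, -0.45, -0.3, 0.45),
      a     = c(0.8,  0.72, 0.22, 0.15, 0.3,  0.05, 0.04),
      b     = c(0.72, 0.64, 0.34, 0.10, 0.08, 0.05, 0.08),
      phi   = c(10, 10, 40, -30, 65, 0, 20),
      delta = c(0.016, -0.006, 0.004, -0.005, 0.006, 0.005, -0.004)),
    empty = ellipsePhantom(),
    stop("unknown phantom preset: '", preset, "'")
  )
}

#' Generate a head-like ellipse phantom on a grid
#'
#' Rasterizes one of the built-in ellipse phantoms onto an image grid, scaled
#' to fill 95% of the grid's half-extent. The \code{"head"} preset is a
#' skull-like composite of 10 ellipses (outer high-attenuation shell, brain
#' matter, ventricles, and several small low-contrast insets) with composite
#' attenuation in roughly [0, 0.02] mm^-1; \code{"asymmetric"} is an
#' off-center object without mirror symmetry, useful for limited-angle
#' studies; \code{"empty"} has no ellipses.
#'
#' @param grid an [ImageGrid-class] of at least 32 x 32 pixels.
#' @param preset \code{"head"} (default), \code{"asymmetric"} or
#'   \code{"empty"}.
#' @param oversample subpixel sampling factor per axis for anti-aliased
#'   rasterization (area-weight approximation at ellipse boundaries).
#' @return a list with \code{image} (an [AttenuationImage-class]) and
#'   \code{phantom} (the scaled [ellipsePhantom()] in mm units).
#' @export
makeHeadPhantom <- function(grid, preset = "head", oversample = 3L) {
  if (grid@nRows < 32L || grid@nCols < 32L)
    stop("grid too small for a phantom (need at least 32 x 32)")
  ph <- phantomPreset(preset)
  half <- min(grid@nRows, grid@nCols) * grid@pixelSize / 2
  s <- 0.95 * half / 0.92   # outer semi-axis of the presets is 0.92
  ph_mm <- ph
  ph_mm[c("cx", "cy", "a", "b")] <- ph[c("cx", "cy", "a", "b")] * s
  img <- rasterizePhantom(ph_mm, grid, oversample = oversample)
  list(image = img, phantom = ph_mm)
}

#' Rasterize an ellipse phantom
#'
#' Deterministic rasterization: each pixel value is the mean of
#' \code{oversample^2} subpixel point evaluations of the additive ellipse
#' superposition.
#' @param phantom an [ellipsePhantom()]
#' @param grid an [ImageGrid-class]
#' @param oversample subpixel factor per axis (1 = pixel centers only)
#' @return an [AttenuationImage-class]
#' @export
rasterizePhantom <- function(phantom, grid, oversample = 3L) {
  o <- as.integer(oversample)
  stopifnot(o >= 1L)
  nrq <- grid@nRows * o
  ncq <- grid@nCols * o
  hq <- grid@pixelSize / o
  x <- gridXmin(grid) + (seq_len(ncq) - 0.5) * hq
  y <- gridYmax(grid) - (seq_len(nrq) - 0.5) * hq
  X <- matrix(x, nrq, ncq, byrow = TRUE)
  Y <- matrix(y, nrq, ncq)
  fine <- matrix(0, nrq, ncq)
  for (i in seq_len(nrow(phantom))) {
    e <- phantom[i, ]
    cphi <- cos(-e$phi * pi / 180)
    sphi <- sin(-e$phi * pi / 180)
    xr <- (cphi * (X - e$cx) - sphi * (Y - e$cy)) / e$a
    yr <- (sphi * (X - e$cx) + cphi * (Y - e$cy)) / e$b
    fine <- fine + e$delta * (xr * xr + yr * yr <= 1)
  }
  if (o > 1L) {
    # block-average o x o subpixels
    v <- colMeans(matrix(fine, nrow = o))          # average within columns of rows
    v <- matrix(v, grid@nRows, ncq)
    v <- t(matrix(colMeans(matrix(t(v), nrow = o)), grid@nCols, grid@nRows))
  } else {
    v <- fine
  }
  attenuationImage(v, grid)
}

#' Analytic fan-beam sinogram of an ellipse phantom
#'
#' Exact line integrals: each ray's value is the sum over ellipses of
#' (attenuation increment x chord length), with the chord from the
#' closed-form ray/ellipse quadratic. Uses the same ray table as the discrete
#' projector, so the two are directly comparable.
#'
#' @param phantom an [ellipsePhantom()] in mm units
#' @param geom a [ScanGeometry-class]
#' @return a [Sinogram-class]
#' @export
analyticSinogram <- function(phantom, geom) {
  if (nrow(phantom) && any(phantom$a <= 0 | phantom$b <= 0))
    stop("degenerate ellipse: semi-axes must be positive")
  rays <- rayTable(geom)
  vals <- numeric(length(rays$sx))
  for (i in seq_len(nrow(phantom))) {
    e <- phantom[i, ]
    cphi <- cos(-e$phi * pi / 180)
    sphi <- sin(-e$phi * pi / 180)
    px <- (cphi * (rays$sx - e$cx) - sphi * (rays$sy - e$cy)) / e$a
    py <- (sphi * (rays$sx - e$cx) + cphi * (rays$sy - e$cy)) / e$b
    qx <- (cphi * rays$dx - sphi * rays$dy) / e$a
    qy <- (sphi * rays$dx + cphi * rays$dy) / e$b
    A <- qx * qx + qy * qy
    B <- 2 * (px * qx + py * qy)
    C <- px * px + py * py - 1
    disc <- B * B - 4 * A * C
    hit <- disc > 0
    vals[hit] <- vals[hit] + e$delta * sqrt(disc[hit]) / A[hit]
  }
  sinogram(matrix(vals, geom@nViews, geom@nBins), geom)
}

#' Transmission noise model
#'
#' Photon-counting model for low-dose projections: the detected counts along
#' ray i are Poisson with mean \code{I0 * exp(-y_i)} where \code{y_i} is the
#' noise-free line integral, with an electronic floor \code{epsilon} below
#' which counts are clipped (so the log transform stays finite).
#'
#' @param I0 incident photons per ray (blank-scan intensity).
#' @param epsilon count floor, >= 1.
#' @param seed integer seed; every simulated sinogram is reproducible from
#'   it.
#' @return a list of class \code{NoiseModel}
#' @export
noiseModel <- function(I0, epsilon = 1, seed = 1L) {
  if (!is.finite(I0) || I0 <= 0) stop("I0 must be positive")
  if (epsilon < 1) stop("epsilon must be >= 1")
  structure(list(I0 = I0, epsilon = epsilon, seed = as.integer(seed)),
            class = "NoiseModel")
}

#' Add transmission (Poisson) noise to a clean sinogram
#'
#' Draws counts \code{N_i ~ Poisson(I0 exp(-y_i))}, clips them below at the
#' electronic floor, and returns the noisy log-transformed line integrals
#' \code{y_i = log(I0 / N_i)} together with the delta-method per-ray variance
#' estimates \code{sigma_i^2 = exp(y_i) / I0} that define the diagonal
#' statistical weighting matrix of the PWLS data term. Variances are floored
#' at 1e-12 so their inverses stay bounded.
#'
#' For count means above 1e7 the Poisson draw uses a rounded Gaussian
#' approximation (mean lambda, sd sqrt(lambda)), which is numerically
#' indistinguishable at that scale and supports arbitrarily large \code{I0}.
#'
#' @param clean a [Sinogram-class] with non-negative values.
#' @param model a [noiseModel()]
#' @return a list with \code{sinogram} (noisy [Sinogram-class]) and
#'   \code{weights} (matrix of per-ray variance estimates)
#' @export
addTransmissionNoise <- function(clean, model) {
  stopifnot(inherits(model, "NoiseModel"))
  y <- clean@values
  if (any(y < 0)) stop("clean sinogram must be non-negative")
  lambda <- model$I0 * exp(-y)
  counts <- withr::with_seed(model$seed, {
    n <- lambda
    small <- lambda < 1e7
    n[small] <- stats::rpois(sum(small), lambda[small])
    if (any(!small))
      n[!small] <- round(lambda[!small] +
                           sqrt(lambda[!small]) * stats::rnorm(sum(!small)))
    n
  })
  counts <- pmax(counts, model$epsilon)
  ynoisy <- log(model$I0 / counts)
  var <- pmax(exp(ynoisy) / model$I0, 1e-12)
  list(sinogram = sinogram(matrix(ynoisy, nrow(y), ncol(y)), clean@geometry),
       weights = matrix(var, nrow(y), ncol(y)))
}

#' Identity statistical weights (unweighted least squares)
#'
#' All per-ray variances equal to 1, reducing the weighted data term to
#' ordinary least squares. Used when no noise model is available.
#' @param geom a [ScanGeometry-class]
#' @return matrix of ones, nViews x nBins
#' @export
identityWeights <- function(geom) {
  matrix(1, geom@nViews, geom@nBins)
}
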
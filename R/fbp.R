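#' FBP filter specification
#'
#' @param kind \code{"hamming"} (Hamming-windowed ramp, the default) or
#'   \code{"ram-lak"} (pure band-limited ramp).
#' @param cutoff frequency cutoff as a fraction of the detector Nyquist
#'   frequency, in (0, 1].
#' @return a list of class \code{FbpFilterSpec}
#' @export
fbpFilter <- function(kind = c("hamming", "ram-lak"), cutoff = 1) {
  kind <- match.arg(kind)
  if (!(cutoff > 0 && cutoff <= 1)) stop("cutoff must lie in (0, 1]")
  structure(list(kind = kind, cutoff = cutoff), class = "FbpFilterSpec")
}

# band-limited ramp kernel samples h(n * delta), n = 0..nmax
rampKernel <- function(nmax, delta) {
  n <- 0:nmax
  h <- numeric(nmax + 1)
  h[1] <- 1 / (4 * delta^2)
  odd <- which(n %% 2 == 1)
  h[odd] <- -1 / (pi * n[odd] * delta)^2
  h
}

#' Fan-beam filtered back-projection
#'
#' Standard fan-beam FBP for a curved equiangular or flat equispaced
#' detector: cosine (curved) or \eqn{D/\sqrt{D^2+s^2}} (flat) pre-weighting
#' of each bin, ramp filtering along the bin axis (optionally
#' Hamming-windowed), and distance-weighted back projection with the view
#' angular increment as quadrature weight. Deterministic and linear in the
#' sinogram.
#'
#' Limited-angle scans are reconstructed with the same formula over the
#' available range, with no short-scan (Parker) weighting or missing-wedge
#' compensation — intentionally the naive baseline that iterative methods
#' are compared against.
#'
#' @param sino a [Sinogram-class]
#' @param grid the reconstruction [ImageGrid-class]
#' @param filter an [fbpFilter()] specification
#' @return an [AttenuationImage-class]
#' @export
fbpReconstruct <- function(sino, grid, filter = fbpFilter()) {
  geom <- sino@geometry
  if (geom@nViews < 2L) stop("FBP needs at least 2 views")
  if (grid@nRows < 1L || grid@nCols < 1L) stop("empty reconstruction grid")
  dso <- sourceToCenter(geom)
  nb <- geom@nBins
  nv <- geom@nViews
  p <- sino@values
  curved <- geom@detectorShape == "curved"

  if (curved) {
    gam <- fanOffsets(geom)                    # radians
    dstep <- geom@detectorExtent / geom@sourceToDetector / nb
    p1 <- sweep(p, 2, dso * cos(gam), `*`)
    h <- rampKernel(nb - 1, dstep)
    n <- 0:(nb - 1)
    fac <- rep(1, nb)
    nz <- n > 0
    fac[nz] <- ((n[nz] * dstep) / sin(n[nz] * dstep))^2
    g <- 0.5 * fac * h
  } else {
    # rescale the flat detector to the isocenter line
    s_iso <- fanOffsets(geom) * dso / geom@sourceToDetector
    dstep <- (geom@detectorExtent / nb) * dso / geom@sourceToDetector
    p1 <- sweep(p, 2, dso / sqrt(dso^2 + s_iso^2), `*`)
    g <- 0.5 * rampKernel(nb - 1, dstep)
  }

  # circular FFT convolution on a zero-padded length
  L <- 2^ceiling(log2(2 * nb))
  kern <- numeric(L)
  kern[1] <- g[1]
  if (nb > 1) {
    kern[2:nb] <- g[2:nb]
    kern[L - (1:(nb - 1)) + 1] <- g[2:nb]
  }
  K <- Re(stats::fft(kern))
  # frequency window (cycles/sample, Nyquist = 0.5)
  f <- c(0:(L / 2), (L / 2 - 1):1) / L
  fc <- 0.5 * filter$cutoff
  w <- as.numeric(f <= fc + 1e-12)
  if (filter$kind == "hamming")
    w <- w * (0.54 + 0.46 * cos(pi * f / fc))
  Kw <- K * w

  pad <- rbind(t(p1), matrix(0, L - nb, nv))
  Q <- Re(stats::mvfft(stats::mvfft(pad) * Kw, inverse = TRUE)) / L
  Q <- t(Q[1:nb, , drop = FALSE]) * dstep

  betas <- viewAngles(geom) * pi / 180
  dbeta <- geom@angularRange / nv * pi / 180
  img <- .cpp_fbp_backproject(Q, betas, dso, curved, dstep,
                              if (curved) 0 else dso,
                              gridXmin(grid), gridYmax(grid), grid@pixelSize,
                              grid@nRows, grid@nCols)
  attenuationImage(img * dbeta, grid)
}
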
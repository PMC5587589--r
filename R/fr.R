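#' Feature-refinement configuration
#'
#' @param patchSide side of the square patch used for local statistics; odd,
#'   >= 3 (default 3, i.e. N = 9 pixels per patch).
#' @param C stability constant of the structure descriptor, default
#'   1.25e-5.
#' @param kernelSize,sigma size (odd) and standard deviation (pixels) of the
#'   Gaussian kernel producing the degraded image; defaults 3 and 1.
#' @return a list of class \code{FrConfig}
#' @export
frConfig <- function(patchSide = 3L, C = 1.25e-5, kernelSize = 3L,
                     sigma = 1) {
  patchSide <- as.integer(patchSide)
  kernelSize <- as.integer(kernelSize)
  if (patchSide < 3L || patchSide %% 2L == 0L)
    stop("patchSide must be odd and >= 3")
  if (kernelSize < 1L || kernelSize %% 2L == 0L)
    stop("kernelSize must be odd and >= 1")
  if (!(C > 0)) stop("C must be positive")
  if (!(sigma > 0)) stop("sigma must be positive")
  structure(list(patchSide = patchSide, C = C, kernelSize = kernelSize,
                 sigma = sigma), class = "FrConfig")
}

# mirror (symmetric) padding by r pixels on every side
padMirror <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc) stop("kernel/patch larger than the image")
  ri <- c(r:1, 1:nr, nr:(nr - r + 1))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1))
  m[ri, ci, drop = FALSE]
}

# correlation of m with a small k x k kernel under mirror padding
convolveKernel <- function(m, kernel) {
  k <- nrow(kernel)
  r <- (k - 1L) %/% 2L
  p <- padMirror(m, max(r, 1L))
  off <- if (r == 0L) 1L else 0L   # padMirror pads at least 1
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out <- out + kernel[i, j] *
        p[(i + off):(i + off + nr - 1L), (j + off):(j + off + nc - 1L)]
    }
  }
  out
}

gaussianKernel <- function(size, sigma) {
  r <- (size - 1) / 2
  x <- -r:r
  k <- exp(-outer(x^2, x^2, `+`) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian degradation of an image
#'
#' Convolution with a normalized Gaussian kernel under symmetric (mirror)
#' boundary padding; produces the blurred companion image whose local
#' statistics the structure descriptor compares against. Constant images are
#' exact fixed points and the image mean is preserved up to rounding.
#'
#' @param image an [AttenuationImage-class] or numeric matrix
#' @param config an [frConfig()]
#' @return numeric matrix, same shape
#' @export
degradeImage <- function(image, config = frConfig()) {
  m <- asValues(image)
  if (config$kernelSize > min(dim(m)))
    stop("Gaussian kernel larger than the image")
  convolveKernel(m, gaussianKernel(config$kernelSize, config$sigma))
}

#' Local patch statistics of two images
#'
#' At each pixel i, over the patchSide x patchSide neighborhood centered at
#' i (mirror padding at borders), computes the patch means P(i), Q(i) of the
#' two images, the unbiased (1/(N-1)) patch standard deviations sigma_p,
#' sigma_q, and the patch covariance sigma_qp.
#'
#' @param a,b numeric matrices (or [AttenuationImage-class]) of equal shape;
#'   conventionally the current iterate and its degraded copy.
#' @param config an [frConfig()]
#' @return list of class \code{PatchStats} with matrices \code{meanP},
#'   \code{meanQ}, \code{sigmaP}, \code{sigmaQ}, \code{sigmaQP}
#' @export
localStatistics <- function(a, b, config = frConfig()) {
  a <- asValues(a); b <- asValues(b)
  if (!identical(dim(a), dim(b))) stop("images must have the same shape")
  k <- config$patchSide
  if (k > min(dim(a))) stop("patch larger than the image")
  box <- matrix(1, k, k)   # unit weights + final division keep constants exact
  N <- k^2
  P <- convolveKernel(a, box) / N
  Q <- convolveKernel(b, box) / N
  Ea2 <- convolveKernel(a * a, box) / N
  Eb2 <- convolveKernel(b * b, box) / N
  Eab <- convolveKernel(a * b, box) / N
  fac <- N / (N - 1)
  vp <- pmax(fac * (Ea2 - P^2), 0)
  vq <- pmax(fac * (Eb2 - Q^2), 0)
  cqp <- fac * (Eab - P * Q)
  structure(list(meanP = P, meanQ = Q, sigmaP = sqrt(vp), sigmaQ = sqrt(vq),
                 sigmaQP = cqp), class = "PatchStats")
}

#' Structure descriptor map
#'
#' Per-pixel feature descriptor
#' \deqn{f_t = 1 - \left|\frac{2\sigma_{qp} + C}
#'   {\sigma_p^2 + \sigma_q^2 + C}\right|}
#' built from the local statistics of the image and its Gaussian-degraded
#' copy. Values lie in [0, 1]; larger values mark pixels whose neighborhood
#' changes under blurring, i.e. likely structure (edges, fine detail),
#' while flat regions score 0.
#'
#' @param image the current iterate, [AttenuationImage-class] or matrix
#' @param config an [frConfig()]
#' @return list of class \code{FeatureMap} with \code{ft} (matrix in [0,1]),
#'   \code{stats} (the [localStatistics()]) and \code{degraded} (the blurred
#'   image)
#' @export
featureDescriptor <- function(image, config = frConfig()) {
  m <- asValues(image)
  mud <- degradeImage(m, config)
  st <- localStatistics(m, mud, config)
  C <- config$C
  ft <- 1 - abs((2 * st$sigmaQP + C) / (st$sigmaP^2 + st$sigmaQ^2 + C))
  # the bound |2*sigmaQP + C| <= sigmaP^2 + sigmaQ^2 + C holds exactly;
  # clip only floating-point rounding spill
  ft <- pmin(pmax(ft, 0), 1)
  structure(list(ft = ft, stats = st, degraded = mud), class = "FeatureMap")
}

#' Feature-refinement update
#'
#' Blends back the descriptor-weighted residual between successive iterates
#' and clamps to non-negative values:
#' \deqn{\mu_{new} = P[\mu^{n+1} + f_t \odot (\mu^n - \mu^{n+1})]}
#' where P sets negative entries to 0.
#'
#' @param muPrev the previous iterate \eqn{\mu^n}
#' @param muNew the fresh PWLS-TV iterate \eqn{\mu^{n+1}}
#' @param ft a [featureDescriptor()] result or a matrix in [0, 1]
#' @return an [AttenuationImage-class]
#' @export
frUpdate <- function(muPrev, muNew, ft) {
  if (inherits(ft, "FeatureMap")) ft <- ft$ft
  a <- asValues(muPrev); b <- asValues(muNew)
  if (!identical(dim(a), dim(b)) || !identical(dim(a), dim(ft)))
    stop("images and feature map must have the same shape")
  if (any(ft < 0) || any(ft > 1))
    stop("feature map outside [0, 1]: descriptor bug")
  out <- pmax(b + ft * (a - b), 0)
  grid <- if (is(muNew, "AttenuationImage")) muNew@grid
          else makeGrid(nrow(b), ncol(b), 1)
  attenuationImage(out, grid)
}
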
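#' Reconstruction run configuration
#'
#' @param method \code{"fbp"}, \code{"pwls-tv"} or \code{"pwls-tv-fr"}.
#' @param grid reconstruction [ImageGrid-class], or \code{NULL} to use
#'   [defaultGrid()] of the sinogram's geometry.
#' @param tv a [tvConfig()]
#' @param fr an [frConfig()]
#' @param filter an [fbpFilter()] used for the FBP baseline / initialization.
#' @param maxIterations iteration budget for the iterative methods, >= 1.
#' @param tol relative image-change stopping tolerance.
#' @return a list of class \code{ReconConfig}
#' @export
reconConfig <- function(method = c("pwls-tv-fr", "pwls-tv", "fbp"),
                        grid = NULL, tv = tvConfig(), fr = frConfig(),
                        filter = fbpFilter(), maxIterations = 100L,
                        tol = 1e-6) {
  method <- match.arg(method)
  maxIterations <- as.integer(maxIterations)
  if (maxIterations < 1L) stop("maxIterations must be >= 1")
  structure(list(method = method, grid = grid, tv = tv, fr = fr,
                 filter = filter, maxIterations = maxIterations, tol = tol),
            class = "ReconConfig")
}

#' Full reconstruction pipeline
#'
#' Runs one of the three reconstruction methods on a measured sinogram:
#' \describe{
#'   \item{fbp}{a single filtered back-projection.}
#'   \item{pwls-tv}{FBP initialization, then repeated [pwlsTvUpdate()]
#'     steepest-descent updates of the TV-penalized weighted least-squares
#'     cost.}
#'   \item{pwls-tv-fr}{as pwls-tv, with one feature-refinement step
#'     ([featureDescriptor()] on the fresh iterate, then [frUpdate()])
#'     after every PWLS-TV update.}
#' }
#' Iteration stops at \code{maxIterations}, when the line search degenerates
#' (zero gradient), or when the relative image change drops below
#' \code{tol}. The run is fully deterministic given its inputs.
#'
#' @param y measured [Sinogram-class]
#' @param weights per-ray variance matrix, or \code{NULL} for
#'   [identityWeights()]
#' @param config a [reconConfig()]
#' @param muTrue optional ground-truth [AttenuationImage-class]; when given,
#'   per-iteration RMSE and PSNR are recorded.
#' @param verbose print a per-iteration log line.
#' @return a list of class \code{EvaluationReport} with elements
#'   \code{image} (the reconstruction), \code{method}, \code{iterations},
#'   \code{rmse}, \code{psnr} (final metrics, NA without \code{muTrue}),
#'   \code{history} (per-iteration data frame: n, tau, wlsCost, tv, rmse,
#'   psnr), \code{featureMap} (last descriptor, pwls-tv-fr only) and
#'   \code{config}.
#' @export
reconstruct <- function(y, weights = NULL, config = reconConfig(),
                        muTrue = NULL, verbose = FALSE) {
  stopifnot(is(y, "Sinogram"), inherits(config, "ReconConfig"))
  geom <- y@geometry
  grid <- if (is.null(config$grid)) defaultGrid(geom) else config$grid
  if (is.null(weights)) weights <- identityWeights(geom)
  if (!identical(dim(weights), dim(y@values)))
    stop("weights shape must match the sinogram")
  if (!is.null(muTrue) && !identical(dim(muTrue@values),
                                     c(grid@nRows, grid@nCols)))
    stop("muTrue shape must match the reconstruction grid")

  mu <- fbpReconstruct(y, grid, config$filter)
  fm <- NULL
  hist <- list()
  iterations <- 0L

  if (config$method != "fbp") {
    for (n in seq_len(config$maxIterations)) {
      muNew <- pwlsTvUpdate(mu, y, weights, geom, config$tv)
      if (config$method == "pwls-tv-fr") {
        fm <- featureDescriptor(muNew, config$fr)
        muOut <- frUpdate(mu, muNew, fm)
      } else {
        muOut <- muNew
      }
      iterations <- n
      rec <- data.frame(
        n = n, tau = attr(muNew, "tau"), wlsCost = attr(muNew, "wlsCost"),
        tv = tvValue(muOut@values, config$tv$alpha),
        rmse = if (is.null(muTrue)) NA_real_ else rmse(muOut, muTrue),
        psnr = if (is.null(muTrue)) NA_real_ else psnr(muOut, muTrue))
      hist[[n]] <- rec
      if (verbose)
        message(sprintf("iter %3d  tau %.3e  wls %.6e  tv %.4e  rmse %s",
                        n, rec$tau, rec$wlsCost, rec$tv,
                        ifelse(is.na(rec$rmse), "-", sprintf("%.4e", rec$rmse))))
      delta <- sqrt(sum((muOut@values - mu@values)^2))
      base <- sqrt(sum(mu@values^2))
      mu <- muOut
      if (isTRUE(attr(muNew, "converged"))) break
      if (base > 0 && delta / base < config$tol) break
    }
  }

  history <- if (length(hist)) do.call(rbind, hist) else
    data.frame(n = integer(), tau = numeric(), wlsCost = numeric(),
               tv = numeric(), rmse = numeric(), psnr = numeric())
  structure(list(
    image = mu,
    method = config$method,
    iterations = iterations,
    rmse = if (is.null(muTrue)) NA_real_ else rmse(mu, muTrue),
    psnr = if (is.null(muTrue)) NA_real_ else psnr(mu, muTrue),
    history = history,
    featureMap = fm,
    config = config), class = "EvaluationReport")
}

#' Root mean squared error
#'
#' \deqn{RMSE = \sqrt{\sum_m (\mu(m) - \mu_{true}(m))^2 / Q}}
#' over all Q pixels.
#' @param mu,muTrue [AttenuationImage-class] or numeric matrices of equal
#'   shape
#' @return scalar RMSE (same units as the images)
#' @export
rmse <- function(mu, muTrue) {
  a <- asValues(mu); b <- asValues(muTrue)
  if (!identical(dim(a), dim(b))) stop("images must have the same shape")
  sqrt(sum((a - b)^2) / length(a))
}

#' Peak signal-to-noise ratio
#'
#' \deqn{PSNR = 10 \log_{10}\!\left[\frac{MAX^2(\mu_{true})}
#'   {\sum_m (\mu(m)-\mu_{true}(m))^2 / (Q-1)}\right]}
#' The default \code{"q-1"} convention divides the error sum by Q - 1; the
#' conventional form (divide by Q) is available as \code{"q"}. A perfect
#' reconstruction returns \code{Inf}.
#'
#' @inheritParams rmse
#' @param convention \code{"q-1"} (default) or \code{"q"}
#' @return PSNR in dB
#' @export
psnr <- function(mu, muTrue, convention = c("q-1", "q")) {
  convention <- match.arg(convention)
  a <- asValues(mu); b <- asValues(muTrue)
  if (!identical(dim(a), dim(b))) stop("images must have the same shape")
  Q <- length(a)
  if (Q < 2) stop("need at least 2 pixels")
  mx <- max(b)
  if (!(mx > 0)) stop("muTrue must have a positive maximum")
  sse <- sum((a - b)^2)
  if (sse == 0) return(Inf)
  den <- if (convention == "q-1") Q - 1 else Q
  10 * log10(mx^2 / (sse / den))
}

#' Horizontal image profile
#'
#' Convenience extractor for line plots through a reconstruction: the pixel
#' values of one image row over a column range.
#' @param image an [AttenuationImage-class] or matrix
#' @param row 1-based row index
#' @param cols 1-based column indices (default: all)
#' @return data frame with columns \code{col} and \code{value}
#' @export
horizontalProfile <- function(image, row, cols = NULL) {
  m <- asValues(image)
  if (is.null(cols)) cols <- seq_len(ncol(m))
  data.frame(col = cols, value = m[row, cols])
}
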
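#' TV configuration
#'
#' @param alpha smoothing constant added under the square root of the TV
#'   functional so it stays differentiable; default 1e-8.
#' @param beta TV step weight in the image update; default exp(-2).
#' @param tvStepMode how the TV step is scaled: \code{"raw"} subtracts
#'   \code{beta * gradTV} exactly as the update rule is written;
#'   \code{"scaled"} subtracts \code{beta * ||tau H|| * gradTV / ||gradTV||},
#'   i.e. beta is the length of the TV step relative to the data step
#'   (adaptive-steepest-descent style). See the package vignette for why the
#'   scaled form is the default.
#' @return a list of class \code{TvConfig}
#' @export
tvConfig <- function(alpha = 1e-8, beta = exp(-2),
                     tvStepMode = c("scaled", "raw")) {
  if (!(alpha > 0)) stop("alpha must be positive")
  if (beta < 0) stop("beta must be non-negative")
  structure(list(alpha = alpha, beta = beta,
                 tvStepMode = match.arg(tvStepMode)),
            class = "TvConfig")
}

asValues <- function(x) if (is(x, "AttenuationImage")) x@values else x

#' Smoothed total variation of an image
#'
#' \deqn{TV(\mu) = \sum_{s,t} \sqrt{(\mu_{s,t}-\mu_{s-1,t})^2 +
#'   (\mu_{s,t}-\mu_{s,t-1})^2 + \alpha}}
#' summed over every pixel whose upper and left neighbors both exist
#' (s >= 1, t >= 1 in 0-based indices), so an R x C image contributes
#' (R-1)(C-1) terms.
#'
#' @param image an [AttenuationImage-class] or numeric matrix, at least 2x2.
#' @param alpha smoothing constant, >= 0 (0 gives the exact, non-smooth TV).
#' @return scalar TV value
#' @export
tvValue <- function(image, alpha = 1e-8) {
  m <- asValues(image)
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 2L || nc < 2L) stop("image must be at least 2 x 2")
  dv <- m[2:nr, 2:nc, drop = FALSE] - m[1:(nr - 1), 2:nc, drop = FALSE]
  dh <- m[2:nr, 2:nc, drop = FALSE] - m[2:nr, 1:(nc - 1), drop = FALSE]
  sum(sqrt(dv^2 + dh^2 + alpha))
}

#' Gradient of the smoothed total variation
#'
#' Exact analytic partial derivative of [tvValue()] with respect to every
#' pixel; each pixel appears in up to three square-root terms (its own and
#' those of its lower and right neighbors). Where a term's root is exactly
#' zero (possible only with \code{alpha = 0}) its subgradient contribution is
#' taken as 0.
#'
#' @inheritParams tvValue
#' @return numeric matrix, same shape as the image
#' @export
tvGradient <- function(image, alpha = 1e-8) {
  m <- asValues(image)
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 2L || nc < 2L) stop("image must be at least 2 x 2")
  dv <- m[2:nr, 2:nc, drop = FALSE] - m[1:(nr - 1), 2:nc, drop = FALSE]
  dh <- m[2:nr, 2:nc, drop = FALSE] - m[2:nr, 1:(nc - 1), drop = FALSE]
  r <- sqrt(dv^2 + dh^2 + alpha)
  inv <- ifelse(r > 0, 1 / r, 0)
  g <- matrix(0, nr, nc)
  g[2:nr, 2:nc] <- g[2:nr, 2:nc] + (dv + dh) * inv
  g[1:(nr - 1), 2:nc] <- g[1:(nr - 1), 2:nc] - dv * inv
  g[2:nr, 1:(nc - 1)] <- g[2:nr, 1:(nc - 1)] - dh * inv
  g
}

checkWeights <- function(weights) {
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("statistical weights (variances) must be positive and finite")
  invisible(TRUE)
}

#' Weighted least-squares gradient
#'
#' The gradient of the weighted data-fidelity term
#' \eqn{\frac12 (G\mu - y)^T \Sigma^{-1} (G\mu - y)}:
#' \deqn{H = G^T(\Sigma^{-1}(G\mu^n - y))}
#' with \eqn{\Sigma} the diagonal matrix of per-ray variances.
#'
#' @param mu current iterate, an [AttenuationImage-class]
#' @param y measured [Sinogram-class]
#' @param weights per-ray variance matrix (see [addTransmissionNoise()],
#'   [identityWeights()])
#' @param geom a [ScanGeometry-class]
#' @return an [AttenuationImage-class] holding H
#' @export
wlsGradient <- function(mu, y, weights, geom) {
  checkWeights(weights)
  resid <- forwardProject(mu, geom)@values - y@values
  H <- backProject(sinogram(resid / weights, geom), geom, mu@grid)
  # piggy-back the cost at mu so callers can log it without reprojecting
  attr(H, "wlsCost") <- 0.5 * sum(resid^2 / weights)
  H
}

#' Exact line-search step size
#'
#' The minimizer of the weighted quadratic cost along the steepest-descent
#' direction H:
#' \deqn{\tau = \frac{H^T H}{(GH)^T \Sigma^{-1} (GH)}}
#' If H is (numerically) zero the step is 0 and the result carries
#' \code{attr(., "converged") = TRUE}.
#'
#' @param H the gradient image from [wlsGradient()]
#' @param geom a [ScanGeometry-class]
#' @param weights per-ray variance matrix
#' @return scalar step size with logical attribute \code{converged}
#' @export
stepSize <- function(H, geom, weights) {
  checkWeights(weights)
  hv <- asValues(H)
  num <- sum(hv^2)
  gh <- forwardProject(attenuationImage(hv, H@grid), geom)@values
  den <- sum(gh^2 / weights)
  if (!(den > 1e-30)) {
    tau <- 0
    attr(tau, "converged") <- TRUE
    return(tau)
  }
  tau <- num / den
  attr(tau, "converged") <- FALSE
  tau
}

#' One PWLS-TV image update
#'
#' Steepest-descent update of the TV-penalized weighted least-squares cost:
#' \deqn{\mu^{n+1} = \mu^n - \tau^n H - \beta_{step} \nabla TV(\mu^n)}
#' with H and \eqn{\tau^n} from [wlsGradient()] and [stepSize()]. Depending
#' on \code{config$tvStepMode}, \eqn{\beta_{step}} is \code{beta} itself
#' (\code{"raw"}) or \code{beta * ||tau H|| / ||gradTV||} (\code{"scaled"},
#' the default), making beta the TV step length relative to the data step.
#' No non-negativity constraint is applied here; the clamp belongs to the
#' feature-refinement step.
#'
#' @inheritParams wlsGradient
#' @param config a [tvConfig()]
#' @return the updated [AttenuationImage-class]; attributes \code{tau},
#'   \code{converged} record the line-search step.
#' @export
pwlsTvUpdate <- function(mu, y, weights, geom, config = tvConfig()) {
  H <- wlsGradient(mu, y, weights, geom)
  tau <- stepSize(H, geom, weights)
  dataStep <- as.numeric(tau) * H@values
  if (config$beta > 0) {
    g <- tvGradient(mu@values, config$alpha)
    if (config$tvStepMode == "scaled") {
      gn <- sqrt(sum(g^2))
      scale <- if (gn > 0) config$beta * sqrt(sum(dataStep^2)) / gn else 0
    } else {
      scale <- config$beta
    }
    tvStep <- scale * g
  } else {
    tvStep <- 0
  }
  out <- attenuationImage(mu@values - dataStep - tvStep, mu@grid)
  attr(out, "tau") <- as.numeric(tau)
  attr(out, "converged") <- isTRUE(attr(tau, "converged"))
  attr(out, "wlsCost") <- attr(H, "wlsCost")
  out
}

#' Weighted data-fidelity cost
#'
#' \eqn{\frac12 (G\mu - y)^T \Sigma^{-1} (G\mu - y)}; used for logging and
#' descent checks.
#' @inheritParams wlsGradient
#' @return scalar cost
#' @export
wlsCost <- function(mu, y, weights, geom) {
  checkWeights(weights)
  r <- forwardProject(mu, geom)@values - y@values
  0.5 * sum(r^2 / weights)
}
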
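# Small geometries, grids and independent oracles shared across tests.

# desk-scale fan-beam geometry (20 views x 24 bins unless overridden)
tinyGeom <- function(nViews = 20, nBins = 24, angularRange = 360,
                     shape = "curved") {
  makeGeometry(NULL, nViews = nViews, angularRange = angularRange,
               nBins = nBins, sourceToDetector = 100, centerToDetector = 50,
               detectorExtent = 2 * asin(10 / 50) * 100,
               detectorShape = shape)
}

tinyGrid <- function(geom, n = 16) makeGrid(n, n, 2 * fovRadius(geom) / n)

randomImage <- function(grid, sd = 1) {
  attenuationImage(matrix(rnorm(grid@nRows * grid@nCols, sd = sd),
                          grid@nRows, grid@nCols), grid)
}

randomSinogram <- function(geom, sd = 1) {
  sinogram(matrix(rnorm(geom@nViews * geom@nBins, sd = sd),
                  geom@nViews, geom@nBins), geom)
}

# dense system matrix oracle: build G column by column by projecting unit
# impulses, so adjointness and gradient formulas can be checked by explicit
# matrix algebra
denseSystemMatrix <- function(geom, grid) {
  n <- grid@nRows * grid@nCols
  G <- matrix(0, geom@nViews * geom@nBins, n)
  for (j in seq_len(n)) {
    e <- matrix(0, grid@nRows, grid@nCols)
    e[j] <- 1
    G[, j] <- as.vector(values(forwardProject(attenuationImage(e, grid),
                                              geom)))
  }
  G
}

# golden-section minimizer, independent 1-D oracle for the line-search step
goldenSection <- function(f, lower, upper, iterations = 90) {
  phi <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  c <- b - phi * (b - a); d <- a + phi * (b - a)
  fc <- f(c); fd <- f(d)
  for (i in seq_len(iterations)) {
    if (fc < fd) {
      b <- d; d <- c; fd <- fc
      c <- b - phi * (b - a); fc <- f(c)
    } else {
      a <- c; c <- d; fc <- fd
      d <- a + phi * (b - a); fd <- f(d)
    }
  }
  (a + b) / 2
}

# naive double-loop implementation of the patch statistics (mirror padding),
# independent of the convolution-based implementation
naivePatchStats <- function(a, b, k) {
  r <- (k - 1) / 2
  nr <- nrow(a); nc <- ncol(a)
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  N <- k^2
  P <- Q <- sp <- sq <- sqp <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- reflect((i - r):(i + r), nr)
      ci <- reflect((j - r):(j + r), nc)
      pa <- a[ri, ci]; pb <- b[ri, ci]
      P[i, j] <- mean(pa); Q[i, j] <- mean(pb)
      sp[i, j] <- sqrt(sum((pa - P[i, j])^2) / (N - 1))
      sq[i, j] <- sqrt(sum((pb - Q[i, j])^2) / (N - 1))
      sqp[i, j] <- sum((pa - P[i, j]) * (pb - Q[i, j])) / (N - 1)
    }
  }
  list(meanP = P, meanQ = Q, sigmaP = sp, sigmaQ = sq, sigmaQP = sqp)
}
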
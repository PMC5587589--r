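test_that("TV value matches hand-evaluated cases", {
  expect_equal(tvValue(matrix(5, 10, 10), alpha = 1e-8), 81 * 1e-4)
  m <- rbind(c(0, 1), c(0, 1))
  expect_equal(tvValue(m, alpha = 0), 1)
  set.seed(30)
  r <- matrix(rnorm(64), 8, 8)
  expect_equal(tvValue(r + 3.7, 1e-8), tvValue(r, 1e-8))   # shift invariance
  expect_error(tvValue(matrix(1, 1, 5)), "2 x 2")
  # lower bound: nTerms * sqrt(alpha), equality iff constant
  expect_gt(tvValue(r, 1e-8), 49 * 1e-4)
})

test_that("TV gradient is the exact derivative (finite-difference oracle)", {
  set.seed(31)
  h <- 1e-7
  for (rep in 1:50) {
    m <- matrix(rnorm(64), 8, 8)
    g <- tvGradient(m, alpha = 1e-8)
    fd <- matrix(0, 8, 8)
    for (j in seq_len(64)) {
      mp <- m; mm <- m
      mp[j] <- mp[j] + h; mm[j] <- mm[j] - h
      fd[j] <- (tvValue(mp, 1e-8) - tvValue(mm, 1e-8)) / (2 * h)
    }
    expect_lt(max(abs(g - fd)), 1e-5)
  }
  expect_lt(max(abs(tvGradient(matrix(2, 6, 6), 1e-8))), 1e-12)
  # 0-homogeneity at alpha = 0 on a strictly monotone image
  mono <- outer(1:6, 1:6, function(i, j) i + 2 * j + 0.1 * i * j)
  expect_equal(tvGradient(3 * mono, 0), tvGradient(mono, 0))
})

test_that("WLS gradient matches explicit matrix algebra", {
  set.seed(32)
  g <- tinyGeom(nViews = 20, nBins = 24)
  grid <- tinyGrid(g, 16)
  G <- denseSystemMatrix(g, grid)
  mu <- randomImage(grid)
  y <- randomSinogram(g)
  w <- matrix(runif(20 * 24, 0.5, 2), 20, 24)
  H <- wlsGradient(mu, y, w, g)
  oracle <- t(G) %*% ((G %*% as.vector(values(mu)) - as.vector(values(y))) /
                        as.vector(w))
  expect_equal(as.vector(values(H)), as.vector(oracle), tolerance = 1e-10)
  # zero residual => zero gradient
  y0 <- forwardProject(mu, g)
  expect_lt(max(abs(values(wlsGradient(mu, y0, w, g)))), 1e-12)
  # doubling variances halves H
  H2 <- wlsGradient(mu, y, 2 * w, g)
  expect_equal(values(H2), values(H) / 2, tolerance = 1e-12)
  expect_error(wlsGradient(mu, y, -w, g), "positive")
})

test_that("line-search step minimizes the weighted quadratic", {
  set.seed(33)
  g <- tinyGeom(nViews = 12, nBins = 16)
  grid <- tinyGrid(g, 12)
  for (rep in 1:20) {
    w <- if (rep %% 2) identityWeights(g) else
      matrix(runif(12 * 16, 0.2, 5), 12, 16)
    mu <- randomImage(grid)
    y <- randomSinogram(g)
    H <- wlsGradient(mu, y, w, g)
    tau <- stepSize(H, g, w)
    f <- function(t) wlsCost(attenuationImage(values(mu) - t * values(H),
                                              grid), y, w, g)
    tstar <- goldenSection(f, 0, 10 * as.numeric(tau))
    expect_lt(abs(as.numeric(tau) - tstar) / tstar, 1e-6)
  }
})

test_that("zero gradient yields a zero step flagged as converged", {
  g <- tinyGeom(nViews = 6, nBins = 8)
  grid <- tinyGrid(g, 8)
  H0 <- attenuationImage(0, grid)
  tau <- stepSize(H0, g, identityWeights(g))
  expect_equal(as.numeric(tau), 0)
  expect_true(attr(tau, "converged"))
})

test_that("the update is a fixed point at zero residual with beta = 0", {
  set.seed(34)
  g <- tinyGeom(nViews = 12, nBins = 16)
  grid <- tinyGrid(g, 12)
  mu <- randomImage(grid)
  y <- forwardProject(mu, g)
  up <- pwlsTvUpdate(mu, y, identityWeights(g), g, tvConfig(beta = 0))
  expect_equal(values(up), values(mu), tolerance = 1e-12)
})

test_that("exact line search descends the weighted cost monotonically", {
  set.seed(35)
  g <- tinyGeom(nViews = 12, nBins = 16)
  grid <- tinyGrid(g, 12)
  truth <- rasterizePhantom(ellipsePhantom(0, 1, 5, 4, 15, 0.01), grid)
  nz <- addTransmissionNoise(analyticSinogram(
    ellipsePhantom(0, 1, 5, 4, 15, 0.01), g), noiseModel(1e4, seed = 5))
  mu <- truth
  cfg <- tvConfig(beta = 0)
  costs <- numeric(10)
  for (i in 1:10) {
    mu <- pwlsTvUpdate(mu, nz$sinogram, nz$weights, g, cfg)
    costs[i] <- attr(mu, "wlsCost")
  }
  final <- wlsCost(mu, nz$sinogram, nz$weights, g)
  expect_true(all(diff(c(costs, final)) < 0))
})

test_that("the update composes wlsGradient, stepSize and the TV gradient", {
  set.seed(36)
  g <- tinyGeom(nViews = 12, nBins = 16)
  grid <- tinyGrid(g, 12)
  mu <- randomImage(grid)
  y <- randomSinogram(g)
  w <- matrix(runif(12 * 16, 0.5, 2), 12, 16)
  for (mode in c("raw", "scaled")) {
    cfg <- tvConfig(alpha = 1e-8, beta = 0.05, tvStepMode = mode)
    up <- pwlsTvUpdate(mu, y, w, g, cfg)
    H <- wlsGradient(mu, y, w, g)
    tau <- as.numeric(stepSize(H, g, w))
    gtv <- tvGradient(values(mu), 1e-8)
    betaStep <- if (mode == "raw") 0.05 else
      0.05 * sqrt(sum((tau * values(H))^2)) / sqrt(sum(gtv^2))
    hand <- values(mu) - tau * values(H) - betaStep * gtv
    expect_equal(values(up), hand, tolerance = 1e-12)
  }
  expect_error(tvConfig(alpha = 0), "alpha")
  expect_error(tvConfig(beta = -1), "beta")
})
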
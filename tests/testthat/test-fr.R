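test_that("Gaussian degradation is normalized and mirror-padded", {
  cfg <- frConfig()
  const <- matrix(3.2, 12, 12)
  expect_equal(degradeImage(const, cfg), const)
  # unit impulse reproduces the kernel table
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  k <- pwlsfr:::gaussianKernel(3, 1)
  out <- degradeImage(imp, cfg)
  expect_equal(out[4:6, 4:6], k)
  expect_equal(sum(out), 1)
  # mean preservation under symmetric padding
  set.seed(40)
  m <- matrix(rnorm(15 * 11), 15, 11)
  expect_equal(mean(degradeImage(m, cfg)), mean(m), tolerance = 1e-12)
  expect_error(degradeImage(matrix(1, 2, 2), frConfig(kernelSize = 5)),
               "larger")
})

test_that("local statistics match a naive double-loop implementation", {
  cfg <- frConfig(patchSide = 3)
  # constants: all sigmas zero, means equal the constants
  st0 <- localStatistics(matrix(2, 8, 8), matrix(7, 8, 8), cfg)
  expect_true(all(st0$sigmaP == 0) && all(st0$sigmaQ == 0) &&
                all(st0$sigmaQP == 0))
  expect_true(all(st0$meanP == 2) && all(st0$meanQ == 7))
  # hand case: a = b = [[1,2,3],[4,5,6],[7,8,9]] => sigmaQP = sigmaP^2
  a <- matrix(1:9, 3, 3, byrow = TRUE)
  st <- localStatistics(a, a, cfg)
  expect_equal(st$sigmaQP, st$sigmaP^2)
  expect_equal(st$sigmaP, st$sigmaQ)
  ref <- naivePatchStats(a, a, 3)
  for (f in names(ref)) expect_equal(st[[f]], ref[[f]], tolerance = 1e-12)
  # random pair against the loop oracle, plus Cauchy-Schwarz
  set.seed(41)
  for (rep in 1:5) {
    x <- matrix(rnorm(100), 10, 10)
    y <- matrix(rnorm(100), 10, 10)
    st <- localStatistics(x, y, cfg)
    ref <- naivePatchStats(x, y, 3)
    for (f in names(ref)) expect_equal(st[[f]], ref[[f]], tolerance = 1e-10)
    expect_true(all(abs(st$sigmaQP) <= st$sigmaP * st$sigmaQ + 1e-12))
  }
  expect_error(localStatistics(matrix(1, 3, 3), matrix(1, 4, 4), cfg),
               "shape")
})

test_that("Cauchy-Schwarz holds across 50 random image pairs", {
  set.seed(42)
  cfg <- frConfig(patchSide = 3)
  for (rep in 1:50) {
    x <- matrix(rnorm(64, sd = runif(1, 0.1, 10)), 8, 8)
    y <- x + matrix(rnorm(64, sd = 0.5), 8, 8)
    st <- localStatistics(x, y, cfg)
    expect_true(all(abs(st$sigmaQP) <= st$sigmaP * st$sigmaQ + 1e-10))
  }
})

test_that("the structure descriptor stays in [0,1] and vanishes where it should", {
  cfg <- frConfig()
  # constant image: all sigmas zero => ft = 1 - |C/C| = 0
  fd <- featureDescriptor(matrix(0.01, 16, 16), cfg)
  expect_true(all(fd$ft == 0))
  # identity degradation (sigma -> 0 kernel): self-similarity => ft = 0
  cfg0 <- frConfig(sigma = 1e-4)
  set.seed(43)
  m <- matrix(runif(256), 16, 16)
  fd0 <- featureDescriptor(m, cfg0)
  expect_lt(max(fd0$ft), 1e-10)
  # bounds on random images of wildly different scales
  for (rep in 1:50) {
    img <- matrix(rnorm(144, sd = 10^runif(1, -4, 2)), 12, 12)
    ft <- featureDescriptor(img, cfg)$ft
    expect_gte(min(ft), 0)
    expect_lte(max(ft), 1)
  }
})

test_that("the descriptor is edge-selective", {
  cfg <- frConfig()
  step <- cbind(matrix(0.005, 32, 16), matrix(0.015, 32, 16))
  ft <- featureDescriptor(step, cfg)$ft
  nearEdge <- ft[, 16:17]
  flat <- ft[, c(1:12, 21:32)]
  expect_gt(mean(nearEdge), mean(flat))
})

test_that("feature-refinement blend honors its endpoint and clamp contracts", {
  grid <- makeGrid(4, 4, 1)
  a <- attenuationImage(matrix(c(-0.2, 0.5, 1, 2), 4, 4), grid)   # mu^n
  b <- attenuationImage(matrix(c(-0.1, 0.3, 2, 1), 4, 4), grid)   # mu^n+1
  ones <- matrix(1, 4, 4); zeros <- matrix(0, 4, 4)
  expect_equal(values(frUpdate(a, b, ones)), pmax(values(a), 0))
  expect_equal(values(frUpdate(a, b, zeros)), pmax(values(b), 0))
  # zero residual: result is the clamped iterate
  expect_equal(values(frUpdate(b, b, matrix(0.37, 4, 4))),
               pmax(values(b), 0))
  # hand case: blend of -0.1 and -0.2 at ft = 0.5 clamps to 0
  g1 <- makeGrid(1, 2, 1)
  out <- frUpdate(attenuationImage(matrix(c(-0.2, 1), 1, 2), g1),
                  attenuationImage(matrix(c(-0.1, 3), 1, 2), g1),
                  matrix(0.5, 1, 2))
  expect_equal(values(out), matrix(c(0, 2), 1, 2))
  expect_true(all(values(out) >= 0))
  expect_error(frUpdate(a, b, ones * 1.5), "\\[0, 1\\]")
  expect_error(frUpdate(a, b, matrix(1, 3, 3)), "shape")
})

test_that("fr configuration rejects invalid parameters", {
  expect_error(frConfig(patchSide = 4), "odd")
  expect_error(frConfig(patchSide = 1), "odd")
  expect_error(frConfig(C = 0), "positive")
  expect_error(frConfig(kernelSize = 2), "odd")
  expect_error(frConfig(sigma = 0), "positive")
})
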
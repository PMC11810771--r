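impls <- c("unthreaded", "threaded", "vectorized")

test_that("conv2d identity and constant-image cases hold for every implementation", {
  img <- generateImage(11, 13, seed = 1)
  for (impl in impls) {
    expect_equal(conv2d(img, matrix(1, 1, 1), impl), img)
    # delta kernel: identity for any odd K
    for (K in c(3L, 5L, 9L)) {
      delta <- matrix(0, K, K); delta[(K + 1) %/% 2, (K + 1) %/% 2] <- 1
      expect_equal(conv2d(img, delta, impl), img, tolerance = 1e-12)
    }
    # all-ones 3x3 on constant c: every pixel 9c, including clamped borders
    cimg <- matrix(2.5, 6, 7)
    expect_equal(conv2d(cimg, matrix(1, 3, 3), impl), matrix(22.5, 6, 7))
  }
})

test_that("conv2d matches the nested-loop oracle on random inputs", {
  set.seed(42)
  for (rep in 1:5) {
    img <- matrix(rnorm(7 * 7), 7, 7)
    kern <- matrix(rnorm(9), 3, 3)
    ref <- convOracle(img, kern)
    for (impl in impls)
      expect_lt(relDiff(conv2d(img, kern, impl), ref), 1e-12)
  }
  # larger kernel than image exercises deep clamping
  img <- matrix(rnorm(16), 4, 4)
  kern <- matrix(rnorm(49), 7, 7)
  ref <- convOracle(img, kern)
  for (impl in impls)
    expect_lt(relDiff(conv2d(img, kern, impl), ref), 1e-12)
})

test_that("conv2d rejects even kernels and unknown implementations", {
  img <- matrix(0, 4, 4)
  expect_error(conv2d(img, matrix(1, 2, 2)), "odd")
  expect_error(conv2d(img, matrix(1, 3, 3), "gpu"), "unknown implementation")
})

test_that("catmullRomZoom identity, partition of unity and shape contract", {
  s <- generateImage(5, 6, seed = 2)
  for (impl in impls) {
    expect_equal(catmullRomZoom(s, 1, impl), s)
    # constant frame stays constant at any magnification (weights sum to 1)
    cst <- matrix(3.7, 4, 4)
    z <- catmullRomZoom(cst, 3, impl)
    expect_equal(dim(z), c(12L, 12L))
    expect_equal(z, matrix(3.7, 12, 12), tolerance = 1e-12)
  }
  stack <- generateImage(4, 5, frames = 3, seed = 3)
  z <- catmullRomZoom(stack, 2)
  expect_equal(dim(z), c(3L, 8L, 10L))
  expect_error(catmullRomZoom(s, 0), "positive integer")
})

test_that("catmullRomZoom reproduces linear ramps at interior samples", {
  ramp <- generateImage(8, 8, kind = "ramp", rampCoef = c(0.5, 0.25, 1))
  mag <- 2L
  for (impl in impls) {
    z <- catmullRomZoom(ramp, mag, impl)
    # interior output pixels (2 input pixels away from every border)
    ii <- (2 * mag + 1):(6 * mag)
    expected <- outer(ii - 1, ii - 1, function(i, j)
      0.5 * (j / mag) + 0.25 * (i / mag) + 1)
    expect_equal(z[ii, ii], expected, tolerance = 1e-10)
  }
})

test_that("catmullRomZoom matches the per-pixel evaluation oracle", {
  set.seed(7)
  f <- matrix(rnorm(16), 4, 4)
  ref <- crZoomOracle(f, 2L)
  for (impl in impls)
    expect_lt(relDiff(catmullRomZoom(f, 2, impl), ref), 1e-12)
  # and per frame of a stack
  stack <- generateImage(3, 3, frames = 2, seed = 8)
  z <- catmullRomZoom(stack, 3, "threaded")
  for (t in 1:2)
    expect_lt(relDiff(matrix(z[t, , ], 9, 9),
                      crZoomOracle(matrix(stack[t, , ], 3, 3), 3L)), 1e-12)
})

test_that("nlmDenoise invariances: constants, huge h limit, parameter errors", {
  cimg <- matrix(1.25, 8, 8)
  for (impl in impls) {
    out <- nlmDenoise(cimg, nlmParams(3, 2, 0, 0.5), impl)
    expect_equal(out, cimg)  # all patch distances zero -> exact constant
  }
  # h far above image range: weights ~1, each pixel -> window mean
  set.seed(9)
  img <- matrix(runif(49), 7, 7)
  out <- nlmDenoise(img, nlmParams(3, 2, 0, 1e6), "unthreaded")
  winMean <- convOracle(img, matrix(1 / 25, 5, 5))
  expect_equal(out, winMean, tolerance = 1e-6)
  expect_error(nlmParams(h = 0), "positive")
  expect_error(nlmParams(h = -1), "positive")
})

test_that("nlmDenoise matches the quadruple-loop weight-sum oracle", {
  set.seed(10)
  img <- matrix(runif(81), 9, 9)
  ref <- nlmOracle(img, 3L, 2L, 0, 0.5)
  for (impl in impls)
    expect_lt(relDiff(nlmDenoise(img, nlmParams(3, 2, 0, 0.5), impl), ref),
              1e-10)
  # even patch size rounds up to the next odd
  ref4 <- nlmOracle(img, 4L, 2L, 0.1, 0.3)
  expect_lt(relDiff(nlmDenoise(img, nlmParams(4, 2, 0.1, 0.3), "vectorized"),
                    ref4), 1e-10)
})

test_that("all implementations of each method agree on randomized inputs", {
  set.seed(11)
  for (rep in 1:6) {
    H <- sample(5:20, 1); W <- sample(5:20, 1)
    img <- matrix(rnorm(H * W), H, W)
    K <- sample(c(3, 5, 7), 1)
    kern <- matrix(rnorm(K * K), K, K)
    cref <- conv2d(img, kern, "unthreaded")
    expect_lt(relDiff(conv2d(img, kern, "threaded"), cref), 1e-6)
    expect_lt(relDiff(conv2d(img, kern, "vectorized"), cref), 1e-6)

    mag <- sample(2:4, 1)
    zref <- catmullRomZoom(img, mag, "unthreaded")
    expect_lt(relDiff(catmullRomZoom(img, mag, "threaded"), zref), 1e-6)
    expect_lt(relDiff(catmullRomZoom(img, mag, "vectorized"), zref), 1e-6)

    p <- nlmParams(sample(3:5, 1), sample(2:3, 1), runif(1, 0, 0.2),
                   runif(1, 0.2, 1))
    nref <- nlmDenoise(img, p, "unthreaded")
    expect_lt(relDiff(nlmDenoise(img, p, "threaded"), nref), 1e-6)
    expect_lt(relDiff(nlmDenoise(img, p, "vectorized"), nref), 1e-6)
  }
})
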
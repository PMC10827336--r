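test_that("spatial contrast matches the K = sigma/mean definition", {
  f <- matrix(1:9, 3, 3, byrow = TRUE)
  k <- kValues(spatialContrast(f, 3))
  expect_equal(k[2, 2], sqrt(mean((1:9 - 5)^2)) / 5, tolerance = 1e-12)
  expect_equal(k[2, 2], 0.5164, tolerance = 1e-4)

  # constant frames carry no contrast
  expect_true(all(kValues(spatialContrast(matrix(4, 12, 12), 5)) == 0))

  # a zero-mean (dark) region yields K = 0, not NaN
  f2 <- matrix(0, 9, 9); f2[1, 1] <- 0
  expect_true(all(kValues(spatialContrast(f2, 3)) == 0))
})

test_that("spatial contrast equals the brute-force neighbourhood oracle", {
  set.seed(101)
  for (win in c(3L, 5L, 7L)) {
    f <- matrix(stats::rexp(64 * 64), 64, 64)
    expect_equal(kValues(spatialContrast(f, win)),
                 bruteForceContrast(f, win), tolerance = 1e-10)
  }
})

test_that("spatial contrast is invariant under intensity rescaling", {
  set.seed(102)
  f <- matrix(stats::rexp(40 * 40), 40, 40)
  k1 <- kValues(spatialContrast(f, 7))
  for (c in c(0.25, 3, 1700)) {
    expect_equal(kValues(spatialContrast(c * f, 7)), k1, tolerance = 1e-10)
  }
})

test_that("spatial contrast rejects invalid windows and empty frames", {
  f <- matrix(1, 10, 10)
  expect_error(spatialContrast(f, 4), "odd")
  expect_error(spatialContrast(f, 11), "odd|within")
  expect_error(spatialContrast(matrix(numeric(0), 0, 0), 3), "non-empty")
})

test_that("temporal contrast applies the definition along time", {
  same <- FrameStack(replicate(4, matrix(7, 6, 6), simplify = FALSE))
  for (ci in temporalContrast(same, 3))
    expect_true(all(kValues(ci) == 0))

  two <- FrameStack(list(matrix(2, 4, 4), matrix(4, 4, 4)))
  expect_equal(kValues(temporalContrast(two, 2)[[1]])[1, 1], 1 / 3,
               tolerance = 1e-12)
  expect_error(temporalContrast(two, 3), "fewer frames")
})

test_that("temporal and spatial contrast agree on stationary speckle", {
  cfg <- simulationConfig(shape = c(128L, 128L), grainSigmaPx = 1,
                          tauTissue = 0.05, exposureSubsteps = 1L,
                          nFrames = 25L, seed = 4L)
  sim <- simulateSequence(cfg)
  tk <- mean(kValues(temporalContrast(sim@stack, 25L)[[1]]))
  sk <- mean(kValues(spatialContrast(frames(sim)[[1]], 13L)))
  expect_lt(abs(tk / sk - 1), 0.05)
})

test_that("flow index is clamped elementwise 1/max(K, kFloor)^2", {
  k <- matrix(c(0.5, 1, 0, 2), 2, 2)
  fi <- flowValues(flowIndex(k, 1e-3))
  expect_equal(fi[1, 1], 4)
  expect_equal(fi[2, 1], 1)
  expect_equal(fi[1, 2], 1e6)
  expect_true(all(is.finite(fi)))
  expect_error(flowIndex(k, 0), "positive")
  # monotone decreasing in K
  ks <- seq(0.1, 1.5, by = 0.1)
  expect_true(all(diff(flowValues(flowIndex(matrix(ks, 1)))[1, ]) < 0))
})

test_that("contrast map rendering hits the blue and red endpoints", {
  v <- matrix(c(0, 5, 10, 5), 2, 2)
  img <- renderContrastMap(v, vmin = 0, vmax = 10)
  expect_equal(img[1, 2, ], c(1, 0, 0))   # vmax -> red (high flow)
  expect_equal(img[1, 1, ], c(0, 0, 1))   # vmin -> blue (low flow)
  expect_equal(img[2, 1, ], img[2, 2, ])  # equal values, identical colour
  # reversed-K rendering: low contrast renders red
  ci <- new("ContrastImage", k = matrix(c(0.2, 0.9), 1), window = 3L,
            method = "spatial")
  img2 <- renderContrastMap(ci, vmin = 0.2, vmax = 0.9)
  expect_equal(img2[1, 1, ], c(1, 0, 0))
  expect_error(renderContrastMap(v, vmin = 2, vmax = 2), "vmin")
})

test_that("contrast thresholding separates static background from tissue", {
  cfg <- simulationConfig(shape = c(144L, 256L), tauTissue = 0.1,
                          tissueRect = boundingBox(40, 30, 160, 84),
                          nFrames = 1L, seed = 9L)
  sim <- simulateSequence(cfg)
  k <- spatialContrast(frames(sim)[[1]], 11L)
  mask <- segmentBackground(k, 0.6)
  bg <- truthBackgroundMask(sim, 0)
  # judge interiors: the sliding window mixes regions within half a
  # window of the boundary
  bgI <- erodeMask(bg, 7L); tiI <- erodeMask(!bg, 7L)
  expect_gt(mean(mask[bgI]), 0.95)
  expect_gt(mean(!mask[tiI]), 0.95)
  # threshold edge cases
  expect_true(all(!segmentBackground(k, max(kValues(k)) + 1)))
  expect_true(all(segmentBackground(k, -1e-9)))
})
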
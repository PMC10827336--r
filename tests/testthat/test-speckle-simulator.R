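test_that("synthetic speckle is fully developed (exponential intensity)", {
  f <- synthSpeckleField(c(512L, 512L), 1.5, seed = 71L)
  I <- Mod(f)^2
  expect_lt(abs(mean(I) - 1), 1e-9)          # unit mean by construction
  # K = sigma/mean = 1 for exponential statistics
  expect_lt(abs(stats::sd(I) / mean(I) - 1), 0.05)
  # KS distance against the fitted exponential
  ks <- suppressWarnings(stats::ks.test(as.vector(I), "pexp",
                                        rate = 1 / mean(I)))
  expect_lt(unname(ks$statistic), 0.05)
  # determinism
  f2 <- synthSpeckleField(c(512L, 512L), 1.5, seed = 71L)
  expect_identical(f, f2)
})

test_that("field evolution is an AR(1) with preserved statistics", {
  f <- synthSpeckleField(c(256L, 256L), 1.5, seed = 72L)
  expect_identical(evolveField(f, 1), f)

  g <- evolveField(f, 0, seed = 73L)
  expect_lt(abs(stats::cor(as.vector(Mod(f)^2), as.vector(Mod(g)^2))), 0.05)

  expect_error(evolveField(f, 1.2), "rho")

  # stationarity under repeated evolution
  h <- f
  set.seed(74)
  for (i in 1:20) h <- evolveField(h, 0.8)
  expect_lt(abs(mean(Mod(h)^2) - 1), 0.05)
})

test_that("a fully static configuration yields identical frames", {
  cfg <- simulationConfig(shape = c(64L, 64L), tauTissue = Inf,
                          exposureSubsteps = 1L, nFrames = 4L, seed = 75L)
  sim <- simulateSequence(cfg)
  for (i in 2:4) expect_identical(frames(sim)[[i]], frames(sim)[[1]])
})

test_that("occluded lesions stand out from perfused tissue in contrast", {
  cfg <- simulationConfig(shape = c(128L, 192L), tauTissue = 0.1,
                          tauLesion = 100,
                          lesions = list(rectRoi(60, 40, 80, 40, id = "R1")),
                          nFrames = 1L, exposureSubsteps = 8L, seed = 76L)
  sim <- simulateSequence(cfg)
  k <- kValues(spatialContrast(frames(sim)[[1]], 7L))
  lm <- erodeMask(truthLesionMask(sim, 0), 4L)
  tm <- erodeMask(!truthLesionMask(sim, 0), 4L)
  sep <- (mean(k[lm]) - mean(k[tm])) /
    sqrt((stats::var(k[lm]) + stats::var(k[tm])) / 2)
  expect_gt(sep, 3)
})

test_that("ground-truth centers follow the configured trajectory exactly", {
  cfg <- simulationConfig(shape = c(64L, 96L),
                          lesions = list(circleRoi(40, 32, 8, id = "C1")),
                          trajectory = linearTrajectory(5L, c(2, 0)),
                          nFrames = 5L, exposureSubsteps = 1L, seed = 77L)
  sim <- simulateSequence(cfg)
  tc <- truthCenters(sim)
  expect_equal(diff(tc$cx), rep(2, 4))
  expect_equal(diff(tc$cy), rep(0, 4))
  expect_equal(tc$cx[1], 40)
})

test_that("contrast falls monotonically with faster flow, at every seed", {
  for (seed in c(81L, 82L, 83L, 84L, 85L)) {
    ks <- vapply(c(100, 10, 1, 0.1), function(tau) {
      cfg <- simulationConfig(shape = c(96L, 96L), tauTissue = tau,
                              exposureSubsteps = 8L, nFrames = 1L,
                              seed = seed)
      mean(kValues(spatialContrast(frames(simulateSequence(cfg))[[1]], 7L)))
    }, numeric(1))
    expect_true(all(diff(ks) < 0))
  }
})

test_that("longer exposure integration never increases contrast", {
  ks <- vapply(c(1L, 2L, 4L, 8L, 16L), function(M) {
    cfg <- simulationConfig(shape = c(96L, 96L), tauTissue = 2,
                            exposureSubsteps = M, nFrames = 1L, seed = 86L)
    mean(kValues(spatialContrast(frames(simulateSequence(cfg))[[1]], 7L)))
  }, numeric(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- slowScenario(seed = 3L, nFrames = 4L)
  s1 <- simulateSequence(cfg)
  s2 <- simulateSequence(cfg)
  expect_identical(frames(s1), frames(s2))
  expect_identical(truthCenters(s1), truthCenters(s2))
})

test_that("a trajectory leaving the frame entirely is rejected", {
  expect_error(simulateSequence(
    simulationConfig(shape = c(32L, 32L),
                     trajectory = matrix(c(0, 40, 0, 0), 2, 2),
                     nFrames = 2L, seed = 1L)),
    "out of frame")
})
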
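test_that("the trained filter self-detects the target on its own frame", {
  img <- texturedScene()
  st <- initTracker(img, boundingBox(64, 64, 32, 32))
  out <- trackStep(st, img)
  expect_lt(sqrt(sum((bboxCenter(out$result) - c(80, 80))^2)), 1)
  expect_gt(out$result@responsePeak, 0)
  expect_false(out$result@lost)
})

test_that("an untextured template is rejected at initialization", {
  expect_error(initTracker(matrix(5, 100, 100), boundingBox(30, 30, 20, 20)),
               "degenerate|texture")
})

test_that("bbox preconditions are enforced", {
  img <- texturedScene()
  expect_error(initTracker(img, boundingBox(280, 10, 30, 30)), "within")
  expect_error(initTracker(img, boundingBox(10, 10, 3, 3)), "area")
})

test_that("a single-frame translation is recovered to within a pixel", {
  st <- initTracker(texturedScene(), boundingBox(64, 64, 32, 32))
  out <- trackStep(st, texturedScene(c(5, 3)))
  expect_lt(abs(bboxCenter(out$result)[1] - 85), 1)
  expect_lt(abs(bboxCenter(out$result)[2] - 83), 1)
})

test_that("static noisy sequences accumulate less than 2 px of drift", {
  set.seed(21)
  img <- texturedScene()
  st <- initTracker(img, boundingBox(64, 64, 32, 32))
  for (i in 1:30) {
    noisy <- img + stats::rnorm(length(img), sd = stats::sd(img) / 10)  # ~20 dB
    out <- trackStep(st, noisy)
    st <- out$state
  }
  expect_lt(sqrt(sum((bboxCenter(out$result) - c(80, 80))^2)), 2)
})

test_that("slow motion is tracked and fast motion beyond the search window fails", {
  st <- initTracker(texturedScene(), boundingBox(64, 64, 32, 32))
  err <- numeric(50)
  for (i in 1:50) {
    out <- trackStep(st, texturedScene(c(2 * i, 0)))
    st <- out$state
    err[i] <- sqrt(sum((bboxCenter(out$result) - c(80 + 2 * i, 80))^2))
  }
  expect_lte(mean(err), 2)

  st2 <- initTracker(texturedScene(), boundingBox(64, 64, 32, 32),
                     trackerConfig(searchRadiusPx = 10))
  err2 <- numeric(10)
  for (i in 1:10) {
    out2 <- trackStep(st2, texturedScene(c(15 * i, 0)))
    st2 <- out2$state
    err2[i] <- sqrt(sum((bboxCenter(out2$result) - c(80 + 15 * i, 80))^2))
  }
  expect_gt(mean(err2), 5)
})

test_that("tracked bbox size never changes during a run", {
  st <- initTracker(texturedScene(), boundingBox(64, 64, 32, 32))
  for (i in 1:10) {
    out <- trackStep(st, texturedScene(c(2 * i, i)))
    st <- out$state
    expect_identical(c(out$result@bbox@w, out$result@bbox@h), c(32, 32))
  }
})

test_that("tracking is equivariant under a global scene translation", {
  mk <- function(off) texturedScene(off)[21:140, 21:260]
  st1 <- initTracker(mk(c(0, 0)), boundingBox(44, 44, 32, 32))
  st2 <- initTracker(mk(c(9, 6)), boundingBox(53, 50, 32, 32))
  for (i in 1:8) {
    o1 <- trackStep(st1, mk(c(2 * i, i))); st1 <- o1$state
    o2 <- trackStep(st2, mk(c(2 * i + 9, i + 6))); st2 <- o2$state
    expect_equal(bboxCenter(o2$result) - bboxCenter(o1$result), c(9, 6),
                 tolerance = 1e-8)
  }
})

test_that("the spatial reliability mask isolates a bright disc", {
  nr <- 64L; nc <- 64L
  px <- rep(0:(nc - 1), each = nr); py <- rep(0:(nr - 1), times = nc)
  disc <- matrix(as.numeric((px - 32)^2 + (py - 32)^2 <= 12^2), nr, nc)
  set.seed(31)
  patch <- disc * 10 + 1 + matrix(stats::rnorm(nr * nc, sd = 0.3), nr, nc)
  m <- spatialReliabilityMask(patch, boundingBox(17, 17, 30, 30))
  inDisc <- disc > 0
  expect_gt(mean(m[inDisc]), 0.9)          # covers the disc
  expect_gt(mean(m[!inDisc] == 0), 0.9)    # excludes the background ring
  expect_lte(sum(m), nr * nc)

  # uniform patch falls back to all-ones over the bbox
  mu <- spatialReliabilityMask(matrix(2, nr, nc), boundingBox(17, 17, 30, 30))
  expect_equal(sum(mu), 30 * 30)
  expect_true(all(mu[20, 20] == 1))
})

test_that("the displacement threshold gates ROI updates", {
  roi <- circleRoi(50, 50, 10)
  r1 <- roiUpdate(roi, c(50, 50), c(50.4, 50.3), 1.0)
  expect_false(r1$moved)
  expect_equal(r1$roi@center, c(50, 50))

  r2 <- roiUpdate(roi, c(50, 50), c(55, 50), 1.0)
  expect_true(r2$moved)
  expect_equal(r2$roi@center, c(55, 50))

  r3 <- roiUpdate(roi, c(50, 50), c(50.01, 50), 0)
  expect_true(r3$moved)
  expect_error(roiUpdate(roi, c(0, 0), c(1, 1), -1), ">= 0")
})

test_that("sub-threshold jitter leaves the ROI trajectory exactly constant", {
  set.seed(41)
  roi <- circleRoi(50, 50, 10)
  center <- c(50, 50)
  for (i in 1:200) {
    jitter <- stats::runif(2, -0.6, 0.6)   # magnitude < 1 px threshold
    upd <- roiUpdate(roi, center, center + jitter, 1.0)
    roi <- upd$roi
    expect_false(upd$moved)
  }
  expect_identical(roi@center, c(50, 50))
})

test_that("a lesion is tracked across a simulated moving sequence", {
  cfg <- simulationConfig(shape = c(144L, 256L),
                          lesions = list(rectRoi(20, 52, 80, 40, id = "R1")),
                          tissueRect = boundingBox(4, 16, 248, 112),
                          trajectory = linearTrajectory(30L, c(2, 0)),
                          nFrames = 30L, seed = 5L)
  sim <- simulateSequence(cfg)
  res <- processSequence(sim@stack, cfg@lesions, runConfig())
  tr <- res@trajectories
  tc <- truthCenters(sim)
  err <- sqrt((tr$cx - tc$cx)^2 + (tr$cy - tc$cy)^2)
  expect_lte(mean(err), 2)
  expect_false(any(tr$lost))
})
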
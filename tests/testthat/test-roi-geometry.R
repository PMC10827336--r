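test_that("analytic ROI areas match the printed physical values", {
  scale <- 0.025                       # 40 px per cm
  circle1cm <- circleRoi(50, 50, 0.5 / scale)
  expect_equal(roiArea(circle1cm, scale), 0.785, tolerance = 1e-3)
  rect1x2cm <- rectRoi(10, 10, 1 / scale, 2 / scale)
  expect_equal(roiArea(rect1x2cm, scale), 2.0, tolerance = 1e-12)
  expect_error(roiArea(circle1cm, 0), "positive")
  expect_error(polygonRoi(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
})

test_that("rasterization uses boundary-inclusive pixel-center membership", {
  sq <- polygonRoi(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  expect_equal(sum(roiMask(sq, c(20L, 20L))), 121L)

  circ <- roiMask(circleRoi(40, 40, 20), c(90L, 90L))
  expect_lt(abs(sum(circ) / (pi * 400) - 1), 0.02)

  expect_warning(m <- roiMask(circleRoi(-50, -50, 5), c(30L, 30L)),
                 "no pixel")
  expect_equal(sum(m), 0L)
})

test_that("rasterized area converges to the analytic area", {
  for (r in c(20, 35)) {
    m <- roiMask(circleRoi(60, 60, r), c(120L, 120L))
    expect_lt(abs(sum(m) / (pi * r^2) - 1), 0.02)
  }
  tri <- polygonRoi(rbind(c(5, 5), c(85, 10), c(40, 90)))
  m <- roiMask(tri, c(100L, 100L))
  expect_lt(abs(sum(m) / roiArea(tri) - 1), 0.05)
})

test_that("mean intensity equals a brute-force masked mean", {
  img <- matrix(3.5, 40, 40)
  roi <- circleRoi(20, 20, 8)
  expect_equal(meanIntensity(img, roi), 3.5)

  # symmetric half/half split across the ROI
  img2 <- matrix(0, 41, 41); img2[, 1:20] <- 10
  sq <- polygonRoi(rbind(c(10.5, 10), c(28.5, 10), c(28.5, 30), c(10.5, 30)))
  expect_equal(meanIntensity(img2, sq), 5.0)

  set.seed(7)
  img3 <- matrix(stats::runif(50 * 50), 50, 50)
  roi3 <- polygonRoi(rbind(c(4, 8), c(44, 3), c(30, 45)))
  m <- roiMask(roi3, dim(img3))
  expect_equal(meanIntensity(img3, roi3), sum(img3[m]) / sum(m))

  # relabeling pixels outside the mask does not change the mean
  img4 <- img3; img4[!m] <- 99
  expect_equal(meanIntensity(img4, roi3), meanIntensity(img3, roi3))

  expect_error(meanIntensity(img, circleRoi(500, 500, 3)), "outside")
})

test_that("circumscribed bbox is minimal and contains the mask", {
  b <- circumscribedBbox(circleRoi(50, 50, 10))
  expect_equal(c(b@x, b@y, b@w, b@h), c(40, 40, 20, 20))
  b2 <- circumscribedBbox(polygonRoi(rbind(c(0, 0), c(4, 0), c(2, 6))))
  expect_equal(c(b2@x, b2@y, b2@w, b2@h), c(0, 0, 4, 6))
  # every mask-true pixel center lies inside the bbox
  set.seed(8)
  for (i in 1:5) {
    v <- matrix(stats::runif(8, 5, 55), 4, 2)
    roi <- tryCatch(polygonRoi(v), error = function(e) NULL)
    if (is.null(roi)) next
    m <- roiMask(roi, c(60L, 60L))
    bb <- circumscribedBbox(roi)
    idx <- which(m, arr.ind = TRUE)
    px <- idx[, 2L] - 1; py <- idx[, 1L] - 1
    expect_true(all(px >= bb@x - 1e-9 & px <= bb@x + bb@w + 1e-9))
    expect_true(all(py >= bb@y - 1e-9 & py <= bb@y + bb@h + 1e-9))
  }
})

test_that("translation preserves shape and area and shifts the bbox", {
  c0 <- circleRoi(10, 10, 5)
  expect_equal(translateRoi(c0, 0, 0)@center, c(10, 10))
  c1 <- translateRoi(c0, 5, 3)
  expect_equal(c1@center, c(15, 13))
  expect_equal(c1@radius, 5)

  set.seed(9)
  for (i in 1:5) {
    v <- matrix(stats::runif(10, 0, 40), 5, 2)
    roi <- tryCatch(polygonRoi(v), error = function(e) NULL)
    if (is.null(roi)) next
    dx <- stats::runif(1, -7, 7); dy <- stats::runif(1, -7, 7)
    tr <- translateRoi(roi, dx, dy)
    expect_equal(roiArea(tr), roiArea(roi), tolerance = 1e-12)
    b0 <- circumscribedBbox(roi); b1 <- circumscribedBbox(tr)
    expect_equal(c(b1@x - b0@x, b1@y - b0@y), c(dx, dy), tolerance = 1e-12)
  }
})

test_that("ROI files round-trip through the JSON/YAML schema", {
  rois <- list(circleRoi(12.5, 30, 7.25, id = "C1"),
               polygonRoi(rbind(c(1, 2), c(9, 2), c(5, 11)), id = "P1"))
  for (ext in c("json", "yaml")) {
    p <- file.path(tempdir(), paste0("rois.", ext))
    writeRoiFile(rois, p)
    back <- readRoiFile(p)
    expect_equal(back[[1]]@center, c(12.5, 30))
    expect_equal(back[[1]]@radius, 7.25)
    expect_equal(back[[2]]@vertices, rois[[2]]@vertices)
    expect_equal(vapply(back, roiId, character(1)), c("C1", "P1"))
    unlink(p)
  }
})
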
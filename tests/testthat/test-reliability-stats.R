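test_that("ICC(2,1) handles perfect agreement and agreement-free data", {
  r <- iccTwoWay(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(iccValue(r), 1.0)
  expect_equal(iccCategory(r), "excellent")

  set.seed(51)
  noise <- matrix(stats::rnorm(400), 200, 2)
  expect_lt(abs(iccValue(iccTwoWay(noise))), 0.15)

  expect_error(iccTwoWay(cbind(c(1, 2), c(1, 2))), "n >= 3")
  expect_error(iccTwoWay(matrix(1:6, 6, 1)), "k >= 2")
  expect_error(iccTwoWay(matrix(5, 4, 2)), "zero total variance")
})

test_that("ICC matches the independent ANOVA oracle to 1e-6", {
  expect_equal(iccValue(iccTwoWay(rbind(c(9, 8), c(1, 2), c(8, 9),
                                        c(2, 1), c(6, 5)))),
               iccAovOracle(rbind(c(9, 8), c(1, 2), c(8, 9),
                                  c(2, 1), c(6, 5))),
               tolerance = 1e-6)
  set.seed(52)
  for (i in 1:50) {
    n <- sample(4:30, 1); k <- sample(2:5, 1)
    m <- matrix(stats::rnorm(n * k, mean = rep(stats::rnorm(n, sd = 2), k)),
                n, k)
    expect_equal(iccValue(iccTwoWay(m)), iccAovOracle(m), tolerance = 1e-6)
  }
})

test_that("ICC is invariant under shift and positive scaling", {
  set.seed(53)
  m <- simulateTwoWay(40, 3, 0.6)
  base <- iccValue(iccTwoWay(m))
  expect_equal(iccValue(iccTwoWay(m + 17.3)), base, tolerance = 1e-10)
  expect_equal(iccValue(iccTwoWay(m * 4.2)), base, tolerance = 1e-10)
})

test_that("ICC recovers a known variance ratio from simulated raters", {
  set.seed(54)
  for (rho in c(0.2, 0.5, 0.9)) {
    est <- mean(replicate(5, iccValue(iccTwoWay(simulateTwoWay(500, 2, rho)))))
    expect_lt(abs(est - rho), 0.05)
  }
})

test_that("the variance decomposition is internally consistent", {
  set.seed(55)
  m <- simulateTwoWay(100, 2, 0.7)
  r <- iccTwoWay(m)
  expect_gte(r@sigmaB2, 0)
  expect_gte(r@sigmaW2, 0)
  expect_equal(r@icc, r@sigmaB2 / (r@sigmaB2 + r@sigmaW2), tolerance = 1e-8)
})

test_that("reliability bands follow the 0.5/0.75/0.9 cut points", {
  expect_equal(classifyReliability(0.134), "poor")
  expect_equal(classifyReliability(0.49999), "poor")
  expect_equal(classifyReliability(0.5), "moderate")
  expect_equal(classifyReliability(0.75), "good")
  expect_equal(classifyReliability(0.9), "excellent")
  expect_equal(classifyReliability(0.976), "excellent")
  expect_equal(classifyReliability(-0.1), "poor")
  expect_error(classifyReliability(1.2), "<= 1")
})

test_that("the moving average has the exact kernel behaviour", {
  expect_equal(movingAverage(c(3, 1, 4, 1, 5), 1L), c(3, 1, 4, 1, 5))
  expect_equal(movingAverage(rep(2.5, 10), 5L), rep(2.5, 10))

  imp <- c(0, 0, 0, 1, 0, 0, 0)
  expect_equal(movingAverage(imp, 3L), c(0, 0, 1/3, 1/3, 1/3, 0, 0))

  expect_error(movingAverage(1:10, 4L), "odd")
  expect_error(movingAverage(1:3, 5L), "odd|within")
})

test_that("averaging suppresses motion-artifact spikes", {
  t <- seq(0, 4 * pi, length.out = 120)
  clean <- sin(t)
  corrupted <- clean
  corrupted[c(20, 55, 90)] <- corrupted[c(20, 55, 90)] + c(4, -5, 4.5)
  filt <- movingAverage(corrupted, 5L)
  expect_lt(max(abs(filt - clean)), max(abs(corrupted - clean)))

  # trace container round-trip keeps metadata
  tr <- perfusionTrace(corrupted, roiId = "C1", source = "manual")
  ftr <- movingAverage(tr, 5L)
  expect_equal(traceValues(ftr), filt)
  expect_equal(roiId(ftr), "C1")
})
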
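# Shared fixtures and independent oracles, all built in code.

# Textured scene with a bright Gaussian blob at (cx, cy) = (80, 80) + off,
# over a smooth moving background; used for tracker tests.
texturedScene <- function(off = c(0, 0), nr = 160L, nc = 288L) {
  x <- outer(seq_len(nr), seq_len(nc), function(r, c) {
    sin((c - off[1L]) / 7) + cos((r - off[2L]) / 9) +
      0.6 * sin((c - off[1L]) / 2.3) * cos((r - off[2L]) / 1.9) +
      0.4 * cos((c - off[1L]) / 3.1 + (r - off[2L]) / 2.6)
  })
  cx <- 80 + off[1L]; cy <- 80 + off[2L]
  x + 3 * exp(-(outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, `+`)) /
                (2 * 8^2))
}

# Brute-force spatial contrast: per-pixel loop over the symmetric-reflected
# neighbourhood, population sd / mean.
bruteForceContrast <- function(frame, window) {
  p <- (window - 1L) %/% 2L
  refl <- function(n) {
    idx <- seq.int(1L - p, n + p)
    per <- (idx - 1L) %% (2L * n)
    ifelse(per >= n, 2L * n - 1L - per, per) + 1L
  }
  fp <- frame[refl(nrow(frame)), refl(ncol(frame))]
  out <- matrix(0, nrow(frame), ncol(frame))
  for (r in seq_len(nrow(frame))) {
    for (c in seq_len(ncol(frame))) {
      v <- fp[r:(r + 2L * p), c:(c + 2L * p)]
      m <- mean(v)
      out[r, c] <- if (m > 0) sqrt(mean((v - m)^2)) / m else 0
    }
  }
  out
}

# Independent ICC(2,1) oracle assembled from stats::aov mean squares.
iccAovOracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   target = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ target + rater, data = df))[[1L]]
  rn <- trimws(rownames(tab))
  msr <- tab[rn == "target", "Mean Sq"]
  msc <- tab[rn == "rater", "Mean Sq"]
  mse <- tab[rn == "Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Synthetic two-way random data with known variance ratio rho*.
simulateTwoWay <- function(n, k, rho, raterFrac = 0.1) {
  t <- stats::rnorm(n, sd = sqrt(rho))
  r <- stats::rnorm(k, sd = sqrt((1 - rho) * raterFrac))
  e <- matrix(stats::rnorm(n * k, sd = sqrt((1 - rho) * (1 - raterFrac))),
              n, k)
  outer(t, rep(1, k)) + outer(rep(1, n), r) + e
}

# Erode a logical mask by b pixels (4-neighbourhood), to restrict
# region statistics to interiors where a sliding window does not straddle
# the region boundary.
erodeMask <- function(m, b) {
  for (i in seq_len(b)) {
    m <- m & rbind(m[-1L, ], FALSE) & rbind(FALSE, m[-nrow(m), ]) &
      cbind(m[, -1L], FALSE) & cbind(FALSE, m[, -ncol(m)])
  }
  m
}
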
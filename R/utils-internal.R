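# Internal numerics shared across modules. Pixel coordinates are 0-based
# (x = column, y = row) with pixel centers at integers; R matrix indices are
# 1-based, so matrix[r, c] holds pixel (x = c - 1, y = r - 1).

# Signed shoelace area is direction-dependent; callers want magnitude.
shoelaceArea <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

# Edge-inclusive symmetric reflection indices: for n = 3, p = 2 the left
# extension reads 2, 1 | 1, 2, 3 | 3, 2.
reflectIndex <- function(n, p) {
  idx <- seq.int(1L - p, n + p)
  per <- ((idx - 1L) %% (2L * n))
  per <- ifelse(per >= n, 2L * n - 1L - per, per)
  per + 1L
}

padSymmetric <- function(m, p) {
  m[reflectIndex(nrow(m), p), reflectIndex(ncol(m), p), drop = FALSE]
}

# Sliding window x window box sums over a symmetrically padded matrix,
# via a summed-area table; returns a matrix shaped like the input.
boxSum <- function(m, window) {
  p <- (window - 1L) %/% 2L
  mp <- padSymmetric(m, p)
  sat <- apply(apply(mp, 2L, cumsum), 1L, cumsum)  # transposed SAT
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  nr <- nrow(m); nc <- ncol(m)
  r2 <- (1L + 2L * p):(nr + 2L * p) + 1L
  r1 <- 1L:nr
  c2 <- (1L + 2L * p):(nc + 2L * p) + 1L
  c1 <- 1L:nc
  sat[r2, c2] - sat[r1, c2] - sat[r2, c1] + sat[r1, c1]
}

# Bilinear sample of matrix m at real-valued pixel coordinates (x, y),
# 0-based, clamped to the image border (replicate padding).
bilinearSample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x1 + 1)
  i10 <- cbind(y1 + 1, x0 + 1); i11 <- cbind(y1 + 1, x1 + 1)
  m[i00] * (1 - fx) * (1 - fy) + m[i01] * fx * (1 - fy) +
    m[i10] * (1 - fx) * fy + m[i11] * fx * fy
}

# Rigid sub-pixel shift: output pixel (x, y) takes the input value at
# (x - dx, y - dy), border-clamped.
shiftImage <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  xs <- rep(0:(nc - 1), each = nr) - dx
  ys <- rep(0:(nr - 1), times = nc) - dy
  matrix(bilinearSample(m, xs, ys), nr, nc)
}

# Extract a (h x w) patch centered at real-valued (cx, cy), border-clamped.
extractPatch <- function(m, cx, cy, w, h) {
  xs <- cx - (w - 1) / 2 + 0:(w - 1)
  ys <- cy - (h - 1) / 2 + 0:(h - 1)
  matrix(bilinearSample(m, rep(xs, each = h), rep(ys, times = w)), h, w)
}

hannWindow <- function(h, w) {
  wy <- if (h > 1) 0.5 * (1 - cos(2 * pi * (0:(h - 1)) / (h - 1))) else 1
  wx <- if (w > 1) 0.5 * (1 - cos(2 * pi * (0:(w - 1)) / (w - 1))) else 1
  outer(wy, wx)
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

bboxCenterXY <- function(b) c(b@x + b@w / 2, b@y + b@h / 2)

stopifnotArg <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
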
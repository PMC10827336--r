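#' Spatial speckle contrast
#'
#' Computes the per-pixel speckle contrast K = sigma / <I>, the ratio of the
#' population standard deviation to the mean of the intensity over the
#' \code{window} x \code{window} neighbourhood centered on each pixel.
#' Borders are handled by edge-inclusive symmetric reflection so the output
#' has the same shape as the input and ROIs near the border remain
#' analyzable. Pixels whose neighbourhood mean is 0 get K = 0.
#'
#' K is scale-invariant (a ratio), so it is insensitive to illumination
#' gain. Lower K means stronger motion blur of the speckle during the
#' exposure, i.e. faster flow.
#'
#' @param frame numeric matrix of non-negative intensities (a raw speckle
#'   frame), or a \linkS4class{FrameStack} (the indicated frame is used).
#' @param window odd integer window side, \code{3 <= window <= min(dim)}.
#'   The 7x7 default is common LASCA practice.
#' @param frameIndex which frame of a stack to use (1-based), default 1.
#' @return a \linkS4class{ContrastImage}.
#' @examples
#' f <- matrix(1:9, 3, 3, byrow = TRUE)
#' kValues(spatialContrast(f, 3))[2, 2]  # 0.5164 = popsd(1:9) / 5
#' @export
spatialContrast <- function(frame, window = 7L, frameIndex = 1L) {
  if (is(frame, "FrameStack")) frame <- frame@frames[[frameIndex]]
  stopifnotArg(is.matrix(frame) && length(frame) > 0,
               "frame must be a non-empty matrix")
  stopifnotArg(all(is.finite(frame)) && all(frame >= 0),
               "frame must hold finite non-negative intensities")
  window <- as.integer(window)
  stopifnotArg(length(window) == 1L && window %% 2L == 1L && window >= 3L &&
               window <= min(dim(frame)),
               "window must be odd and within [3, min(rows, cols)]")
  n <- as.numeric(window)^2
  m1 <- boxSum(frame, window) / n
  m2 <- boxSum(frame * frame, window) / n
  v <- pmax(m2 - m1 * m1, 0)          # population variance; clamp fp noise
  k <- matrix(0, nrow(frame), ncol(frame))
  pos <- m1 > 0
  k[pos] <- sqrt(v[pos]) / m1[pos]
  new("ContrastImage", k = k, window = window, method = "spatial")
}

#' Temporal speckle contrast
#'
#' Applies the contrast definition along the time axis: for each pixel, K =
#' population sd / mean over a sliding window of \code{depth} consecutive
#' frames. One \linkS4class{ContrastImage} is returned per window position
#' (so \code{length(frames) - depth + 1} images).
#'
#' @param stack a \linkS4class{FrameStack} (or list of matrices) with at
#'   least \code{depth} aligned frames.
#' @param depth temporal window, integer >= 2.
#' @return list of \linkS4class{ContrastImage}.
#' @export
temporalContrast <- function(stack, depth = 5L) {
  fr <- if (is(stack, "FrameStack")) stack@frames else stack
  depth <- as.integer(depth)
  stopifnotArg(depth >= 2L, "depth must be >= 2")
  stopifnotArg(length(fr) >= depth, "stack holds fewer frames than depth")
  nWin <- length(fr) - depth + 1L
  out <- vector("list", nWin)
  for (i in seq_len(nWin)) {
    s1 <- 0; s2 <- 0
    for (j in i:(i + depth - 1L)) { s1 <- s1 + fr[[j]]; s2 <- s2 + fr[[j]]^2 }
    m1 <- s1 / depth
    v <- pmax(s2 / depth - m1 * m1, 0)
    k <- matrix(0, nrow(m1), ncol(m1))
    pos <- m1 > 0
    k[pos] <- sqrt(v[pos]) / m1[pos]
    out[[i]] <- new("ContrastImage", k = k, window = depth,
                    method = "temporal")
  }
  out
}

#' Relative flow index 1/K^2
#'
#' Converts a contrast image into the relative flow index 1 / max(K,
#' kFloor)^2, exploiting the proportionality between 1/K^2 and flow speed.
#' The index is reported in arbitrary units (AU); no absolute velocity
#' calibration is attempted.
#'
#' @param contrast a \linkS4class{ContrastImage} (or bare K matrix).
#' @param kFloor positive clamp applied to K before inversion (keeps the
#'   index finite over static, near-zero-K regions). Default 1e-3.
#' @return a \linkS4class{FlowIndexImage}.
#' @export
flowIndex <- function(contrast, kFloor = 1e-3) {
  k <- if (is(contrast, "ContrastImage")) contrast@k else contrast
  stopifnotArg(is.numeric(kFloor) && length(kFloor) == 1L && kFloor > 0,
               "kFloor must be a single positive value")
  stopifnotArg(all(k >= 0), "contrast values must be >= 0")
  new("FlowIndexImage", values = 1 / pmax(k, kFloor)^2, kFloor = kFloor)
}

#' Render a perfusion colour map
#'
#' Maps per-pixel flow (1/K^2, or reversed K) linearly onto a blue-to-red
#' colour scale: high flow (low contrast) renders red, low flow (high
#' contrast) renders blue. Values are clipped to [vmin, vmax]. The result
#' is a rows x cols x 3 array in [0, 1], suitable for
#' \code{png::writePNG}.
#'
#' @param contrast \linkS4class{ContrastImage}, \linkS4class{FlowIndexImage}
#'   or bare matrix of the quantity to render.
#' @param vmin,vmax display range (vmin < vmax). When NULL, the observed
#'   range of the rendered quantity is used.
#' @param invert set TRUE when passing a ContrastImage so that low K maps
#'   to the red end (the default for ContrastImage input).
#' @return numeric array rows x cols x 3 (RGB in [0, 1]).
#' @export
renderContrastMap <- function(contrast, vmin = NULL, vmax = NULL,
                              invert = is(contrast, "ContrastImage")) {
  v <- if (is(contrast, "ContrastImage")) contrast@k
       else if (is(contrast, "FlowIndexImage")) contrast@values
       else contrast
  if (is.null(vmin)) vmin <- min(v)
  if (is.null(vmax)) vmax <- max(v)
  stopifnotArg(vmin < vmax, "vmin must be < vmax")
  u <- (pmin(pmax(v, vmin), vmax) - vmin) / (vmax - vmin)
  if (invert) u <- 1 - u    # low contrast = high flow = red end
  ramp <- grDevices::colorRamp(c("#0000FF", "#00FFFF", "#00FF00",
                                 "#FFFF00", "#FF0000"), space = "rgb")
  rgb <- ramp(as.vector(u)) / 255
  array(rgb, dim = c(nrow(v), ncol(v), 3L))
}

#' Segment static background by contrast thresholding
#'
#' A static scene (e.g. a light-absorbing cloth behind the limb) keeps its
#' fully developed speckle, K close to 1, while perfused tissue blurs to
#' much lower K. Thresholding the contrast image therefore separates
#' background from tissue.
#'
#' @param contrast a \linkS4class{ContrastImage} (or K matrix).
#' @param threshold contrast threshold; pixels with K > threshold are
#'   flagged as background.
#' @return logical matrix, TRUE on background, FALSE on tissue (the
#'   foreground is the complement).
#' @export
segmentBackground <- function(contrast, threshold = 0.6) {
  k <- if (is(contrast, "ContrastImage")) contrast@k else contrast
  k > threshold
}
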
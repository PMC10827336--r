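#' Tracker settings
#'
#' Defaults follow standard discriminative-correlation-filter practice:
#' exponential moving-average learning rate 0.02, ridge regularization
#' lambda = 0.01, search template padded to 2x the bounding box, cosine
#' (Hann) window on the template, Gaussian target response with sigma =
#' sqrt(w h) / 16 (sharp enough for sub-pixel localization). Feature channels for monochrome speckle are raw
#' intensity, gradient magnitude and orientation-binned gradients (4
#' bins). The displacement threshold (1 px Euclidean) is the smallest
#' value that suppresses sub-pixel bounding-box jitter on a static target.
#'
#' @param learningRate filter EMA learning rate in (0, 1].
#' @param lambda ridge regularization of the filter denominator.
#' @param padding template size as a multiple of the bbox size.
#' @param sigmaFactor Gaussian target sigma = sigmaFactor * sqrt(w * h).
#' @param orientBins number of gradient-orientation channels.
#' @param searchRadiusPx cap on the per-frame displacement considered in
#'   the response map (default 10 px — a standard search-window
#'   restriction; set Inf for the whole template).
#' @param displacementThresholdPx bbox displacement below which the target
#'   is considered stationary.
#' @param lostResponseFrac fraction of the training-frame response peak
#'   below which the target is declared lost (bbox held, frame flagged).
#' @param weightLearningRate EMA rate for channel-reliability weights.
#' @param maskFloor soft floor applied to the spatial reliability mask so
#'   some background context survives the masking.
#' @return named list of settings.
#' @export
trackerConfig <- function(learningRate = 0.02, lambda = 0.01, padding = 2,
                          sigmaFactor = 0.0625, orientBins = 4L,
                          searchRadiusPx = 10,
                          displacementThresholdPx = 1.0,
                          lostResponseFrac = 0.2,
                          weightLearningRate = 0.2, maskFloor = 0.25) {
  list(learningRate = learningRate, lambda = lambda, padding = padding,
       sigmaFactor = sigmaFactor, orientBins = as.integer(orientBins),
       searchRadiusPx = searchRadiusPx,
       displacementThresholdPx = displacementThresholdPx,
       lostResponseFrac = lostResponseFrac,
       weightLearningRate = weightLearningRate, maskFloor = maskFloor)
}

# Feature channels of a template patch: normalized intensity, gradient
# magnitude, and hard-binned gradient orientations weighted by magnitude.
featureChannels <- function(patch, orientBins) {
  s <- stats::sd(patch)
  if (!is.finite(s) || s < 1e-12)
    stop("degenerate template: patch has no texture", call. = FALSE)
  nr <- nrow(patch); nc <- ncol(patch)
  gx <- (patch[, c(2:nc, nc)] - patch[, c(1, 1:(nc - 1))]) / 2
  gy <- (patch[c(2:nr, nr), ] - patch[c(1, 1:(nr - 1)), ]) / 2
  gm <- sqrt(gx^2 + gy^2)
  chans <- list(intensity = (patch - mean(patch)) / s,
                gradmag = (gm - mean(gm)) / (stats::sd(gm) + 1e-12))
  ang <- atan2(gy, gx) %% pi
  binW <- pi / orientBins
  for (b in seq_len(orientBins)) {
    sel <- ang >= (b - 1) * binW & ang < b * binW
    ob <- gm * sel
    chans[[paste0("orient", b)]] <- ob / (stats::sd(ob) + 1e-12)
  }
  chans
}

#' Spatial reliability mask
#'
#' Estimates a per-pixel foreground probability for the template patch
#' from intensity histograms of the bounding-box interior (foreground
#' model) against the surrounding padding ring (background model), via
#' Bayes' rule with area priors. The probability map is binarized at 0.5
#' and regularized to its largest connected component. When the two
#' histograms are indistinguishable, or the component covers less than
#' \code{minCoverage} of the bounding-box area, the mask falls back to
#' all-ones over the bounding box.
#'
#' @param patch numeric template patch (contains the bbox plus padding).
#' @param bbox \linkS4class{BoundingBox} in patch-local 0-based
#'   coordinates.
#' @param nBins histogram bins.
#' @param minCoverage minimal mask area as a fraction of the bbox area.
#' @return numeric 0/1 matrix shaped like the patch.
#' @export
spatialReliabilityMask <- function(patch, bbox, nBins = 16L,
                                   minCoverage = 0.25) {
  nr <- nrow(patch); nc <- ncol(patch)
  px <- rep(0:(nc - 1), each = nr); py <- rep(0:(nr - 1), times = nc)
  inBox <- matrix(px >= bbox@x & px < bbox@x + bbox@w &
                  py >= bbox@y & py < bbox@y + bbox@h, nr, nc)
  fallback <- matrix(0, nr, nc); fallback[inBox] <- 1
  rng <- range(patch)
  if (diff(rng) < 1e-12) return(fallback)
  breaks <- seq(rng[1L], rng[2L], length.out = nBins + 1L)
  bin <- pmin(findInterval(patch, breaks, rightmost.closed = TRUE), nBins)
  cf <- tabulate(bin[inBox], nBins) + 1   # Laplace smoothing
  cb <- tabulate(bin[!inBox], nBins) + 1
  pf <- cf / sum(cf); pb <- cb / sum(cb)
  if (sum(abs(pf - pb)) < 0.05) return(fallback)   # indistinguishable
  af <- sum(inBox) / length(inBox)
  post <- pf[bin] * af / (pf[bin] * af + pb[bin] * (1 - af))
  m <- matrix(as.numeric(post > 0.5), nr, nc)
  if (any(m > 0)) {
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(lab[lab > 0])
    m <- matrix(as.numeric(lab == which.max(sizes)), nr, nc)
  }
  if (sum(m) < minCoverage * bbox@w * bbox@h) return(fallback)
  m
}

trainingTransforms <- function(cfg, tw, th, bw, bh) {
  cx0 <- floor(tw / 2); cy0 <- floor(th / 2)
  sigma <- cfg$sigmaFactor * sqrt(bw * bh)
  g <- exp(-(outer((0:(th - 1) - cy0)^2, (0:(tw - 1) - cx0)^2, `+`)) /
             (2 * sigma^2))
  list(ghat = fft2(g), hann = hannWindow(th, tw), cx0 = cx0, cy0 = cy0)
}

# Training features are windowed AND constrained to the spatial reliability
# mask (the filter learns from the foreground); detection features are only
# cosine-windowed — masking the test patch would anchor the response to the
# previous target position.
maskedFeatureFFT <- function(patch, cfg, hann, mask = NULL) {
  env <- if (is.null(mask)) hann
         else hann * (cfg$maskFloor + (1 - cfg$maskFloor) * mask)
  lapply(featureChannels(patch, cfg$orientBins),
         function(ch) fft2(ch * env))
}

#' Initialize the correlation-filter tracker
#'
#' Trains per-channel correlation filters on the first frame: features are
#' extracted from a template patch (bbox padded 2x), windowed by a cosine
#' window and the spatial reliability mask, and each channel's filter is
#' the ridge-regularized frequency-domain solution whose response to the
#' training patch is a Gaussian peaked at the bbox center
#' (self-detection). Channel weights start uniform. The bbox size stays
#' fixed for the whole run.
#'
#' @param image numeric matrix (typically the speckle-contrast image of
#'   the first frame; raw frames work too).
#' @param bbox initial \linkS4class{BoundingBox} (within the image, area
#'   >= 16 px).
#' @param config settings from \code{\link{trackerConfig}}.
#' @return a \linkS4class{TrackerState}.
#' @export
initTracker <- function(image, bbox, config = trackerConfig()) {
  stopifnotArg(is.matrix(image), "image must be a matrix")
  stopifnotArg(bbox@w * bbox@h >= 16, "bbox area must be >= 16 px")
  stopifnotArg(bbox@x >= 0 && bbox@y >= 0 &&
               bbox@x + bbox@w <= ncol(image) &&
               bbox@y + bbox@h <= nrow(image),
               "bbox must lie within the image")
  ctr <- bboxCenterXY(bbox)
  tw <- max(8L, as.integer(round(config$padding * bbox@w)))
  th <- max(8L, as.integer(round(config$padding * bbox@h)))
  tt <- trainingTransforms(config, tw, th, bbox@w, bbox@h)
  patch <- extractPatch(image, ctr[1L], ctr[2L], tw, th)
  localBbox <- boundingBox(tt$cx0 - bbox@w / 2, tt$cy0 - bbox@h / 2,
                           bbox@w, bbox@h)
  mask <- spatialReliabilityMask(patch, localBbox)
  Fs <- maskedFeatureFFT(patch, config, tt$hann, mask)
  num <- lapply(Fs, function(Fc) tt$ghat * Conj(Fc))
  den <- lapply(Fs, function(Fc) Fc * Conj(Fc))
  wts <- rep(1 / length(Fs), length(Fs))
  st <- new("TrackerState", num = num, den = den, channelWeights = wts,
            spatialMask = mask, templateSize = c(tw, th),
            lastBbox = bbox, ghat = tt$ghat, hann = tt$hann,
            peakRef = 1, origin = c(0, 0), config = config)
  self <- responseMap(st, maskedFeatureFFT(patch, config, tt$hann))
  st@peakRef <- self$peak
  st@origin <- responseOrigin(self$R, tw, th)
  st
}

# Sub-pixel peak of a self-response: the filter is trained under the
# spatial reliability mask but detects on unmasked features, so its
# self-response peak sits slightly off the nominal template center.
# Displacements are measured relative to this origin.
responseOrigin <- function(R, tw, th) {
  wd <- wrappedDisplacement(tw, th)
  pk <- arrayInd(which.max(R), dim(R))
  r <- pk[1L]; c <- pk[2L]
  rm <- function(i, j) R[(i - 1) %% th + 1, (j - 1) %% tw + 1]
  c(wd$dx[r, c] + quadraticPeakOffset(rm(r, c - 1), R[pk], rm(r, c + 1)),
    wd$dy[r, c] + quadraticPeakOffset(rm(r - 1, c), R[pk], rm(r + 1, c)))
}

# Channel-weighted correlation response for precomputed (detection-side)
# feature FFTs. Regularization is relative to each channel's spectral
# energy so the filter is scale-invariant; channel quality is the
# peak-to-sidelobe ratio of its response.
responseMap <- function(state, Fs) {
  cfg <- state@config
  perChannelPsr <- numeric(length(Fs))
  R <- 0
  for (i in seq_along(Fs)) {
    den <- state@den[[i]]
    Hc <- state@num[[i]] / (den + cfg$lambda * mean(Re(den)))
    Rc <- Re(ifft2(Hc * Fs[[i]]))
    perChannelPsr[i] <- (max(Rc) - mean(Rc)) / (stats::sd(Rc) + 1e-12)
    R <- R + state@channelWeights[i] * Rc
  }
  list(R = R, peak = max(R), channelPsr = perChannelPsr)
}

# Displacement grids (wrapped) for a template of size (tw, th) whose target
# response peaks at (cx0, cy0).
wrappedDisplacement <- function(tw, th) {
  cx0 <- floor(tw / 2); cy0 <- floor(th / 2)
  dx <- ((0:(tw - 1)) - cx0 + tw / 2) %% tw - tw / 2
  dy <- ((0:(th - 1)) - cy0 + th / 2) %% th - th / 2
  list(dx = matrix(dx, th, tw, byrow = TRUE), dy = matrix(dy, th, tw))
}

quadraticPeakOffset <- function(rm1, r0, rp1) {
  if (!all(is.finite(c(rm1, r0, rp1)))) return(0)
  d <- rm1 - 2 * r0 + rp1
  if (abs(d) < 1e-12) return(0)
  off <- 0.5 * (rm1 - rp1) / d
  max(min(off, 0.5), -0.5)
}

#' One tracking step
#'
#' Extracts the template patch at the last bbox position of the new frame,
#' correlates it with the per-channel filters, and moves the bbox to the
#' channel-weighted response maximum (sub-pixel refined by a quadratic fit
#' around the peak, optionally restricted to \code{searchRadiusPx}).
#' Filters and the reliability mask are then updated at the new position
#' by exponential moving average, and channel weights are re-estimated
#' from each channel's response peak. If the response peak falls below
#' the lost-target floor the bbox is held and the frame flagged rather
#' than erroring.
#'
#' @param state a \linkS4class{TrackerState}.
#' @param image matrix with the same dimensions as the initialization
#'   frame.
#' @return list with elements \code{state} (updated
#'   \linkS4class{TrackerState}) and \code{result}
#'   (\linkS4class{TrackResult}).
#' @export
trackStep <- function(state, image) {
  cfg <- state@config
  tw <- state@templateSize[1L]; th <- state@templateSize[2L]
  prevCtr <- bboxCenterXY(state@lastBbox)
  patch <- extractPatch(image, prevCtr[1L], prevCtr[2L], tw, th)
  Fs <- maskedFeatureFFT(patch, cfg, state@hann)
  rsp <- responseMap(state, Fs)
  R <- rsp$R
  wd <- wrappedDisplacement(tw, th)
  if (is.finite(cfg$searchRadiusPx))
    R[wd$dx^2 + wd$dy^2 > cfg$searchRadiusPx^2] <- -Inf
  pk <- arrayInd(which.max(R), dim(R))
  peak <- R[pk]
  lost <- peak < cfg$lostResponseFrac * state@peakRef
  if (lost) {
    res <- new("TrackResult", bbox = state@lastBbox, center = prevCtr,
               responsePeak = peak, moved = FALSE, lost = TRUE)
    return(list(state = state, result = res))
  }
  r <- pk[1L]; c <- pk[2L]
  rm <- function(i, j) R[(i - 1) %% th + 1, (j - 1) %% tw + 1]
  subX <- quadraticPeakOffset(rm(r, c - 1), peak, rm(r, c + 1))
  subY <- quadraticPeakOffset(rm(r - 1, c), peak, rm(r + 1, c))
  dx <- wd$dx[r, c] + subX - state@origin[1L]
  dy <- wd$dy[r, c] + subY - state@origin[2L]
  newCtr <- prevCtr + c(dx, dy)
  newBbox <- boundingBox(newCtr[1L] - state@lastBbox@w / 2,
                         newCtr[2L] - state@lastBbox@h / 2,
                         state@lastBbox@w, state@lastBbox@h)
  # model update at the new position
  upPatch <- extractPatch(image, newCtr[1L], newCtr[2L], tw, th)
  cx0 <- floor(tw / 2); cy0 <- floor(th / 2)
  localBbox <- boundingBox(cx0 - state@lastBbox@w / 2,
                           cy0 - state@lastBbox@h / 2,
                           state@lastBbox@w, state@lastBbox@h)
  newMask <- spatialReliabilityMask(upPatch, localBbox)
  upFs <- maskedFeatureFFT(upPatch, cfg, state@hann, newMask)
  lr <- cfg$learningRate
  for (i in seq_along(upFs)) {
    state@num[[i]] <- (1 - lr) * state@num[[i]] +
      lr * state@ghat * Conj(upFs[[i]])
    state@den[[i]] <- (1 - lr) * state@den[[i]] +
      lr * upFs[[i]] * Conj(upFs[[i]])
  }
  wNew <- pmax(rsp$channelPsr, 1e-9)
  wNew <- wNew / sum(wNew)
  w <- (1 - cfg$weightLearningRate) * state@channelWeights +
    cfg$weightLearningRate * wNew
  state@channelWeights <- w / sum(w)
  state@spatialMask <- newMask
  state@lastBbox <- newBbox
  selfR <- responseMap(state, maskedFeatureFFT(upPatch, cfg, state@hann))$R
  state@origin <- responseOrigin(selfR, tw, th)
  state@peakRef <- (1 - lr) * state@peakRef + lr * peak
  moved <- sqrt(dx^2 + dy^2) > cfg$displacementThresholdPx
  res <- new("TrackResult", bbox = newBbox, center = newCtr,
             responsePeak = peak, moved = moved, lost = FALSE)
  list(state = state, result = res)
}

#' Displacement-threshold ROI update
#'
#' The tracked bounding box jitters slightly even on a stationary target;
#' repositioning the ROI on every frame would propagate that jitter into
#' the perfusion trace. The ROI is therefore moved only when the Euclidean
#' displacement of the bbox center exceeds \code{thresholdPx}; below the
#' threshold the target is considered stationary and the ROI keeps its
#' position.
#'
#' @param roi the current \linkS4class{Roi}.
#' @param prevCenter,newCenter bbox centers (cx, cy) of the previous and
#'   current frame.
#' @param thresholdPx displacement threshold in pixels (>= 0); default
#'   1 px.
#' @return list(roi = updated Roi, moved = logical).
#' @export
roiUpdate <- function(roi, prevCenter, newCenter, thresholdPx = 1.0) {
  stopifnotArg(thresholdPx >= 0, "thresholdPx must be >= 0")
  d <- newCenter - prevCenter
  if (sqrt(sum(d^2)) > thresholdPx) {
    list(roi = translateRoi(roi, d[1L], d[2L]), moved = TRUE)
  } else {
    list(roi = roi, moved = FALSE)
  }
}
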
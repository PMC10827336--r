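#' Synthesize a fully developed speckle field
#'
#' Draws a circularly symmetric complex Gaussian field, low-pass filters it
#' in the frequency domain to the requested grain scale, and normalizes to
#' unit mean intensity. Because filtering preserves Gaussianity, the
#' pointwise intensity |field|^2 is exactly exponentially distributed, so a
#' static scene has global contrast sigma/mean = 1 — the defining property
#' of fully developed speckle.
#'
#' @param shape integer (rows, cols).
#' @param grainSigmaPx spatial grain scale in pixels (>= 1).
#' @param seed optional integer seed; when NULL the current RNG stream is
#'   used (so a sequence of calls inside a seeded simulation stays
#'   reproducible).
#' @return complex matrix with attribute \code{grainSigmaPx}; intensity =
#'   \code{Mod(field)^2}.
#' @export
synthSpeckleField <- function(shape, grainSigmaPx = 1.5, seed = NULL) {
  stopifnotArg(grainSigmaPx >= 1, "grainSigmaPx must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  nr <- shape[1L]; nc <- shape[2L]
  w <- matrix(complex(real = stats::rnorm(nr * nc),
                      imaginary = stats::rnorm(nr * nc)), nr, nc)
  fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  # transfer function of a Gaussian kernel with spatial sigma grainSigmaPx
  H <- exp(-2 * pi^2 * grainSigmaPx^2 * outer(fy^2, fx^2, `+`))
  f <- ifft2(fft2(w) * H)
  f <- f / sqrt(mean(Mod(f)^2))
  attr(f, "grainSigmaPx") <- grainSigmaPx
  f
}

#' Evolve a speckle field by one decorrelation step
#'
#' First-order autoregressive update on the complex field (not the
#' intensity): field' = rho field + sqrt(1 - rho^2) w, with w an
#' independent unit field of the same grain. This keeps single-frame
#' statistics exactly fully developed at every step, while successive
#' intensities decorrelate with coefficient rho^2. With rho =
#' exp(-dt/tau), tau is the field decorrelation time.
#'
#' @param field complex field from \code{\link{synthSpeckleField}}.
#' @param rho correlation coefficient in [0, 1].
#' @param seed optional integer seed for the innovation field.
#' @return evolved complex field (same grain attribute).
#' @export
evolveField <- function(field, rho, seed = NULL) {
  stopifnotArg(is.numeric(rho) && length(rho) == 1L && rho >= 0 && rho <= 1,
               "rho must lie in [0, 1]")
  if (rho == 1) return(field)
  g <- attr(field, "grainSigmaPx")
  if (is.null(g)) g <- 1.5
  w <- synthSpeckleField(dim(field), g, seed = seed)
  out <- rho * field + sqrt(1 - rho^2) * w
  attr(out, "grainSigmaPx") <- g
  out
}

#' Trajectory helpers
#'
#' \code{linearTrajectory} produces absolute per-frame offsets advancing by
#' \code{velocity} pixels per frame from (0, 0).
#' \code{oscillatingTrajectory} produces a triangle-wave sweep along
#' direction (vx, vy) at \code{speed} px/frame with the given half-period,
#' emulating the repetitive limb movements of a tracking session.
#'
#' @param nFrames number of frames.
#' @param velocity numeric (vx, vy), px per frame.
#' @return nFrames x 2 matrix of absolute (dx, dy) offsets.
#' @export
linearTrajectory <- function(nFrames, velocity = c(2, 0)) {
  cbind((0:(nFrames - 1)) * velocity[1L], (0:(nFrames - 1)) * velocity[2L])
}

#' @rdname linearTrajectory
#' @param speed magnitude in px/frame.
#' @param direction unit-direction (vx, vy) of the sweep.
#' @param halfPeriod frames per half cycle.
#' @export
oscillatingTrajectory <- function(nFrames, speed = 2,
                                  direction = c(1, 0), halfPeriod = 12L) {
  d <- direction / sqrt(sum(direction^2))
  s <- numeric(nFrames)
  pos <- 0; sgn <- 1
  for (i in seq_len(nFrames)) {
    s[i] <- pos
    if (i %% halfPeriod == 0L) sgn <- -sgn
    pos <- pos + sgn * speed
  }
  cbind(s * d[1L], s * d[2L])
}

#' Simulation settings constructor
#'
#' Defaults emulate the package's reference imaging geometry: 40 px per cm
#' (pixelScaleCm = 0.025, consistent with a ~20 x 15 cm field imaged at
#' 1280 x 1024), perfused tissue with a short decorrelation time, static
#' occluding lesion patches (the analogue of adhesive opaque patches taped
#' to skin), and a static light-absorbing cloth outside the tissue
#' rectangle. Time unit = one simulator sub-step; a frame integrates
#' \code{exposureSubsteps} sub-steps (exposure blur), so the frame interval
#' equals \code{exposureSubsteps} base steps.
#'
#' @param shape frame size (rows, cols).
#' @param grainSigmaPx speckle grain scale (px).
#' @param tauTissue,tauLesion,tauBackground decorrelation times in base
#'   steps (Inf = static).
#' @param lesions list of \linkS4class{Roi} lesion patches.
#' @param tissueRect \linkS4class{BoundingBox} of the tissue region, or
#'   NULL for tissue filling the frame.
#' @param backgroundIntensity cloth intensity relative to tissue mean (1).
#' @param flowModAmplitude relative sinusoidal modulation of the tissue
#'   decorrelation rate across frames (physiological perfusion
#'   variability); 0 (default) = stationary flow.
#' @param flowModPeriodFrames modulation period in frames.
#' @param analysisRois analysis ROIs paired with the lesions (default:
#'   the lesion geometries).
#' @param trajectory nFrames x 2 absolute offsets (px); default all zero.
#' @param nFrames number of frames.
#' @param exposureSubsteps M, sub-steps integrated per frame.
#' @param pixelScaleCm cm per pixel.
#' @param gainCounts camera counts per unit intensity; with mean tissue
#'   intensity 1 and exponential statistics, 65535/8 keeps clipping below
#'   5e-4 of pixels.
#' @param noiseSd additive Gaussian read noise (intensity units).
#' @param seed RNG seed.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(shape = c(144L, 256L), grainSigmaPx = 1.5,
                             tauTissue = 0.5, tauLesion = 1e8,
                             tauBackground = Inf,
                             lesions = list(), tissueRect = NULL,
                             backgroundIntensity = 0.08,
                             flowModAmplitude = 0,
                             flowModPeriodFrames = 24,
                             analysisRois = NULL,
                             trajectory = NULL, nFrames = 10L,
                             exposureSubsteps = 8L, pixelScaleCm = 0.025,
                             gainCounts = 65535 / 8, noiseSd = 0,
                             seed = 1L) {
  if (is.null(trajectory)) trajectory <- matrix(0, nFrames, 2L)
  if (is.null(analysisRois)) analysisRois <- lesions
  new("SimulationConfig", shape = as.integer(shape),
      grainSigmaPx = grainSigmaPx, tauTissue = tauTissue,
      tauLesion = tauLesion, tauBackground = tauBackground,
      lesions = lesions, tissueRect = tissueRect,
      backgroundIntensity = backgroundIntensity,
      flowModAmplitude = flowModAmplitude,
      flowModPeriodFrames = flowModPeriodFrames,
      analysisRois = analysisRois,
      trajectory = trajectory, nFrames = as.integer(nFrames),
      exposureSubsteps = as.integer(exposureSubsteps),
      pixelScaleCm = pixelScaleCm, gainCounts = gainCounts,
      noiseSd = noiseSd, seed = as.integer(seed))
}

rhoFromTau <- function(tau) if (is.infinite(tau)) 1 else exp(-1 / tau)

#' Simulate a dynamic speckle sequence with ground truth
#'
#' Per frame: each region's complex field evolves through M sub-steps with
#' its own rho = exp(-1/tau); the frame is the mean of the M sub-step
#' intensity composites (exposure integration); lesion patches (long tau)
#' are composited over tissue (short tau) and the area outside the tissue
#' rectangle is static low-intensity cloth; the whole scene is then rigidly
#' shifted by the frame's trajectory offset (bilinear, border-clamped) and
#' digitized to 16-bit camera counts. Ground-truth lesion centers (initial
#' center + offset) are recorded per frame.
#'
#' Fully deterministic under the configured seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{SimulatedSequence}.
#' @export
simulateSequence <- function(config) {
  validObject(config)
  traj <- config@trajectory
  nr <- config@shape[1L]; nc <- config@shape[2L]
  if (any(abs(traj[, 1L]) >= nc) || any(abs(traj[, 2L]) >= nr))
    stop("trajectory pushes the scene fully out of frame", call. = FALSE)
  set.seed(config@seed)
  g <- config@grainSigmaPx
  tissueF <- synthSpeckleField(config@shape, g)
  lesionF <- if (length(config@lesions)) synthSpeckleField(config@shape, g)
             else NULL
  bgF <- if (!is.null(config@tissueRect)) synthSpeckleField(config@shape, g)
         else NULL
  lesionMasks <- lapply(config@lesions, roiMask, imageShape = config@shape)
  bgMask <- if (!is.null(config@tissueRect)) {
    b <- config@tissueRect
    px <- rep(0:(nc - 1), each = nr); py <- rep(0:(nr - 1), times = nc)
    matrix(!(px >= b@x & px < b@x + b@w & py >= b@y & py < b@y + b@h), nr, nc)
  } else NULL
  rhoL <- rhoFromTau(config@tauLesion)
  rhoB <- rhoFromTau(config@tauBackground)
  M <- config@exposureSubsteps
  frames <- vector("list", config@nFrames)
  for (f in seq_len(config@nFrames)) {
    # physiological flow variability: sinusoidal modulation of the tissue
    # decorrelation rate (faster rate = faster flow = lower contrast)
    rateScale <- 1 + config@flowModAmplitude *
      sin(2 * pi * (f - 1) / config@flowModPeriodFrames)
    rhoT <- if (is.infinite(config@tauTissue)) 1 else
      exp(-rateScale / config@tauTissue)
    acc <- matrix(0, nr, nc)
    for (s in seq_len(M)) {
      tissueF <- evolveField(tissueF, rhoT)
      if (!is.null(lesionF)) lesionF <- evolveField(lesionF, rhoL)
      if (!is.null(bgF)) bgF <- evolveField(bgF, rhoB)
      I <- Mod(tissueF)^2
      if (!is.null(lesionF)) {
        IL <- Mod(lesionF)^2
        for (m in lesionMasks) I[m] <- IL[m]
      }
      if (!is.null(bgF)) {
        IB <- config@backgroundIntensity * Mod(bgF)^2
        I[bgMask] <- IB[bgMask]
      }
      acc <- acc + I
    }
    I <- acc / M
    if (config@noiseSd > 0)
      I <- pmax(I + matrix(stats::rnorm(nr * nc, sd = config@noiseSd), nr, nc), 0)
    if (traj[f, 1L] != 0 || traj[f, 2L] != 0)
      I <- shiftImage(I, traj[f, 1L], traj[f, 2L])
    frames[[f]] <- matrix(pmin(round(I * config@gainCounts), 65535), nr, nc)
  }
  stack <- FrameStack(frames, exposureMs = 5, bitDepth = 16L)
  truth <- do.call(rbind, lapply(seq_along(config@lesions), function(j) {
    c0 <- bboxCenterXY(circumscribedBbox(config@lesions[[j]]))
    data.frame(frame = 0:(config@nFrames - 1L),
               roi_id = config@lesions[[j]]@id,
               cx = c0[1L] + traj[, 1L], cy = c0[2L] + traj[, 2L])
  }))
  if (is.null(truth))
    truth <- data.frame(frame = integer(), roi_id = character(),
                        cx = numeric(), cy = numeric())
  new("SimulatedSequence", stack = stack, truth = truth, config = config)
}

#' Ground-truth masks of a simulated sequence
#'
#' Re-rasterizes a lesion ROI (or the background-cloth region) at its
#' ground-truth position in a given frame.
#'
#' @param seq a \linkS4class{SimulatedSequence}.
#' @param frame 0-based frame index.
#' @param lesion lesion index (1-based) into the config's lesion list.
#' @return logical matrix.
#' @export
truthLesionMask <- function(seq, frame, lesion = 1L) {
  off <- seq@config@trajectory[frame + 1L, ]
  roiMask(translateRoi(seq@config@lesions[[lesion]], off[1L], off[2L]),
          seq@config@shape)
}

#' @rdname truthLesionMask
#' @export
truthBackgroundMask <- function(seq, frame) {
  stopifnotArg(!is.null(seq@config@tissueRect),
               "sequence was simulated without a background region")
  b <- seq@config@tissueRect
  off <- seq@config@trajectory[frame + 1L, ]
  nr <- seq@config@shape[1L]; nc <- seq@config@shape[2L]
  px <- rep(0:(nc - 1), each = nr) - off[1L]
  py <- rep(0:(nr - 1), times = nc) - off[2L]
  matrix(!(px >= b@x & px < b@x + b@w & py >= b@y & py < b@y + b@h), nr, nc)
}

#' Ground-truth lesion centers
#'
#' @param seq a \linkS4class{SimulatedSequence}.
#' @return data.frame (frame, roi_id, cx, cy).
#' @export
truthCenters <- function(seq) seq@truth
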
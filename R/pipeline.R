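#' Pipeline run settings
#'
#' @param contrastWindow spatial contrast window (odd, default 7).
#' @param tracking track ROIs (TRUE) or keep them at their initial
#'   coordinates (FALSE).
#' @param tracker tracker settings from \code{\link{trackerConfig}}.
#' @param displacementThresholdPx ROI displacement-update threshold (px).
#' @param kFloor flow-index clamp.
#' @param auScale arbitrary-unit scale applied to trace values.
#' @param traceSource "flow" (mean 1/K^2, default) or "contrast" (mean K).
#' @param trackOn "contrast" (track on the K map, default: lesions are
#'   visible there and the contrast image is computed before tracking in
#'   the processing chain) or "raw".
#' @param filterWindow odd moving-average window applied to exported
#'   traces (1 = none).
#' @param seed RNG seed recorded with the run.
#' @return a \linkS4class{RunConfig}.
#' @export
runConfig <- function(contrastWindow = 7L, tracking = TRUE,
                      tracker = trackerConfig(),
                      displacementThresholdPx = 1.0, kFloor = 1e-3,
                      auScale = 100, traceSource = "flow",
                      trackOn = "contrast", filterWindow = 1L, seed = 1L) {
  new("RunConfig", contrastWindow = as.integer(contrastWindow),
      tracking = tracking, tracker = tracker,
      displacementThresholdPx = displacementThresholdPx, kFloor = kFloor,
      auScale = auScale, traceSource = traceSource, trackOn = trackOn,
      filterWindow = as.integer(filterWindow), seed = as.integer(seed))
}

traceImage <- function(contrast, config) {
  if (config@traceSource == "flow") {
    flowIndex(contrast, config@kFloor)@values * config@auScale
  } else contrast@k * config@auScale
}

#' Process a speckle sequence into per-ROI perfusion traces
#'
#' Per frame, in order: compute the spatial contrast image; when tracking
#' is enabled, advance each ROI's correlation-filter tracker on that image
#' (or on the raw frame, per config) and apply the displacement-threshold
#' ROI update; finally record the mean flow index (or contrast) within the
#' current ROI. With tracking off, ROIs stay at their initial coordinates.
#' A lost target is flagged in the trajectory and the run continues with
#' the bbox held.
#'
#' @param stack a \linkS4class{FrameStack}.
#' @param rois list of \linkS4class{Roi} (must lie within frame 0).
#' @param config a \linkS4class{RunConfig}.
#' @param verbose emit a per-frame processing-order record via
#'   \code{message()}.
#' @return an \linkS4class{ExperimentResult} with auto traces and
#'   trajectories (no reference arm, no ICC).
#' @export
processSequence <- function(stack, rois, config = runConfig(),
                            verbose = FALSE) {
  stopifnotArg(nFrames(stack) >= 1L, "stack must hold at least one frame")
  shape <- dim(stack@frames[[1L]])
  for (r in rois)
    stopifnotArg(any(suppressWarnings(roiMask(r, shape))),
                 paste0("ROI '", r@id, "' lies outside frame 0"))
  set.seed(config@seed)
  nR <- length(rois); nF <- nFrames(stack)
  current <- rois
  trackers <- vector("list", nR)
  values <- matrix(NA_real_, nF, nR)
  traj <- vector("list", nF * nR)
  cfgT <- config@tracker
  cfgT$displacementThresholdPx <- config@displacementThresholdPx
  for (f in seq_len(nF)) {
    frame <- stack@frames[[f]]
    contrast <- spatialContrast(frame, config@contrastWindow)
    trackImg <- if (config@trackOn == "contrast") contrast@k else frame
    steps <- "contrast"
    for (i in seq_len(nR)) {
      moved <- FALSE; peak <- NA_real_; lost <- FALSE
      if (config@tracking && f == 1L) {
        trackers[[i]] <- initTracker(trackImg,
                                     circumscribedBbox(current[[i]]), cfgT)
        steps <- c(steps, "track-init")
      } else if (config@tracking) {
        prevCtr <- bboxCenterXY(trackers[[i]]@lastBbox)
        st <- trackStep(trackers[[i]], trackImg)
        trackers[[i]] <- st$state
        peak <- st$result@responsePeak
        lost <- st$result@lost
        upd <- roiUpdate(current[[i]], prevCtr, st$result@center,
                         config@displacementThresholdPx)
        current[[i]] <- upd$roi
        moved <- upd$moved
        steps <- c(steps, "track")
      }
      ctr <- bboxCenterXY(circumscribedBbox(current[[i]]))
      values[f, i] <- meanIntensity(traceImage(contrast, config),
                                    current[[i]])
      traj[[(f - 1L) * nR + i]] <- data.frame(
        frame = f - 1L, roi_id = rois[[i]]@id, cx = ctr[1L], cy = ctr[2L],
        moved = moved, response_peak = peak, lost = lost)
    }
    if (verbose)
      message(sprintf("frame %d: %s -> trace", f - 1L,
                      paste(unique(steps), collapse = " -> ")))
  }
  traces <- stats::setNames(lapply(seq_len(nR), function(i) {
    tr <- perfusionTrace(values[, i], roiId = rois[[i]]@id,
                         frameIndices = stack@frameIndices,
                         source = "auto")
    if (config@filterWindow > 1L)
      tr <- movingAverage(tr, config@filterWindow)
    list(reference = NULL, auto = tr)
  }), vapply(rois, function(r) r@id, character(1)))
  new("ExperimentResult", traces = traces,
      trajectories = do.call(rbind, traj), icc = list(),
      configHash = hashConfig(list(contrastWindow = config@contrastWindow,
                                   tracking = config@tracking,
                                   tracker = cfgT,
                                   kFloor = config@kFloor,
                                   auScale = config@auScale,
                                   traceSource = config@traceSource,
                                   trackOn = config@trackOn)),
      seed = config@seed)
}

#' Manual-vs-automatic agreement experiment on simulated data
#'
#' Emulates the tracking-validation protocol: a speckle sequence with
#' occluding lesion patches and rigid motion is simulated; the reference
#' ("manual") trace repositions each ROI at its ground-truth center in
#' every frame — the idealization of an assessor redrawing the ROI per
#' frame; the auto trace comes from \code{\link{processSequence}} with the
#' ROI placed only in the first frame. Per-ROI agreement is quantified
#' with \code{\link{iccTwoWay}} on the paired traces.
#'
#' @param simConfig a \linkS4class{SimulationConfig} with >= 1 lesion.
#' @param config a \linkS4class{RunConfig}.
#' @param verbose forwarded to \code{\link{processSequence}}.
#' @return an \linkS4class{ExperimentResult} with both arms and per-ROI
#'   ICC results.
#' @export
runAgreementExperiment <- function(simConfig, config = runConfig(),
                                   verbose = FALSE) {
  stopifnotArg(length(simConfig@lesions) >= 1L,
               "simulation must define at least one lesion ROI")
  sim <- simulateSequence(simConfig)
  rois <- lapply(simConfig@analysisRois, function(r)
    translateRoi(r, simConfig@trajectory[1L, 1L],
                 simConfig@trajectory[1L, 2L]))
  auto <- processSequence(sim@stack, rois, config, verbose = verbose)
  nF <- nFrames(sim)
  traces <- auto@traces
  iccs <- list()
  for (j in seq_along(rois)) {
    id <- rois[[j]]@id
    ref <- numeric(nF)
    for (f in seq_len(nF)) {
      off <- simConfig@trajectory[f, ]
      roiF <- translateRoi(simConfig@analysisRois[[j]], off[1L], off[2L])
      contrast <- spatialContrast(sim@stack@frames[[f]],
                                  config@contrastWindow)
      ref[f] <- meanIntensity(traceImage(contrast, config), roiF)
    }
    refTr <- perfusionTrace(ref, roiId = id,
                            frameIndices = sim@stack@frameIndices,
                            source = "manual")
    if (config@filterWindow > 1L)
      refTr <- movingAverage(refTr, config@filterWindow)
    traces[[id]]$reference <- refTr
    iccs[[id]] <- iccTwoWay(cbind(manual = refTr@values,
                                  auto = traces[[id]]$auto@values))
  }
  new("ExperimentResult", traces = traces,
      trajectories = auto@trajectories, icc = iccs,
      configHash = hashConfig(list(sim = simConfig@seed,
                                   run = auto@configHash)),
      seed = simConfig@seed)
}

#' Reference simulation scenarios
#'
#' Fixed study conditions used for validation. \code{slowScenario}: a
#' 1 x 2 cm-equivalent rectangular lesion (80 x 40 px at 40 px/cm)
#' centered in the tissue region, oscillating horizontally at 2 px/frame —
#' the slow-motion regime in which tracking should agree with perfect
#' repositioning. \code{fastScenario}: a 1 cm-diameter circular lesion
#' (r = 20 px) at the edge of the tissue region, half over the dark
#' background cloth, sweeping at 15 px/frame — the fast-motion
#' small-target regime expected to degrade agreement. Both scenarios
#' modulate the tissue flow sinusoidally (amplitude 0.7) so the perfusion
#' trace carries the physiological between-frame variance that agreement
#' is measured against.
#'
#' @param seed RNG seed.
#' @param nFrames number of frames (default 48).
#' @return a \linkS4class{SimulationConfig}.
#' @export
slowScenario <- function(seed = 1L, nFrames = 48L) {
  simulationConfig(
    shape = c(144L, 256L),
    lesions = list(rectRoi(30, 52, 80, 40, id = "R1")),
    analysisRois = list(rectRoi(22, 44, 96, 56, id = "R1")),
    tissueRect = boundingBox(4, 16, 248, 112),
    flowModAmplitude = 0.7,
    trajectory = oscillatingTrajectory(nFrames, speed = 2,
                                       halfPeriod = 12L),
    nFrames = nFrames, seed = as.integer(seed))
}

#' @rdname slowScenario
#' @export
fastScenario <- function(seed = 1L, nFrames = 48L) {
  simulationConfig(
    shape = c(144L, 256L),
    lesions = list(circleRoi(196, 72, 20, id = "C1")),
    analysisRois = list(circleRoi(196, 72, 26, id = "C1")),
    tissueRect = boundingBox(4, 16, 192, 112),
    flowModAmplitude = 0.7,
    trajectory = oscillatingTrajectory(nFrames, speed = 15,
                                       halfPeriod = 3L),
    nFrames = nFrames, seed = as.integer(seed))
}
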
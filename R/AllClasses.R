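#' @import methods
NULL

#' Stack of raw speckle frames
#'
#' Container for an ordered sequence of single-channel intensity images
#' acquired (or simulated) at a fixed exposure. Frames are numeric matrices
#' of identical dimension; pixel values are non-negative camera counts or
#' arbitrary linear intensities. The pixel coordinate convention used
#' throughout the package is 0-based, \code{x} = column, \code{y} = row,
#' with pixel centers at integer coordinates.
#'
#' @slot frames list of numeric matrices (rows x cols), one per frame.
#' @slot exposureMs exposure time in milliseconds (metadata only).
#' @slot bitDepth nominal camera bit depth, 8 or 16.
#' @slot frameIndices 0-based integer frame indices.
#' @slot timestampsS acquisition timestamps in seconds.
#' @export
setClass("FrameStack",
  representation(
    frames = "list",
    exposureMs = "numeric",
    bitDepth = "integer",
    frameIndices = "integer",
    timestampsS = "numeric"
  )
)

setValidity("FrameStack", function(object) {
  fr <- object@frames
  if (length(fr) == 0L) return("stack must contain at least one frame")
  if (!all(vapply(fr, is.matrix, logical(1))))
    return("all frames must be matrices")
  d <- dim(fr[[1L]])
  if (!all(vapply(fr, function(m) identical(dim(m), d), logical(1))))
    return("all frames must share the same dimensions")
  if (any(vapply(fr, function(m) any(!is.finite(m)) || any(m < 0), logical(1))))
    return("pixel values must be finite and non-negative")
  if (!object@bitDepth %in% c(8L, 16L)) return("bitDepth must be 8 or 16")
  if (length(object@exposureMs) != 1L || object@exposureMs <= 0)
    return("exposureMs must be a single positive value")
  if (length(object@frameIndices) != length(fr))
    return("frameIndices length must equal the number of frames")
  if (length(object@timestampsS) != length(fr))
    return("timestampsS length must equal the number of frames")
  TRUE
})

#' Speckle-contrast image
#'
#' Per-pixel speckle contrast K = sigma / mean (population standard
#' deviation over the local window divided by the local mean), computed
#' either over a spatial neighbourhood or along the time axis. K is 0
#' wherever the local mean is 0 (dark background), never NaN.
#'
#' @slot k numeric matrix of contrast values, same shape as the source frame.
#' @slot window spatial window side (odd integer) or temporal depth.
#' @slot method \code{"spatial"} or \code{"temporal"}.
#' @export
setClass("ContrastImage",
  representation(k = "matrix", window = "integer", method = "character")
)

setValidity("ContrastImage", function(object) {
  if (any(!is.finite(object@k)) || any(object@k < 0))
    return("contrast values must be finite and non-negative")
  if (!object@method %in% c("spatial", "temporal"))
    return("method must be 'spatial' or 'temporal'")
  TRUE
})

#' Relative flow-index image
#'
#' Per-pixel 1 / max(K, kFloor)^2, a relative (arbitrary-unit) surrogate for
#' flow speed: faster flow blurs the speckle, lowering K and raising the
#' index. The clamp at \code{kFloor} keeps the map finite where K -> 0.
#'
#' @slot values numeric matrix of positive flow-index values.
#' @slot kFloor positive clamp applied to K before inversion.
#' @export
setClass("FlowIndexImage",
  representation(values = "matrix", kFloor = "numeric")
)

setValidity("FlowIndexImage", function(object) {
  if (object@kFloor <= 0) return("kFloor must be positive")
  if (any(!is.finite(object@values)) || any(object@values <= 0))
    return("flow-index values must be finite and positive")
  TRUE
})

#' Regions of interest
#'
#' A \code{Roi} delimits the analysis region over a lesion: either a circle
#' (center + radius, pixels) or a simple polygon (ordered vertices, pixels).
#' Coordinates are 0-based with \code{x} = column and \code{y} = row;
#' sub-pixel (real-valued) positions are allowed, and masks are
#' re-rasterized from the real-valued geometry each time so repeated
#' translation accumulates no rounding error.
#'
#' @slot id character label, e.g. \code{"C1"} or \code{"R1"}.
#' @export
setClass("Roi", representation("VIRTUAL", id = "character"))

#' @rdname Roi-class
#' @slot center numeric length-2 (cx, cy) in pixels.
#' @slot radius positive radius in pixels.
#' @export
setClass("CircleRoi",
  contains = "Roi",
  representation(center = "numeric", radius = "numeric")
)

setValidity("CircleRoi", function(object) {
  if (length(object@center) != 2L || any(!is.finite(object@center)))
    return("center must be two finite coordinates (cx, cy)")
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius <= 0)
    return("radius must be a single positive value")
  TRUE
})

#' @rdname Roi-class
#' @slot vertices n x 2 numeric matrix of (x, y) vertices, n >= 3.
#' @export
setClass("PolygonRoi",
  contains = "Roi",
  representation(vertices = "matrix")
)

setValidity("PolygonRoi", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L || nrow(v) < 3L)
    return("vertices must be an n x 2 numeric matrix with n >= 3")
  if (any(!is.finite(v))) return("vertex coordinates must be finite")
  a <- shoelaceArea(v)
  if (a <= 0) return("polygon is degenerate (collinear or repeated vertices)")
  TRUE
})

#' Axis-aligned bounding box
#'
#' Half-open region [x, x+w) x [y, y+h) in pixel coordinates; the
#' circumscribed rectangle of an ROI and the unit tracked by the
#' correlation-filter tracker.
#'
#' @slot x,y top-left corner (pixels, may be real-valued).
#' @slot w,h positive extents (pixels).
#' @export
setClass("BoundingBox",
  representation(x = "numeric", y = "numeric", w = "numeric", h = "numeric")
)

setValidity("BoundingBox", function(object) {
  v <- c(object@x, object@y, object@w, object@h)
  if (length(v) != 4L || any(!is.finite(v)))
    return("x, y, w, h must be single finite values")
  if (object@w <= 0 || object@h <= 0) return("w and h must be positive")
  TRUE
})

#' Correlation-filter tracker state
#'
#' Discriminative correlation filter with spatial and channel reliability.
#' Filters are stored per feature channel in the frequency domain as
#' numerator/denominator accumulators (updated by exponential moving
#' average); \code{channelWeights} are non-negative and sum to 1;
#' \code{spatialMask} is the foreground reliability mask over the template.
#' The bounding-box size is fixed for the whole run (no scale or rotation
#' adaptation).
#'
#' @slot num,den lists of complex matrices, one per feature channel.
#' @slot channelWeights non-negative weights summing to 1.
#' @slot spatialMask numeric matrix (template-sized) in [0, 1].
#' @slot templateSize integer (width, height) of the template patch.
#' @slot lastBbox last accepted \linkS4class{BoundingBox}.
#' @slot ghat frequency-domain target response (Gaussian peak).
#' @slot hann cosine (Hann) window over the template.
#' @slot peakRef response peak measured on the training frame, used as the
#'   reference for lost-target detection.
#' @slot origin sub-pixel self-response peak offset of the trained filter,
#'   subtracted from measured displacements.
#' @slot config list of tracker settings (see \code{\link{trackerConfig}}).
#' @export
setClass("TrackerState",
  representation(
    num = "list", den = "list",
    channelWeights = "numeric",
    spatialMask = "matrix",
    templateSize = "integer",
    lastBbox = "BoundingBox",
    ghat = "matrix",
    hann = "matrix",
    peakRef = "numeric",
    origin = "numeric",
    config = "list"
  )
)

setValidity("TrackerState", function(object) {
  if (abs(sum(object@channelWeights) - 1) > 1e-8 ||
      any(object@channelWeights < 0))
    return("channelWeights must be non-negative and sum to 1")
  if (!identical(dim(object@spatialMask),
                 c(object@templateSize[2L], object@templateSize[1L])))
    return("spatialMask dimensions must equal the template dimensions")
  TRUE
})

#' Result of one tracking step
#'
#' @slot bbox updated \linkS4class{BoundingBox}.
#' @slot center bbox center (cx, cy), real-valued.
#' @slot responsePeak peak of the channel-weighted correlation response.
#' @slot moved TRUE iff the displacement-threshold rule fired.
#' @slot lost TRUE when the response fell below the lost-target floor and
#'   the previous bbox was held.
#' @export
setClass("TrackResult",
  representation(
    bbox = "BoundingBox", center = "numeric",
    responsePeak = "numeric", moved = "logical", lost = "logical"
  )
)

#' Per-ROI perfusion time series
#'
#' Mean flow index (or contrast) within an ROI, one value per frame, in
#' arbitrary units (AU).
#'
#' @slot roiId ROI label.
#' @slot values ordered numeric trace values.
#' @slot frameIndices strictly increasing 0-based frame indices.
#' @slot source \code{"manual"} (reference positions) or \code{"auto"}
#'   (tracked positions).
#' @export
setClass("PerfusionTrace",
  representation(
    roiId = "character", values = "numeric",
    frameIndices = "integer", source = "character"
  )
)

setValidity("PerfusionTrace", function(object) {
  if (length(object@values) != length(object@frameIndices))
    return("values and frameIndices must have equal length")
  if (length(object@frameIndices) > 1L && any(diff(object@frameIndices) <= 0))
    return("frameIndices must be strictly increasing")
  if (!object@source %in% c("manual", "auto"))
    return("source must be 'manual' or 'auto'")
  TRUE
})

#' Intraclass correlation result
#'
#' Two-way random, single-measure, absolute-agreement ICC (ICC(2,1)) with
#' its variance components: rho = sigmaB2 / (sigmaB2 + sigmaW2), where
#' sigmaB2 is the between-target variance of interest and sigmaW2 aggregates
#' rater and residual variance.
#'
#' @slot icc the intraclass correlation coefficient (<= 1; may be slightly
#'   negative for agreement-free data).
#' @slot sigmaB2,sigmaW2 variance components (clamped at 0).
#' @slot nTargets,kRaters design dimensions.
#' @slot msr,msc,mse two-way ANOVA mean squares (rows, columns, error).
#' @slot category reliability band: poor / moderate / good / excellent.
#' @export
setClass("IccResult",
  representation(
    icc = "numeric", sigmaB2 = "numeric", sigmaW2 = "numeric",
    nTargets = "integer", kRaters = "integer",
    msr = "numeric", msc = "numeric", mse = "numeric",
    category = "character"
  )
)

setValidity("IccResult", function(object) {
  if (object@icc > 1 + 1e-12) return("icc must be <= 1")
  if (object@sigmaB2 < 0 || object@sigmaW2 < 0)
    return("variance components must be non-negative")
  TRUE
})

#' Dynamic-speckle simulation settings
#'
#' Forward model for a desk-scale emulation of a speckle-imaging session:
#' fully developed speckle with per-region decorrelation times (background
#' cloth, perfused tissue, occluding lesion patches standing in for
#' adhesive opaque patches on skin), exposure integration over M sub-steps,
#' and rigid in-plane motion with a recorded ground-truth trajectory.
#' Time is measured in simulator base steps: a frame integrates M
#' consecutive sub-steps, and each region's field decorrelates between
#' sub-steps with rho = exp(-1 / tau).
#'
#' @slot shape frame size (rows, cols).
#' @slot grainSigmaPx speckle grain scale in pixels (>= 1).
#' @slot tauTissue,tauLesion,tauBackground decorrelation times in base
#'   steps; \code{Inf} freezes the region.
#' @slot lesions list of \linkS4class{Roi} lesion patches.
#' @slot tissueRect \linkS4class{BoundingBox} of the tissue region
#'   (outside = light-absorbing cloth), or NULL for tissue everywhere.
#' @slot backgroundIntensity mean cloth intensity relative to tissue (= 1).
#' @slot flowModAmplitude relative amplitude of the sinusoidal modulation
#'   of the tissue decorrelation rate across frames (emulates physiological
#'   perfusion variability; 0 = stationary flow).
#' @slot flowModPeriodFrames period of the flow modulation, in frames.
#' @slot analysisRois list of \linkS4class{Roi} analysis regions paired
#'   with the lesions (default: the lesion geometries themselves); an
#'   analysis ROI may include a margin of perfused tissue around the
#'   occluding patch, as a clinician drawing around a wound would.
#' @slot trajectory nFrames x 2 matrix of absolute per-frame (dx, dy)
#'   scene offsets in pixels.
#' @slot nFrames number of frames.
#' @slot exposureSubsteps M, sub-steps integrated per frame.
#' @slot pixelScaleCm physical scale, cm per pixel.
#' @slot gainCounts camera counts per unit mean intensity (16-bit output).
#' @slot noiseSd additive Gaussian read-noise, in units of mean intensity.
#' @slot seed RNG seed.
#' @export
setClass("SimulationConfig",
  representation(
    shape = "integer", grainSigmaPx = "numeric",
    tauTissue = "numeric", tauLesion = "numeric", tauBackground = "numeric",
    lesions = "list", tissueRect = "ANY",
    backgroundIntensity = "numeric",
    flowModAmplitude = "numeric", flowModPeriodFrames = "numeric",
    analysisRois = "list",
    trajectory = "matrix", nFrames = "integer",
    exposureSubsteps = "integer", pixelScaleCm = "numeric",
    gainCounts = "numeric", noiseSd = "numeric", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  if (length(object@shape) != 2L || any(object@shape < 8L))
    return("shape must be (rows, cols), each >= 8")
  if (object@grainSigmaPx < 1) return("grainSigmaPx must be >= 1")
  if (any(c(object@tauTissue, object@tauLesion, object@tauBackground) <= 0))
    return("all decorrelation times must be positive")
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  if (nrow(object@trajectory) != object@nFrames)
    return("trajectory must have one (dx, dy) row per frame")
  if (object@exposureSubsteps < 1L) return("exposureSubsteps must be >= 1")
  if (object@pixelScaleCm <= 0) return("pixelScaleCm must be positive")
  if (!all(vapply(object@lesions, is, logical(1), "Roi")))
    return("lesions must be a list of Roi objects")
  if (object@flowModAmplitude < 0 || object@flowModAmplitude >= 1)
    return("flowModAmplitude must lie in [0, 1)")
  if (length(object@analysisRois) != length(object@lesions))
    return("analysisRois must pair one ROI with each lesion")
  TRUE
})

#' Simulated speckle sequence with ground truth
#'
#' @slot stack the simulated \linkS4class{FrameStack} (16-bit counts).
#' @slot truth data.frame (frame, roi_id, cx, cy): per-frame ground-truth
#'   lesion centers, consistent with the configured trajectory.
#' @slot config the generating \linkS4class{SimulationConfig}.
#' @export
setClass("SimulatedSequence",
  representation(stack = "FrameStack", truth = "data.frame",
                 config = "SimulationConfig")
)

#' Pipeline run settings
#'
#' @slot contrastWindow spatial contrast window (odd).
#' @slot tracking logical: track ROIs or hold them at their initial
#'   coordinates.
#' @slot tracker list of tracker settings (\code{\link{trackerConfig}}).
#' @slot displacementThresholdPx ROI-update displacement threshold (px).
#' @slot kFloor clamp for flow-index inversion.
#' @slot auScale multiplicative arbitrary-unit scale applied to traces.
#' @slot traceSource \code{"flow"} (mean 1/K^2, default) or
#'   \code{"contrast"} (mean K).
#' @slot trackOn \code{"contrast"} (track on the K map, default) or
#'   \code{"raw"} (track on the raw frame).
#' @slot filterWindow moving-average window for trace filtering (odd; 1 =
#'   no filtering).
#' @slot seed RNG seed for any stochastic tie-break.
#' @export
setClass("RunConfig",
  representation(
    contrastWindow = "integer", tracking = "logical", tracker = "list",
    displacementThresholdPx = "numeric", kFloor = "numeric",
    auScale = "numeric", traceSource = "character", trackOn = "character",
    filterWindow = "integer", seed = "integer"
  )
)

setValidity("RunConfig", function(object) {
  if (object@contrastWindow < 3L || object@contrastWindow %% 2L == 0L)
    return("contrastWindow must be an odd integer >= 3")
  if (object@displacementThresholdPx < 0)
    return("displacementThresholdPx must be >= 0")
  if (object@kFloor <= 0) return("kFloor must be positive")
  if (!object@traceSource %in% c("flow", "contrast"))
    return("traceSource must be 'flow' or 'contrast'")
  if (!object@trackOn %in% c("contrast", "raw"))
    return("trackOn must be 'contrast' or 'raw'")
  if (object@filterWindow < 1L || object@filterWindow %% 2L == 0L)
    return("filterWindow must be an odd integer >= 1")
  TRUE
})

#' End-to-end experiment result
#'
#' @slot traces named list (per ROI id) of lists with elements
#'   \code{reference} and \code{auto} (\linkS4class{PerfusionTrace}).
#' @slot trajectories data.frame (frame, roi_id, cx, cy, moved,
#'   response_peak, lost).
#' @slot icc named list of \linkS4class{IccResult}, per ROI (empty when no
#'   reference arm exists).
#' @slot configHash hash of the run configuration, for provenance.
#' @slot seed seed used for the run.
#' @export
setClass("ExperimentResult",
  representation(
    traces = "list", trajectories = "data.frame", icc = "list",
    configHash = "character", seed = "integer"
  )
)
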
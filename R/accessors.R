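#' Build a FrameStack
#'
#' @param frames list of numeric matrices (or a single matrix).
#' @param exposureMs exposure time in ms (metadata).
#' @param bitDepth 8 or 16.
#' @param timestampsS per-frame timestamps in seconds; defaults to frame
#'   index (unit spacing).
#' @return a \linkS4class{FrameStack}.
#' @export
FrameStack <- function(frames, exposureMs = 5, bitDepth = 16L,
                       timestampsS = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  idx <- seq_along(frames) - 1L
  if (is.null(timestampsS)) timestampsS <- as.numeric(idx)
  new("FrameStack", frames = frames, exposureMs = exposureMs,
      bitDepth = as.integer(bitDepth), frameIndices = idx,
      timestampsS = timestampsS)
}

#' Accessors
#'
#' Small accessor generics for the package's S4 containers, so user code
#' never reaches into slots.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "FrameStack", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("frames", "SimulatedSequence", function(x) x@stack@frames)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "FrameStack", function(x) length(x@frames))
#' @rdname accessors
#' @export
setMethod("nFrames", "SimulatedSequence", function(x) length(x@stack@frames))

#' @rdname accessors
#' @export
setGeneric("kValues", function(x) standardGeneric("kValues"))
#' @rdname accessors
#' @export
setMethod("kValues", "ContrastImage", function(x) x@k)

#' @rdname accessors
#' @export
setGeneric("flowValues", function(x) standardGeneric("flowValues"))
#' @rdname accessors
#' @export
setMethod("flowValues", "FlowIndexImage", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("roiId", function(x) standardGeneric("roiId"))
#' @rdname accessors
#' @export
setMethod("roiId", "Roi", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("roiId", "PerfusionTrace", function(x) x@roiId)

#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setMethod("traceValues", "PerfusionTrace", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("iccValue", function(x) standardGeneric("iccValue"))
#' @rdname accessors
#' @export
setMethod("iccValue", "IccResult", function(x) x@icc)

#' @rdname accessors
#' @export
setGeneric("iccCategory", function(x) standardGeneric("iccCategory"))
#' @rdname accessors
#' @export
setMethod("iccCategory", "IccResult", function(x) x@category)

#' @rdname accessors
#' @export
setGeneric("bboxCenter", function(x) standardGeneric("bboxCenter"))
#' @rdname accessors
#' @export
setMethod("bboxCenter", "BoundingBox", function(x) bboxCenterXY(x))
#' @rdname accessors
#' @export
setMethod("bboxCenter", "TrackResult", function(x) x@center)

#' @rdname accessors
#' @export
setGeneric("lastBbox", function(x) standardGeneric("lastBbox"))
#' @rdname accessors
#' @export
setMethod("lastBbox", "TrackerState", function(x) x@lastBbox)

#' @rdname accessors
#' @export
setGeneric("channelWeights", function(x) standardGeneric("channelWeights"))
#' @rdname accessors
#' @export
setMethod("channelWeights", "TrackerState", function(x) x@channelWeights)

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames[[1L]])
  cat(sprintf("FrameStack: %d frame(s) of %d x %d, %d-bit, exposure %.3g ms\n",
              length(object@frames), d[1L], d[2L], object@bitDepth,
              object@exposureMs))
})

setMethod("show", "ContrastImage", function(object) {
  cat(sprintf("ContrastImage (%s, window %d): %d x %d, K in [%.3f, %.3f]\n",
              object@method, object@window, nrow(object@k), ncol(object@k),
              min(object@k), max(object@k)))
})

setMethod("show", "FlowIndexImage", function(object) {
  cat(sprintf("FlowIndexImage (kFloor %.1e): %d x %d, range [%.3g, %.3g] AU\n",
              object@kFloor, nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "CircleRoi", function(object) {
  cat(sprintf("CircleRoi '%s': center (%.2f, %.2f), r = %.2f px\n",
              object@id, object@center[1L], object@center[2L], object@radius))
})

setMethod("show", "PolygonRoi", function(object) {
  cat(sprintf("PolygonRoi '%s': %d vertices, area %.1f px^2\n",
              object@id, nrow(object@vertices), shoelaceArea(object@vertices)))
})

setMethod("show", "BoundingBox", function(object) {
  cat(sprintf("BoundingBox: x = %.2f, y = %.2f, w = %.2f, h = %.2f\n",
              object@x, object@y, object@w, object@h))
})

setMethod("show", "IccResult", function(object) {
  cat(sprintf(
    "ICC(2,1) = %.4f [%s]  (sigmaB2 = %.4g, sigmaW2 = %.4g, n = %d, k = %d)\n",
    object@icc, object@category, object@sigmaB2, object@sigmaW2,
    object@nTargets, object@kRaters))
})

setMethod("show", "PerfusionTrace", function(object) {
  cat(sprintf("PerfusionTrace '%s' (%s): %d frames, mean %.3g AU\n",
              object@roiId, object@source, length(object@values),
              mean(object@values)))
})

setMethod("show", "TrackerState", function(object) {
  cat(sprintf(
    "TrackerState: template %d x %d, %d channel(s), weights %s\n",
    object@templateSize[1L], object@templateSize[2L], length(object@num),
    paste(sprintf("%.2f", object@channelWeights), collapse = "/")))
})

setMethod("show", "SimulatedSequence", function(object) {
  cat(sprintf(
    "SimulatedSequence: %d frame(s) %d x %d, %d lesion(s), M = %d, seed %d\n",
    object@config@nFrames, object@config@shape[1L], object@config@shape[2L],
    length(object@config@lesions), object@config@exposureSubsteps,
    object@config@seed))
})
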
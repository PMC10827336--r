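#' Two-way random intraclass correlation (ICC(2,1))
#'
#' Quantifies absolute agreement between k raters (e.g. manual vs.
#' automatic perfusion measurements) over n targets (frames) under the
#' two-way random model: rho = sigmaB^2 / (sigmaB^2 + sigmaW^2), where
#' sigmaB^2 is the between-target variance of interest and sigmaW^2
#' aggregates rater and residual variance. Computed from the two-way
#' ANOVA mean squares as the single-measure absolute-agreement form:
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)).
#'
#' The ICC is invariant under adding a constant to all cells and under
#' positive rescaling. Values at the band boundaries are assigned the
#' upper category (0.75 is "good").
#'
#' @param data n x k numeric matrix (targets x raters), n >= 3, k >= 2,
#'   no missing cells.
#' @return an \linkS4class{IccResult}.
#' @examples
#' iccTwoWay(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4)))  # perfect agreement
#' @export
iccTwoWay <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  stopifnotArg(n >= 3L && k >= 2L, "need n >= 3 targets and k >= 2 raters")
  stopifnotArg(all(is.finite(data)), "data must have no missing cells")
  grand <- mean(data)
  rowM <- rowMeans(data); colM <- colMeans(data)
  ssr <- k * sum((rowM - grand)^2)
  ssc <- n * sum((colM - grand)^2)
  sst <- sum((data - grand)^2)
  sse <- sst - ssr - ssc
  if (sst < 1e-12 * max(1, grand^2))
    stop("undefined ICC: zero total variance", call. = FALSE)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- max(sse / ((n - 1) * (k - 1)), 0)
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  sigmaB2 <- max((msr - mse) / k, 0)
  sigmaRater2 <- max((msc - mse) / n, 0)
  sigmaW2 <- sigmaRater2 + mse
  new("IccResult", icc = icc, sigmaB2 = sigmaB2, sigmaW2 = sigmaW2,
      nTargets = n, kRaters = k, msr = msr, msc = msc, mse = mse,
      category = classifyReliability(icc))
}

#' Reliability category of an ICC value
#'
#' Standard banding: below 0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good,
#' 0.9 and above excellent. Boundary values belong to the upper band.
#'
#' @param icc ICC value (<= 1).
#' @return one of "poor", "moderate", "good", "excellent".
#' @export
classifyReliability <- function(icc) {
  stopifnotArg(icc <= 1 + 1e-12, "icc must be <= 1")
  if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc < 0.9) "good"
  else "excellent"
}

#' Moving-average trace filter
#'
#' Centered moving mean with symmetric reflection at the ends, used to
#' suppress instantaneous motion-artifact spikes in perfusion traces.
#' Output length equals input length; w = 1 is the identity.
#'
#' @param trace a \linkS4class{PerfusionTrace} or bare numeric vector.
#' @param w odd window, 1 <= w <= length(trace).
#' @return filtered object of the same type as the input.
#' @export
movingAverage <- function(trace, w = 5L) {
  v <- if (is(trace, "PerfusionTrace")) trace@values else trace
  w <- as.integer(w)
  stopifnotArg(w >= 1L && w %% 2L == 1L && w <= length(v),
               "w must be odd and within [1, length(trace)]")
  if (w > 1L) {
    p <- (w - 1L) %/% 2L
    idx <- reflectIndex(length(v), p)
    v <- as.numeric(stats::filter(v[idx], rep(1 / w, w), sides = 2L))
    v <- v[(p + 1L):(length(v) - p)]
  }
  if (is(trace, "PerfusionTrace")) {
    new("PerfusionTrace", roiId = trace@roiId, values = v,
        frameIndices = trace@frameIndices, source = trace@source)
  } else v
}

#' Build a perfusion trace
#'
#' @param values numeric per-frame mean ROI values (AU).
#' @param roiId ROI label.
#' @param frameIndices 0-based frame indices (default 0, 1, ...).
#' @param source "manual" or "auto".
#' @return a \linkS4class{PerfusionTrace}.
#' @export
perfusionTrace <- function(values, roiId = "C1", frameIndices = NULL,
                           source = "auto") {
  if (is.null(frameIndices)) frameIndices <- seq_along(values) - 1L
  new("PerfusionTrace", roiId = roiId, values = as.numeric(values),
      frameIndices = as.integer(frameIndices), source = source)
}
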
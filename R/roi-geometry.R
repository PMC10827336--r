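#' Construct regions of interest
#'
#' ROIs are defined in 0-based pixel coordinates (x = column, y = row) and
#' may sit at sub-pixel positions; the tracker emits real-valued centers
#' and masks are re-rasterized from the exact geometry every frame.
#'
#' @param cx,cy circle center in pixels.
#' @param r circle radius in pixels (> 0).
#' @param id character label (e.g. "C1", "R1").
#' @return a \linkS4class{CircleRoi} / \linkS4class{PolygonRoi}.
#' @examples
#' circleRoi(50, 50, 20, id = "C1")
#' rectRoi(10, 10, 80, 40, id = "R1")
#' @export
circleRoi <- function(cx, cy, r, id = "C1") {
  new("CircleRoi", id = id, center = c(cx, cy), radius = r)
}

#' @rdname circleRoi
#' @param vertices n x 2 matrix of (x, y) vertices, ordered along the
#'   boundary, n >= 3, non-degenerate.
#' @export
polygonRoi <- function(vertices, id = "P1") {
  new("PolygonRoi", id = id, vertices = as.matrix(vertices))
}

#' @rdname circleRoi
#' @param x,y top-left corner of an axis-aligned rectangle ROI.
#' @param w,h rectangle extents in pixels.
#' @export
rectRoi <- function(x, y, w, h, id = "R1") {
  polygonRoi(cbind(c(x, x + w, x + w, x),
                   c(y, y, y + h, y + h)), id = id)
}

#' @rdname circleRoi
#' @export
boundingBox <- function(x, y, w, h) new("BoundingBox", x = x, y = y, w = w, h = h)

# Even-odd point-in-polygon with boundary-inclusive convention.
pointsInPolygon <- function(px, py, v, eps = 1e-9) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  onEdge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]; xj <- v[j, 1L]; yj <- v[j, 2L]
    # boundary test: point within segment bounding range and collinear
    dx <- xj - xi; dy <- yj - yi
    cross <- (px - xi) * dy - (py - yi) * dx
    within <- (px >= pmin(xi, xj) - eps) & (px <= pmax(xi, xj) + eps) &
              (py >= pmin(yi, yj) - eps) & (py <= pmax(yi, yj) + eps)
    onEdge <- onEdge | (abs(cross) <= eps * (abs(dx) + abs(dy) + 1) & within)
    crosses <- ((yi > py) != (yj > py)) &
               (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onEdge
}

#' Rasterize an ROI to a pixel mask
#'
#' A pixel belongs to the mask when its center (integer coordinates) lies
#' inside or on the ROI boundary: circles use (px-cx)^2 + (py-cy)^2 <= r^2,
#' polygons the even-odd rule with boundary-inclusive convention.
#'
#' @param roi a \linkS4class{Roi}.
#' @param imageShape integer (rows, cols).
#' @return logical matrix (rows x cols). An ROI entirely outside the image
#'   yields an all-FALSE mask with a warning.
#' @export
roiMask <- function(roi, imageShape) {
  stopifnotArg(length(imageShape) == 2L && all(imageShape >= 1),
               "imageShape must be positive (rows, cols)")
  nr <- imageShape[1L]; nc <- imageShape[2L]
  px <- rep(0:(nc - 1), each = nr)
  py <- rep(0:(nr - 1), times = nc)
  m <- if (is(roi, "CircleRoi")) {
    (px - roi@center[1L])^2 + (py - roi@center[2L])^2 <= roi@radius^2
  } else {
    pointsInPolygon(px, py, roi@vertices)
  }
  m <- matrix(m, nr, nc)
  if (!any(m)) warning("ROI '", roi@id, "' covers no pixel of the image")
  m
}

#' Analytic ROI area
#'
#' Circle: pi r^2 scale^2; polygon: shoelace formula times scale^2.
#'
#' @param roi a \linkS4class{Roi}.
#' @param pixelScaleCm physical scale in cm per pixel (> 0). Default 1
#'   returns the area in px^2.
#' @return area in cm^2 (or px^2 at unit scale).
#' @examples
#' roiArea(circleRoi(0, 0, 0.5 / 0.025), pixelScaleCm = 0.025)  # 0.785 cm^2
#' @export
roiArea <- function(roi, pixelScaleCm = 1) {
  stopifnotArg(is.numeric(pixelScaleCm) && pixelScaleCm > 0,
               "pixelScaleCm must be positive")
  a <- if (is(roi, "CircleRoi")) pi * roi@radius^2 else shoelaceArea(roi@vertices)
  a * pixelScaleCm^2
}

#' Mean intensity within an ROI
#'
#' Arithmetic mean of the image values at mask-true pixels; the quantity
#' traced over time for perfusion analysis.
#'
#' @param image numeric matrix (raw frame, contrast or flow-index values).
#' @param roi a \linkS4class{Roi}.
#' @return scalar mean; an ROI with an empty mask is an error.
#' @export
meanIntensity <- function(image, roi) {
  if (is(image, "ContrastImage")) image <- image@k
  if (is(image, "FlowIndexImage")) image <- image@values
  m <- suppressWarnings(roiMask(roi, dim(image)))
  stopifnotArg(any(m), "ROI lies outside the image (empty mask)")
  mean(image[m])
}

#' Circumscribed bounding box of an ROI
#'
#' The minimal axis-aligned rectangle containing the ROI; its center drives
#' the tracking-based ROI repositioning.
#'
#' @param roi a \linkS4class{Roi}.
#' @return a \linkS4class{BoundingBox}.
#' @export
circumscribedBbox <- function(roi) {
  if (is(roi, "CircleRoi")) {
    boundingBox(roi@center[1L] - roi@radius, roi@center[2L] - roi@radius,
                2 * roi@radius, 2 * roi@radius)
  } else {
    v <- roi@vertices
    boundingBox(min(v[, 1L]), min(v[, 2L]),
                max(v[, 1L]) - min(v[, 1L]), max(v[, 2L]) - min(v[, 2L]))
  }
}

#' Translate an ROI
#'
#' Shifts every defining coordinate by (dx, dy); shape and area are
#' preserved exactly.
#'
#' @param roi a \linkS4class{Roi}.
#' @param dx,dy displacement in pixels (may be sub-pixel).
#' @return the translated \linkS4class{Roi}.
#' @export
translateRoi <- function(roi, dx, dy) {
  if (is(roi, "CircleRoi")) {
    circleRoi(roi@center[1L] + dx, roi@center[2L] + dy, roi@radius,
              id = roi@id)
  } else {
    polygonRoi(cbind(roi@vertices[, 1L] + dx, roi@vertices[, 2L] + dy),
               id = roi@id)
  }
}
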
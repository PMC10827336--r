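# Readers/writers for frame stacks (multi-page TIFF, PNG or PGM frame
# directories), ROI definition files (JSON/YAML) and result tables (CSV).

readPgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, 2L)
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM file (P2/P5): ", path, call. = FALSE)
  tokens <- character(0)
  # header tokens: width, height, maxval (comments start with '#')
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L)
    if (length(ch) == 0L) stop("truncated PGM header: ", path, call. = FALSE)
    if (ch == "#") {
      repeat { ch <- readChar(con, 1L); if (!length(ch) || ch == "\n") break }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) { tokens <- c(tokens, paste(buf, collapse = ""))
                         buf <- character(0) }
    } else buf <- c(buf, ch)
  }
  w <- as.integer(tokens[1L]); h <- as.integer(tokens[2L])
  maxval <- as.integer(tokens[3L])
  n <- w * h
  vals <- if (magic == "P5") {
    sz <- if (maxval > 255L) 2L else 1L
    as.numeric(readBin(con, "integer", n, size = sz, signed = FALSE,
                       endian = "big"))
  } else {
    as.numeric(scan(con, what = integer(), n = n, quiet = TRUE))
  }
  matrix(vals, h, w, byrow = TRUE)
}

writePgm <- function(m, path, maxval = 65535L) {
  con <- file(path, "wb"); on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(m), nrow(m), maxval), con,
            eos = NULL)
  writeBin(as.integer(t(m)), con, size = if (maxval > 255L) 2L else 1L,
           endian = "big")
}

#' Read a frame stack
#'
#' Accepts a multi-page TIFF file or a directory of single-channel PNG or
#' PGM frames (ordered by filename). Pixel values are returned as integer
#' counts at the source bit depth; all frames must share one shape.
#'
#' @param path TIFF file or frame directory.
#' @param exposureMs exposure metadata to attach (ms).
#' @return a \linkS4class{FrameStack}.
#' @export
readStack <- function(path, exposureMs = 5) {
  if (!file.exists(path)) stop("no such file or directory: ", path,
                               call. = FALSE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|pgm)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      stop("no PNG/PGM frames found in directory: ", path, call. = FALSE)
    frames <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) {
        m <- png::readPNG(f)
        if (length(dim(m)) == 3L) m <- m[, , 1L]
        round(m * 65535)
      } else readPgm(f)
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, function(m) {
      if (length(dim(m)) == 3L) m <- m[, , 1L]
      m * 1.0
    })
  }
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L)
    stop("frames have mixed shapes in: ", path, call. = FALSE)
  FrameStack(frames, exposureMs = exposureMs, bitDepth = 16L)
}

#' Write a frame stack
#'
#' Writes the stack as a 16-bit multi-page TIFF (values taken as counts in
#' [0, 65535]); reading it back with \code{\link{readStack}} reproduces the
#' pixel values bit-for-bit.
#'
#' @param stack a \linkS4class{FrameStack} or \linkS4class{SimulatedSequence}.
#' @param path output .tif path.
#' @return the path, invisibly.
#' @export
writeStack <- function(stack, path) {
  if (is(stack, "SimulatedSequence")) stack <- stack@stack
  tiff::writeTIFF(lapply(stack@frames, function(m) m / 65535),
                  path, bits.per.sample = 16L)
  invisible(path)
}

roiToList <- function(roi) {
  if (is(roi, "CircleRoi")) {
    list(id = roi@id, shape = "circle",
         center = as.numeric(roi@center), radius = roi@radius)
  } else {
    list(id = roi@id, shape = "polygon",
         vertices = lapply(seq_len(nrow(roi@vertices)),
                           function(i) as.numeric(roi@vertices[i, ])))
  }
}

roiFromList <- function(x) {
  if (x$shape == "circle") {
    circleRoi(x$center[[1L]], x$center[[2L]], x$radius, id = x$id)
  } else {
    polygonRoi(do.call(rbind, lapply(x$vertices, unlist)), id = x$id)
  }
}

#' Read/write ROI definition files
#'
#' ROIs are exchanged as a small JSON or YAML schema: a list of
#' \code{\{id, shape, center|vertices, radius\}} entries (format chosen by
#' file extension).
#'
#' @param path .json/.yaml/.yml file.
#' @return list of \linkS4class{Roi}.
#' @export
readRoiFile <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else yaml::read_yaml(path)
  lapply(raw, roiFromList)
}

#' @rdname readRoiFile
#' @param rois list of \linkS4class{Roi}.
#' @export
writeRoiFile <- function(rois, path) {
  lst <- lapply(rois, roiToList)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  } else yaml::write_yaml(lst, path)
  invisible(path)
}

#' Export trace CSVs and agreement reports
#'
#' Writes, under \code{dir}: \code{traces.csv} (frame, roi_id, source,
#' value), \code{trajectories.csv} (frame, roi_id, cx, cy, moved,
#' response_peak, lost), \code{icc_report.csv} (per-ROI ICC, variance
#' components and category), and \code{config.yaml} with the run
#' provenance (config hash and seed).
#'
#' @param result an \linkS4class{ExperimentResult}.
#' @param dir output directory (created if needed).
#' @param renders optional named list of RGB arrays (from
#'   \code{\link{renderContrastMap}}) written as PNGs.
#' @return \code{dir}, invisibly.
#' @export
writeOutputs <- function(result, dir, renders = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- do.call(rbind, unlist(lapply(result@traces, function(pair) {
    lapply(Filter(Negate(is.null), pair), function(t)
      data.frame(frame = t@frameIndices, roi_id = t@roiId,
                 source = t@source, value = t@values))
  }), recursive = FALSE))
  utils::write.csv(tr, file.path(dir, "traces.csv"), row.names = FALSE)
  utils::write.csv(result@trajectories, file.path(dir, "trajectories.csv"),
                   row.names = FALSE)
  if (length(result@icc)) {
    rep <- do.call(rbind, lapply(names(result@icc), function(id) {
      r <- result@icc[[id]]
      data.frame(roi_id = id, icc = r@icc, sigma_b2 = r@sigmaB2,
                 sigma_w2 = r@sigmaW2, n = r@nTargets, k = r@kRaters,
                 category = r@category)
    }))
    utils::write.csv(rep, file.path(dir, "icc_report.csv"),
                     row.names = FALSE)
  }
  for (nm in names(renders))
    png::writePNG(renders[[nm]], file.path(dir, paste0(nm, ".png")))
  yaml::write_yaml(list(config_hash = result@configHash,
                        seed = result@seed),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

hashConfig <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(x), tmp)
  unname(tools::md5sum(tmp))
}
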
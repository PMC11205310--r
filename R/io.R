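#' Write an image series to a directory
#'
#' Writes each frame as an 8-bit grayscale PNG plus a manifest CSV
#' (\code{frame_index}, \code{filename}, \code{mode}, \code{truth_label})
#' and, for generated series, a \code{config.json} with the scene and
#' optics settings.
#'
#' @param series a \linkS4class{LabelledSeries}.
#' @param dir destination directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeSeries <- function(series, dir) {
  stopifnot(is(series, "LabelledSeries"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- series@manifest
  for (i in seq_along(series@frames))
    saveDropletImage(series@frames[[i]], file.path(dir, man$filename[i]))
  manPath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manPath, row.names = FALSE)
  if (length(series@scene)) {
    jsonlite::write_json(list(scene = series@scene, optics = series@optics),
                         file.path(dir, "config.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(manPath)
}

#' Read an image series from a manifest
#'
#' Loads a series written by [writeSeries()] (or any directory holding
#' frames plus a manifest CSV with columns \code{frame_index},
#' \code{filename}, \code{mode} and optionally \code{truth_label}).
#' Frames that fail to decode are skipped with a warning.
#'
#' @param path the series directory or the manifest CSV path.
#' @return A \linkS4class{LabelledSeries}; missing truth labels are NA.
#' @export
readSeries <- function(path) {
  manPath <- if (dir.exists(path)) file.path(path, "manifest.csv") else path
  if (!file.exists(manPath))
    stop("series manifest not found: ", manPath)
  man <- utils::read.csv(manPath, stringsAsFactors = FALSE)
  need <- c("frame_index", "filename", "mode")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (!"truth_label" %in% names(man)) man$truth_label <- NA
  base <- dirname(manPath)
  frames <- list()
  truth <- logical()
  keep <- logical(nrow(man))
  for (i in seq_len(nrow(man))) {
    f <- file.path(base, man$filename[i])
    img <- tryCatch(
      loadDropletImage(f, mode = man$mode[i],
                       frameIndex = man$frame_index[i]),
      error = function(e) {
        warning("skipping frame ", man$frame_index[i], ": ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(img)) {
      frames[[length(frames) + 1L]] <- img
      truth <- c(truth, as.logical(man$truth_label[i]))
      keep[i] <- TRUE
    }
  }
  new("LabelledSeries", frames = frames, truth = truth,
      manifest = man[keep, , drop = FALSE])
}

#' Write a calibration profile to JSON
#'
#' Serializes a \linkS4class{CalibrationProfile}: WPC baseline and margins,
#' contour-count reference points and rule parameters, DIS score cut-offs.
#' The DIS reference mask is stored as a PNG sidecar next to the JSON
#' (\code{<path>_reference.png}) with its metadata in the JSON.
#'
#' @param profile a \linkS4class{CalibrationProfile}.
#' @param path destination JSON path.
#' @return \code{path}, invisibly.
#' @export
writeCalibration <- function(profile, path) {
  stopifnot(is(profile, "CalibrationProfile"))
  out <- list(mode = profile@mode, maxShift = profile@maxShift)
  if (!is.null(profile@wpc)) {
    w <- profile@wpc
    out$wpc <- list(baseline = w@baseline,
                    marginFraction = w@marginFraction,
                    cutoffHigh = w@cutoffHigh, cutoffLow = w@cutoffLow,
                    sidedness = w@sidedness, mode = w@mode,
                    nCalibration = w@nCalibration, binarize = w@binarize)
  }
  if (!is.null(profile@cc)) {
    cc <- profile@cc
    out$cc <- list(points = cc@points[, c("label", "row", "col", "area")],
                   areaChangeThreshold = cc@areaChangeThreshold,
                   maxMatchDistance = cc@maxMatchDistance,
                   mode = cc@mode, nCalibration = cc@nCalibration,
                   minArea = cc@minArea, sigma = cc@sigma)
  }
  if (!is.null(profile@dis)) {
    ref <- profile@dis$reference
    cut <- profile@dis$cutoffs
    refPng <- paste0(tools::file_path_sans_ext(path), "_reference.png")
    png::writePNG(mask(ref) * 1, refPng)
    out$dis <- list(
      reference = list(file = basename(refPng),
                       threshold = ref@threshold,
                       whiteCount = ref@whiteCount,
                       nSourceFrames = ref@nSourceFrames,
                       mode = ref@mode),
      cutoffs = list(udMax = cut@udMax, odMax = cut@odMax,
                     disMin = cut@disMin,
                     votesRequired = cut@votesRequired, k = cut@k,
                     nCalibration = cut@nCalibration))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a calibration profile from JSON
#'
#' @param path a JSON file written by [writeCalibration()].
#' @return A \linkS4class{CalibrationProfile}.
#' @export
readCalibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  wpc <- NULL
  if (!is.null(x$wpc)) {
    wpc <- new("WpcCutoff", baseline = x$wpc$baseline,
               marginFraction = x$wpc$marginFraction,
               cutoffHigh = x$wpc$cutoffHigh, cutoffLow = x$wpc$cutoffLow,
               sidedness = x$wpc$sidedness, mode = x$wpc$mode,
               nCalibration = as.integer(x$wpc$nCalibration),
               binarize = as.list(x$wpc$binarize))
  }
  cc <- NULL
  if (!is.null(x$cc)) {
    pts <- as.data.frame(x$cc$points)
    cc <- new("CcBaseline", points = pts,
              areaChangeThreshold = x$cc$areaChangeThreshold,
              maxMatchDistance = x$cc$maxMatchDistance, mode = x$cc$mode,
              nCalibration = as.integer(x$cc$nCalibration),
              minArea = as.integer(x$cc$minArea), sigma = x$cc$sigma)
  }
  dis <- NULL
  if (!is.null(x$dis)) {
    refPng <- file.path(dirname(path), x$dis$reference$file)
    m <- png::readPNG(refPng)
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    ref <- new("ReferenceImage", mask = m > 0.5,
               threshold = x$dis$reference$threshold,
               whiteCount = as.integer(x$dis$reference$whiteCount),
               nSourceFrames = as.integer(x$dis$reference$nSourceFrames),
               mode = x$dis$reference$mode)
    cut <- new("DisCutoffs", udMax = x$dis$cutoffs$udMax,
               odMax = x$dis$cutoffs$odMax, disMin = x$dis$cutoffs$disMin,
               votesRequired = as.integer(x$dis$cutoffs$votesRequired),
               k = x$dis$cutoffs$k,
               nCalibration = as.integer(x$dis$cutoffs$nCalibration))
    dis <- list(reference = ref, cutoffs = cut)
  }
  new("CalibrationProfile", mode = x$mode, wpc = wpc, cc = cc, dis = dis,
      maxShift = as.integer(x$maxShift))
}

#' Write a run report
#'
#' Writes the per-detector summary as JSON and, optionally, the per-frame
#' scores as CSV.
#'
#' @param report a \linkS4class{RunReport}.
#' @param path destination JSON path.
#' @param scoresCsv optional path for the per-frame score table.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path, scoresCsv = NULL) {
  stopifnot(is(report, "RunReport"))
  out <- list(nFrames = report@nFrames, actualCount = report@actualCount,
              mode = report@mode, perDetector = report@perDetector,
              timingsSeconds = as.list(report@timings))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(scoresCsv))
    utils::write.csv(report@records, scoresCsv, row.names = FALSE)
  invisible(path)
}
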
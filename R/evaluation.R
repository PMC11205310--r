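#' Per-run detection accuracy
#'
#' The run-level accuracy used throughout:
#' \deqn{A = \frac{\textrm{number of particles detected in droplet images}}
#'                {\textrm{actual number of particles}} \times 100\%.}
#' With a reference count of zero the ratio is undefined and \code{NA} is
#' returned (a not-applicable run). False positives can push A above 100%;
#' it is reported as defined, and [runBatch()] additionally reports the
#' confusion counts whenever ground truth is available.
#'
#' @param detectedCount number of frames flagged as containing a particle.
#' @param actualCount reference particle count (slide count or truth sum).
#' @return Accuracy in percent, or \code{NA} when \code{actualCount} is 0.
#' @examples
#' accuracy(6, 6)
#' accuracy(93, 100)
#' @export
accuracy <- function(detectedCount, actualCount) {
  stopifnot(detectedCount >= 0, actualCount >= 0)
  if (actualCount < 1) return(NA_real_)
  detectedCount / actualCount * 100
}

#' Calibrate all detectors from empty-droplet frames
#'
#' Builds a full \linkS4class{CalibrationProfile} from a set of cropped
#' empty-droplet frames. The first \code{nReference} frames (default 20)
#' build the DIS reference image; the remaining held-out frames (at least
#' 10) calibrate the WPC cut-off, the contour-count baseline and the DIS
#' score cut-offs, so no detector is calibrated on frames that shaped the
#' reference.
#'
#' For diffuse-mode profiles the WPC detector defaults to a hard threshold
#' at 128 with dark polarity (opaque particles appear as dark patches on
#' the bright disc) and the glare-point detectors (CC, DIS) are skipped
#' unless explicitly requested.
#'
#' @param emptyImages list of cropped empty-droplet
#'   \linkS4class{DropletImage}.
#' @param detectors subset of \code{c("wpc", "cc", "dis")} to calibrate;
#'   defaults to all three in glare mode, WPC only in diffuse mode.
#' @param marginFraction WPC margin (default 0.15).
#' @param sidedness WPC sidedness, \code{"above_only"} or
#'   \code{"two_sided"}.
#' @param wpcBinarize binarization spec for WPC scoring; NULL picks the
#'   mode default.
#' @param minArea,maxMatchDistance,areaChangeThreshold,sigma contour-count
#'   parameters, see [calibrateCc()].
#' @param k,votesRequired DIS calibration parameters, see [calibrateDis()].
#' @param maxShift maximum template-matching shift, pixels.
#' @param nReference frames reserved for the DIS reference (default 20).
#' @param allowSmall relax the minimum frame counts.
#' @return A \linkS4class{CalibrationProfile}.
#' @export
calibrateProfile <- function(emptyImages, detectors = NULL,
                             marginFraction = 0.15,
                             sidedness = c("above_only", "two_sided"),
                             wpcBinarize = NULL, minArea = 5L,
                             maxMatchDistance = 15,
                             areaChangeThreshold = 0.30, sigma = 1, k = 3,
                             votesRequired = 2L, maxShift = 10L,
                             nReference = 20L, allowSmall = FALSE) {
  sidedness <- match.arg(sidedness)
  if (!length(emptyImages))
    stop("calibration error: no empty-droplet frames supplied")
  mode <- imageMode(emptyImages[[1L]])
  if (is.null(detectors))
    detectors <- if (mode == "glare") c("wpc", "cc", "dis") else "wpc"
  detectors <- match.arg(detectors, c("wpc", "cc", "dis"),
                         several.ok = TRUE)
  if (is.null(wpcBinarize)) {
    wpcBinarize <- if (mode == "glare") list(method = "otsu") else
      list(method = "hard", cutoff = 128, polarity = "dark_foreground")
  }
  if ("dis" %in% detectors) {
    if (length(emptyImages) < nReference + 10L && !allowSmall)
      stop("calibration error: need at least ", nReference + 10L,
           " empty frames for a DIS-calibrated profile (got ",
           length(emptyImages), ")")
    refFrames <- emptyImages[seq_len(min(nReference, length(emptyImages)))]
    heldOut <- emptyImages[-seq_len(min(nReference, length(emptyImages)))]
    if (!length(heldOut)) heldOut <- refFrames  # allowSmall degenerate case
  } else {
    refFrames <- emptyImages
    heldOut <- emptyImages
  }
  wpc <- NULL
  if ("wpc" %in% detectors) {
    bins <- lapply(heldOut, .binarizeFor, binarize = wpcBinarize)
    wpc <- calibrateWpc(bins, marginFraction = marginFraction,
                        sidedness = sidedness, mode = mode,
                        binarize = wpcBinarize, allowSmall = allowSmall)
  }
  cc <- NULL
  if ("cc" %in% detectors) {
    cc <- calibrateCc(heldOut, minArea = minArea,
                      maxMatchDistance = maxMatchDistance,
                      areaChangeThreshold = areaChangeThreshold,
                      sigma = sigma)
  }
  dis <- NULL
  if ("dis" %in% detectors) {
    ref <- buildReference(refFrames, allowSmall = allowSmall)
    cut <- calibrateDis(heldOut, ref, k = k,
                        votesRequired = votesRequired,
                        maxShift = maxShift, allowSmall = allowSmall)
    dis <- list(reference = ref, cutoffs = cut)
  }
  new("CalibrationProfile", mode = mode, wpc = wpc, cc = cc, dis = dis,
      maxShift = as.integer(maxShift))
}

.recordRow <- function(rec, truth) {
  sc <- rec@scores
  data.frame(
    frame_index = rec@frameIndex, detector = rec@detector,
    detected = rec@detected, truth = truth,
    wpc = sc$wpc %||% NA_real_,
    nPoints = sc$nPoints %||% NA_integer_,
    nAppeared = sc$nAppeared %||% NA_integer_,
    nDisappeared = sc$nDisappeared %||% NA_integer_,
    maxAreaChange = sc$maxAreaChange %||% NA_real_,
    ud = sc$ud %||% NA_real_, od = sc$od %||% NA_real_,
    dis = sc$dis %||% NA_real_)
}

#' Run the detectors over an image series
#'
#' Applies the requested detectors to every frame of a series, each
#' detector seeing identical preprocessed inputs, and assembles the
#' per-frame records, per-detector detected counts, the run accuracy
#' against the reference particle count, and -- when ground-truth labels
#' exist -- the confusion counts. Detection is fully deterministic: no
#' randomness enters any detector path.
#'
#' @param series a \linkS4class{LabelledSeries} (from [generateSeries()] or
#'   [readSeries()]).
#' @param profile a \linkS4class{CalibrationProfile} of matching
#'   illumination mode.
#' @param detectors subset of \code{c("wpc", "cc", "dis")}; defaults to all
#'   detectors calibrated in the profile.
#' @param referenceCount actual particle count of the run (the microscope
#'   slide count); defaults to the number of TRUE truth labels.
#' @param cropSize frames larger than this are localized and cropped first
#'   (default 200); frames already at or below this size pass through.
#' @return A \linkS4class{RunReport}.
#' @export
runBatch <- function(series, profile, detectors = NULL,
                     referenceCount = NULL, cropSize = 200L) {
  stopifnot(is(series, "LabelledSeries"),
            is(profile, "CalibrationProfile"))
  if (is.null(detectors)) {
    detectors <- c("wpc", "cc", "dis")[c(!is.null(profile@wpc),
                                         !is.null(profile@cc),
                                         !is.null(profile@dis))]
  }
  detectors <- match.arg(detectors, c("wpc", "cc", "dis"),
                         several.ok = TRUE)
  for (d in detectors) {
    cal <- switch(d, wpc = profile@wpc, cc = profile@cc, dis = profile@dis)
    if (is.null(cal))
      stop("configuration error: detector '", d,
           "' requested but not calibrated in the profile")
  }
  frames <- seriesFrames(series)
  if (!length(frames)) stop("empty series")
  if (imageMode(frames[[1L]]) != profile@mode)
    stop("configuration error: series mode '", imageMode(frames[[1L]]),
         "' does not match calibration mode '", profile@mode, "'")
  truth <- truthLabels(series)
  rows <- vector("list", length(frames) * length(detectors))
  timings <- stats::setNames(numeric(length(detectors)), detectors)
  n <- 0L
  for (i in seq_along(frames)) {
    img <- frames[[i]]
    if (any(dim(pixels(img)) > cropSize))
      img <- locateAndCrop(img, size = cropSize)
    for (d in detectors) {
      t0 <- proc.time()[["elapsed"]]
      rec <- switch(d,
        wpc = classifyWpc(img, profile@wpc),
        cc = {
          bin <- gaussianSmooth(otsuThreshold(img), profile@cc@sigma)
          classifyCc(extractGlarePoints(bin, profile@cc@minArea,
                                        frameIndex(img)),
                     profile@cc)
        },
        dis = classifyDis(similarityScores(img, profile@dis$reference,
                                           profile@maxShift),
                          profile@dis$cutoffs, frameIndex(img)))
      timings[d] <- timings[d] + (proc.time()[["elapsed"]] - t0)
      n <- n + 1L
      rows[[n]] <- .recordRow(rec, truth[i])
    }
  }
  records <- do.call(rbind, rows[seq_len(n)])
  actual <- if (!is.null(referenceCount)) as.integer(referenceCount)
            else as.integer(sum(truth, na.rm = TRUE))
  per <- do.call(rbind, lapply(detectors, function(d) {
    r <- records[records$detector == d, ]
    det <- sum(r$detected)
    hasTruth <- !is.na(r$truth)
    data.frame(
      detector = d, detectedCount = det,
      accuracyPercent = accuracy(det, actual),
      truePositives = sum(r$detected & r$truth & hasTruth),
      falsePositives = sum(r$detected & !r$truth & hasTruth),
      falseNegatives = sum(!r$detected & r$truth & hasTruth))
  }))
  new("RunReport", records = records, perDetector = per,
      nFrames = length(frames), actualCount = actual,
      mode = profile@mode, timings = timings)
}
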
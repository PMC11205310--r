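#' Extract glare points from a binarized crop
#'
#' Finds the connected foreground components (8-connectivity) of a
#' binarized, de-speckled glare-mode crop and returns one glare point per
#' component with area at least \code{minArea}. The area is the enclosed
#' pixel count of the component; the contour is the set of component pixels
#' touching the background. Labels are assigned in row-major order of the
#' centroids.
#'
#' @param binary a \linkS4class{BinaryImage}.
#' @param minArea minimum component area in pixels (default 5) -- suppresses
#'   residual speckle.
#' @param frameIndex frame index recorded on the result.
#' @return A \linkS4class{GlarePointSet} (possibly empty).
#' @examples
#' m <- matrix(FALSE, 40, 40)
#' m[5:9, 5:9] <- TRUE; m[20:24, 30:34] <- TRUE
#' extractGlarePoints(BinaryImage(m, 0))
#' @export
extractGlarePoints <- function(binary, minArea = 5L, frameIndex = 0L) {
  stopifnot(is(binary, "BinaryImage"))
  m <- mask(binary)
  lab <- .label8(m)
  k <- max(lab)
  pts <- data.frame(label = integer(), row = numeric(), col = numeric(),
                    area = integer())
  pts$contour <- list()
  if (k > 0L) {
    idx <- which(lab > 0L, arr.ind = TRUE)
    comp <- lab[lab > 0L]
    areas <- tabulate(comp, nbins = k)
    keep <- which(areas >= minArea)
    if (length(keep)) {
      rows <- vapply(keep, function(j) mean(idx[comp == j, 1L]), numeric(1L))
      cols <- vapply(keep, function(j) mean(idx[comp == j, 2L]), numeric(1L))
      ord <- order(rows, cols)
      keep <- keep[ord]
      contours <- lapply(keep, function(j) .componentContour(lab, j))
      pts <- data.frame(label = seq_along(keep), row = rows[ord],
                        col = cols[ord], area = as.integer(areas[keep]))
      pts$contour <- contours
    }
  }
  new("GlarePointSet", points = pts, frameIndex = as.integer(frameIndex))
}

# boundary pixels of component j: component pixels with a 4-neighbour that
# is outside the component (or outside the image)
.componentContour <- function(lab, j) {
  inC <- lab == j
  n <- nrow(inC); p <- ncol(inC)
  pad <- matrix(FALSE, n + 2L, p + 2L)
  pad[2:(n + 1L), 2:(p + 1L)] <- inC
  core <- pad[2:(n + 1L), 2:(p + 1L)]
  interior <- core &
    pad[1:n, 2:(p + 1L)] & pad[3:(n + 2L), 2:(p + 1L)] &
    pad[2:(n + 1L), 1:p] & pad[2:(n + 1L), 3:(p + 2L)]
  which(core & !interior, arr.ind = TRUE)
}

#' Match current glare points to a baseline
#'
#' Pairs the glare points of the current frame with the reference points of
#' the calibration baseline by greedy nearest-centroid matching: the
#' globally closest unmatched pair is paired first, and pairing stops at the
#' maximum match distance. Each point is matched at most once; leftover
#' current points are flagged \emph{appeared}, leftover baseline points
#' \emph{disappeared}.
#'
#' @param current a \linkS4class{GlarePointSet}.
#' @param baseline a \linkS4class{CcBaseline}.
#' @return A list with \code{pairs} (data.frame: \code{currentLabel},
#'   \code{baselineLabel}, \code{distance}, \code{currentArea},
#'   \code{baselineArea}), \code{appeared} (current labels) and
#'   \code{disappeared} (baseline labels).
#' @export
matchGlarePoints <- function(current, baseline) {
  stopifnot(is(current, "GlarePointSet"), is(baseline, "CcBaseline"))
  cur <- glarePoints(current)
  ref <- baseline@points
  pairs <- data.frame(currentLabel = integer(), baselineLabel = integer(),
                      distance = numeric(), currentArea = numeric(),
                      baselineArea = numeric())
  if (nrow(cur) && nrow(ref)) {
    d <- sqrt(outer(cur$row, ref$row, "-")^2 +
              outer(cur$col, ref$col, "-")^2)
    freeC <- rep(TRUE, nrow(cur))
    freeR <- rep(TRUE, nrow(ref))
    repeat {
      d2 <- d
      d2[!freeC, ] <- Inf
      d2[, !freeR] <- Inf
      best <- which.min(d2)
      if (!length(best) || !is.finite(d2[best]) ||
          d2[best] > baseline@maxMatchDistance) break
      i <- (best - 1L) %% nrow(cur) + 1L
      j <- (best - 1L) %/% nrow(cur) + 1L
      pairs <- rbind(pairs, data.frame(
        currentLabel = cur$label[i], baselineLabel = ref$label[j],
        distance = d[i, j], currentArea = cur$area[i],
        baselineArea = ref$area[j]))
      freeC[i] <- FALSE
      freeR[j] <- FALSE
      if (!any(freeC) || !any(freeR)) break
    }
    appeared <- cur$label[freeC]
    disappeared <- ref$label[freeR]
  } else {
    appeared <- cur$label
    disappeared <- ref$label
  }
  list(pairs = pairs, appeared = appeared, disappeared = disappeared)
}

#' Classify one frame with the contour-count (CC) rule
#'
#' A frame is a detection iff (a) any glare point appeared or disappeared
#' relative to the baseline, or (b) any matched glare point changed its
#' enclosed area by strictly more than the area-change threshold (default
#' 30%) in either direction. A change of exactly the threshold does not
#' trigger.
#'
#' @param current a \linkS4class{GlarePointSet} of the frame.
#' @param baseline a calibrated \linkS4class{CcBaseline}.
#' @return A \linkS4class{DetectionRecord}; its \code{triggers} list the
#'   appeared/disappeared labels and the area-changed pairs.
#' @export
classifyCc <- function(current, baseline) {
  stopifnot(is(current, "GlarePointSet"), is(baseline, "CcBaseline"))
  if (nrow(baseline@points) == 0L)
    stop("calibration error: contour-count baseline is empty")
  m <- matchGlarePoints(current, baseline)
  rel <- if (nrow(m$pairs)) {
    abs(m$pairs$currentArea - m$pairs$baselineArea) / m$pairs$baselineArea
  } else numeric()
  changed <- which(rel > baseline@areaChangeThreshold)
  hit <- length(m$appeared) > 0L || length(m$disappeared) > 0L ||
    length(changed) > 0L
  DetectionRecord(frameIndex(current), "cc", hit,
    scores = list(nPoints = nrow(glarePoints(current)),
                  nAppeared = length(m$appeared),
                  nDisappeared = length(m$disappeared),
                  maxAreaChange = if (length(rel)) max(rel) else 0),
    triggers = list(appeared = m$appeared, disappeared = m$disappeared,
                    areaChanged = m$pairs[changed, , drop = FALSE]))
}

#' Calibrate the contour-count baseline from empty droplets
#'
#' Builds the reference glare-point set: each empty frame is binarized
#' (Otsu), de-speckled (Gaussian mask smoothing) and its glare points
#' extracted; frames are then matched across the calibration set and the
#' per-point centroid and enclosed area averaged. If the per-frame point
#' counts disagree, the majority count is used and the discordant frames
#' are dropped with a warning.
#'
#' @param emptyImages list of cropped empty-droplet
#'   \linkS4class{DropletImage}.
#' @param minArea minimum glare-point area, pixels (default 5).
#' @param maxMatchDistance maximum centroid pairing distance, pixels
#'   (default 15; generous relative to the ~1 px trigger jitter).
#' @param areaChangeThreshold relative area change of the detection rule
#'   (default 0.30).
#' @param sigma mask-smoothing sigma, pixels (default 1).
#' @return A \linkS4class{CcBaseline}.
#' @export
calibrateCc <- function(emptyImages, minArea = 5L, maxMatchDistance = 15,
                        areaChangeThreshold = 0.30, sigma = 1) {
  n <- length(emptyImages)
  if (n < 1L)
    stop("calibration error: need at least one empty-droplet frame")
  sets <- lapply(emptyImages, function(img) {
    extractGlarePoints(gaussianSmooth(otsuThreshold(img), sigma),
                       minArea = minArea, frameIndex = frameIndex(img))
  })
  counts <- vapply(sets, length, integer(1L))
  tab <- table(counts)
  majority <- as.integer(names(tab)[which.max(tab)])
  if (any(counts != majority)) {
    warning("inconsistent glare-point counts across calibration frames (",
            paste(unique(counts), collapse = ", "), "); using the ",
            sum(counts == majority), " frame(s) with the majority count ",
            majority)
    sets <- sets[counts == majority]
  }
  if (majority == 0L)
    stop("calibration error: no glare points found in calibration frames")
  anchor <- glarePoints(sets[[1L]])
  acc <- anchor[, c("label", "row", "col", "area")]
  acc$row <- acc$row; acc$col <- acc$col; acc$area <- as.numeric(acc$area)
  cnt <- rep(1L, nrow(acc))
  if (length(sets) > 1L) {
    tmpBase <- new("CcBaseline", points = anchor,
                   areaChangeThreshold = areaChangeThreshold,
                   maxMatchDistance = maxMatchDistance, mode = "glare",
                   nCalibration = 1L)
    for (s in sets[-1L]) {
      mm <- matchGlarePoints(s, tmpBase)
      if (nrow(mm$pairs)) {
        j <- match(mm$pairs$baselineLabel, acc$label)
        i <- match(mm$pairs$currentLabel, glarePoints(s)$label)
        acc$row[j] <- acc$row[j] + glarePoints(s)$row[i]
        acc$col[j] <- acc$col[j] + glarePoints(s)$col[i]
        acc$area[j] <- acc$area[j] + glarePoints(s)$area[i]
        cnt[j] <- cnt[j] + 1L
      }
    }
  }
  acc$row <- acc$row / cnt
  acc$col <- acc$col / cnt
  acc$area <- acc$area / cnt
  mode <- imageMode(emptyImages[[1L]])
  new("CcBaseline", points = acc,
      areaChangeThreshold = areaChangeThreshold,
      maxMatchDistance = maxMatchDistance, mode = mode,
      nCalibration = as.integer(length(sets)),
      minArea = as.integer(minArea), sigma = sigma)
}
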
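#' Build the mean empty-droplet reference image
#'
#' Averages the grayscale crops of empty droplets pixel-wise and binarizes
#' the mean with Otsu's method. The reference white-pixel count is the
#' denominator of the underfill (UD) and overfill (OD) scores. Twenty
#' source frames are required by default.
#'
#' @param emptyImages list of cropped empty-droplet
#'   \linkS4class{DropletImage} of identical shape.
#' @param minFrames minimum number of source frames (default 20).
#' @param allowSmall set TRUE to accept fewer frames.
#' @return A \linkS4class{ReferenceImage}.
#' @export
buildReference <- function(emptyImages, minFrames = 20L,
                           allowSmall = FALSE) {
  n <- length(emptyImages)
  if (n < minFrames && !allowSmall)
    stop("calibration error: need at least ", minFrames,
         " empty-droplet frames (got ", n,
         "); set allowSmall = TRUE to override")
  if (n < 1L) stop("calibration error: no empty-droplet frames supplied")
  meanPx <- Reduce(`+`, lapply(emptyImages, pixels)) / n
  meanImg <- DropletImage(meanPx, mode = imageMode(emptyImages[[1L]]))
  bin <- otsuThreshold(meanImg)
  white <- sum(mask(bin))
  if (white == 0L)
    stop("calibration error: mean empty-droplet image binarizes to an ",
         "all-dark mask (degenerate reference)")
  new("ReferenceImage", mask = mask(bin), threshold = maskThreshold(bin),
      whiteCount = as.integer(white), nSourceFrames = as.integer(n),
      mode = imageMode(emptyImages[[1L]]))
}

.checkScorable <- function(aligned, ref) {
  stopifnot(is(aligned, "BinaryImage"), is(ref, "ReferenceImage"))
  if (!all(dim(mask(aligned)) == dim(mask(ref))))
    stop("frame and reference must have identical shape")
  if (ref@whiteCount < 1L)
    stop("calibration error: reference white-pixel count is zero")
}

#' Underfill (UD) score
#'
#' Percentage of reference-mask pixels missing from the frame, i.e. pixels
#' that are white in the reference and black in the (aligned) frame,
#' relative to the reference white-pixel count:
#' \deqn{UD = \frac{\textrm{missing pixels}}
#'                 {\textrm{reference pixels}} \times 100\%.}
#'
#' @param aligned a \linkS4class{BinaryImage} already aligned to the
#'   reference (see [alignToReference()]).
#' @param ref a \linkS4class{ReferenceImage}.
#' @return UD score in percent, in \code{[0, 100]}.
#' @export
udScore <- function(aligned, ref) {
  .checkScorable(aligned, ref)
  sum(mask(ref) & !mask(aligned)) / ref@whiteCount * 100
}

#' Overfill (OD) score
#'
#' Percentage of surplus pixels in the frame, i.e. pixels that are black in
#' the reference and white in the (aligned) frame, relative to the
#' reference white-pixel count. Unlike UD it is not bounded by 100: a frame
#' can contain more surplus pixels than the reference has white pixels.
#'
#' @inheritParams udScore
#' @return OD score in percent (>= 0).
#' @export
odScore <- function(aligned, ref) {
  .checkScorable(aligned, ref)
  sum(!mask(ref) & mask(aligned)) / ref@whiteCount * 100
}

#' Droplet image similarity (DIS) score
#'
#' Combined similarity of a frame to the reference:
#' \deqn{DIS = 100\% - \frac{UD + OD}{2}.}
#' A perfect match gives 100; the score is deliberately not clamped, so a
#' gross mismatch can drive it negative.
#'
#' @param ud underfill score, percent (>= 0).
#' @param od overfill score, percent (>= 0).
#' @return DIS score in percent.
#' @examples
#' disScore(15, 20)   # 82.5
#' @export
disScore <- function(ud, od) {
  if (any(ud < 0) || any(od < 0))
    stop("UD and OD scores must be non-negative")
  100 - (ud + od) / 2
}

#' Score one frame against the reference
#'
#' Convenience pipeline: binarize (Otsu), align to the reference by
#' template matching, and compute the UD/OD/DIS scores.
#'
#' @param image a cropped \linkS4class{DropletImage}.
#' @param ref a \linkS4class{ReferenceImage}.
#' @param maxShift maximum alignment shift, pixels.
#' @return A \linkS4class{SimilarityScores}.
#' @export
similarityScores <- function(image, ref, maxShift = 10L) {
  stopifnot(is(image, "DropletImage"), is(ref, "ReferenceImage"))
  bin <- otsuThreshold(image)
  al <- alignToReference(bin, ref, maxShift = maxShift)
  ud <- udScore(al$aligned, ref)
  od <- odScore(al$aligned, ref)
  new("SimilarityScores", ud = ud, od = od, dis = disScore(ud, od))
}

#' Calibrate the DIS score cut-offs from held-out empty droplets
#'
#' Scores empty droplets that were \emph{not} used to build the reference
#' and sets each cut-off at mean + k standard deviations of the empty-frame
#' scores (default k = 3, a standard false-positive control). The
#' similarity cut-off follows by construction:
#' \code{disMin = 100 - (udMax + odMax)/2}.
#'
#' @param emptyImages list of held-out empty-droplet
#'   \linkS4class{DropletImage} (at least 10).
#' @param ref the \linkS4class{ReferenceImage}.
#' @param k sigma multiplier (default 3).
#' @param votesRequired deviating scores needed for a detection (default 2).
#' @param maxShift maximum alignment shift, pixels.
#' @param allowSmall set TRUE to accept fewer than 10 frames.
#' @return A \linkS4class{DisCutoffs}.
#' @export
calibrateDis <- function(emptyImages, ref, k = 3, votesRequired = 2L,
                         maxShift = 10L, allowSmall = FALSE) {
  n <- length(emptyImages)
  if (n < 10L && !allowSmall)
    stop("calibration error: need at least 10 held-out empty frames (got ",
         n, "); set allowSmall = TRUE to override")
  if (n < 1L) stop("calibration error: no held-out empty frames supplied")
  sc <- lapply(emptyImages, similarityScores, ref = ref,
               maxShift = maxShift)
  uds <- vapply(sc, function(s) s@ud, numeric(1L))
  ods <- vapply(sc, function(s) s@od, numeric(1L))
  sdOr0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  udMax <- mean(uds) + k * sdOr0(uds)
  odMax <- mean(ods) + k * sdOr0(ods)
  new("DisCutoffs", udMax = udMax, odMax = odMax,
      disMin = 100 - (udMax + odMax) / 2,
      votesRequired = as.integer(votesRequired), k = k,
      nCalibration = as.integer(n))
}

#' Classify one frame with the two-of-three DIS rule
#'
#' Each score casts a vote when it deviates strictly beyond its cut-off:
#' UD above \code{udMax}, OD above \code{odMax}, DIS below \code{disMin}.
#' The frame is a detection when at least \code{votesRequired} scores
#' (default two of the three) deviate simultaneously. A score exactly at
#' its cut-off does not vote.
#'
#' @param scores a \linkS4class{SimilarityScores}.
#' @param cutoffs a calibrated \linkS4class{DisCutoffs}.
#' @param frameIndex frame index recorded on the result.
#' @return A \linkS4class{DetectionRecord}; \code{triggers$votes} names the
#'   deviating scores.
#' @export
classifyDis <- function(scores, cutoffs, frameIndex = 0L) {
  stopifnot(is(scores, "SimilarityScores"), is(cutoffs, "DisCutoffs"))
  votes <- c(ud = scores@ud > cutoffs@udMax,
             od = scores@od > cutoffs@odMax,
             dis = scores@dis < cutoffs@disMin)
  DetectionRecord(frameIndex, "dis",
                  sum(votes) >= cutoffs@votesRequired,
                  scores = list(ud = scores@ud, od = scores@od,
                                dis = scores@dis),
                  triggers = list(votes = names(votes)[votes],
                                  nVotes = sum(votes)))
}
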
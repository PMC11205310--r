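#' White pixel count (WPC) score
#'
#' The fraction of white (foreground) pixels in a binarized droplet crop:
#' \deqn{WPC = \frac{\textrm{number of white pixels}}
#'                  {\textrm{total number of pixels}}.}
#' An encapsulated particle perturbs the glare points, so the white-pixel
#' fraction of a particle-bearing droplet deviates from the empty-droplet
#' baseline.
#'
#' @param binary a \linkS4class{BinaryImage}.
#' @return A \linkS4class{WpcResult}.
#' @examples
#' m <- matrix(FALSE, 200, 200); m[1:40, 1:100] <- TRUE
#' wpcScore(BinaryImage(m, 0))
#' @export
wpcScore <- function(binary) {
  stopifnot(is(binary, "BinaryImage"))
  m <- mask(binary)
  total <- length(m)
  if (total < 1L) stop("cannot score a zero-pixel image")
  white <- sum(m)
  new("WpcResult", wpc = white / total, whitePixels = as.integer(white),
      totalPixels = as.integer(total))
}

#' Calibrate the WPC detection cut-off from empty droplets
#'
#' The baseline is the arithmetic mean WPC over a set of binarized
#' empty-droplet crops (ten by default in the acquisition protocol); a
#' relative margin (default 15%) above and below it defines the detection
#' cut-offs. At least ten calibration frames are required unless explicitly
#' overridden.
#'
#' @param emptyBinaries list of \linkS4class{BinaryImage} from empty
#'   droplets.
#' @param marginFraction relative margin (default 0.15).
#' @param sidedness \code{"above_only"} (the printed rule: only an increased
#'   white-pixel count counts) or \code{"two_sided"} (glare points may also
#'   disappear, decreasing the count).
#' @param mode illumination regime the calibration applies to.
#' @param binarize list describing the binarization the scored frames went
#'   through (recorded so classification can reproduce it); see
#'   \linkS4class{WpcCutoff}.
#' @param allowSmall set TRUE to accept fewer than ten calibration frames.
#' @return A \linkS4class{WpcCutoff}.
#' @export
calibrateWpc <- function(emptyBinaries, marginFraction = 0.15,
                         sidedness = c("above_only", "two_sided"),
                         mode = c("glare", "diffuse"),
                         binarize = list(method = "otsu"),
                         allowSmall = FALSE) {
  sidedness <- match.arg(sidedness)
  mode <- match.arg(mode)
  n <- length(emptyBinaries)
  if (n < 10L && !allowSmall)
    stop("calibration error: need at least 10 empty-droplet frames (got ",
         n, "); set allowSmall = TRUE to override")
  if (n < 1L) stop("calibration error: no empty-droplet frames supplied")
  wpcs <- vapply(emptyBinaries, function(b) wpcScore(b)@wpc, numeric(1L))
  baseline <- mean(wpcs)
  new("WpcCutoff", baseline = baseline, marginFraction = marginFraction,
      cutoffHigh = baseline * (1 + marginFraction),
      cutoffLow = baseline * (1 - marginFraction),
      sidedness = sidedness, mode = mode, nCalibration = as.integer(n),
      binarize = binarize)
}

.binarizeFor <- function(image, binarize) {
  method <- binarize$method %||% "otsu"
  if (method == "otsu") {
    otsuThreshold(image)
  } else if (method == "hard") {
    hardThreshold(image, binarize$cutoff %||% 128,
                  binarize$polarity %||% "bright_foreground")
  } else {
    stop("unknown binarization method: ", method)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify one frame with the WPC rule
#'
#' Binarizes the crop as recorded in the calibration, scores it, and applies
#' the cut-off rule: with \code{above_only} sidedness a frame is a detection
#' iff its WPC lies strictly above the upper cut-off; with \code{two_sided}
#' also iff it lies strictly below the lower cut-off. A score exactly at a
#' cut-off is not a detection.
#'
#' @param image a cropped \linkS4class{DropletImage}.
#' @param cutoff a calibrated \linkS4class{WpcCutoff} of matching
#'   illumination mode.
#' @return A \linkS4class{DetectionRecord} with the score attached.
#' @export
classifyWpc <- function(image, cutoff) {
  stopifnot(is(image, "DropletImage"), is(cutoff, "WpcCutoff"))
  if (imageMode(image) != cutoff@mode)
    stop("configuration error: image mode '", imageMode(image),
         "' does not match calibration mode '", cutoff@mode, "'")
  res <- wpcScore(.binarizeFor(image, cutoff@binarize))
  hit <- res@wpc > cutoff@cutoffHigh ||
    (cutoff@sidedness == "two_sided" && res@wpc < cutoff@cutoffLow)
  DetectionRecord(frameIndex(image), "wpc", hit,
                  scores = list(wpc = res@wpc),
                  triggers = list(whitePixels = res@whitePixels))
}
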
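#' @import methods
NULL

.validIntensities <- function(px) {
  if (!is.matrix(px) || !is.numeric(px))
    return("'pixels' must be a numeric matrix")
  if (nrow(px) < 1L || ncol(px) < 1L)
    return("image must have at least one row and one column")
  if (anyNA(px) || any(!is.finite(px)))
    return("intensities must be finite and non-missing")
  if (min(px) < 0 || max(px) > 255)
    return("intensities must lie in [0, 255]")
  TRUE
}

#' DropletImage: a single grayscale droplet frame
#'
#' An 8-bit-scale grayscale frame of one free-falling droplet, together with
#' its acquisition metadata: the illumination regime under which it was
#' captured and its position in the image series.
#'
#' @slot pixels numeric matrix (rows x cols) of intensities in \code{[0, 255]}.
#' @slot mode character, illumination regime: \code{"glare"} (glare-point
#'   projection by directed LEDs) or \code{"diffuse"} (diffuse anterior white
#'   light).
#' @slot frameIndex integer frame index within a series (0-based, as written
#'   to series manifests).
#'
#' @seealso [DropletImage()] for construction, [otsuThreshold()],
#'   [locateAndCrop()]
#' @name DropletImage-class
#' @rdname DropletImage-class
#' @exportClass DropletImage
setClass("DropletImage",
  representation(pixels = "matrix", mode = "character",
                 frameIndex = "integer"),
  prototype(mode = "glare", frameIndex = 0L),
  validity = function(object) {
    msg <- .validIntensities(object@pixels)
    if (!isTRUE(msg)) return(msg)
    if (length(object@mode) != 1L ||
        !object@mode %in% c("glare", "diffuse"))
      return("'mode' must be \"glare\" or \"diffuse\"")
    if (length(object@frameIndex) != 1L || is.na(object@frameIndex) ||
        object@frameIndex < 0L)
      return("'frameIndex' must be a single non-negative integer")
    TRUE
  })

#' @param pixels numeric matrix of intensities in \code{[0, 255]}.
#' @param mode illumination regime, \code{"glare"} or \code{"diffuse"}.
#' @param frameIndex integer frame index (0-based).
#' @return A \linkS4class{DropletImage}.
#' @examples
#' img <- DropletImage(matrix(0, 10, 10))
#' dim(pixels(img))
#' @rdname DropletImage-class
#' @export
DropletImage <- function(pixels, mode = c("glare", "diffuse"),
                         frameIndex = 0L) {
  mode <- match.arg(mode)
  new("DropletImage", pixels = pixels, mode = mode,
      frameIndex = as.integer(frameIndex))
}

#' BinaryImage: a thresholded droplet mask
#'
#' Boolean foreground mask derived from a \linkS4class{DropletImage} by
#' global thresholding. The polarity records which side of the threshold is
#' foreground: \code{"bright_foreground"} keeps pixels strictly above the
#' threshold (glare points, droplet disc), \code{"dark_foreground"} keeps
#' pixels strictly below it (opaque particles under diffuse illumination).
#'
#' @slot mask logical matrix, \code{TRUE} = foreground.
#' @slot threshold numeric threshold actually applied, in \code{[0, 255]}.
#' @slot polarity \code{"bright_foreground"} or \code{"dark_foreground"}.
#'
#' @name BinaryImage-class
#' @rdname BinaryImage-class
#' @exportClass BinaryImage
setClass("BinaryImage",
  representation(mask = "matrix", threshold = "numeric",
                 polarity = "character"),
  prototype(threshold = 0, polarity = "bright_foreground"),
  validity = function(object) {
    if (!is.logical(object@mask))
      return("'mask' must be a logical matrix")
    if (anyNA(object@mask))
      return("'mask' must not contain NA")
    if (length(object@threshold) != 1L || is.na(object@threshold) ||
        object@threshold < 0 || object@threshold > 255)
      return("'threshold' must be a single value in [0, 255]")
    if (!object@polarity %in% c("bright_foreground", "dark_foreground"))
      return("'polarity' must be bright_foreground or dark_foreground")
    TRUE
  })

#' @param mask logical matrix, \code{TRUE} = foreground.
#' @param threshold the intensity threshold that produced the mask.
#' @param polarity which side of the threshold is foreground.
#' @return A \linkS4class{BinaryImage}.
#' @rdname BinaryImage-class
#' @export
BinaryImage <- function(mask, threshold, polarity = "bright_foreground") {
  new("BinaryImage", mask = mask, threshold = as.numeric(threshold),
      polarity = polarity)
}

#' GlarePointSet: labelled glare-point blobs of one frame
#'
#' The connected bright components ("glare points") extracted from a
#' binarized glare-mode crop. Each point carries a label, its centroid in
#' pixel coordinates, its enclosed surface area in pixels, and its boundary
#' contour. Labels are assigned in row-major order of the centroids and are
#' unique within a frame.
#'
#' @slot points data.frame with columns \code{label}, \code{row}, \code{col},
#'   \code{area} and a list column \code{contour} of boundary-pixel
#'   coordinate matrices.
#' @slot frameIndex integer frame index of the source frame.
#'
#' @seealso [extractGlarePoints()]
#' @name GlarePointSet-class
#' @rdname GlarePointSet-class
#' @exportClass GlarePointSet
setClass("GlarePointSet",
  representation(points = "data.frame", frameIndex = "integer"),
  prototype(frameIndex = 0L),
  validity = function(object) {
    need <- c("label", "row", "col", "area")
    if (!all(need %in% names(object@points)))
      return(paste("'points' needs columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(object@points$label))
      return("glare-point labels must be unique within a frame")
    TRUE
  })

#' WpcResult: white pixel count score of one frame
#'
#' @slot wpc numeric fraction of white (foreground) pixels in \code{[0, 1]}.
#' @slot whitePixels integer count of foreground pixels.
#' @slot totalPixels integer total pixel count of the crop.
#' @name WpcResult-class
#' @rdname WpcResult-class
#' @exportClass WpcResult
setClass("WpcResult",
  representation(wpc = "numeric", whitePixels = "integer",
                 totalPixels = "integer"),
  validity = function(object) {
    if (object@totalPixels < 1L) return("'totalPixels' must be >= 1")
    if (object@whitePixels < 0L || object@whitePixels > object@totalPixels)
      return("'whitePixels' must lie in [0, totalPixels]")
    if (abs(object@wpc - object@whitePixels / object@totalPixels) > 1e-12)
      return("'wpc' must equal whitePixels / totalPixels")
    TRUE
  })

#' WpcCutoff: calibrated white-pixel-count detection cut-offs
#'
#' Baseline WPC of empty droplets plus the detection margins. The baseline is
#' the arithmetic mean WPC over the calibration frames; the cut-offs add and
#' subtract a relative margin (default 15%). With sidedness
#' \code{"above_only"} only scores strictly above the upper cut-off count as
#' detections; \code{"two_sided"} also flags scores strictly below the lower
#' cut-off (glare points can disappear as well as appear).
#'
#' @slot baseline mean empty-droplet WPC.
#' @slot marginFraction relative margin, default 0.15.
#' @slot cutoffHigh \code{baseline * (1 + marginFraction)}.
#' @slot cutoffLow \code{baseline * (1 - marginFraction)}.
#' @slot sidedness \code{"above_only"} or \code{"two_sided"}.
#' @slot mode illumination regime the calibration applies to.
#' @slot nCalibration number of empty frames used.
#' @slot binarize list describing the binarization applied before scoring:
#'   \code{method} (\code{"otsu"} or \code{"hard"}), and for \code{"hard"}
#'   also \code{cutoff} and \code{polarity}.
#' @name WpcCutoff-class
#' @rdname WpcCutoff-class
#' @exportClass WpcCutoff
setClass("WpcCutoff",
  representation(baseline = "numeric", marginFraction = "numeric",
                 cutoffHigh = "numeric", cutoffLow = "numeric",
                 sidedness = "character", mode = "character",
                 nCalibration = "integer", binarize = "list"),
  validity = function(object) {
    if (!(object@cutoffLow <= object@baseline &&
          object@baseline <= object@cutoffHigh))
      return("cutoffLow <= baseline <= cutoffHigh must hold")
    if (!object@sidedness %in% c("above_only", "two_sided"))
      return("'sidedness' must be above_only or two_sided")
    TRUE
  })

#' CcBaseline: glare-point baseline for the contour-count detector
#'
#' Reference glare points of the empty droplet: per-point mean centroid and
#' mean enclosed area across the calibration frames, plus the matching and
#' detection parameters of the contour-count rule.
#'
#' @slot points data.frame with columns \code{label}, \code{row}, \code{col},
#'   \code{area} (mean over calibration frames).
#' @slot areaChangeThreshold relative area change that triggers a detection
#'   when exceeded strictly (default 0.30).
#' @slot maxMatchDistance maximum centroid distance (pixels) for pairing a
#'   current glare point with a baseline point.
#' @slot mode illumination regime (always \code{"glare"} in practice).
#' @slot nCalibration number of empty frames used.
#' @slot minArea minimum glare-point area used during extraction, pixels.
#' @slot sigma mask-smoothing sigma used during extraction, pixels.
#' @name CcBaseline-class
#' @rdname CcBaseline-class
#' @exportClass CcBaseline
setClass("CcBaseline",
  representation(points = "data.frame", areaChangeThreshold = "numeric",
                 maxMatchDistance = "numeric", mode = "character",
                 nCalibration = "integer", minArea = "integer",
                 sigma = "numeric"),
  prototype(minArea = 5L, sigma = 1),
  validity = function(object) {
    if (object@areaChangeThreshold <= 0)
      return("'areaChangeThreshold' must be > 0")
    if (object@nCalibration < 1L)
      return("baseline requires at least one empty frame")
    TRUE
  })

#' ReferenceImage: mean empty-droplet reference mask
#'
#' Pixel-wise mean of empty-droplet grayscale crops, Otsu-binarized. Its
#' white-pixel count is the denominator of the underfill (UD) and overfill
#' (OD) scores.
#'
#' @slot mask logical matrix, the binarized mean image.
#' @slot threshold Otsu threshold applied to the mean image.
#' @slot whiteCount number of white pixels in the reference mask (> 0).
#' @slot nSourceFrames number of empty frames averaged (default >= 20).
#' @slot mode illumination regime.
#' @name ReferenceImage-class
#' @rdname ReferenceImage-class
#' @exportClass ReferenceImage
setClass("ReferenceImage",
  representation(mask = "matrix", threshold = "numeric",
                 whiteCount = "integer", nSourceFrames = "integer",
                 mode = "character"),
  validity = function(object) {
    if (object@whiteCount < 1L)
      return("reference mask must contain white pixels")
    if (object@whiteCount != sum(object@mask))
      return("'whiteCount' must equal the number of TRUE mask pixels")
    TRUE
  })

#' DisCutoffs: calibrated droplet-image-similarity cut-offs
#'
#' Score cut-offs for the two-of-three detection rule. \code{udMax} and
#' \code{odMax} are mean + k*sd of the UD and OD scores of held-out empty
#' frames; \code{disMin} is fixed to \code{100 - (udMax + odMax)/2} so a DIS
#' vote is consistent with the two component votes.
#'
#' @slot udMax maximum non-deviating underfill score (percent).
#' @slot odMax maximum non-deviating overfill score (percent).
#' @slot disMin minimum non-deviating similarity score (percent).
#' @slot votesRequired number of simultaneously deviating scores needed for a
#'   detection (1, 2 or 3; default 2).
#' @slot k sigma multiplier used during calibration.
#' @slot nCalibration number of held-out empty frames used.
#' @name DisCutoffs-class
#' @rdname DisCutoffs-class
#' @exportClass DisCutoffs
setClass("DisCutoffs",
  representation(udMax = "numeric", odMax = "numeric", disMin = "numeric",
                 votesRequired = "integer", k = "numeric",
                 nCalibration = "integer"),
  prototype(votesRequired = 2L, k = 3),
  validity = function(object) {
    if (!object@votesRequired %in% 1:3)
      return("'votesRequired' must be 1, 2 or 3")
    if (abs(object@disMin - (100 - (object@udMax + object@odMax) / 2)) >
        1e-9)
      return("disMin must equal 100 - (udMax + odMax)/2")
    TRUE
  })

#' SimilarityScores: UD/OD/DIS scores of one frame
#'
#' @slot ud underfill score in percent (reference pixels gone black).
#' @slot od overfill score in percent (background pixels gone white).
#' @slot dis similarity score in percent, \code{100 - (ud + od)/2}; may be
#'   negative for gross mismatch.
#' @name SimilarityScores-class
#' @rdname SimilarityScores-class
#' @exportClass SimilarityScores
setClass("SimilarityScores",
  representation(ud = "numeric", od = "numeric", dis = "numeric"),
  validity = function(object) {
    if (object@ud < 0 || object@od < 0)
      return("UD and OD scores cannot be negative")
    if (object@ud > 100)
      return("UD is a fraction of the reference mask and cannot exceed 100")
    if (abs(object@dis - (100 - (object@ud + object@od) / 2)) > 1e-9)
      return("dis must equal 100 - (ud + od)/2")
    TRUE
  })

#' CalibrationProfile: per-detector empty-droplet baselines
#'
#' Container holding whatever subset of the three detector calibrations has
#' been built for one illumination regime: the WPC cut-off, the contour-count
#' baseline, and the similarity reference plus score cut-offs.
#'
#' @slot mode illumination regime the profile applies to.
#' @slot wpc \linkS4class{WpcCutoff} or NULL.
#' @slot cc \linkS4class{CcBaseline} or NULL.
#' @slot dis list with elements \code{reference}
#'   (\linkS4class{ReferenceImage}) and \code{cutoffs}
#'   (\linkS4class{DisCutoffs}), or NULL.
#' @slot maxShift maximum template-matching shift (pixels) used when scoring
#'   frames against the reference.
#' @seealso [calibrateProfile()], [runBatch()]
#' @name CalibrationProfile-class
#' @rdname CalibrationProfile-class
#' @exportClass CalibrationProfile
setClass("CalibrationProfile",
  representation(mode = "character", wpc = "ANY", cc = "ANY", dis = "ANY",
                 maxShift = "integer"),
  prototype(wpc = NULL, cc = NULL, dis = NULL, maxShift = 10L))

#' DetectionRecord: one frame, one detector, one decision
#'
#' @slot frameIndex integer frame index (0-based).
#' @slot detector \code{"wpc"}, \code{"cc"} or \code{"dis"}.
#' @slot detected logical decision.
#' @slot scores named list of detector-specific scores.
#' @slot triggers named list describing what triggered the decision
#'   (contour-count points, similarity votes); may be empty.
#' @name DetectionRecord-class
#' @rdname DetectionRecord-class
#' @exportClass DetectionRecord
setClass("DetectionRecord",
  representation(frameIndex = "integer", detector = "character",
                 detected = "logical", scores = "list", triggers = "list"),
  prototype(triggers = list()),
  validity = function(object) {
    if (!object@detector %in% c("wpc", "cc", "dis"))
      return("'detector' must be one of wpc, cc, dis")
    TRUE
  })

DetectionRecord <- function(frameIndex, detector, detected, scores,
                            triggers = list()) {
  new("DetectionRecord", frameIndex = as.integer(frameIndex),
      detector = detector, detected = detected, scores = scores,
      triggers = triggers)
}

#' LabelledSeries: an image series with ground-truth labels
#'
#' A series of droplet frames as produced by [generateSeries()] or loaded by
#' [readSeries()], with a per-frame ground-truth label (particle present) and
#' the series manifest.
#'
#' @slot frames list of \linkS4class{DropletImage}.
#' @slot truth logical vector, one entry per frame.
#' @slot manifest data.frame with columns \code{frame_index},
#'   \code{filename}, \code{mode}, \code{truth_label}.
#' @slot scene list of scene-generator settings (empty for loaded data).
#' @slot optics list of optical-model settings (empty for loaded data).
#' @name LabelledSeries-class
#' @rdname LabelledSeries-class
#' @exportClass LabelledSeries
setClass("LabelledSeries",
  representation(frames = "list", truth = "logical", manifest = "data.frame",
                 scene = "list", optics = "list"),
  prototype(scene = list(), optics = list()),
  validity = function(object) {
    if (length(object@frames) != length(object@truth))
      return("one truth label per frame is required")
    if (nrow(object@manifest) != length(object@frames))
      return("manifest must have one row per frame")
    TRUE
  })

#' RunReport: per-run detection counts and accuracy
#'
#' Result of [runBatch()]: the per-frame detection records (flattened to a
#' data.frame) and, per detector, the detected count, the accuracy
#' \code{A = detected / actual * 100} against the reference particle count,
#' and -- when ground truth is available -- the confusion counts. The
#' accuracy is reported as defined even when false positives push it above
#' 100; the confusion counts disambiguate.
#'
#' @slot records data.frame of per-frame, per-detector results.
#' @slot perDetector data.frame with one row per detector: detected count,
#'   accuracy (percent), true/false positives, false negatives.
#' @slot nFrames number of frames evaluated.
#' @slot actualCount reference particle count (denominator of the accuracy).
#' @slot mode illumination regime of the series.
#' @slot timings named numeric vector of per-detector elapsed seconds.
#' @name RunReport-class
#' @rdname RunReport-class
#' @exportClass RunReport
setClass("RunReport",
  representation(records = "data.frame", perDetector = "data.frame",
                 nFrames = "integer", actualCount = "integer",
                 mode = "character", timings = "numeric"),
  prototype(timings = numeric()))

#' OpticalConfig: geometric-optics model settings
#'
#' Parameters of the minimal ray-optics model used to place glare points on
#' synthetic droplets: refractive indices, illumination wavelength and
#' incidence angle, number of LEDs, and the droplet radius on the sensor.
#' When \code{nDroplet} is NA it is taken from a fixed water dispersion table
#' by wavelength (shorter wavelengths refract more strongly:
#' n(405) > n(465) > n(635)).
#'
#' @slot nDroplet refractive index of the droplet liquid.
#' @slot nAmbient refractive index of the surrounding medium (air, 1.0).
#' @slot wavelengthNm LED wavelength, one of 405, 465, 635 nm.
#' @slot incidenceDeg angle of incidence of the LED beam on the droplet
#'   surface, degrees (default 40).
#' @slot nLeds number of LEDs projecting glare points (4 or 6).
#' @slot dropletRadiusPx droplet radius on the sensor, pixels.
#' @seealso [opticalConfig()], [traceGlarePoint()]
#' @name OpticalConfig-class
#' @rdname OpticalConfig-class
#' @exportClass OpticalConfig
setClass("OpticalConfig",
  representation(nDroplet = "numeric", nAmbient = "numeric",
                 wavelengthNm = "numeric", incidenceDeg = "numeric",
                 nLeds = "integer", dropletRadiusPx = "numeric"),
  validity = function(object) {
    if (!(object@nDroplet > object@nAmbient && object@nAmbient >= 1))
      return("need nDroplet > nAmbient >= 1")
    if (!(object@incidenceDeg > 0 && object@incidenceDeg < 90))
      return("'incidenceDeg' must lie strictly between 0 and 90 degrees")
    if (!object@nLeds %in% c(4L, 6L))
      return("'nLeds' must be 4 or 6")
    if (object@dropletRadiusPx <= 0)
      return("'dropletRadiusPx' must be positive")
    TRUE
  })

#' SceneConfig: synthetic-frame rendering settings
#'
#' Rendering parameters of the synthetic droplet-frame generator: the
#' illumination regime to emulate, frame and blob geometry, intensities,
#' sensor noise and droplet position jitter.
#'
#' @slot mode \code{"glare"} or \code{"diffuse"}.
#' @slot frameSize side length of the square frame in pixels (default 200,
#'   the crop size used by all detectors).
#' @slot glareSpotRadiusPx radius of a rendered glare spot, pixels.
#' @slot glareIntensity peak intensity of glare spots (glare mode) and of
#'   the droplet disc (diffuse mode).
#' @slot backgroundIntensity frame background intensity.
#' @slot noiseSd Gaussian sensor-noise standard deviation (intensity units).
#' @slot jitterSd droplet position jitter standard deviation (pixels);
#'   models trigger-timing variability, applied as an integer translation.
#' @slot seed integer default seed for rendering functions.
#' @seealso [sceneConfig()], [renderEmptyDroplet()], [generateSeries()]
#' @name SceneConfig-class
#' @rdname SceneConfig-class
#' @exportClass SceneConfig
setClass("SceneConfig",
  representation(mode = "character", frameSize = "integer",
                 glareSpotRadiusPx = "numeric", glareIntensity = "numeric",
                 backgroundIntensity = "numeric", noiseSd = "numeric",
                 jitterSd = "numeric", seed = "integer"),
  validity = function(object) {
    if (!object@mode %in% c("glare", "diffuse"))
      return("'mode' must be glare or diffuse")
    if (object@noiseSd < 0 || object@jitterSd < 0)
      return("'noiseSd' and 'jitterSd' must be >= 0")
    if (object@frameSize < 2L)
      return("'frameSize' must be at least 2 pixels")
    TRUE
  })

#' ParticleEffect: how a particle perturbs the rendered droplet
#'
#' Describes the image-level effect of an encapsulated particle. In glare
#' mode a particle grows, shrinks, adds or removes a glare point; in diffuse
#' mode an opaque particle appears as a dark patch while a transparent
#' particle (\code{"none"}) leaves the frame unchanged.
#'
#' @slot kind one of \code{"grow_spot"}, \code{"shrink_spot"},
#'   \code{"add_spot"}, \code{"remove_spot"}, \code{"dark_patch"},
#'   \code{"none"}.
#' @slot magnitude relative area change for grow/shrink, patch radius in
#'   pixels for \code{"dark_patch"}; ignored for \code{"none"}.
#' @slot targetSpot 1-based index of the affected glare spot, or
#'   \code{"random"}.
#' @seealso [particleEffect()], [renderParticleDroplet()]
#' @name ParticleEffect-class
#' @rdname ParticleEffect-class
#' @exportClass ParticleEffect
setClass("ParticleEffect",
  representation(kind = "character", magnitude = "numeric",
                 targetSpot = "ANY"),
  prototype(magnitude = 0, targetSpot = 1L),
  validity = function(object) {
    kinds <- c("grow_spot", "shrink_spot", "add_spot", "remove_spot",
               "dark_patch", "none")
    if (!object@kind %in% kinds)
      return(paste("'kind' must be one of:", paste(kinds, collapse = ", ")))
    if (object@kind != "none" && object@magnitude <= 0)
      return("'magnitude' must be > 0 for all kinds except \"none\"")
    if (object@kind == "shrink_spot" && object@magnitude >= 1)
      return("'shrink_spot' magnitude must be < 1")
    TRUE
  })
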
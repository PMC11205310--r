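#' Accessors for glareDrop classes
#'
#' Small accessor generics for the package's S4 containers: the intensity
#' grid, illumination mode and frame index of a \linkS4class{DropletImage};
#' the mask, threshold and polarity of a \linkS4class{BinaryImage}; the
#' point table of a \linkS4class{GlarePointSet}; the frames and truth labels
#' of a \linkS4class{LabelledSeries}.
#'
#' @param x an object of the relevant class.
#' @return The slot value: a matrix, character, integer, data.frame or list
#'   as appropriate.
#' @examples
#' img <- DropletImage(matrix(128, 5, 5), mode = "diffuse", frameIndex = 3L)
#' imageMode(img)
#' frameIndex(img)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("imageMode", function(x) standardGeneric("imageMode"))
#' @rdname accessors
#' @export
setGeneric("frameIndex", function(x) standardGeneric("frameIndex"))
#' @rdname accessors
#' @export
setGeneric("mask", function(x) standardGeneric("mask"))
#' @rdname accessors
#' @export
setGeneric("maskThreshold", function(x) standardGeneric("maskThreshold"))
#' @rdname accessors
#' @export
setGeneric("polarity", function(x) standardGeneric("polarity"))
#' @rdname accessors
#' @export
setGeneric("glarePoints", function(x) standardGeneric("glarePoints"))
#' @rdname accessors
#' @export
setGeneric("seriesFrames", function(x) standardGeneric("seriesFrames"))
#' @rdname accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
#' @rdname accessors
#' @export
setGeneric("detected", function(x) standardGeneric("detected"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setMethod("pixels", "DropletImage", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("imageMode", "DropletImage", function(x) x@mode)
#' @rdname accessors
#' @export
setMethod("frameIndex", "DropletImage", function(x) x@frameIndex)
#' @rdname accessors
#' @export
setMethod("mask", "BinaryImage", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("mask", "ReferenceImage", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("maskThreshold", "BinaryImage", function(x) x@threshold)
#' @rdname accessors
#' @export
setMethod("polarity", "BinaryImage", function(x) x@polarity)
#' @rdname accessors
#' @export
setMethod("glarePoints", "GlarePointSet", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("frameIndex", "GlarePointSet", function(x) x@frameIndex)
#' @rdname accessors
#' @export
setMethod("seriesFrames", "LabelledSeries", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("truthLabels", "LabelledSeries", function(x) x@truth)
#' @rdname accessors
#' @export
setMethod("detected", "DetectionRecord", function(x) x@detected)
#' @rdname accessors
#' @export
setMethod("scores", "DetectionRecord", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("length", "LabelledSeries", function(x) length(x@frames))
#' @rdname accessors
#' @export
setMethod("length", "GlarePointSet", function(x) nrow(x@points))

setMethod("show", "DropletImage", function(object) {
  cat(sprintf("DropletImage %dx%d [%s], frame %d, intensity range [%g, %g]\n",
              nrow(object@pixels), ncol(object@pixels), object@mode,
              object@frameIndex, min(object@pixels), max(object@pixels)))
})

setMethod("show", "BinaryImage", function(object) {
  cat(sprintf("BinaryImage %dx%d, %s, threshold %g, %d foreground px\n",
              nrow(object@mask), ncol(object@mask), object@polarity,
              object@threshold, sum(object@mask)))
})

setMethod("show", "GlarePointSet", function(object) {
  cat(sprintf("GlarePointSet: %d glare point(s), frame %d\n",
              nrow(object@points), object@frameIndex))
  if (nrow(object@points))
    print(object@points[, c("label", "row", "col", "area")], row.names = FALSE)
})

setMethod("show", "WpcResult", function(object) {
  cat(sprintf("WPC = %.5f (%d / %d white pixels)\n", object@wpc,
              object@whitePixels, object@totalPixels))
})

setMethod("show", "WpcCutoff", function(object) {
  cat(sprintf(paste0("WpcCutoff [%s, %s]: baseline %.5f, margin %g%%,",
                     " cut-offs [%.5f, %.5f], n = %d\n"),
              object@mode, object@sidedness, object@baseline,
              100 * object@marginFraction, object@cutoffLow,
              object@cutoffHigh, object@nCalibration))
})

setMethod("show", "CcBaseline", function(object) {
  cat(sprintf(paste0("CcBaseline [%s]: %d reference glare point(s), area",
                     " change threshold %g%%, match distance %g px,",
                     " n = %d\n"),
              object@mode, nrow(object@points),
              100 * object@areaChangeThreshold, object@maxMatchDistance,
              object@nCalibration))
})

setMethod("show", "ReferenceImage", function(object) {
  cat(sprintf(paste0("ReferenceImage [%s] %dx%d: %d white px,",
                     " Otsu threshold %g, mean of %d empty frames\n"),
              object@mode, nrow(object@mask), ncol(object@mask),
              object@whiteCount, object@threshold, object@nSourceFrames))
})

setMethod("show", "DisCutoffs", function(object) {
  cat(sprintf(paste0("DisCutoffs: UD <= %.3f, OD <= %.3f, DIS >= %.3f",
                     " (k = %g, votes >= %d, n = %d)\n"),
              object@udMax, object@odMax, object@disMin, object@k,
              object@votesRequired, object@nCalibration))
})

setMethod("show", "SimilarityScores", function(object) {
  cat(sprintf("SimilarityScores: UD %.3f%%, OD %.3f%%, DIS %.3f%%\n",
              object@ud, object@od, object@dis))
})

setMethod("show", "DetectionRecord", function(object) {
  sc <- paste(sprintf("%s=%.4g", names(object@scores),
                      unlist(object@scores)), collapse = ", ")
  cat(sprintf("DetectionRecord frame %d [%s]: %s (%s)\n",
              object@frameIndex, object@detector,
              if (object@detected) "DETECTED" else "empty", sc))
})

setMethod("show", "CalibrationProfile", function(object) {
  cat(sprintf("CalibrationProfile [%s]:\n", object@mode))
  cat("  WPC: ", if (is.null(object@wpc)) "not calibrated" else
      sprintf("baseline %.5f (%s)", object@wpc@baseline,
              object@wpc@sidedness), "\n", sep = "")
  cat("  CC:  ", if (is.null(object@cc)) "not calibrated" else
      sprintf("%d reference points", nrow(object@cc@points)), "\n", sep = "")
  cat("  DIS: ", if (is.null(object@dis)) "not calibrated" else
      sprintf("reference %d white px, UD <= %.3f, OD <= %.3f",
              object@dis$reference@whiteCount, object@dis$cutoffs@udMax,
              object@dis$cutoffs@odMax), "\n", sep = "")
})

setMethod("show", "LabelledSeries", function(object) {
  cat(sprintf("LabelledSeries: %d frame(s) [%s], %d with particle\n",
              length(object@frames),
              if (length(object@frames)) object@frames[[1]]@mode else "?",
              sum(object@truth)))
})

setMethod("show", "RunReport", function(object) {
  cat(sprintf("RunReport: %d frames [%s], actual particle count %d\n",
              object@nFrames, object@mode, object@actualCount))
  per <- object@perDetector
  per$accuracyPercent <- sprintf("%.1f", per$accuracyPercent)
  print(per, row.names = FALSE)
})

setMethod("show", "OpticalConfig", function(object) {
  cat(sprintf(paste0("OpticalConfig: n %g / %g, %g nm, incidence %g deg,",
                     " %d LEDs, droplet radius %g px\n"),
              object@nDroplet, object@nAmbient, object@wavelengthNm,
              object@incidenceDeg, object@nLeds, object@dropletRadiusPx))
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(paste0("SceneConfig [%s]: frame %d px, spot radius %g px,",
                     " noise sd %g, jitter sd %g, seed %d\n"),
              object@mode, object@frameSize, object@glareSpotRadiusPx,
              object@noiseSd, object@jitterSd, object@seed))
})
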
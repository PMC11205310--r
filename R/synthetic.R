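# Refractive index of water at the three LED wavelengths. Shorter
# wavelengths see a denser medium (normal dispersion), which is what makes
# the violet glare points brightest and most sensitive to inclusions.
.WATER_INDEX <- c("405" = 1.3428, "465" = 1.3376, "635" = 1.3314)

#' Refractive index of water by LED wavelength
#'
#' Fixed dispersion table used by the optical model when no explicit
#' droplet index is supplied: n(405) > n(465) > n(635).
#'
#' @param wavelengthNm 405, 465 or 635.
#' @return Refractive index of water at that wavelength.
#' @export
waterRefractiveIndex <- function(wavelengthNm) {
  key <- as.character(wavelengthNm)
  if (!key %in% names(.WATER_INDEX))
    stop("no dispersion entry for ", wavelengthNm,
         " nm (available: ", paste(names(.WATER_INDEX), collapse = ", "),
         ")")
  unname(.WATER_INDEX[key])
}

#' Construct an OpticalConfig
#'
#' @param nDroplet droplet refractive index; NA (default) looks it up from
#'   the water dispersion table by wavelength.
#' @param nAmbient ambient refractive index (air, 1.0).
#' @param wavelengthNm LED wavelength: 405, 465 or 635 nm.
#' @param incidenceDeg LED beam angle of incidence, degrees (default 40).
#' @param nLeds number of LEDs (4 or 6; default 6).
#' @param dropletRadiusPx droplet radius on the sensor, pixels (default 70,
#'   sized so the droplet fits a 200 x 200 crop with margin).
#' @return An \linkS4class{OpticalConfig}.
#' @examples
#' opticalConfig(wavelengthNm = 405)
#' @export
opticalConfig <- function(nDroplet = NA_real_, nAmbient = 1.0,
                          wavelengthNm = 405, incidenceDeg = 40,
                          nLeds = 6L, dropletRadiusPx = 70) {
  if (is.na(nDroplet)) nDroplet <- waterRefractiveIndex(wavelengthNm)
  new("OpticalConfig", nDroplet = nDroplet, nAmbient = nAmbient,
      wavelengthNm = wavelengthNm, incidenceDeg = incidenceDeg,
      nLeds = as.integer(nLeds), dropletRadiusPx = dropletRadiusPx)
}

#' Construct a SceneConfig
#'
#' Mode-specific defaults: glare frames are dark-field (background 8, spot
#' peak 230); diffuse frames show a bright droplet disc (235) on a bright
#' background (200). Noise sd 5 and integer jitter sd 1 px emulate sensor
#' noise and trigger-timing variability of the capture setup.
#'
#' @param mode \code{"glare"} or \code{"diffuse"}.
#' @param frameSize frame side length, pixels (default 200).
#' @param glareSpotRadiusPx glare-spot radius, pixels (default 4).
#' @param glareIntensity glare-spot peak / diffuse-disc intensity.
#' @param backgroundIntensity frame background intensity.
#' @param noiseSd Gaussian sensor noise sd, intensity units (default 5).
#' @param jitterSd droplet position jitter sd, pixels (default 1).
#' @param seed default seed used by the rendering functions.
#' @return A \linkS4class{SceneConfig}.
#' @export
sceneConfig <- function(mode = c("glare", "diffuse"), frameSize = 200L,
                        glareSpotRadiusPx = 4,
                        glareIntensity = if (mode == "glare") 230 else 235,
                        backgroundIntensity = if (mode == "glare") 8
                                              else 200,
                        noiseSd = 5, jitterSd = 1, seed = 1L) {
  mode <- match.arg(mode)
  new("SceneConfig", mode = mode, frameSize = as.integer(frameSize),
      glareSpotRadiusPx = glareSpotRadiusPx,
      glareIntensity = glareIntensity,
      backgroundIntensity = backgroundIntensity, noiseSd = noiseSd,
      jitterSd = jitterSd, seed = as.integer(seed))
}

#' Construct a ParticleEffect
#'
#' @param kind \code{"grow_spot"}, \code{"shrink_spot"}, \code{"add_spot"},
#'   \code{"remove_spot"}, \code{"dark_patch"} or \code{"none"}.
#' @param magnitude relative area change for grow/shrink (e.g. 0.5 grows
#'   the spot area by 50%), patch radius in pixels for \code{"dark_patch"}.
#' @param targetSpot 1-based index of the affected glare spot, or
#'   \code{"random"}.
#' @return A \linkS4class{ParticleEffect}.
#' @examples
#' particleEffect("remove_spot", targetSpot = 2)
#' @export
particleEffect <- function(kind = c("none", "grow_spot", "shrink_spot",
                                    "add_spot", "remove_spot",
                                    "dark_patch"),
                           magnitude = if (kind == "dark_patch") 10 else
                                       if (kind == "none") 0 else 0.5,
                           targetSpot = 1L) {
  kind <- match.arg(kind)
  if (!identical(targetSpot, "random")) targetSpot <- as.integer(targetSpot)
  new("ParticleEffect", kind = kind, magnitude = magnitude,
      targetSpot = targetSpot)
}

.refractVec <- function(d, n, eta) {
  cosi <- -sum(d * n)
  sin2t <- eta^2 * (1 - cosi^2)
  if (sin2t > 1) return(NULL)               # total internal reflection
  d * eta + n * (eta * cosi - sqrt(1 - sin2t))
}

#' Trace the glare-point ray through a droplet
#'
#' Two-dimensional geometric-optics trace of one LED ray on a circular
#' droplet cross-section: Snell refraction at entry, an internal chord,
#' partial reflection at the back water/air interface, a second chord, and
#' refraction at exit. This single-internal-reflection path is the one that
#' produces the characteristic glare points of an empty droplet; full Mie
#' scattering is deliberately not modelled.
#'
#' The trace is carried out with vector geometry on the unit circle, so the
#' reported internal angle can be checked independently against the
#' closed-form Snell relation \eqn{\sin\theta_t = (n_a/n_d)\sin\theta_i}.
#' If the droplet/ambient index combination produces total internal
#' reflection at the back interface (impossible for a ray that entered by
#' refraction, but reachable with hand-set indices), the ray is followed
#' for up to three internal bounces and flagged.
#'
#' @param cfg an \linkS4class{OpticalConfig}.
#' @return A list: \code{thetaIncidenceDeg}, \code{thetaInternalDeg}
#'   (angle of the refracted ray to the surface normal, from the vector
#'   trace), \code{exitAngleDeg} (exit direction relative to the optical
#'   axis), \code{exitPoint} (x, y on the unit circle),
#'   \code{ringFraction} (transverse offset of the exit point as a fraction
#'   of the droplet radius -- the radius of the glare-point ring),
#'   \code{totalInternalReflection}, \code{nDroplet}.
#' @examples
#' traceGlarePoint(opticalConfig(wavelengthNm = 405))$thetaInternalDeg
#' @export
traceGlarePoint <- function(cfg) {
  stopifnot(is(cfg, "OpticalConfig"))
  a <- cfg@incidenceDeg * pi / 180
  d0 <- c(cos(-a), sin(-a))                 # toward +x (camera axis)
  p <- c(-d0[2L], d0[1L])
  E <- -cos(a) * d0 + sin(a) * p            # entry point on unit circle
  t1 <- .refractVec(d0, E, cfg@nAmbient / cfg@nDroplet)
  # entering a denser medium: refraction always succeeds
  thetaInternal <- acos(min(1, abs(sum(t1 * E)))) * 180 / pi
  E2 <- E - 2 * sum(E * t1) * t1            # far intersection of the chord
  tir <- FALSE
  dir <- t1
  pos <- E2
  # partial reflection at the back interface starts the glare-point path;
  # if refraction out is impossible we keep reflecting (up to 3 bounces)
  for (bounce in 1:3) {
    dir <- dir - 2 * sum(dir * pos) * pos
    pos2 <- pos - 2 * sum(pos * dir) * dir
    dOut <- .refractVec(dir, -pos2, cfg@nDroplet / cfg@nAmbient)
    if (!is.null(dOut)) {
      return(list(thetaIncidenceDeg = cfg@incidenceDeg,
                  thetaInternalDeg = thetaInternal,
                  exitAngleDeg = atan2(dOut[2L], dOut[1L]) * 180 / pi,
                  exitPoint = pos2, ringFraction = abs(pos2[2L]),
                  totalInternalReflection = tir && bounce > 1,
                  nDroplet = cfg@nDroplet))
    }
    tir <- TRUE
    pos <- pos2
  }
  list(thetaIncidenceDeg = cfg@incidenceDeg,
       thetaInternalDeg = thetaInternal, exitAngleDeg = NA_real_,
       exitPoint = pos, ringFraction = abs(pos[2L]),
       totalInternalReflection = TRUE, nDroplet = cfg@nDroplet)
}

# glare-spot centres for one rendered droplet: one spot per LED on the
# ring whose radius comes from the traced exit point, azimuths equally
# distributed (the LEDs sit at equal angles around the dispense axis)
.spotLayout <- function(scene, optics, centre) {
  ring <- traceGlarePoint(optics)$ringFraction * optics@dropletRadiusPx
  nL <- optics@nLeds
  az <- (seq_len(nL) - 1L) * 2 * pi / nL + pi / nL
  data.frame(row = centre[1L] + ring * sin(az),
             col = centre[2L] + ring * cos(az),
             radius = rep(scene@glareSpotRadiusPx, nL),
             ring = rep(ring, nL), az = az)
}

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# paint anti-aliased discs onto a canvas by maximum combination
.paintDisc <- function(canvas, rowGrid, colGrid, r0, c0, radius,
                       intensity) {
  d <- sqrt((rowGrid - r0)^2 + (colGrid - c0)^2)
  cov <- pmin(pmax(radius + 0.5 - d, 0), 1)
  pmax(canvas, intensity * cov)
}

.renderFrame <- function(scene, optics, effect, frameIndex = 0L) {
  fs <- scene@frameSize
  R <- optics@dropletRadiusPx
  if (fs < 2 * R)
    stop("configuration error: frame size ", fs,
         " cannot hold a droplet of radius ", R)
  jitter <- round(stats::rnorm(2L, 0, scene@jitterSd))
  centre <- c((fs + 1) / 2 + jitter[1L], (fs + 1) / 2 + jitter[2L])
  rowGrid <- matrix(seq_len(fs), fs, fs)
  colGrid <- matrix(seq_len(fs), fs, fs, byrow = TRUE)
  d <- sqrt((rowGrid - centre[1L])^2 + (colGrid - centre[2L])^2)
  if (scene@mode == "glare") {
    if (effect@kind == "dark_patch")
      stop("'dark_patch' is only valid in diffuse mode")
    px <- matrix(scene@backgroundIntensity, fs, fs)
    rim <- abs(d - R) <= 1
    px[rim] <- pmax(px[rim], min(scene@backgroundIntensity + 32, 255))
    spots <- .spotLayout(scene, optics, centre)
    if (max(spots$ring) + scene@glareSpotRadiusPx > R)
      stop("configuration error: glare-spot placement falls outside the ",
           "droplet disc")
    target <- effect@targetSpot
    if (identical(target, "random")) target <- sample.int(nrow(spots), 1L)
    if (effect@kind %in% c("grow_spot", "shrink_spot", "remove_spot")) {
      if (target < 1L || target > nrow(spots))
        stop("'targetSpot' index ", target, " exceeds the ", nrow(spots),
             " rendered glare spots")
    }
    if (effect@kind == "grow_spot") {
      spots$radius[target] <- spots$radius[target] *
        sqrt(1 + effect@magnitude)
    } else if (effect@kind == "shrink_spot") {
      spots$radius[target] <- spots$radius[target] *
        sqrt(1 - effect@magnitude)
    } else if (effect@kind == "remove_spot") {
      spots <- spots[-target, , drop = FALSE]
    } else if (effect@kind == "add_spot") {
      az <- spots$az[1L] + pi / optics@nLeds
      ring <- 0.55 * spots$ring[1L]
      spots <- rbind(spots, data.frame(
        row = centre[1L] + ring * sin(az),
        col = centre[2L] + ring * cos(az),
        radius = scene@glareSpotRadiusPx * sqrt(effect@magnitude),
        ring = ring, az = az))
    }
    for (i in seq_len(nrow(spots))) {
      px <- .paintDisc(px, rowGrid, colGrid, spots$row[i], spots$col[i],
                       spots$radius[i], scene@glareIntensity)
    }
  } else {
    if (!effect@kind %in% c("none", "dark_patch"))
      stop("glare-point effects are only valid in glare mode")
    px <- matrix(scene@backgroundIntensity, fs, fs)
    px[d <= R] <- scene@glareIntensity
    px[abs(d - R) <= 1] <- 160              # faint disc edge
    if (effect@kind == "dark_patch") {
      # opaque particle: dark patch inside the droplet disc
      pr <- centre[1L] - 0.3 * R
      pc <- centre[2L]
      pd <- sqrt((rowGrid - pr)^2 + (colGrid - pc)^2)
      px[pd <= effect@magnitude] <- 40
    }
  }
  if (scene@noiseSd > 0)
    px <- px + stats::rnorm(length(px), 0, scene@noiseSd)
  px <- round(pmin(pmax(px, 0), 255))
  DropletImage(px, mode = scene@mode, frameIndex = frameIndex)
}

#' Render a synthetic empty droplet
#'
#' Renders one empty-droplet frame under the configured illumination
#' regime. In glare mode the frame shows a dark background, a faint droplet
#' rim and one glare spot per LED on the ring given by the ray trace; in
#' diffuse mode a bright droplet disc with no spots. Rendering is a pure
#' function of the configurations and the seed.
#'
#' @param scene a \linkS4class{SceneConfig}.
#' @param optics an \linkS4class{OpticalConfig}.
#' @param seed seed for jitter and sensor noise; defaults to the scene
#'   seed. \code{NULL} draws from the current RNG state.
#' @param frameIndex frame index recorded on the frame.
#' @return A \linkS4class{DropletImage}.
#' @examples
#' img <- renderEmptyDroplet(sceneConfig("glare"), opticalConfig())
#' range(pixels(img))
#' @export
renderEmptyDroplet <- function(scene, optics, seed = scene@seed,
                               frameIndex = 0L) {
  .withSeed(seed,
            .renderFrame(scene, optics, particleEffect("none"), frameIndex))
}

#' Render a synthetic droplet containing a particle
#'
#' As [renderEmptyDroplet()], with the particle's image-level effect
#' applied: a glare spot grown, shrunk, added or removed (glare mode), or a
#' dark patch painted inside the disc (diffuse mode, opaque particle). The
#' \code{"none"} effect models a transparent particle under diffuse
#' illumination and renders identically to the empty droplet for the same
#' seed.
#'
#' @inheritParams renderEmptyDroplet
#' @param effect a \linkS4class{ParticleEffect} valid for the scene mode.
#' @return A \linkS4class{DropletImage}.
#' @export
renderParticleDroplet <- function(scene, optics, effect,
                                  seed = scene@seed, frameIndex = 0L) {
  stopifnot(is(effect, "ParticleEffect"))
  .withSeed(seed, .renderFrame(scene, optics, effect, frameIndex))
}

#' Generate a labelled synthetic image series
#'
#' Generates a seeded series of droplet frames in which the listed frames
#' contain a particle (with the given effect) and all others are empty,
#' mirroring the acquisition protocol: series of 200 frames with between 6
#' and 30 particle-bearing droplets, one droplet per frame. When
#' \code{particleFrames} is NULL, a particle count is drawn uniformly from
#' 6 to 30 and the frames placed at random.
#'
#' @param scene a \linkS4class{SceneConfig}.
#' @param optics an \linkS4class{OpticalConfig}.
#' @param nFrames number of frames (default 200).
#' @param particleFrames 0-based indices of particle-bearing frames, or
#'   NULL for the random preset.
#' @param effect the \linkS4class{ParticleEffect} applied to particle
#'   frames.
#' @param seed series seed; every random draw (frame selection, jitter,
#'   noise) derives from it.
#' @return A \linkS4class{LabelledSeries}.
#' @examples
#' s <- generateSeries(sceneConfig("glare", frameSize = 120L),
#'                     opticalConfig(dropletRadiusPx = 40),
#'                     nFrames = 5, particleFrames = c(1, 3),
#'                     effect = particleEffect("remove_spot"), seed = 7)
#' sum(truthLabels(s))
#' @export
generateSeries <- function(scene, optics, nFrames = 200L,
                           particleFrames = NULL,
                           effect = particleEffect("remove_spot"),
                           seed = scene@seed) {
  stopifnot(is(scene, "SceneConfig"), is(optics, "OpticalConfig"))
  nFrames <- as.integer(nFrames)
  .withSeed(seed, {
    if (is.null(particleFrames)) {
      nP <- sample(6:30, 1L)
      particleFrames <- sort(sample.int(nFrames, nP) - 1L)
    }
    particleFrames <- as.integer(particleFrames)
    if (anyDuplicated(particleFrames))
      stop("duplicate particle frame indices")
    if (length(particleFrames) &&
        (min(particleFrames) < 0L || max(particleFrames) >= nFrames))
      stop("particle frame indices must lie in [0, nFrames)")
    truth <- logical(nFrames)
    truth[particleFrames + 1L] <- TRUE
    frames <- vector("list", nFrames)
    none <- particleEffect("none")
    for (i in seq_len(nFrames)) {
      frames[[i]] <- .renderFrame(scene, optics,
                                  if (truth[i]) effect else none,
                                  frameIndex = i - 1L)
    }
    manifest <- data.frame(
      frame_index = seq_len(nFrames) - 1L,
      filename = sprintf("frame_%04d.png", seq_len(nFrames) - 1L),
      mode = scene@mode, truth_label = truth)
    new("LabelledSeries", frames = frames, truth = truth,
        manifest = manifest,
        scene = list(mode = scene@mode, frameSize = scene@frameSize,
                     glareSpotRadiusPx = scene@glareSpotRadiusPx,
                     glareIntensity = scene@glareIntensity,
                     backgroundIntensity = scene@backgroundIntensity,
                     noiseSd = scene@noiseSd, jitterSd = scene@jitterSd,
                     seed = seed),
        optics = list(nDroplet = optics@nDroplet,
                      nAmbient = optics@nAmbient,
                      wavelengthNm = optics@wavelengthNm,
                      incidenceDeg = optics@incidenceDeg,
                      nLeds = optics@nLeds,
                      dropletRadiusPx = optics@dropletRadiusPx,
                      effect = effect@kind,
                      effectMagnitude = effect@magnitude))
  })
}
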
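test_that("the traced internal angle obeys Snell's law", {
  # vector-geometry trace against the closed-form sine relation
  for (nD in c(1.30, 1.33, 1.3428, 1.45, 1.6)) {
    for (inc in c(10, 25, 40, 60, 80)) {
      cfg <- opticalConfig(nDroplet = nD, incidenceDeg = inc)
      tr <- traceGlarePoint(cfg)
      closed <- asin(sin(inc * pi / 180) / nD) * 180 / pi
      expect_lt(abs(tr$thetaInternalDeg - closed), 1e-12)
      expect_false(tr$totalInternalReflection)
      expect_false(is.na(tr$exitAngleDeg))
    }
  }
})

test_that("matched indices give no refraction; denser droplets bend more", {
  # nDroplet -> nAmbient: the internal angle approaches the incidence angle
  near <- opticalConfig(nDroplet = 1 + 1e-9, nAmbient = 1,
                        incidenceDeg = 40)
  expect_equal(traceGlarePoint(near)$thetaInternalDeg, 40,
               tolerance = 1e-5)

  # strictly decreasing internal angle with increasing droplet index
  angles <- vapply(c(1.2, 1.33, 1.45, 1.6, 1.8), function(nD) {
    traceGlarePoint(opticalConfig(nDroplet = nD,
                                  incidenceDeg = 40))$thetaInternalDeg
  }, numeric(1))
  expect_true(all(diff(angles) < 0))
})

test_that("dispersion orders the wavelengths violet < blue < red", {
  # n(405) > n(465) > n(635): violet light is refracted most strongly,
  # giving the smallest internal angle and a shifted glare point
  th <- vapply(c(405, 465, 635), function(wl) {
    traceGlarePoint(opticalConfig(wavelengthNm = wl))$thetaInternalDeg
  }, numeric(1))
  expect_lt(th[1], th[2])
  expect_lt(th[2], th[3])

  rings <- vapply(c(405, 635), function(wl) {
    traceGlarePoint(opticalConfig(wavelengthNm = wl))$ringFraction
  }, numeric(1))
  expect_false(isTRUE(all.equal(rings[1], rings[2])))  # shifted position

  expect_error(opticalConfig(wavelengthNm = 550), "dispersion")
})

test_that("rendered empties show one glare point per LED", {
  for (nL in c(4L, 6L)) {
    img <- renderEmptyDroplet(smallScene(), smallOptics(nLeds = nL),
                              seed = 9)
    gp <- extractGlarePoints(gaussianSmooth(otsuThreshold(img), 1))
    expect_identical(length(gp), nL)
  }
})

test_that("rendering is a pure function of configuration and seed", {
  scene <- smallScene(noiseSd = 5, jitterSd = 1)
  optics <- smallOptics()
  a <- renderEmptyDroplet(scene, optics, seed = 77)
  b <- renderEmptyDroplet(scene, optics, seed = 77)
  expect_identical(pixels(a), pixels(b))
  c <- renderEmptyDroplet(scene, optics, seed = 78)
  expect_false(identical(pixels(a), pixels(c)))
})

test_that("particle effects modify glare spots as specified", {
  scene <- smallScene()
  optics <- smallOptics()
  empty <- renderEmptyDroplet(scene, optics, seed = 12)
  baseGp <- glarePoints(extractGlarePoints(
    gaussianSmooth(otsuThreshold(empty), 1)))
  expect_identical(nrow(baseGp), 6L)

  # grow_spot 0.5: the affected spot's pixel count grows ~50%
  grown <- renderParticleDroplet(scene, optics,
                                 particleEffect("grow_spot", 0.5, 1L),
                                 seed = 12)
  gp <- glarePoints(extractGlarePoints(
    gaussianSmooth(otsuThreshold(grown), 1)))
  expect_identical(nrow(gp), 6L)
  ratio <- max(gp$area) / max(baseGp$area)
  expect_equal(ratio, 1.5, tolerance = 0.12)   # lattice discretization

  # remove_spot: one fewer component
  removed <- renderParticleDroplet(scene, optics,
                                   particleEffect("remove_spot"),
                                   seed = 12)
  expect_identical(length(extractGlarePoints(
    gaussianSmooth(otsuThreshold(removed), 1))), 5L)

  # add_spot: one more component
  added <- renderParticleDroplet(scene, optics,
                                 particleEffect("add_spot", 1),
                                 seed = 12)
  expect_identical(length(extractGlarePoints(
    gaussianSmooth(otsuThreshold(added), 1))), 7L)

  expect_error(renderParticleDroplet(scene, optics,
    particleEffect("remove_spot", targetSpot = 9L), seed = 12),
    "exceeds")
})

test_that("transparent particles are invisible; opaque ones leave a patch", {
  scene <- smallScene("diffuse")
  optics <- smallOptics()
  empty <- renderEmptyDroplet(scene, optics, seed = 13)
  none <- renderParticleDroplet(scene, optics, particleEffect("none"),
                                seed = 13)
  expect_identical(pixels(none), pixels(empty))

  patch <- renderParticleDroplet(scene, optics,
                                 particleEffect("dark_patch", 8),
                                 seed = 13)
  wpcEmpty <- wpcScore(hardThreshold(empty, 128, "dark_foreground"))@wpc
  wpcPatch <- wpcScore(hardThreshold(patch, 128, "dark_foreground"))@wpc
  expect_identical(wpcEmpty, 0)
  expect_gt(wpcPatch, 0)

  expect_error(renderParticleDroplet(smallScene("glare"), optics,
    particleEffect("dark_patch", 8), seed = 1), "diffuse")
  expect_error(renderParticleDroplet(scene, optics,
    particleEffect("remove_spot"), seed = 1), "glare mode")
})

test_that("a glare spot placed outside the droplet disc is rejected", {
  tight <- opticalConfig(dropletRadiusPx = 6)
  scene <- sceneConfig("glare", frameSize = 40L, glareSpotRadiusPx = 4,
                       noiseSd = 0, jitterSd = 0)
  expect_error(renderEmptyDroplet(scene, tight, seed = 1),
               "outside the droplet")
})

test_that("generated series carry correct truth labels deterministically", {
  scene <- smallScene(noiseSd = 3, jitterSd = 1)
  optics <- smallOptics()
  s <- generateSeries(scene, optics, nFrames = 20,
                      particleFrames = c(2, 5, 11),
                      effect = particleEffect("remove_spot"), seed = 99)
  expect_identical(length(s), 20L)
  expect_identical(sum(truthLabels(s)), 3L)
  expect_true(all(which(truthLabels(s)) == c(3, 6, 12)))
  expect_identical(s@manifest$truth_label, truthLabels(s))

  s2 <- generateSeries(scene, optics, nFrames = 20,
                       particleFrames = c(2, 5, 11),
                       effect = particleEffect("remove_spot"), seed = 99)
  for (i in seq_len(20))
    expect_identical(pixels(seriesFrames(s)[[i]]),
                     pixels(seriesFrames(s2)[[i]]))

  expect_error(generateSeries(scene, optics, nFrames = 10,
                              particleFrames = c(1, 1), seed = 1),
               "duplicate")
  expect_error(generateSeries(scene, optics, nFrames = 10,
                              particleFrames = 10, seed = 1),
               "\\[0, nFrames\\)")

  # random preset draws 6-30 particle frames
  preset <- generateSeries(scene, optics, nFrames = 50,
                           particleFrames = NULL, seed = 5)
  expect_gte(sum(truthLabels(preset)), 6L)
  expect_lte(sum(truthLabels(preset)), 30L)
})
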
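test_that("run accuracy is the exact detected/actual percentage", {
  expect_identical(accuracy(6, 6), 100)
  expect_identical(accuracy(93, 100), 93)
  expect_identical(accuracy(0, 10), 0)
  expect_identical(accuracy(12, 10), 120)   # FPs can exceed 100%, reported
  expect_true(is.na(accuracy(3, 0)))        # not-applicable run
})

.glareFixture <- function(noiseSd = 3, jitterSd = 1) {
  scene <- smallScene(noiseSd = noiseSd, jitterSd = jitterSd)
  optics <- smallOptics()
  empties <- emptyFrames(30L, scene, optics, seedBase = 5000L)
  profile <- calibrateProfile(empties, sidedness = "two_sided")
  list(scene = scene, optics = optics, profile = profile)
}

test_that("an all-empty series yields zero detections for every detector", {
  fx <- .glareFixture()
  s <- generateSeries(fx$scene, fx$optics, nFrames = 15,
                      particleFrames = integer(), seed = 71)
  rep <- runBatch(s, fx$profile, referenceCount = 1L)
  expect_true(all(rep@perDetector$detectedCount == 0))
  expect_true(all(rep@perDetector$falsePositives == 0))
})

test_that("remove_spot particles are fully recovered at low noise", {
  fx <- .glareFixture(noiseSd = 0, jitterSd = 0)
  s <- generateSeries(fx$scene, fx$optics, nFrames = 25,
                      particleFrames = c(1, 7, 13, 19, 23),
                      effect = particleEffect("remove_spot"), seed = 72)
  rep <- runBatch(s, fx$profile)
  expect_identical(rep@actualCount, 5L)
  cc <- rep@perDetector[rep@perDetector$detector == "cc", ]
  dis <- rep@perDetector[rep@perDetector$detector == "dis", ]
  expect_identical(cc$detectedCount, 5L)
  expect_identical(cc$accuracyPercent, 100)
  expect_identical(dis$accuracyPercent, 100)
  # bookkeeping: detections = TP + FP, per record flags
  for (d in c("wpc", "cc", "dis")) {
    r <- rep@perDetector[rep@perDetector$detector == d, ]
    expect_identical(r$detectedCount, r$truePositives + r$falsePositives)
    expect_identical(r$detectedCount,
                     sum(rep@records$detected[rep@records$detector == d]))
  }
})

test_that("runBatch is deterministic and validates its configuration", {
  fx <- .glareFixture()
  s <- generateSeries(fx$scene, fx$optics, nFrames = 10,
                      particleFrames = c(2, 6), seed = 73)
  r1 <- runBatch(s, fx$profile)
  r2 <- runBatch(s, fx$profile)
  expect_identical(r1@records, r2@records)
  expect_identical(r1@perDetector, r2@perDetector)

  dif <- generateSeries(smallScene("diffuse"), fx$optics, nFrames = 3,
                        particleFrames = integer(), seed = 74)
  expect_error(runBatch(dif, fx$profile), "mode")

  wpcOnly <- new("CalibrationProfile", mode = "glare",
                 wpc = fx$profile@wpc, cc = NULL, dis = NULL,
                 maxShift = 10L)
  expect_error(runBatch(s, wpcOnly, detectors = c("wpc", "cc")),
               "not calibrated")
})

test_that("series round-trip through PNG + manifest preserves detection", {
  fx <- .glareFixture()
  s <- generateSeries(fx$scene, fx$optics, nFrames = 8,
                      particleFrames = c(1, 5),
                      effect = particleEffect("remove_spot"), seed = 75)
  dir <- file.path(tempdir(), "gd-series-roundtrip")
  writeSeries(s, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "config.json")))
  back <- readSeries(dir)
  expect_identical(length(back), 8L)
  expect_identical(truthLabels(back), truthLabels(s))
  for (i in seq_len(8))
    expect_equal(pixels(seriesFrames(back)[[i]]),
                 pixels(seriesFrames(s)[[i]]))
  r1 <- runBatch(s, fx$profile)
  r2 <- runBatch(back, fx$profile)
  expect_identical(r1@perDetector, r2@perDetector)
  unlink(dir, recursive = TRUE)
})

test_that("calibration profiles survive the JSON round-trip", {
  fx <- .glareFixture()
  path <- file.path(tempdir(), "gd-cal.json")
  writeCalibration(fx$profile, path)
  back <- readCalibration(path)
  expect_equal(back@wpc@baseline, fx$profile@wpc@baseline)
  expect_identical(back@wpc@sidedness, fx$profile@wpc@sidedness)
  expect_equal(back@cc@points$area, fx$profile@cc@points$area)
  expect_identical(back@dis$reference@mask, fx$profile@dis$reference@mask)
  expect_equal(back@dis$cutoffs@udMax, fx$profile@dis$cutoffs@udMax)

  s <- generateSeries(fx$scene, fx$optics, nFrames = 6,
                      particleFrames = c(2), seed = 76)
  expect_identical(runBatch(s, back)@perDetector,
                   runBatch(s, fx$profile)@perDetector)
  unlink(c(path, sub("\\.json$", "_reference.png", path)))
})

test_that("the CLI simulates, calibrates and evaluates a series", {
  base <- file.path(tempdir(), "gd-cli")
  unlink(base, recursive = TRUE)
  dir.create(base)
  sdir <- file.path(base, "series")
  edir <- file.path(base, "empty")
  cal <- file.path(base, "cal.json")
  repj <- file.path(base, "report.json")

  expect_identical(gpdCli(c("simulate", "--mode", "glare", "--n-frames",
    "40", "--particles", "0", "--noise-sd", "3", "--seed", "7", "--out",
    edir)), 0L)
  expect_identical(gpdCli(c("simulate", "--mode", "glare", "--n-frames",
    "12", "--particles", "3", "--effect", "remove_spot", "--noise-sd",
    "3", "--seed", "8", "--out", sdir)), 0L)
  expect_length(list.files(sdir, pattern = "\\.png$"), 12L)

  expect_identical(gpdCli(c("calibrate", "--series", edir, "--sidedness",
    "two_sided", "--out", cal)), 0L)
  expect_true(file.exists(cal))

  expect_identical(suppressMessages(gpdCli(c("evaluate", "--series", sdir,
    "--calibration", cal, "--out", repj))), 0L)
  rep <- jsonlite::read_json(repj, simplifyVector = TRUE)
  expect_identical(rep$nFrames, 12L)
  expect_identical(sort(rep$perDetector$detector), c("cc", "dis", "wpc"))

  # usage errors exit 2, runtime errors exit 1
  expect_identical(gpdCli(character()), 2L)
  expect_identical(gpdCli(c("simulate", "--mode")), 2L)
  expect_identical(suppressMessages(gpdCli(c("detect", "--series",
    file.path(base, "nope"), "--calibration", cal))), 1L)
  unlink(base, recursive = TRUE)
})
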
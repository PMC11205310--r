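test_that("PNG and TIFF frames load, rescale to 0-255, and round-trip", {
  px <- matrix(c(0, 64, 128, 255), 2, 2)
  f <- tempfile(fileext = ".png")
  saveDropletImage(DropletImage(px), f)
  back <- loadDropletImage(f)
  expect_equal(pixels(back), px)

  # constant all-zero image
  f0 <- tempfile(fileext = ".png")
  png::writePNG(matrix(0, 4, 4), f0)
  z <- loadDropletImage(f0)
  expect_identical(range(pixels(z)), c(0, 0))

  # 16-bit TIFF endpoints map to intensity endpoints
  f16 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(c(0, 1, 1, 0), 2, 2), f16, bits.per.sample = 16L)
  t16 <- loadDropletImage(f16)
  expect_setequal(unique(as.vector(pixels(t16))), c(0, 255))

  expect_error(loadDropletImage(tempfile(fileext = ".png")), "not found")
  fbad <- tempfile(fileext = ".xyz")
  writeLines("not an image", fbad)
  expect_error(loadDropletImage(fbad), "format")
})

test_that("Otsu threshold matches exhaustive between-class-variance search", {
  # bimodal image: threshold separates the halves exactly
  px <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  bin <- otsuThreshold(DropletImage(px))
  expect_gt(maskThreshold(bin), 9)
  expect_lt(maskThreshold(bin), 200)
  expect_identical(sum(mask(bin)), 50L)
  expect_identical(maskThreshold(bin), as.numeric(bruteOtsu(px)))

  # random images agree with the naive oracle, including the low tie-break
  set.seed(11)
  for (i in 1:25) {
    px <- random8bit(16L)
    expect_identical(maskThreshold(otsuThreshold(DropletImage(px))),
                     as.numeric(bruteOtsu(px)))
  }

  # two blobs on zero background: foreground count is the summed blob area
  px <- matrix(0, 30, 30)
  px[3:7, 3:7] <- 210
  px[20:23, 12:17] <- 190
  bin <- otsuThreshold(DropletImage(px))
  expect_identical(sum(mask(bin)), 25L + 24L)

  # constant image: defined fallback
  bin <- otsuThreshold(DropletImage(matrix(42, 5, 5)))
  expect_false(any(mask(bin)))
  expect_identical(maskThreshold(bin), 42)
})

test_that("hard thresholding honours cutoff and polarity", {
  px <- matrix(220, 10, 10)
  px[4:6, 4:6] <- 30
  img <- DropletImage(px, mode = "diffuse")
  expect_true(all(mask(hardThreshold(img, 0))))  # all pixels >= 30 > 0
  expect_false(any(mask(hardThreshold(img, 255))))
  dark <- hardThreshold(img, 128, "dark_foreground")
  expect_identical(sum(mask(dark)), 9L)
  expect_true(all(which(mask(dark), arr.ind = TRUE)[, 1] %in% 4:6))
  expect_error(hardThreshold(img, 300), "cutoff")
})

test_that("Gaussian smoothing is identity at sigma 0 and on constants", {
  px <- matrix(sample(0:255, 144, replace = TRUE), 12, 12)
  img <- DropletImage(px)
  expect_identical(pixels(gaussianSmooth(img, 0)), px)
  flat <- DropletImage(matrix(77, 15, 15))
  expect_equal(pixels(gaussianSmooth(flat, 2)), pixels(flat))
  expect_error(gaussianSmooth(img, -1), "sigma")
})

test_that("Gaussian smoothing spreads a point source and stays in range", {
  px <- matrix(0, 15, 15)
  px[8, 8] <- 255
  sm <- pixels(gaussianSmooth(DropletImage(px), 1))
  expect_gt(sm[8, 8], sm[7, 8])
  expect_gt(sm[8, 8], sm[8, 7])
  expect_gt(sm[8, 8], sm[7, 7])
  expect_true(all(sm >= 0 & sm <= 255))

  # mask smoothing removes isolated speckle but keeps blobs
  m <- matrix(FALSE, 20, 20)
  m[3, 17] <- TRUE                 # single speckle pixel
  m[10:14, 5:9] <- TRUE            # 5x5 blob
  sm <- mask(gaussianSmooth(BinaryImage(m, 0), 1))
  expect_false(sm[3, 17])
  expect_true(sm[12, 7])
})

test_that("locateAndCrop centres the droplet and is idempotent", {
  px <- matrix(5, 1024, 1280)
  px[491:510, 691:710] <- 240      # blob centred at (500.5, 700.5)
  crop <- locateAndCrop(DropletImage(px), size = 200)
  expect_identical(dim(pixels(crop)), c(200L, 200L))
  ctr <- which(pixels(crop) > 100, arr.ind = TRUE)
  expect_lt(abs(mean(ctr[, 1]) - 100.5), 2)
  expect_lt(abs(mean(ctr[, 2]) - 100.5), 2)

  again <- locateAndCrop(crop, size = 200)
  expect_identical(pixels(again), pixels(crop))

  expect_error(locateAndCrop(DropletImage(matrix(7, 300, 300)), 200),
               "localization")
})

test_that("crops overrunning the frame edge are padded with background", {
  px <- matrix(12, 300, 300)
  px[5:14, 5:14] <- 250            # droplet near the corner
  crop <- locateAndCrop(DropletImage(px), size = 100)
  expect_identical(dim(pixels(crop)), c(100L, 100L))
  expect_true(all(pixels(crop)[1:10, 1:10] == 12))  # padded corner
  expect_identical(sum(pixels(crop) == 250), 100L)
})

test_that("alignment recovers planted shifts exactly on clean masks", {
  set.seed(21)
  ref <- randomMask(40L, density = 0.25)
  refBin <- BinaryImage(ref, 0)

  al <- alignToReference(refBin, refBin, maxShift = 6)
  expect_identical(al$shift, c(dy = 0L, dx = 0L))
  expect_false(al$onBoundary)

  # spec contract: frame = reference translated by (+3, -2)
  img <- BinaryImage(bruteShift(ref, 3L, -2L), 0)
  al <- alignToReference(img, refBin, maxShift = 10)
  expect_identical(al$shift, c(dy = -3L, dx = 2L))
  # region that survives both translations matches the reference exactly
  expect_identical(mask(al$aligned)[1:37, 3:40], ref[1:37, 3:40])

  # property: any |shift| <= maxShift is recovered, matching brute force
  for (i in 1:20) {
    dy <- sample(-5:5, 1L)
    dx <- sample(-5:5, 1L)
    img <- BinaryImage(bruteShift(ref, dy, dx), 0)
    al <- alignToReference(img, refBin, maxShift = 5)
    expect_identical(unname(al$shift), c(-dy, -dx))
    bb <- bruteBestShift(ref, mask(img), 5L)
    expect_identical(unname(al$shift), c(bb$dy, bb$dx))
  }
})

test_that("out-of-window shifts land on the boundary and are flagged", {
  set.seed(22)
  ref <- matrix(FALSE, 40, 40)
  ref[15:25, 15:25] <- TRUE
  img <- BinaryImage(bruteShift(ref, 12L, 0L), 0)
  al <- alignToReference(img, BinaryImage(ref, 0), maxShift = 5)
  expect_true(al$onBoundary)
  expect_identical(unname(al$shift[1]), -5L)

  expect_error(
    alignToReference(BinaryImage(ref, 0),
                     BinaryImage(matrix(FALSE, 40, 40), 0), 5),
    "reference mask is empty")
})

test_that("imaging operations do not modify their inputs", {
  set.seed(31)
  px <- random8bit(20L)
  img <- DropletImage(px)
  invisible(otsuThreshold(img))
  invisible(gaussianSmooth(img, 1.5))
  invisible(hardThreshold(img, 100))
  expect_identical(pixels(img), px)
})
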
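#' Read a droplet frame from disk
#'
#' Reads an 8-bit (or deeper) grayscale PNG or TIFF frame and rescales it to
#' the 0--255 intensity range. Multi-channel rasters are collapsed to
#' grayscale by channel averaging.
#'
#' @param path path to a PNG or TIFF file.
#' @param mode illumination regime to record, \code{"glare"} or
#'   \code{"diffuse"}.
#' @param frameIndex frame index to record (0-based).
#' @return A \linkS4class{DropletImage}.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(64), 8, 8), f)
#' loadDropletImage(f)
#' @export
loadDropletImage <- function(path, mode = c("glare", "diffuse"),
                             frameIndex = 0L) {
  mode <- match.arg(mode)
  if (!file.exists(path))
    stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (use PNG or TIFF)"))
  if (is.list(raw)) raw <- raw[[1]]
  if (length(dim(raw)) == 3L) raw <- apply(raw, c(1L, 2L), mean)
  if (!is.matrix(raw) || nrow(raw) < 1L || ncol(raw) < 1L)
    stop("zero-sized or malformed image: ", path)
  # readPNG/readTIFF normalize to [0, 1] regardless of source bit depth
  DropletImage(raw * 255, mode = mode, frameIndex = frameIndex)
}

#' Write a droplet frame to disk
#'
#' @param image a \linkS4class{DropletImage}.
#' @param path destination path ending in .png, .tif or .tiff.
#' @return \code{path}, invisibly.
#' @export
saveDropletImage <- function(image, path) {
  stopifnot(is(image, "DropletImage"))
  ext <- tolower(tools::file_ext(path))
  norm <- pixels(image) / 255
  switch(ext,
    png = png::writePNG(norm, path),
    tif = ,
    tiff = tiff::writeTIFF(norm, path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "'"))
  invisible(path)
}

#' Otsu binarization
#'
#' Global thresholding by Otsu's method: the threshold maximizing the
#' between-class intensity variance over the 256-bin histogram of the
#' (rounded) 8-bit intensities. Among tied maximizers the lowest threshold
#' is chosen, so the output is deterministic. The foreground mask keeps
#' pixels strictly above the threshold (bright foreground).
#'
#' A constant image has no between-class variance to maximize; it yields an
#' all-background mask with the constant recorded as the threshold.
#'
#' @param image a \linkS4class{DropletImage}.
#' @return A \linkS4class{BinaryImage} with \code{bright_foreground}
#'   polarity.
#' @examples
#' px <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
#' bin <- otsuThreshold(DropletImage(px))
#' maskThreshold(bin)
#' sum(mask(bin))
#' @export
otsuThreshold <- function(image) {
  stopifnot(is(image, "DropletImage"))
  px <- pixels(image)
  v <- pmin(pmax(round(px), 0), 255)
  if (min(v) == max(v))
    return(BinaryImage(matrix(FALSE, nrow(px), ncol(px)),
                       threshold = min(v)))
  h <- tabulate(as.integer(v) + 1L, nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  cw <- cumsum(h)                 # pixels with intensity <= t
  cm <- cumsum(lev * h)
  total <- cm[256L]
  t <- 0:254
  w0 <- cw[t + 1L]
  w1 <- n - w0
  m0 <- cm[t + 1L] / w0
  m1 <- (total - cm[t + 1L]) / w1
  varB <- w0 * w1 * (m0 - m1)^2
  varB[w0 == 0 | w1 == 0] <- 0
  thr <- t[which.max(varB)]       # which.max returns the first (lowest) tie
  BinaryImage(px > thr, threshold = thr)
}

#' Hard (fixed) thresholding
#'
#' Binarizes at a fixed intensity cut-off. With bright polarity the mask
#' keeps pixels strictly above the cut-off; with dark polarity strictly
#' below it. The dark polarity extracts opaque particles, which appear as
#' dark patches on the bright droplet disc under diffuse illumination.
#'
#' @param image a \linkS4class{DropletImage}.
#' @param cutoff intensity cut-off in \code{[0, 255]}.
#' @param polarity \code{"bright_foreground"} or \code{"dark_foreground"}.
#' @return A \linkS4class{BinaryImage}.
#' @export
hardThreshold <- function(image, cutoff,
                          polarity = c("bright_foreground",
                                       "dark_foreground")) {
  stopifnot(is(image, "DropletImage"))
  polarity <- match.arg(polarity)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 ||
      cutoff > 255)
    stop("'cutoff' must be a single intensity in [0, 255]")
  px <- pixels(image)
  m <- if (polarity == "bright_foreground") px > cutoff else px < cutoff
  BinaryImage(m, threshold = cutoff, polarity = polarity)
}

#' Gaussian smoothing
#'
#' Gaussian low-pass filtering. On a \linkS4class{DropletImage} the
#' grayscale intensities are smoothed and clamped back into the input's
#' intensity range. On a \linkS4class{BinaryImage} the 0/1 mask is smoothed
#' and re-thresholded at 0.5, which removes single stray foreground or
#' background pixels while preserving blob geometry -- the de-speckling step
#' of the contour-count pipeline.
#'
#' @param x a \linkS4class{DropletImage} or \linkS4class{BinaryImage}.
#' @param sigma Gaussian standard deviation in pixels; 0 returns the input
#'   unchanged.
#' @return An object of the same class as \code{x}.
#' @export
setGeneric("gaussianSmooth", function(x, sigma = 1) {
  standardGeneric("gaussianSmooth")
})

.checkSigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("'sigma' must be a single non-negative number")
}

#' @rdname gaussianSmooth
#' @export
setMethod("gaussianSmooth", "DropletImage", function(x, sigma = 1) {
  .checkSigma(sigma)
  if (sigma == 0) return(x)
  px <- pixels(x)
  sm <- EBImage::gblur(px / 255, sigma = sigma) * 255
  sm <- pmin(pmax(sm, min(px)), max(px))
  initialize(x, pixels = sm)
})

#' @rdname gaussianSmooth
#' @export
setMethod("gaussianSmooth", "BinaryImage", function(x, sigma = 1) {
  .checkSigma(sigma)
  if (sigma == 0) return(x)
  sm <- EBImage::gblur(mask(x) * 1, sigma = sigma)
  initialize(x, mask = sm > 0.5)
})

.modalIntensity <- function(px) {
  v <- as.integer(pmin(pmax(round(px), 0), 255))
  which.max(tabulate(v + 1L, nbins = 256L)) - 1L
}

#' Locate the droplet and crop a fixed-size window around it
#'
#' Localizes the droplet as the centroid of the foreground of a coarse Otsu
#' pass (glare points in glare mode, the bright droplet disc in diffuse
#' mode) and returns a square window of side \code{size} centred on it. A
#' window overrunning the frame edge is padded with the modal background
#' intensity, so no spurious edges are introduced.
#'
#' @param image a \linkS4class{DropletImage}; typically a full sensor frame.
#' @param size crop side length in pixels (default 200).
#' @param minForeground minimum number of foreground pixels required to
#'   accept the localization (default 20).
#' @return A \code{size} x \code{size} \linkS4class{DropletImage}.
#' @examples
#' px <- matrix(5, 300, 300)
#' px[140:160, 190:210] <- 240
#' crop <- locateAndCrop(DropletImage(px), size = 100)
#' dim(pixels(crop))
#' @export
locateAndCrop <- function(image, size = 200L, minForeground = 20L) {
  stopifnot(is(image, "DropletImage"))
  px <- pixels(image)
  size <- as.integer(size)
  if (size < 1L || size > min(dim(px)))
    stop("'size' must be between 1 and the smallest image dimension")
  fg <- mask(otsuThreshold(image))
  if (sum(fg) < minForeground)
    stop("droplet localization failed: fewer than ", minForeground,
         " foreground pixels")
  idx <- which(fg, arr.ind = TRUE)
  cr <- mean(idx[, 1L])
  cc <- mean(idx[, 2L])
  half <- size %/% 2L
  r0 <- as.integer(floor(cr + 0.5)) - half     # window rows r0+1 .. r0+size
  c0 <- as.integer(floor(cc + 0.5)) - half
  pad <- .modalIntensity(px)
  out <- matrix(as.numeric(pad), size, size)
  rs <- (r0 + 1L):(r0 + size)
  cs <- (c0 + 1L):(c0 + size)
  vr <- which(rs >= 1L & rs <= nrow(px))
  vc <- which(cs >= 1L & cs <= ncol(px))
  out[vr, vc] <- px[rs[vr], cs[vc]]
  initialize(image, pixels = out)
}

.shiftMask <- function(m, dy, dx, fill = FALSE) {
  out <- matrix(fill, nrow(m), ncol(m))
  src_r <- seq_len(nrow(m)) - dy
  src_c <- seq_len(ncol(m)) - dx
  vr <- which(src_r >= 1L & src_r <= nrow(m))
  vc <- which(src_c >= 1L & src_c <= ncol(m))
  if (length(vr) && length(vc))
    out[vr, vc] <- m[src_r[vr], src_c[vc]]
  out
}

#' Translational alignment against a reference mask
#'
#' Template matching by two-dimensional cross-correlation: finds the integer
#' translation within \code{[-maxShift, maxShift]^2} that maximizes the
#' overlap between the binarized frame and the reference mask, and returns
#' the shifted frame. This compensates the frame-to-frame droplet position
#' jitter caused by trigger-timing variability. The correlation surface is
#' computed by FFT; ties are broken by the smallest \code{|dy| + |dx|},
#' then by row-major order of \code{(dy, dx)}.
#'
#' A best shift lying on the search boundary is flagged
#' (\code{onBoundary = TRUE}): the true displacement may exceed the window.
#'
#' @param binary a \linkS4class{BinaryImage} of the frame.
#' @param reference a \linkS4class{BinaryImage} or
#'   \linkS4class{ReferenceImage} of identical shape.
#' @param maxShift maximum shift searched, pixels (default 10).
#' @return A list with elements \code{shift} (named integer vector
#'   \code{dy}, \code{dx} to apply to the frame), \code{aligned} (the
#'   shifted \linkS4class{BinaryImage}), \code{score} (overlap pixel count)
#'   and \code{onBoundary}.
#' @export
alignToReference <- function(binary, reference, maxShift = 10L) {
  stopifnot(is(binary, "BinaryImage"))
  ref <- if (is(reference, "ReferenceImage")) mask(reference)
         else mask(reference)
  img <- mask(binary)
  if (!all(dim(ref) == dim(img)))
    stop("frame and reference must have identical shape")
  if (!any(ref))
    stop("calibration error: reference mask is empty")
  M <- as.integer(maxShift)
  if (M < 0L) stop("'maxShift' must be >= 0")
  if (M == 0L) {
    return(list(shift = c(dy = 0L, dx = 0L), aligned = binary,
                score = sum(ref & img), onBoundary = FALSE))
  }
  P1 <- nrow(ref) + M
  P2 <- ncol(ref) + M
  A <- matrix(0, P1, P2); A[seq_len(nrow(ref)), seq_len(ncol(ref))] <- ref
  B <- matrix(0, P1, P2); B[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  # C[dy, dx] = sum over pixels of ref * (img shifted by (dy, dx))
  C <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(B)),
                     inverse = TRUE)) / (P1 * P2)
  g <- expand.grid(dy = -M:M, dx = -M:M)
  sc <- round(C[cbind((g$dy %% P1) + 1L, (g$dx %% P2) + 1L)])
  best <- order(-sc, abs(g$dy) + abs(g$dx), g$dy, g$dx)[1L]
  dy <- g$dy[best]; dx <- g$dx[best]
  aligned <- initialize(binary, mask = .shiftMask(img, dy, dx))
  list(shift = c(dy = dy, dx = dx), aligned = aligned,
       score = as.integer(sc[best]),
       onBoundary = abs(dy) == M || abs(dx) == M)
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so
# labels touching only diagonally are merged with a small union-find pass.
.label8 <- function(m) {
  lab <- EBImage::imageData(EBImage::bwlabel(m * 1))
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  k <- max(lab)
  if (k <= 1L) return(lab)
  n <- nrow(lab); p <- ncol(lab)
  pairs <- NULL
  r1 <- seq_len(n - 1L); c1 <- seq_len(p - 1L)
  # down-right diagonal neighbours
  a <- lab[r1, c1]; b <- lab[r1 + 1L, c1 + 1L]
  sel <- a > 0L & b > 0L & a != b
  if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  # down-left diagonal neighbours
  a <- lab[r1, c1 + 1L]; b <- lab[r1 + 1L, c1]
  sel <- a > 0L & b > 0L & a != b
  if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  if (is.null(pairs)) return(lab)
  parent <- seq_len(k)
  findRoot <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- findRoot(pairs[i, 1L])
    rb <- findRoot(pairs[i, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(k), findRoot, integer(1L))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}
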
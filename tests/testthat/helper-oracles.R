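# Independent brute-force oracles used to verify the optimized
# implementations, plus small fixture builders.

# Otsu by naive exhaustive search: for every candidate threshold compute
# the two class means directly and keep the lowest maximizer.
bruteOtsu <- function(px) {
  v <- as.vector(pmin(pmax(round(px), 0), 255))
  if (min(v) == max(v)) return(min(v))
  bestT <- NA_integer_
  bestVar <- -1
  for (t in 0:254) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    w1 <- length(hi) / length(v)
    varB <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (varB > bestVar + 1e-9) {
      bestVar <- varB
      bestT <- t
    }
  }
  bestT
}

# 8-connected components by explicit stack-based flood fill.
bruteComponents8 <- function(m, minArea = 1L) {
  n <- nrow(m); p <- ncol(m)
  seen <- matrix(FALSE, n, p)
  areas <- integer()
  for (r in seq_len(n)) for (c in seq_len(p)) {
    if (!m[r, c] || seen[r, c]) next
    stack <- list(c(r, c))
    seen[r, c] <- TRUE
    area <- 0L
    while (length(stack)) {
      q <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      area <- area + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- q[1L] + dr; cc <- q[2L] + dc
        if (rr >= 1L && rr <= n && cc >= 1L && cc <= p &&
            m[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
    areas <- c(areas, area)
  }
  areas[areas >= minArea]
}

# translate a logical matrix, filling with FALSE (independent of the
# package's internal helper)
bruteShift <- function(m, dy, dx) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(FALSE, n, p)
  for (r in seq_len(n)) for (c in seq_len(p)) {
    sr <- r - dy; sc <- c - dx
    if (sr >= 1L && sr <= n && sc >= 1L && sc <= p) out[r, c] <- m[sr, sc]
  }
  out
}

# exhaustive best-shift search with the same tie-break contract
bruteBestShift <- function(ref, img, M) {
  best <- NULL
  for (dy in -M:M) for (dx in -M:M) {
    sc <- sum(ref & bruteShift(img, dy, dx))
    cand <- list(dy = dy, dx = dx, score = sc)
    if (is.null(best) || sc > best$score ||
        (sc == best$score &&
         (abs(dy) + abs(dx) < abs(best$dy) + abs(best$dx)))) {
      best <- cand
    }
  }
  best
}

randomMask <- function(n = 32L, p = n, density = 0.3) {
  matrix(stats::runif(n * p) < density, n, p)
}

random8bit <- function(n = 24L, p = n) {
  matrix(sample(0:255, n * p, replace = TRUE), n, p)
}

# small, fast scene/optics used by most synthetic tests
smallScene <- function(mode = "glare", noiseSd = 0, jitterSd = 0,
                       seed = 1L) {
  sceneConfig(mode, frameSize = 120L, noiseSd = noiseSd,
              jitterSd = jitterSd, seed = seed)
}

smallOptics <- function(nLeds = 6L) {
  opticalConfig(nLeds = nLeds, dropletRadiusPx = 40)
}

# empty-droplet calibration frames
emptyFrames <- function(n, scene, optics, seedBase = 1000L) {
  lapply(seq_len(n), function(i) {
    renderEmptyDroplet(scene, optics, seed = seedBase + i,
                       frameIndex = i - 1L)
  })
}
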
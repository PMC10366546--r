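## Frame averaging and per-pixel fluctuation maps (assembly stability).

#' Per-pixel mean and SD maps over a frame range
#'
#' Averages a drift-free movie segment pixel by pixel and computes the
#' population standard deviation of each pixel's height trajectory. Stable
#' regions show near-zero SD; regions where stripes associate and
#' dissociate (typically near the membrane edge) light up.
#'
#' @param stack a [TopographStack-class].
#' @param frameRange integer(2) first/last frame (1-based, inclusive);
#'   default all frames. At least 2 frames are required.
#' @return A [StabilityMaps-class].
#' @export
stabilityMaps <- function(stack, frameRange = NULL) {
  stopifnot(is(stack, "TopographStack"))
  if (is.null(frameRange)) frameRange <- c(1L, nFrames(stack))
  frameRange <- as.integer(frameRange)
  idx <- frameRange[1]:frameRange[2]
  if (length(idx) < 2) stop("need at least 2 frames for stability maps")
  fs <- stack@frames[idx]
  n <- length(fs)
  s1 <- Reduce(`+`, fs)
  s2 <- Reduce(`+`, lapply(fs, function(m) m * m))
  mu <- s1 / n
  va <- pmax(s2 / n - mu * mu, 0)   # population variance, clipped at 0
  ts <- stack@timestamps[idx]
  new("StabilityMaps",
      mean = Topograph(mu, stack@pixelSize),
      sd = Topograph(sqrt(va), stack@pixelSize),
      frameRange = frameRange,
      duration = max(ts) - min(ts))
}

#' Mean +/- SD height profile along a line, across frames
#'
#' Extracts the same line profile (see [extractProfile()]) from every frame
#' in the range and returns the per-position mean and population SD across
#' frames: the numerical equivalent of a mean line profile with an SD band.
#' Because profile extraction is linear in the image, the mean profile
#' equals the profile of the mean frame.
#'
#' @param stack a [TopographStack-class].
#' @param p0,p1 segment endpoints (x, y) in nm.
#' @param width parallel averaging width in pixels.
#' @param frameRange integer(2), default all frames.
#' @param reference height reference subtracted (nm).
#' @return data.frame with columns `position`, `mean`, `sd`.
#' @export
lineStability <- function(stack, p0, p1, width = 1L, frameRange = NULL,
                          reference = 0) {
  stopifnot(is(stack, "TopographStack"))
  if (is.null(frameRange)) frameRange <- c(1L, nFrames(stack))
  idx <- frameRange[1]:frameRange[2]
  profs <- lapply(idx, function(i)
    extractProfile(getFrame(stack, i), p0, p1, width,
                   reference = reference)$height)
  H <- do.call(cbind, profs)
  pos <- extractProfile(getFrame(stack, idx[1]), p0, p1, width,
                        reference = reference)$position
  mu <- rowMeans(H)
  sdv <- sqrt(pmax(rowMeans(H * H) - mu * mu, 0))
  data.frame(position = pos, mean = mu, sd = sdv)
}
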
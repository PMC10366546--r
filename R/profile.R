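## Height profiles, protrusion detection and notched-box statistics.

#' Extract a height profile along a line segment
#'
#' Bilinear sampling of the height map along the segment from `p0` to `p1`
#' at `step` intervals (default: one pixel), averaged over `width` parallel
#' profiles offset perpendicular to the segment at one-pixel spacing.
#' Heights are reported relative to `reference` (default mica = 0).
#' Bilinear interpolation is exact on affine height fields, so a ramp is
#' reproduced without error. The segment, including all offset lines, must
#' lie inside the image.
#'
#' @param topo a [Topograph-class].
#' @param p0,p1 numeric(2) segment endpoints (x, y) in nm.
#' @param width number of parallel profiles averaged (odd; 1 = none).
#' @param step sampling step in nm (default pixel size).
#' @param reference height subtracted from the profile, nm.
#' @return data.frame with columns `position` (nm along the segment,
#'   strictly increasing from 0) and `height` (nm); the averaging width is
#'   attached as attribute `"averagingWidth"`.
#' @export
extractProfile <- function(topo, p0, p1, width = 1L, step = NULL,
                           reference = 0) {
  stopifnot(is(topo, "Topograph"), length(p0) == 2L, length(p1) == 2L,
            width >= 1L)
  px <- topo@pixelSize
  if (is.null(step)) step <- px
  d <- p1 - p0
  L <- sqrt(sum(d^2))
  if (L <= 0) stop("p0 and p1 must differ")
  u <- d / L
  nrm <- c(-u[2], u[1])  # unit normal
  pos <- seq(0, L, by = step)
  offs <- (seq_len(width) - (width + 1) / 2) * px
  acc <- matrix(0, length(pos), length(offs))
  for (k in seq_along(offs)) {
    xs <- p0[1] + pos * u[1] + offs[k] * nrm[1]
    ys <- p0[2] + pos * u[2] + offs[k] * nrm[2]
    acc[, k] <- bilinearSample(topo@heights, px, xs, ys)
  }
  out <- data.frame(position = pos, height = rowMeans(acc) - reference)
  attr(out, "averagingWidth") <- as.integer(width)
  out
}

# Prominence of peaks on a run-compressed profile: peak value minus the
# higher of the valley floors towards the nearest at-least-as-high terrain
# (or the series end) on either side.
peakProminence <- function(v, peakIdx) {
  vapply(peakIdx, function(i) {
    vp <- v[i]
    lb <- if (i > 1) {
      left <- v[seq_len(i - 1)]
      hi <- which(left >= vp)
      if (length(hi) && max(hi) < length(left))
        min(left[(max(hi) + 1):length(left)])
      else if (length(hi)) vp else min(left)
    } else vp
    rb <- if (i < length(v)) {
      right <- v[(i + 1):length(v)]
      hi <- which(right >= vp)
      if (length(hi) && min(hi) > 1) min(right[seq_len(min(hi) - 1)])
      else if (length(hi)) vp else min(right)
    } else vp
    vp - max(lb, rb)
  }, numeric(1))
}

#' Detect protrusions along a profile and label them cyclically
#'
#' Local maxima with prominence at least `minProminence` and mutual spacing
#' at least `minSeparation`; when two candidates fall closer than the
#' minimum separation the higher one is kept. Surviving peaks are labelled
#' cyclically from the start of the profile as 1, 2, 3, 1*, 2*, 3*, ...
#' (stars count repeat units), reflecting the three-dimer decomposition of
#' the crystal repeat unit; `phase` rotates which peak is called "1".
#'
#' @param profile data.frame from [extractProfile()] (columns `position`,
#'   `height`).
#' @param minSeparation minimum peak spacing, nm (default 2, below the
#'   3.6 nm dimer pitch).
#' @param minProminence minimum prominence, nm (default 0.05, above the
#'   noise scale).
#' @param phase integer 0..2 rotating the cyclic labels.
#' @return data.frame with columns `position`, `height`, `label`, `base`
#'   (integer 1..3) and `unit` (repeat-unit counter); zero rows when the
#'   profile has no qualifying peak.
#' @export
detectProtrusions <- function(profile, minSeparation = 2,
                              minProminence = 0.05, phase = 0L) {
  stopifnot(all(c("position", "height") %in% names(profile)))
  h <- profile$height
  n <- length(h)
  if (n < 3)
    return(data.frame(position = numeric(), height = numeric(),
                      label = character(), base = integer(),
                      unit = integer(), stringsAsFactors = FALSE))
  # run-compress so that flat-topped (plateau) protrusions count once,
  # at their centre sample
  runs <- rle(h)
  m <- length(runs$values)
  runEnd <- cumsum(runs$lengths)
  runStart <- runEnd - runs$lengths + 1L
  cand <- integer()
  if (m >= 3) {
    v <- runs$values
    candRun <- which(v[2:(m - 1)] > v[1:(m - 2)] & v[2:(m - 1)] > v[3:m]) + 1L
    if (length(candRun)) {
      prom <- peakProminence(v, candRun)
      candRun <- candRun[prom >= minProminence]
    }
    cand <- runStart[candRun] + (runs$lengths[candRun] - 1L) %/% 2L
  }
  if (length(cand) > 1) {
    keepIdx <- integer()
    for (i in cand[order(-h[cand], profile$position[cand])]) {
      if (!length(keepIdx) ||
          all(abs(profile$position[keepIdx] - profile$position[i]) >=
              minSeparation))
        keepIdx <- c(keepIdx, i)
    }
    cand <- sort(keepIdx)
  }
  if (!length(cand))
    return(data.frame(position = numeric(), height = numeric(),
                      label = character(), base = integer(),
                      unit = integer(), stringsAsFactors = FALSE))
  k <- seq_along(cand) - 1L + as.integer(phase)
  base <- (k %% 3L) + 1L
  unit <- k %/% 3L
  data.frame(position = profile$position[cand], height = h[cand],
             label = paste0(base, strrep("*", unit)),
             base = base, unit = unit, stringsAsFactors = FALSE)
}

#' Paired height differences between subsequent protrusions
#'
#' Pools, across all supplied protrusion series, the paired differences
#' between subsequent protrusions along the stripe: h(1) - h(2) for
#' consecutive peaks labelled 1 and 2, h(2) - h(3), and h(3) - h(1*) (the
#' third protrusion against the first of the next repeat unit). Each
#' pairing is summarized by [notchedBox()]. Series with fewer than four
#' labelled peaks cannot contribute a full 3-1* pairing and are skipped
#' with a message.
#'
#' @param seriesList list of data.frames from [detectProtrusions()].
#' @return list with elements `"1-2"`, `"2-3"`, `"3-1*"` (each a
#'   [BoxStats-class], or NULL when a pairing has no data) and `values`
#'   (the pooled difference vectors).
#' @export
heightDifferenceStats <- function(seriesList) {
  if (is.data.frame(seriesList)) seriesList <- list(seriesList)
  d12 <- d23 <- d31 <- numeric()
  for (s in seriesList) {
    if (nrow(s) < 4) {
      message("skipping a protrusion series with fewer than 4 peaks")
      next
    }
    for (i in seq_len(nrow(s) - 1)) {
      b1 <- s$base[i]; b2 <- s$base[i + 1]
      dh <- s$height[i] - s$height[i + 1]
      if (b1 == 1L && b2 == 2L) d12 <- c(d12, dh)
      else if (b1 == 2L && b2 == 3L) d23 <- c(d23, dh)
      else if (b1 == 3L && b2 == 1L) d31 <- c(d31, dh)
    }
  }
  mk <- function(x) if (length(x)) notchedBox(x) else NULL
  list("1-2" = mk(d12), "2-3" = mk(d23), "3-1*" = mk(d31),
       values = list("1-2" = d12, "2-3" = d23, "3-1*" = d31))
}

#' Notched box-plot statistics
#'
#' Median, Tukey-hinge quartiles (the hinge convention of [stats::fivenum()],
#' fixed here because box-plot software conventions differ), extremes, and
#' the McGill notch half-width `1.57 * (Q3 - Q1) / sqrt(n)`, the standard
#' approximate 95% confidence interval for the median. The summary is
#' permutation-invariant and translation-equivariant: adding a constant
#' shifts median and hinges, the notch is unchanged.
#'
#' @param values numeric vector, n >= 1, finite.
#' @return A [BoxStats-class].
#' @examples
#' boxStats(notchedBox(c(1, 2, 3, 4, 5)))
#' @export
notchedBox <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("need at least one value")
  if (any(!is.finite(values))) stop("values must be finite")
  fn <- stats::fivenum(values)
  new("BoxStats", median = fn[3], q1 = fn[2], q3 = fn[4],
      notch = 1.57 * (fn[4] - fn[2]) / sqrt(length(values)),
      min = fn[1], max = fn[5], n = length(values))
}
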
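## Lattice geometry extraction: Gaussian filtering, 2D autocorrelation,
## FFT periodicity estimation and monoclinic unit-cell fitting.

#' Gaussian-smooth a topograph
#'
#' Linear Gaussian convolution of the height map with a kernel of standard
#' deviation `sigma` (nm). The kernel is normalized, so the mean height is
#' preserved up to boundary handling (the filter wraps circularly at the
#' image edge, which preserves the mean exactly). `sigma = 0` is the
#' identity.
#'
#' @param topo a [Topograph-class].
#' @param sigma kernel standard deviation in nm (>= 0).
#' @return A smoothed [Topograph-class].
#' @export
gaussianSmooth <- function(topo, sigma) {
  stopifnot(is(topo, "Topograph"))
  if (!is.finite(sigma) || sigma < 0)
    stop("sigma must be a non-negative number")
  if (sigma == 0) return(topo)
  h <- EBImage::gblur(topo@heights, sigma = sigma / topo@pixelSize)
  Topograph(h, topo@pixelSize, topo@timestamp)
}

#' Normalized 2D autocorrelation of a topograph
#'
#' Computes the autocorrelation function (ACF) of the mean-subtracted,
#' Hann-windowed height map by the spectral route (inverse transform of the
#' power spectrum), normalized to 1 at zero lag and shifted so that the zero
#' lag sits at the centre pixel (`floor(n/2) + 1` in each dimension). The
#' ACF of a real image is even: `ACF(-v) = ACF(v)`. Lattice translations of
#' a periodic image appear as local maxima; the Hann window suppresses
#' boundary leakage at the cost of a gentle radial decay of peak values.
#'
#' @param topo a [Topograph-class]; must not be constant (zero variance has
#'   no normalizable ACF).
#' @param window "hann" (default) or "none".
#' @return A [Topograph-class] holding the ACF over the lag domain, same
#'   pixel size; the zero-lag pixel index is attached as attribute
#'   `"centre"` of the heights matrix.
#' @export
autocorrelation <- function(topo, window = c("hann", "none")) {
  stopifnot(is(topo, "Topograph"))
  window <- match.arg(window)
  h <- topo@heights
  if (stats::sd(as.vector(h)) == 0)
    stop("constant image: autocorrelation undefined (zero variance)")
  h <- h - mean(h)
  if (window == "hann") h <- h * hannWindow(nrow(h), ncol(h))
  F <- stats::fft(h)
  P <- Re(F * Conj(F))
  acf <- Re(stats::fft(P, inverse = TRUE)) / length(P)
  acf <- acf / acf[1, 1]
  acf <- fftShift(acf)
  attr(acf, "centre") <- c(floor(nrow(acf) / 2) + 1L,
                           floor(ncol(acf) / 2) + 1L)
  Topograph(acf, topo@pixelSize, topo@timestamp)
}

#' Lag-vector peaks of an autocorrelation image
#'
#' Local maxima (8-neighbourhood) of the ACF away from the zero lag, with
#' sub-pixel refinement by a 3 x 3 value-weighted centroid. Peaks come in
#' +/- pairs because the ACF is even.
#'
#' @param acf ACF [Topograph-class] from [autocorrelation()].
#' @param minValue minimum ACF value for a peak to count as a lattice
#'   translation. The default 0.35 separates true translations (near the
#'   window-decay envelope) from pseudo-translations of the dimer
#'   sublattice, whose correlation is degraded by the inequivalent dimer
#'   footprints.
#' @param maxLag largest lag magnitude considered, nm (default: a quarter
#'   of the shorter image side, where window decay is still mild).
#' @return data.frame with columns `dx`, `dy` (nm) and `value`.
#' @export
acfPeaks <- function(acf, minValue = 0.35, maxLag = NULL) {
  stopifnot(is(acf, "Topograph"))
  m <- acf@heights
  px <- acf@pixelSize
  ctr <- attr(m, "centre")
  if (is.null(ctr)) ctr <- c(floor(nrow(m) / 2) + 1L, floor(ncol(m) / 2) + 1L)
  if (is.null(maxLag)) maxLag <- min(dim(m)) * px / 4
  pk <- localMaxima(m)
  if (nrow(pk) == 0)
    return(data.frame(dx = numeric(), dy = numeric(), value = numeric()))
  dy <- (pk[, 1] - ctr[1]) * px
  dx <- (pk[, 2] - ctr[2]) * px
  val <- m[pk]
  r <- sqrt(dx^2 + dy^2)
  keep <- val >= minValue & r > 2 * px & r <= maxLag
  pk <- pk[keep, , drop = FALSE]
  if (nrow(pk) == 0)
    return(data.frame(dx = numeric(), dy = numeric(), value = numeric()))
  # sub-pixel 3x3 centroid on ACF values (shifted to be locally positive)
  ref <- t(vapply(seq_len(nrow(pk)), function(i) {
    ii <- pk[i, 1] + (-1:1); jj <- pk[i, 2] + (-1:1)
    w <- m[ii, jj]; w <- w - min(w)
    c(sum(ii * rowSums(w)), sum(jj * colSums(w))) / sum(w)
  }, numeric(2)))
  out <- data.frame(dx = (ref[, 2] - ctr[2]) * px,
                    dy = (ref[, 1] - ctr[1]) * px,
                    value = m[pk])
  out[order(-out$value), , drop = FALSE]
}

#' Estimate dominant periodicities by FFT power-spectrum analysis
#'
#' Finds the `nPeaks` strongest non-DC peaks of the 2D power spectrum of
#' the mean-subtracted, Hann-windowed height map and reports each as a
#' spacing `1/|q|` (nm) and a direction (degrees, image frame). Peaks are
#' 8-neighbourhood local maxima that must exceed `threshold` times the
#' median spectral power and a Bonferroni-style noise floor for the
#' exponential null of a featureless (white-noise) spectrum, so a pure
#' noise image returns an empty set. Peak positions are refined to
#' sub-bin precision by a 3 x 3 power-weighted centroid; conjugate pairs
#' are reported once. Adding a constant to all heights does not change the
#' result (the DC term is excluded).
#'
#' @param topo a [Topograph-class].
#' @param nPeaks maximum number of peaks to report.
#' @param threshold multiple of the median spectral power a candidate must
#'   exceed.
#' @param alpha family-wise false-peak rate for the exponential noise floor.
#' @return data.frame with columns `spacing_nm`, `direction_deg`, `power`
#'   (relative units), sorted by decreasing power; zero rows when nothing
#'   rises above the noise floor (with a diagnostic message).
#' @examples
#' xs <- outer(rep(1, 128), (0:127) * 0.5)
#' topo <- Topograph(cos(2 * pi * xs / 6.5), pixelSize = 0.5)
#' estimatePeriodicities(topo, nPeaks = 1)
#' @export
estimatePeriodicities <- function(topo, nPeaks = 5, threshold = 5,
                                  alpha = 0.01) {
  stopifnot(is(topo, "Topograph"), nPeaks >= 1)
  h <- topo@heights
  nr <- nrow(h); nc <- ncol(h)
  px <- topo@pixelSize
  h <- (h - mean(h)) * hannWindow(nr, nc)
  P <- stats::fft(h)
  P <- Re(P * Conj(P))
  P <- fftShift(P)
  ctr <- c(floor(nr / 2) + 1L, floor(nc / 2) + 1L)
  # null level: median power plus a Bonferroni quantile of the exponential
  # fit (power spectra of white noise are exponentially distributed)
  med <- stats::median(P)
  floorPow <- max(threshold * med,
                  med / log(2) * log(nr * nc / alpha))
  pk <- localMaxima(P)
  if (nrow(pk)) {
    fy <- (pk[, 1] - ctr[1]) / (nr * px)
    fx <- (pk[, 2] - ctr[2]) / (nc * px)
    keep <- P[pk] > floorPow &
      (fy > 0 | (abs(fy) < 1e-12 & fx > 0)) &        # one of each +/- pair
      sqrt(fx^2 + fy^2) > 1e-12
    pk <- pk[keep, , drop = FALSE]
  }
  if (nrow(pk) == 0) {
    message("no spectral peak above the noise floor")
    return(data.frame(spacing_nm = numeric(), direction_deg = numeric(),
                      power = numeric()))
  }
  ref <- t(vapply(seq_len(nrow(pk)), function(i) {
    ii <- pk[i, 1] + (-1:1); jj <- pk[i, 2] + (-1:1)
    w <- P[ii, jj]
    c(sum(ii * rowSums(w)), sum(jj * colSums(w))) / sum(w)
  }, numeric(2)))
  fy <- (ref[, 1] - ctr[1]) / (nr * px)
  fx <- (ref[, 2] - ctr[2]) / (nc * px)
  spacing <- 1 / sqrt(fx^2 + fy^2)
  out <- data.frame(spacing_nm = spacing,
                    direction_deg = atan2(fy, fx) * 180 / pi,
                    power = P[pk])
  out <- out[out$spacing_nm > 2 * px, , drop = FALSE]  # Nyquist
  out <- out[order(-out$power), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, nPeaks)
}

# Lagrange (Gauss) reduction of a 2D lattice basis.
lagrangeReduce <- function(v1, v2) {
  repeat {
    if (sum(v2 * v2) < sum(v1 * v1)) { tmp <- v1; v1 <- v2; v2 <- tmp }
    mu <- round(sum(v1 * v2) / sum(v1 * v1))
    v2n <- v2 - mu * v1
    if (sum(v2n * v2n) >= sum(v2 * v2) - 1e-12) break
    v2 <- v2n
  }
  if (sum(v2 * v2) < sum(v1 * v1)) { tmp <- v1; v1 <- v2; v2 <- tmp }
  list(v1 = v1, v2 = v2)
}

#' Fit a primitive 2D unit cell to autocorrelation peaks
#'
#' Selects the two shortest non-collinear lag vectors, Lagrange-reduces
#' them to the unique reduced basis of the lattice they generate, and
#' reports cell parameters in the convention `a >= b` with gamma given by
#' its obtuse representative in (90, 180] when one exists (negating b flips
#' gamma to 180 - gamma without changing the lattice). The orientation is
#' the angle of vector a in the image frame.
#'
#' Pseudo-translations of the repeat-unit sublattice (e.g. the dimer pitch
#' a/3 along a stripe of three similar but inequivalent dimers) also
#' produce ACF maxima, at degraded correlation. They are removed by an
#' envelope-monotonicity filter: the ACF value of true lattice translations
#' decays monotonically with lag radius (window decay), so any candidate
#' whose value falls below `envelopeFactor` times the best value found at
#' an equal or larger radius cannot be a lattice translation and is
#' dropped.
#'
#' @param peaks either a data.frame of lag vectors with columns `dx`, `dy`
#'   (nm), e.g. from [acfPeaks()], or a [Topograph-class], in which case
#'   [autocorrelation()] and [acfPeaks()] are run first.
#' @param collinearTol angular tolerance (degrees) below which two vectors
#'   count as collinear.
#' @param envelopeFactor envelope-monotonicity factor in (0, 1]; applied
#'   only when the peak table carries ACF values.
#' @param ... passed on to [acfPeaks()] when `peaks` is a Topograph.
#' @return A [Lattice2D-class].
#' @examples
#' pk <- data.frame(dx = c(10.8, -1.146), dy = c(0, 6.5))
#' fitUnitCell(pk)
#' @export
fitUnitCell <- function(peaks, collinearTol = 5, envelopeFactor = 0.8,
                        ...) {
  if (is(peaks, "Topograph")) {
    acf <- if (is.null(attr(peaks@heights, "centre")))
      autocorrelation(peaks) else peaks
    peaks <- acfPeaks(acf, ...)
  }
  stopifnot(is.data.frame(peaks), all(c("dx", "dy") %in% names(peaks)))
  if ("value" %in% names(peaks) && nrow(peaks) > 1) {
    r <- sqrt(peaks$dx^2 + peaks$dy^2)
    ord <- order(r, decreasing = TRUE)
    runMax <- cummax(peaks$value[ord])[order(ord)]  # best value at r >= r_i
    peaks <- peaks[peaks$value >= envelopeFactor * runMax, , drop = FALSE]
  }
  V <- as.matrix(peaks[, c("dx", "dy")])
  V <- V[sqrt(rowSums(V^2)) > 1e-9, , drop = FALSE]
  if (nrow(V) < 2)
    stop("need at least two non-collinear lag vectors")
  ord <- order(rowSums(V^2))
  V <- V[ord, , drop = FALSE]
  v1 <- V[1, ]
  sinTol <- sin(degToRad(collinearTol))
  v2 <- NULL
  for (i in 2:nrow(V)) {
    cr <- abs(v1[1] * V[i, 2] - v1[2] * V[i, 1]) /
      (sqrt(sum(v1^2)) * sqrt(sum(V[i, ]^2)))
    if (cr > sinTol) { v2 <- V[i, ]; break }
  }
  if (is.null(v2))
    stop("all lag peaks are collinear: degenerate lattice")
  red <- lagrangeReduce(v1, v2)
  # a is the longer reduced vector
  a <- red$v2; b <- red$v1
  gamma <- acos(sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))) * 180 / pi
  if (gamma < 90 - 1e-9) { b <- -b; gamma <- 180 - gamma }
  Lattice2D(aLen = sqrt(sum(a^2)), bLen = sqrt(sum(b^2)), gamma = gamma,
            orientation = atan2(a[2], a[1]) * 180 / pi)
}

#' Crop a topograph to a rectangular region of interest
#'
#' Lattice fitting assumes the analyzed image is dominated by one
#' crystalline domain; on partially covered frames, crop to the crystal
#' region first. Coordinates are physical (nm) and inclusive; the crop
#' snaps to pixel boundaries.
#'
#' @param topo a [Topograph-class].
#' @param xlim,ylim numeric(2) region bounds in nm.
#' @return A [Topograph-class] over the cropped grid.
#' @export
cropTopograph <- function(topo, xlim, ylim) {
  stopifnot(is(topo, "Topograph"), length(xlim) == 2L, length(ylim) == 2L)
  px <- topo@pixelSize
  h <- topo@heights
  jj <- max(1L, floor(xlim[1] / px) + 1L):min(ncol(h), ceiling(xlim[2] / px) + 1L)
  ii <- max(1L, floor(ylim[1] / px) + 1L):min(nrow(h), ceiling(ylim[2] / px) + 1L)
  if (length(jj) < 4L || length(ii) < 4L) stop("crop region too small")
  Topograph(h[ii, jj, drop = FALSE], px, topo@timestamp)
}
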
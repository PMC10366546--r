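## Internal numerical helpers shared across modules.

# Run expr with a locally seeded RNG, restoring the caller's stream.
withLocalSeed <- function(seed, expr) {
  if (is.na(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Bilinear interpolation of a height matrix at physical points (nm).
# x rightward along columns, y downward along rows, pixel centres at
# (col-1)*px, (row-1)*px. Points must lie inside the pixel-centre hull.
bilinearSample <- function(h, px, x, y) {
  fj <- x / px + 1  # fractional column
  fi <- y / px + 1  # fractional row
  nr <- nrow(h); nc <- ncol(h)
  eps <- 1e-9
  if (any(fj < 1 - eps | fj > nc + eps | fi < 1 - eps | fi > nr + eps))
    stop("sampling point outside the image")
  fj <- pmin(pmax(fj, 1), nc)
  fi <- pmin(pmax(fi, 1), nr)
  j0 <- pmin(floor(fj), nc - 1L); i0 <- pmin(floor(fi), nr - 1L)
  tx <- fj - j0; ty <- fi - i0
  h[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
    h[cbind(i0, j0 + 1)] * tx * (1 - ty) +
    h[cbind(i0 + 1, j0)] * (1 - tx) * ty +
    h[cbind(i0 + 1, j0 + 1)] * tx * ty
}

# Centre the zero-frequency / zero-lag bin of an FFT-ordered matrix at
# index floor(n/2) + 1 in each dimension (for odd sizes the split must be
# at ceiling(n/2), or the centre lands one pixel off).
fftShift <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  sr <- ceiling(nr / 2); sc <- ceiling(nc / 2)
  m[c((sr + 1):nr, seq_len(sr)), c((sc + 1):nc, seq_len(sc)), drop = FALSE]
}

# Separable 2D Hann window.
hannWindow <- function(nr, nc) {
  wr <- 0.5 - 0.5 * cos(2 * pi * seq(0, nr - 1) / (nr - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * seq(0, nc - 1) / (nc - 1))
  outer(wr, wc)
}

# 8-neighbourhood local maxima of a matrix, excluding the 1-px border.
# Returns a two-column index matrix (row, col).
localMaxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  ctr <- m[ri, ci]
  isMax <- ctr > m[ri - 1, ci] & ctr > m[ri + 1, ci] &
    ctr > m[ri, ci - 1] & ctr > m[ri, ci + 1] &
    ctr > m[ri - 1, ci - 1] & ctr > m[ri - 1, ci + 1] &
    ctr > m[ri + 1, ci - 1] & ctr > m[ri + 1, ci + 1]
  which(isMax, arr.ind = TRUE) + 1L
}

# Rasterize a membrane mask onto the pixel grid of a scan.
maskRaster <- function(mask, shape, px) {
  nr <- shape[1]; nc <- shape[2]
  xs <- (seq_len(nc) - 1) * px
  ys <- (seq_len(nr) - 1) * px
  switch(mask$shape,
    full = matrix(TRUE, nr, nc),
    disc = {
      dx <- outer(rep(1, nr), xs - mask$centre[1])
      dy <- outer(ys - mask$centre[2], rep(1, nc))
      dx * dx + dy * dy <= mask$radius^2
    },
    rect = {
      inx <- xs >= mask$xmin & xs <= mask$xmax
      iny <- ys >= mask$ymin & ys <= mask$ymax
      outer(iny, inx)
    },
    stop("unknown mask shape: ", mask$shape))
}

# Is a physical point (nm) inside the membrane mask?
pointInMask <- function(mask, x, y) {
  switch(mask$shape,
    full = rep(TRUE, length(x)),
    disc = (x - mask$centre[1])^2 + (y - mask$centre[2])^2 <= mask$radius^2,
    rect = x >= mask$xmin & x <= mask$xmax & y >= mask$ymin & y <= mask$ymax,
    stop("unknown mask shape: ", mask$shape))
}

# Signed distance (nm) from a point to the mask boundary; positive inside.
maskBoundaryDistance <- function(mask, x, y) {
  switch(mask$shape,
    full = rep(Inf, length(x)),
    disc = mask$radius - sqrt((x - mask$centre[1])^2 + (y - mask$centre[2])^2),
    rect = pmin(x - mask$xmin, mask$xmax - x, y - mask$ymin, mask$ymax - y),
    stop("unknown mask shape: ", mask$shape))
}

degToRad <- function(d) d * pi / 180
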
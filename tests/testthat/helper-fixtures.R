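# Shared fixtures, memoized so expensive renders happen once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

paperCell <- function(orientation = 0, origin = c(60, 60)) {
  Lattice2D(10.8, 6.6, 100, orientation = orientation, origin = origin)
}

fullLayers <- function() LayerModel(membraneMask = list(shape = "full"))

# Occupancy covering the whole frame with stripes on every lattice row.
fullOccupancy <- function(rows = -30:30, slots = c(-45L, 45L)) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(id = r - min(rows) + 1L, row = r,
               slotMin = slots[1], slotMax = slots[2])))
}

cleanScan <- function(shape = c(256L, 256L)) {
  ScanParams(pixelSize = 0.5, imageShape = shape,
             tipBlurSigma = 0, noiseSigma = 0)
}

# Full-frame crystal render, optionally with default blur/noise.
fullCrystal <- function(orientation = 0, noisy = FALSE, seed = 3L) {
  memo(paste("crystal", orientation, noisy, seed), {
    scan <- if (noisy) ScanParams(seed = seed) else cleanScan()
    renderTopograph(fullOccupancy(), RepeatUnitTemplate(), fullLayers(),
                    paperCell(orientation), scan)
  })
}

# Short movie with ground truth (demo config, optionally noise-free).
demoMovie <- function(nFrames = 10L, seed = 5L, clean = FALSE) {
  memo(paste("movie", nFrames, seed, clean), {
    cfg <- demoConfig(nFrames = nFrames, seed = seed)
    if (clean) cfg$scan <- cleanScan()
    generateMovie(cfg)
  })
}

# Per-frame totals of logged/measured event lengths.
eventTotals <- function(df, frameCol, events, frames) {
  x <- df[df$event %in% events, , drop = FALSE]
  v <- tapply(x$length_nm, factor(x[[frameCol]], levels = frames), sum)
  v[is.na(v)] <- 0
  as.numeric(v)
}

# Small toy protein: an 8-atom chain with reproducible coordinates.
toyStructure <- function(n = 8, seed = 2) {
  set.seed(seed)
  AtomicStructure(data.frame(
    elety = "CA", resid = "GLY", resno = seq_len(n), chain = "A",
    x = rnorm(n), y = rnorm(n), z = rnorm(n), element = "C",
    stringsAsFactors = FALSE))
}

rotateStructure <- function(s, w, shift = c(0, 0, 0)) {
  th <- sqrt(sum(w^2))
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3,
              byrow = TRUE) / max(th, 1e-300)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  a <- atoms(s)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  AtomicStructure(a)
}

# Independent rigid-superposition oracle: best RMSD over a random
# quaternion grid refined by general-purpose optimization (no SVD).
bruteForceRmsd <- function(ref, mobile, selection = "CA", nGrid = 2000) {
  P <- as.matrix(atoms(mobile)[atoms(mobile)$elety %in% selection,
                               c("x", "y", "z")])
  Q <- as.matrix(atoms(ref)[atoms(ref)$elety %in% selection,
                            c("x", "y", "z")])
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(w) {
    th <- sqrt(sum(w^2))
    if (th < 1e-12) return(diag(3))
    K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3,
                byrow = TRUE) / th
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  f <- function(w) sqrt(mean(rowSums((Pc %*% t(rot(w)) - Qc)^2)))
  set.seed(99)
  ws <- matrix(rnorm(3 * nGrid), ncol = 3)
  ws <- ws / sqrt(rowSums(ws^2)) * runif(nGrid, 0, pi)
  vals <- apply(ws, 1, f)
  best <- ws[which.min(vals), ]
  opt <- stats::optim(best, f, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  opt$value
}

# Exhaustive dilation oracle: per-pixel max search over the tip support.
bruteForceDilation <- function(h, px, tip) {
  nr <- nrow(h); nc <- ncol(h)
  rng <- max(h) - min(h)
  th <- tip@halfAngle * pi / 180
  rc <- tip@radius * cos(th)
  rmax <- if (rng <= tip@radius * (1 - sin(th)))
    sqrt(max(tip@radius^2 - (tip@radius - rng)^2, 0))
  else rc + (rng - tip@radius * (1 - sin(th))) * tan(th)
  k <- ceiling(rmax / px)
  out <- h
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    best <- h[i, j]
    for (di in max(1, i - k):min(nr, i + k)) {
      for (dj in max(1, j - k):min(nc, j + k)) {
        r <- sqrt((di - i)^2 + (dj - j)^2) * px
        if (r > rmax) next
        tv <- if (r <= rc) tip@radius - sqrt(tip@radius^2 - r^2) else
          tip@radius - tip@radius * sin(th) + (r - rc) / tan(th)
        cand <- h[di, dj] - tv
        if (cand > best) best <- cand
      }
    }
    out[i, j] <- best
  }
  out
}

# Minimal PDB text fixtures written on the fly.
writeMiniPdb <- function(lines, file = tempfile(fileext = ".pdb")) {
  writeLines(lines, file)
  file
}

pdbAtomLine <- function(serial, name, resn, chain, resno, x, y, z,
                        occ = 1, element = substr(name, 1, 1),
                        alt = " ") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resn, chain, resno, x, y, z, occ, 0, element)
}
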
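## PDB-based operations: superposition RMSD, vertical extent, 2D-crystal
## tiling, pseudo-AFM rendering by tip-shape dilation, and depth contours.

# Bondi van der Waals radii (Angstrom); fixed in-repo for bit-stable
# rasterization. Unlisted elements fall back to 1.7 (carbon).
.bondiRadii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 P = 1.80, S = 1.80, CL = 1.75, BR = 1.85, I = 1.98,
                 SE = 1.90, ZN = 1.39, MG = 1.73, NA. = 2.27, K = 2.75,
                 CA = 2.31, FE = 2.00)

backboneNames <- c("N", "CA", "C", "O")

#' Read an atomic structure from a PDB file
#'
#' Parses a PDB file (via bio3d) into an [AtomicStructure-class]. Alternate
#' locations are resolved to one atom per (chain, residue, atom name) by
#' the highest occupancy, first record on ties. ATOM and HETATM records are
#' kept; waters are dropped. Malformed coordinate records abort with the
#' offending line number.
#'
#' @param file path to a PDB file.
#' @return An [AtomicStructure-class].
#' @export
readStructure <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  lines <- readLines(file, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", file)
  bad <- which(rec & (nchar(lines) < 54 |
    is.na(suppressWarnings(as.numeric(substr(lines, 31, 38)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 39, 46)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 47, 54))))))
  if (length(bad))
    stop("malformed coordinate record at line ", bad[1], " of ", file)
  pdb <- bio3d::read.pdb(file, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$resid != "HOH", , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms left after filtering in ", file)
  # altloc policy: highest occupancy, first on tie
  a$occ <- ifelse(is.na(a$o), 1, a$o)
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  ord <- order(key, -a$occ, seq_len(nrow(a)))
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(key[ord]), , drop = FALSE]
  a <- a[order(a$eleno), , drop = FALSE]
  el <- toupper(trimws(a$elesy))
  el[is.na(el) | el == ""] <- substr(trimws(a$elety[is.na(el) | el == ""]),
                                     1, 1)
  AtomicStructure(data.frame(
    eleno = a$eleno, elety = trimws(a$elety), resid = a$resid,
    resno = a$resno, chain = as.character(a$chain), x = a$x, y = a$y,
    z = a$z, occ = a$occ, element = el, stringsAsFactors = FALSE))
}

# Atom selection helper: "backbone", "CA", "all" or explicit atom names.
selectAtoms <- function(s, selection) {
  a <- atoms(s)
  names <- switch(selection[1],
                  backbone = backboneNames,
                  CA = "CA",
                  all = unique(a$elety),
                  selection)
  a[a$elety %in% names, , drop = FALSE]
}

#' Optimal rigid superposition (Kabsch) and RMSD
#'
#' Pairs atoms of the two structures one-to-one by residue number and atom
#' name (within the selected atom set and optional chains), computes the
#' least-squares optimal rotation/translation of `mobile` onto `ref` with
#' a proper rotation enforced (det = +1), and returns the RMSD over the
#' paired atoms in Angstroms.
#'
#' @param ref,mobile [AtomicStructure-class] objects.
#' @param selection "backbone" (N, CA, C, O; default), "CA", "all", or a
#'   character vector of atom names.
#' @param chainRef,chainMobile optional chain ids restricting each side.
#' @param strict error when the two selections do not correspond 1:1
#'   (default); with `strict = FALSE` the common atoms are used and the
#'   unmatched ones reported in the result (useful for homologues with
#'   unresolved termini).
#' @return list with `rmsd` (Angstrom), `rotation` (3 x 3), `translation`
#'   (applied after rotation), `n` atoms paired, `unmatched` keys.
#' @examples
#' rod <- AtomicStructure(data.frame(elety = "CA", resid = "GLY",
#'   resno = 1:5, chain = "A", x = 0, y = 0, z = seq(0, 12, 3),
#'   element = "C"))
#' kabschRmsd(rod, rod, selection = "CA")$rmsd
#' @export
kabschRmsd <- function(ref, mobile, selection = "backbone",
                       chainRef = NULL, chainMobile = NULL,
                       strict = TRUE) {
  ar <- selectAtoms(ref, selection)
  am <- selectAtoms(mobile, selection)
  if (!is.null(chainRef)) ar <- ar[ar$chain %in% chainRef, , drop = FALSE]
  if (!is.null(chainMobile))
    am <- am[am$chain %in% chainMobile, , drop = FALSE]
  keyR <- paste(ar$resno, ar$elety)
  keyM <- paste(am$resno, am$elety)
  common <- intersect(keyR, keyM)
  missing <- c(setdiff(keyR, keyM), setdiff(keyM, keyR))
  if ((strict && length(missing)) || length(common) < 3)
    stop("atom correspondence failure; unmatched: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ...")
  ar <- ar[match(common, keyR), , drop = FALSE]
  am <- am[match(common, keyM), , drop = FALSE]
  P <- as.matrix(am[, c("x", "y", "z")])   # mobile
  Q <- as.matrix(ar[, c("x", "y", "z")])   # reference
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Pr <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pr - Qc)^2)))
  list(rmsd = rmsd, rotation = R, translation = cq - as.vector(R %*% cp),
       n = nrow(P), unmatched = missing)
}

#' Vertical extent of a structure's backbone along an axis
#'
#' Extent (max minus min projection, converted to nm) of the backbone atoms
#' along a given axis, after excluding a number of flexible N- and
#' C-terminal residues per chain. With the axis set to the membrane normal
#' this is the height the molecule presents to an AFM tip.
#'
#' @param s an [AtomicStructure-class].
#' @param axis numeric(3) direction (need not be normalized), or
#'   "principal" for the longest principal axis of the selected atoms.
#' @param excludeNTerm,excludeCTerm number of residues dropped from each
#'   chain terminus.
#' @param chain optional chain id(s) restricting the selection.
#' @param selection atom selection as in [kabschRmsd()].
#' @return extent in nm.
#' @export
verticalExtent <- function(s, axis = c(0, 0, 1), excludeNTerm = 0,
                           excludeCTerm = 0, chain = NULL,
                           selection = "backbone") {
  a <- selectAtoms(s, selection)
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms selected")
  keep <- unlist(lapply(split(seq_len(nrow(a)), a$chain), function(idx) {
    res <- sort(unique(a$resno[idx]))
    if (excludeNTerm + excludeCTerm >= length(res)) return(integer())
    ok <- res[seq(excludeNTerm + 1, length(res) - excludeCTerm)]
    idx[a$resno[idx] %in% ok]
  }))
  if (!length(keep)) stop("all residues excluded")
  a <- a[keep, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (identical(axis, "principal")) {
    pc <- stats::prcomp(xyz)
    axis <- pc$rotation[, 1]
  }
  axis <- axis / sqrt(sum(axis^2))
  proj <- xyz %*% axis
  (max(proj) - min(proj)) / 10
}

#' Tile a repeat unit into an m x n 2D crystal
#'
#' Places m x n translated copies of the unit on the lattice (copy (i, j)
#' shifted by i*a + j*b, lattice vectors in the xy-plane, nm converted to
#' Angstrom) and relabels chains uniquely. With a single copy the unit is
#' returned unchanged; otherwise chain ids gain a numeric copy suffix
#' (`A.0`, `A.1`, ...), sidestepping the one-letter PDB namespace.
#'
#' @param unit an [AtomicStructure-class].
#' @param lattice a [Lattice2D-class] (nm).
#' @param m,n copies along a and b (>= 1).
#' @return An [AtomicStructure-class] with `m * n *` (unit atom count)
#'   atoms.
#' @export
tileCrystal <- function(unit, lattice, m, n) {
  stopifnot(is(unit, "AtomicStructure"), is(lattice, "Lattice2D"),
            m >= 1, n >= 1)
  if (m == 1 && n == 1) return(unit)
  v <- latticeVectors(lattice) * 10   # nm -> Angstrom
  a <- atoms(unit)
  copies <- vector("list", m * n)
  k <- 0L
  for (i in 0:(m - 1)) for (j in 0:(n - 1)) {
    k <- k + 1L
    ci <- a
    ci$x <- a$x + i * v["a", 1] + j * v["b", 1]
    ci$y <- a$y + i * v["a", 2] + j * v["b", 2]
    ci$chain <- paste0(a$chain, ".", k - 1L)
    copies[[k]] <- ci
  }
  out <- do.call(rbind, copies)
  out$eleno <- seq_len(nrow(out))
  AtomicStructure(out)
}

# Sphere-capped cone tip profile (nm): drop of the tip surface at radial
# distance r from the apex. Tangent-continuous at r = R cos(theta).
tipProfile <- function(r, radius, halfAngleDeg) {
  th <- degToRad(halfAngleDeg)
  rc <- radius * cos(th)
  ifelse(r <= rc,
         radius - sqrt(pmax(radius^2 - r^2, 0)),
         radius - radius * sin(th) + (r - rc) / tan(th))
}

#' Rasterize an atomic structure to a hard-sphere upper envelope
#'
#' Height map (nm) of the upper envelope of atoms modelled as van der
#' Waals spheres (Bondi radii), sampled on a raster of pitch `step`.
#' Heights are measured from the lowest point of the envelope; raster
#' cells not covered by any atom sit at 0, emulating a supporting plane.
#'
#' @param s an [AtomicStructure-class].
#' @param step raster pitch in nm.
#' @param pad margin around the structure, nm.
#' @return A [Topograph-class].
#' @export
rasterizeStructure <- function(s, step = 0.25, pad = 1) {
  a <- atoms(s)
  if (nrow(a) == 0) stop("empty structure")
  rad <- .bondiRadii[a$element]
  rad[is.na(rad)] <- 1.7
  x <- a$x / 10; y <- a$y / 10; z <- a$z / 10; r <- rad / 10
  x0 <- min(x - r) - pad; y0 <- min(y - r) - pad
  nc <- ceiling((max(x + r) + pad - x0) / step) + 1
  nr <- ceiling((max(y + r) + pad - y0) / step) + 1
  zbase <- min(z - r)
  h <- matrix(0, nr, nc)
  for (k in seq_len(nrow(a))) {
    jj <- max(1, floor((x[k] - r[k] - x0) / step) + 1):
      min(nc, ceiling((x[k] + r[k] - x0) / step) + 1)
    ii <- max(1, floor((y[k] - r[k] - y0) / step) + 1):
      min(nr, ceiling((y[k] + r[k] - y0) / step) + 1)
    dx <- (jj - 1) * step + x0 - x[k]
    dy <- (ii - 1) * step + y0 - y[k]
    d2 <- outer(dy^2, dx^2, `+`)
    cap <- d2 <= r[k]^2
    if (!any(cap)) next
    ztop <- z[k] + sqrt(pmax(r[k]^2 - d2, 0)) - zbase
    blk <- h[ii, jj, drop = FALSE]
    blk[cap] <- pmax(blk[cap], ztop[cap])
    h[ii, jj] <- blk
  }
  Topograph(h, step)
}

#' Pseudo-AFM image by grayscale dilation with a tip shape
#'
#' Simulates the topograph an AFM tip of the given sphere-capped-cone
#' shape would record over a rigid surface:
#' `out(x) = max_u (surface(u) - tip(u - x))`, the grayscale dilation of
#' the surface by the inverted tip. Atomic structures are first rasterized
#' to their hard-sphere upper envelope at the tip's scan step. The
#' operation is extensive (`out >= surface`), monotone in the surface, and
#' reduces to the identity for a point tip (R = 0).
#'
#' @param source an [AtomicStructure-class] or [Topograph-class].
#' @param tip a [TipModel-class].
#' @return A [Topograph-class] on the same raster.
#' @examples
#' topo <- Topograph(matrix(0, 32, 32), pixelSize = 0.25)
#' img <- pseudoAFM(topo, TipModel())
#' @export
pseudoAFM <- function(source, tip) {
  stopifnot(is(tip, "TipModel"))
  topo <- if (is(source, "AtomicStructure"))
    rasterizeStructure(source, step = tip@scanStep) else source
  stopifnot(is(topo, "Topograph"))
  h <- topo@heights
  if (length(h) == 0) stop("empty source")
  px <- topo@pixelSize
  rng <- max(h) - min(h)
  # tip support: offsets where the tip drop still matters
  th <- degToRad(tip@halfAngle)
  rc <- tip@radius * cos(th)
  rmax <- if (rng <= tip@radius - tip@radius * sin(th))
    sqrt(pmax(tip@radius^2 - (tip@radius - rng)^2, 0))
  else rc + (rng - tip@radius * (1 - sin(th))) * tan(th)
  kmax <- ceiling(rmax / px)
  out <- h
  nr <- nrow(h); nc <- ncol(h)
  if (kmax > 0) for (di in -kmax:kmax) for (dj in -kmax:kmax) {
    if (di == 0 && dj == 0) next
    r <- sqrt(di^2 + dj^2) * px
    if (r > rmax + 1e-12) next
    tv <- tipProfile(r, tip@radius, tip@halfAngle)
    # out[i,j] vs h[i+di, j+dj] - tv over the valid index overlap
    i1 <- max(1, 1 - di):min(nr, nr - di)
    j1 <- max(1, 1 - dj):min(nc, nc - dj)
    out[i1, j1] <- pmax(out[i1, j1], h[i1 + di, j1 + dj, drop = FALSE] - tv)
  }
  Topograph(out, px, topo@timestamp)
}

#' Iso-height contours at depths below the surface top
#'
#' Level-set polylines of the topograph at heights `top - depth` for each
#' requested depth, the numerical counterpart of relief contour maps of a
#' protein surface. The top is the global maximum (optionally after an
#' exclusion mask). Depths below the global minimum yield an empty contour
#' list at that level, flagged in the result.
#'
#' @param topo a non-constant [Topograph-class].
#' @param depths depths below the top, nm, positive increasing
#'   (e.g. `c(0.5, 1, 2, 3)`).
#' @param exclude optional logical matrix; TRUE pixels are ignored when
#'   locating the top.
#' @return A [ContourSet-class]; unreachable depths carry attribute
#'   `"unreachable"`.
#' @export
depthContours <- function(topo, depths = c(0.5, 1, 2, 3), exclude = NULL) {
  stopifnot(is(topo, "Topograph"))
  h <- topo@heights
  if (max(h) == min(h)) stop("constant topograph has no contours")
  depths <- sort(depths)
  hTop <- if (is.null(exclude)) max(h) else max(h[!exclude])
  px <- topo@pixelSize
  ys <- (seq_len(nrow(h)) - 1) * px
  xs <- (seq_len(ncol(h)) - 1) * px
  unreachable <- numeric()
  contours <- lapply(depths, function(d) {
    lev <- hTop - d
    if (lev < min(h)) {
      unreachable <<- c(unreachable, d)
      return(list())
    }
    cl <- grDevices::contourLines(x = ys, y = xs, z = h, levels = lev)
    lapply(cl, function(p) data.frame(x = p$y, y = p$x))
  })
  out <- new("ContourSet", depths = depths, levels = hTop - depths,
             contours = contours)
  if (length(unreachable)) attr(out, "unreachable") <- unreachable
  out
}
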